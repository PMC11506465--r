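# independent oracles and small fixtures used across tests

# naive loop-based forward pass, kept independent of mlp_forward
naive_forward <- function(params, x) {
  sig <- function(z) 1 / (1 + exp(-z))
  n <- nrow(x)
  out <- matrix(0, n, length(params$b2))
  for (r in seq_len(n)) {
    h <- numeric(length(params$b1))
    for (j in seq_along(h)) {
      acc <- params$b1[j]
      for (i in seq_len(ncol(x))) acc <- acc + x[r, i] * params$W1[i, j]
      h[j] <- sig(acc)
    }
    for (k in seq_along(params$b2)) {
      acc <- params$b2[k]
      for (j in seq_along(h)) acc <- acc + h[j] * params$W2[j, k]
      out[r, k] <- sig(acc)
    }
  }
  out
}

naive_euclid <- function(a, b) {
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  sqrt(acc)
}

# three well-separated Gaussian clusters in 2-D with grades 1..3
make_three_blobs <- function(n_per = 10, sep = 6, sd = 0.3, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  x <- do.call(rbind, lapply(1:3, function(k)
    cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))))
  list(x = x, y = rep(1:3, each = n_per))
}

random_params <- function(spec, seed = 1, range = 1) {
  set.seed(seed)
  list(W1 = matrix(runif(spec$n_input * spec$n_hidden, -range, range),
                   spec$n_input, spec$n_hidden),
       b1 = runif(spec$n_hidden, -range, range),
       W2 = matrix(runif(spec$n_hidden * spec$n_output, -range, range),
                   spec$n_hidden, spec$n_output),
       b2 = runif(spec$n_output, -range, range))
}
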