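#' Backpropagation settings
#'
#' Controls full-batch backpropagation on the mean (per-sample) squared
#' error between sigmoid outputs and one-hot targets. Training uses
#' classical momentum and, by default, an adaptive learning rate in the
#' gradient-descent-with-momentum-and-adaptive-rate tradition: after each
#' epoch the step is kept and the rate multiplied by `lr_increase` if the
#' loss did not grow by more than `max_perf_inc`, otherwise the step is
#' rejected, the velocity reset and the rate multiplied by `lr_decrease`.
#' Set `adaptive = FALSE` for plain fixed-rate descent.
#'
#' @param learning_rate Initial step size, positive.
#' @param epochs Number of full-batch epochs; 0 returns the initial
#'   parameters unchanged.
#' @param momentum Momentum coefficient in \code{[0, 1)}; 0 gives plain
#'   gradient descent.
#' @param adaptive Adapt the learning rate per epoch (default).
#' @param lr_increase,lr_decrease Multiplicative rate update on an
#'   accepted / rejected epoch.
#' @param max_perf_inc Largest tolerated loss ratio for accepting an epoch.
#' @return A list of class `"bp_control"`.
#' @export
bp_control <- function(learning_rate = 0.01, epochs = 2000, momentum = 0.9,
                       adaptive = TRUE, lr_increase = 1.05,
                       lr_decrease = 0.7, max_perf_inc = 1.04) {
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop("'learning_rate' must be positive", call. = FALSE)
  if (epochs < 0 || epochs != round(epochs))
    stop("'epochs' must be a nonnegative integer", call. = FALSE)
  if (momentum < 0 || momentum >= 1)
    stop("'momentum' must be in [0, 1)", call. = FALSE)
  if (lr_increase < 1 || lr_decrease <= 0 || lr_decrease > 1 ||
      max_perf_inc < 1)
    stop("invalid learning-rate adaptation settings", call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 momentum = momentum, adaptive = isTRUE(adaptive),
                 lr_increase = lr_increase, lr_decrease = lr_decrease,
                 max_perf_inc = max_perf_inc),
            class = "bp_control")
}

#' Train the network by backpropagation
#'
#' Full-batch backpropagation from the supplied initial parameters
#' (typically the decoded best chromosome of [ga_evolve()]). The loss is
#' the mean over samples of the summed squared output error; it is
#' recorded before training and after every epoch, so the returned trace
#' has `epochs + 1` entries. With the default adaptive learning rate an
#' epoch that would grow the loss beyond `max_perf_inc` is rolled back, so
#' the final loss never exceeds the initial loss.
#'
#' @param params Initial parameter list (see [decode_params()]).
#' @param x Training feature matrix; `y` integer grades.
#' @param y Integer grades in `1..spec$n_output`.
#' @param spec A [network_spec()].
#' @param control A [bp_control()].
#' @return List: `params` (trained), `loss` (numeric vector of length
#'   `epochs + 1`).
#' @export
train_bp <- function(params, x, y, spec, control = bp_control()) {
  stopifnot(inherits(spec, "mlp_spec"), inherits(control, "bp_control"))
  x <- as_numeric_matrix(x, min_rows = 1)
  check_param_shapes(params, spec)
  target <- one_hot(y, spec$n_output)
  n <- nrow(x)
  lr <- control$learning_rate; mom <- control$momentum
  v <- list(W1 = params$W1 * 0, b1 = params$b1 * 0,
            W2 = params$W2 * 0, b2 = params$b2 * 0)
  fwd <- mlp_forward(params, x, hidden = TRUE)
  loss <- mean(rowSums((fwd$O - target)^2))
  trace <- loss
  for (epoch in seq_len(control$epochs)) {
    d_out <- 2 * (fwd$O - target) / n * fwd$O * (1 - fwd$O)
    d_hid <- (d_out %*% t(params$W2)) * fwd$H * (1 - fwd$H)
    v$W2 <- mom * v$W2 - lr * crossprod(fwd$H, d_out)
    v$b2 <- mom * v$b2 - lr * colSums(d_out)
    v$W1 <- mom * v$W1 - lr * crossprod(x, d_hid)
    v$b1 <- mom * v$b1 - lr * colSums(d_hid)
    cand <- list(W1 = params$W1 + v$W1, b1 = params$b1 + v$b1,
                 W2 = params$W2 + v$W2, b2 = params$b2 + v$b2)
    cand_fwd <- mlp_forward(cand, x, hidden = TRUE)
    cand_loss <- mean(rowSums((cand_fwd$O - target)^2))
    if (control$adaptive && cand_loss > loss * control$max_perf_inc) {
      # reject the epoch: keep parameters, damp the rate, reset momentum
      lr <- lr * control$lr_decrease
      v <- lapply(v, function(q) q * 0)
    } else {
      params <- cand; fwd <- cand_fwd; loss <- cand_loss
      if (control$adaptive) lr <- lr * control$lr_increase
    }
    trace <- c(trace, loss)
  }
  list(params = params, loss = trace)
}
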