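#' Feed-forward network architecture
#'
#' Describes the single-hidden-layer perceptron used for freshness grading:
#' `n_input` features (3 after PCA), `n_hidden` sigmoid units and
#' `n_output` sigmoid output units (3 grades, one-hot targets). The number
#' of free parameters — and so the genetic-algorithm chromosome length —
#' is `n_input*n_hidden + n_hidden + n_hidden*n_output + n_output`.
#'
#' @param n_input,n_hidden,n_output Layer sizes, each at least 1.
#' @return Object of class `"mlp_spec"` with a `n_params` element.
#' @examples
#' network_spec(3, 10, 3)$n_params
#' @export
network_spec <- function(n_input = 3, n_hidden = 10, n_output = 3) {
  sizes <- c(n_input = n_input, n_hidden = n_hidden, n_output = n_output)
  if (any(sizes < 1) || any(sizes != round(sizes)))
    stop("all layer sizes must be positive integers", call. = FALSE)
  structure(list(n_input = as.integer(n_input),
                 n_hidden = as.integer(n_hidden),
                 n_output = as.integer(n_output),
                 n_params = as.integer(n_input * n_hidden + n_hidden +
                                       n_hidden * n_output + n_output)),
            class = "mlp_spec")
}

#' Flatten network parameters to a chromosome and back
#'
#' The genetic algorithm searches a flat real vector holding every weight
#' and bias. The layout is fixed: input-to-hidden weights row-major (one
#' input's fan-out at a time), hidden biases, hidden-to-output weights
#' row-major, output biases. `decode_params(encode_params(...))` is an
#' exact inverse.
#'
#' @param params List with `W1` (`n_input x n_hidden`), `b1`, `W2`
#'   (`n_hidden x n_output`), `b2`.
#' @param genes Numeric vector of length `spec$n_params`.
#' @param spec A [network_spec()].
#' @return `encode_params()`: numeric vector; `decode_params()`: the
#'   parameter list.
#' @export
encode_params <- function(params, spec) {
  check_param_shapes(params, spec)
  c(as.vector(t(params$W1)), params$b1,
    as.vector(t(params$W2)), params$b2)
}

#' @rdname encode_params
#' @export
decode_params <- function(genes, spec) {
  stopifnot(inherits(spec, "mlp_spec"))
  if (length(genes) != spec$n_params)
    stop(sprintf("chromosome length %d does not match spec (%d parameters)",
                 length(genes), spec$n_params), call. = FALSE)
  ni <- spec$n_input; nh <- spec$n_hidden; no <- spec$n_output
  i <- 0L
  take <- function(m) { out <- genes[(i + 1L):(i + m)]; i <<- i + m; out }
  list(W1 = matrix(take(ni * nh), ni, nh, byrow = TRUE),
       b1 = take(nh),
       W2 = matrix(take(nh * no), nh, no, byrow = TRUE),
       b2 = take(no))
}

check_param_shapes <- function(params, spec) {
  stopifnot(inherits(spec, "mlp_spec"))
  ok <- identical(dim(params$W1), c(spec$n_input, spec$n_hidden)) &&
    length(params$b1) == spec$n_hidden &&
    identical(dim(params$W2), c(spec$n_hidden, spec$n_output)) &&
    length(params$b2) == spec$n_output
  if (!ok) stop("parameter shapes do not match the network spec", call. = FALSE)
  invisible(TRUE)
}

# forward pass; returns list(H, O) or just O
mlp_forward <- function(params, x, hidden = FALSE) {
  n <- nrow(x)
  h <- stats::plogis(x %*% params$W1 + rep(params$b1, each = n))
  o <- stats::plogis(h %*% params$W2 + rep(params$b2, each = n))
  if (hidden) list(H = h, O = o) else o
}

#' Network outputs to freshness grades
#'
#' Runs the forward pass and maps each row to the grade (1, 2 or 3) of its
#' largest output unit; exact ties break toward the lower grade.
#'
#' @param params Network parameter list (see [decode_params()]).
#' @param spec A [network_spec()].
#' @param x Feature matrix with `spec$n_input` columns.
#' @return Integer vector of grades.
#' @export
predict_grades <- function(params, spec, x) {
  x <- as_numeric_matrix(x, min_rows = 1)
  if (ncol(x) != spec$n_input)
    stop("feature dimension does not match the network spec", call. = FALSE)
  check_param_shapes(params, spec)
  max.col(mlp_forward(params, x), ties.method = "first")
}

# grades 1..n_output -> one-hot target matrix
one_hot <- function(y, n_classes = 3) {
  y <- as.integer(y)
  if (any(is.na(y)) || any(y < 1) || any(y > n_classes))
    stop("grades must be integers in 1..", n_classes, call. = FALSE)
  diag(n_classes)[y, , drop = FALSE]
}

#' Chromosome fitness on a training set
#'
#' Decodes the chromosome, runs the untrained forward pass and scores it as
#' `1 / (1 + SSE)` where SSE is the summed squared error against one-hot
#' targets. Values lie in (0, 1]; a network reproducing the targets exactly
#' scores 1. Non-finite network output yields fitness 0 with a warning.
#'
#' @param genes Chromosome vector of length `spec$n_params`.
#' @param x Feature matrix; `y` integer grades.
#' @param y Integer grades in `1..spec$n_output`.
#' @param spec A [network_spec()].
#' @return Scalar fitness.
#' @export
chromosome_fitness <- function(genes, x, y, spec) {
  params <- decode_params(genes, spec)
  o <- mlp_forward(params, x)
  if (any(!is.finite(o))) {
    warning("non-finite network output; fitness set to 0", call. = FALSE)
    return(0)
  }
  1 / (1 + sum((o - one_hot(y, spec$n_output))^2))
}
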