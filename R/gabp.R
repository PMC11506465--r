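#' Fit a GA-initialised backpropagation freshness classifier
#'
#' The package's central model: a single-hidden-layer feed-forward network
#' mapping (typically PCA-reduced) gas-sensor features to three freshness
#' grades (1 = fresh, 2 = sub-fresh, 3 = decayed). A real-coded genetic
#' algorithm first searches the space of full weight/bias vectors, scoring
#' each chromosome by `1/(1 + SSE)` on the training set; the best
#' individual is decoded into the network's initial weights and thresholds,
#' which backpropagation then refines. Set `init = "random"` to skip the
#' genetic stage (useful as an ablation baseline).
#'
#' @param x Numeric feature matrix (rows = samples). Features should be on
#'   comparable scales, e.g. principal-component scores of min-max
#'   normalised voltages.
#' @param y Integer grades in `1:3` (or a factor with three levels), one
#'   per row.
#' @param n_hidden Hidden-layer size.
#' @param ga A [ga_control()]; `bp` a [bp_control()].
#' @param bp A [bp_control()].
#' @param init `"ga"` (default) or `"random"` initial weights.
#' @param seed Optional integer seed covering the whole fit (GA and any
#'   random initialisation); fixed seed gives identical models.
#' @return Object of class `"gabp"` with elements `spec`, `params`,
#'   `init`, `ga` (the `"ga_result"`, when used), `loss` (backprop trace),
#'   `levels`, `call`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 3), 20),
#'            matrix(rnorm(40, 6), 20))
#' y <- rep(1:3, each = 20)
#' fit <- gabp(x, y, n_hidden = 4,
#'             ga = ga_control(population_size = 10, generations = 10),
#'             bp = bp_control(epochs = 200), seed = 1)
#' mean(predict(fit, x) == y)
#' @export
gabp <- function(x, y, n_hidden = 10, ga = ga_control(), bp = bp_control(),
                 init = c("ga", "random"), seed = NULL) {
  init <- match.arg(init)
  x <- as_numeric_matrix(x, min_rows = 1)
  if (is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (length(y) != nrow(x))
    stop("'y' must supply one grade per row of 'x'", call. = FALSE)
  if (any(is.na(y)) || any(y < 1L) || any(y > 3L))
    stop("grades must lie in 1:3", call. = FALSE)
  spec <- network_spec(ncol(x), n_hidden, 3)
  if (!is.null(seed)) set.seed(seed)
  ga_res <- NULL
  if (init == "ga") {
    ga_res <- ga_evolve(x, y, spec, ga)
    start <- decode_params(ga_res$best, spec)
  } else {
    start <- decode_params(stats::runif(spec$n_params, ga$gene_bounds[1],
                                        ga$gene_bounds[2]), spec)
  }
  trained <- train_bp(start, x, y, spec, bp)
  structure(list(spec = spec, params = trained$params, init = init,
                 ga = ga_res, loss = trained$loss,
                 n_train = nrow(x), levels = 1:3,
                 train_accuracy = 100 * mean(
                   predict_grades(trained$params, spec, x) == y),
                 call = match.call()),
            class = "gabp")
}

#' @export
print.gabp <- function(x, ...) {
  cat(sprintf("GA-BP freshness classifier (%d-%d-%d network, %s init)\n",
              x$spec$n_input, x$spec$n_hidden, x$spec$n_output, x$init))
  cat(sprintf("  trained on %d samples; final loss %.5f; training accuracy %.2f%%\n",
              x$n_train, x$loss[length(x$loss)], x$train_accuracy))
  invisible(x)
}

#' @export
summary.gabp <- function(object, ...) {
  structure(list(spec = object$spec, init = object$init,
                 n_train = object$n_train,
                 ga_best_fitness = if (!is.null(object$ga))
                   object$ga$best_fitness else NA_real_,
                 initial_loss = object$loss[1],
                 final_loss = object$loss[length(object$loss)],
                 epochs = length(object$loss) - 1L,
                 train_accuracy = object$train_accuracy),
            class = "summary.gabp")
}

#' @export
print.summary.gabp <- function(x, ...) {
  cat(sprintf("GA-BP classifier: %d-%d-%d network, %s initialisation\n",
              x$spec$n_input, x$spec$n_hidden, x$spec$n_output, x$init))
  if (!is.na(x$ga_best_fitness))
    cat(sprintf("  GA best fitness 1/(1+SSE): %.6f\n", x$ga_best_fitness))
  cat(sprintf("  backprop: %d epochs, loss %.5f -> %.5f\n",
              x$epochs, x$initial_loss, x$final_loss))
  cat(sprintf("  training samples: %d, training accuracy: %.2f%%\n",
              x$n_train, x$train_accuracy))
  invisible(x)
}

#' @export
coef.gabp <- function(object, ...) object$params

#' Predict freshness grades
#'
#' @param object A fitted [gabp()] model.
#' @param newdata Feature matrix with the same number of columns the model
#'   was trained on.
#' @param type `"grade"` for integer grades (argmax with ties toward the
#'   lower grade) or `"response"` for the raw 3-column output activations.
#' @param ... Ignored.
#' @return Integer grade vector, or an activation matrix.
#' @export
predict.gabp <- function(object, newdata, type = c("grade", "response"), ...) {
  type <- match.arg(type)
  newdata <- as_numeric_matrix(newdata, min_rows = 1)
  if (type == "response") {
    if (ncol(newdata) != object$spec$n_input)
      stop("feature dimension does not match the fitted model", call. = FALSE)
    return(mlp_forward(object$params, newdata))
  }
  predict_grades(object$params, object$spec, newdata)
}

#' Plot GA and backpropagation training traces
#'
#' Left panel: best GA fitness per generation (when GA initialisation was
#' used); right panel: backpropagation loss per epoch.
#'
#' @param x A fitted [gabp()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gabp <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$ga)) 1 else 2))
  on.exit(graphics::par(op))
  if (!is.null(x$ga))
    graphics::plot(seq_along(x$ga$trace) - 1, x$ga$trace, type = "l",
                   xlab = "generation", ylab = "best fitness 1/(1+SSE)",
                   main = "GA search", ...)
  graphics::plot(seq_along(x$loss) - 1, x$loss, type = "l",
                 xlab = "epoch", ylab = "mean squared error",
                 main = "Backpropagation", ...)
  invisible(x)
}

#' Persist a fitted model as plain text
#'
#' `write_gabp()` writes the architecture and full-precision parameters to
#' a readable text file; `read_gabp()` restores a model giving identical
#' predictions.
#'
#' @param model A fitted [gabp()] model.
#' @param path File path.
#' @return `write_gabp()`: `path`, invisibly. `read_gabp()`: a `"gabp"`
#'   object.
#' @export
write_gabp <- function(model, path) {
  stopifnot(inherits(model, "gabp"))
  genes <- encode_params(model$params, model$spec)
  lines <- c("# gabp model file v1",
             sprintf("n_input %d", model$spec$n_input),
             sprintf("n_hidden %d", model$spec$n_hidden),
             sprintf("n_output %d", model$spec$n_output),
             sprintf("init %s", model$init),
             sprintf("train_accuracy %.17g", model$train_accuracy),
             "genes",
             sprintf("%.17g", genes))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gabp
#' @export
read_gabp <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7 || lines[1] != "# gabp model file v1")
    stop("not a gabp model file: ", path, call. = FALSE)
  kv <- strsplit(lines[2:6], " ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  spec <- network_spec(as.integer(vals["n_input"]),
                       as.integer(vals["n_hidden"]),
                       as.integer(vals["n_output"]))
  stopifnot(lines[7] == "genes")
  genes <- as.numeric(lines[-(1:7)])
  if (length(genes) != spec$n_params)
    stop("model file has wrong parameter count", call. = FALSE)
  structure(list(spec = spec, params = decode_params(genes, spec),
                 init = unname(vals["init"]), ga = NULL, loss = NA_real_,
                 n_train = NA_integer_, levels = 1:3,
                 train_accuracy = as.numeric(vals["train_accuracy"]),
                 call = NULL),
            class = "gabp")
}
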