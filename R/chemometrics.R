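#' Min-max feature scaling
#'
#' `fit_minmax()` learns per-feature minima and maxima from a training
#' matrix; `scale_minmax()` applies the stored transform, mapping the
#' training range of each feature to \code{[0, 1]}. Features that are
#' constant in training are mapped to 0 with a warning (their range carries
#' no information).
#'
#' @param x Numeric matrix or data frame with at least two rows; all
#'   entries must be finite.
#' @return `fit_minmax()`: an object of class `"minmax_scaler"` with
#'   elements `min` and `max`. `scale_minmax()`: the scaled matrix.
#' @examples
#' sc <- fit_minmax(cbind(a = c(2, 4, 6)))
#' scale_minmax(sc, cbind(a = c(2, 4, 6)))
#' @export
fit_minmax <- function(x) {
  x <- as_numeric_matrix(x, min_rows = 2)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  if (any(hi == lo))
    warning("constant feature(s) scaled to 0: ",
            paste(colnames(x)[hi == lo], collapse = ", "), call. = FALSE)
  structure(list(min = lo, max = hi), class = "minmax_scaler")
}

#' @rdname fit_minmax
#' @param scaler A fitted `"minmax_scaler"`.
#' @export
scale_minmax <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  x <- as_numeric_matrix(x, min_rows = 1)
  if (ncol(x) != length(scaler$min))
    stop("feature count does not match the fitted scaler", call. = FALSE)
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1                      # constant features -> 0
  scaled <- sweep(sweep(x, 2, scaler$min), 2, rng, "/")
  scaled[, scaler$max == scaler$min] <- 0
  scaled
}

#' Principal-component analysis of sensor or quality data
#'
#' Fits a PCA by singular-value decomposition of the column-centered data
#' matrix (no variance rescaling; apply [fit_minmax()] first when features
#' have different units). Loadings are orthonormal and ordered by
#' decreasing explained variance; each loading's sign is fixed so that its
#' largest-magnitude entry is positive, making output reproducible.
#'
#' @param x Numeric matrix or data frame (rows = observations).
#' @param n_components Number of components to retain, between 1 and the
#'   number of features.
#' @return Object of class `"enose_pca"`: `center`, `loadings` (features x
#'   components), `explained_variance_ratio` (all computed components),
#'   `n_components`.
#' @seealso [pca_transform()], [cumulative_variance()]
#' @export
fit_pca <- function(x, n_components = 3) {
  x <- as_numeric_matrix(x, min_rows = 2)
  if (n_components < 1 || n_components > ncol(x))
    stop("'n_components' must be between 1 and the number of features",
         call. = FALSE)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  load <- pr$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude entry of each loading is positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  structure(list(center = pr$center, loadings = load,
                 sdev = pr$sdev,
                 explained_variance_ratio = evr,
                 n_components = n_components),
            class = "enose_pca")
}

#' Project data onto fitted principal components
#'
#' @param model A fitted [fit_pca()] model.
#' @param x New data with the same features as used in fitting.
#' @return Score matrix (rows x `n_components`), columns `PC1`, `PC2`, ...
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "enose_pca"))
  x <- as_numeric_matrix(x, min_rows = 1)
  if (ncol(x) != length(model$center))
    stop("feature count does not match the fitted PCA", call. = FALSE)
  scores <- sweep(x, 2, model$center) %*% model$loadings
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Cumulative explained-variance fraction
#'
#' Sum of the explained-variance ratios of the first `k` components.
#'
#' @param model A fitted [fit_pca()] model.
#' @param k Number of leading components, between 1 and `n_components`.
#' @return A fraction in \code{[0, 1]}.
#' @export
cumulative_variance <- function(model, k) {
  stopifnot(inherits(model, "enose_pca"))
  if (k < 1 || k > model$n_components)
    stop("'k' must be between 1 and the number of retained components",
         call. = FALSE)
  sum(model$explained_variance_ratio[seq_len(k)])
}

#' @export
print.enose_pca <- function(x, ...) {
  cat(sprintf("PCA: %d features -> %d components\n",
              nrow(x$loadings), x$n_components))
  cat("cumulative explained variance:",
      paste0(sprintf("%.1f%%",
                     100 * cumsum(x$explained_variance_ratio[
                       seq_len(x$n_components)])), collapse = ", "), "\n")
  invisible(x)
}

#' Pearson correlation of quality indices with remaining shelf life
#'
#' Computes the Pearson correlation of each quality index with the
#' remaining shelf life (time left until the decay deadline). Spoilage
#' indices such as TVB-N and TPC are expected to correlate negatively
#' with remaining shelf life; hardness and sensory scores positively.
#' Zero-variance columns are reported as `NA` with a warning.
#'
#' @param quality Numeric matrix or data frame of quality indices.
#' @param shelf_life Numeric vector (same length as rows of `quality`) of
#'   remaining shelf life, e.g. from [remaining_shelf_life()].
#' @return Named numeric vector of correlations in \code{[-1, 1]}.
#' @export
correlate_with_shelf_life <- function(quality, shelf_life) {
  quality <- as_numeric_matrix(quality, min_rows = 3)
  if (length(shelf_life) != nrow(quality))
    stop("'shelf_life' length must match rows of 'quality'", call. = FALSE)
  if (stats::sd(shelf_life) == 0)
    stop("'shelf_life' has zero variance", call. = FALSE)
  out <- vapply(seq_len(ncol(quality)), function(j) {
    if (stats::sd(quality[, j]) == 0) return(NA_real_)
    stats::cor(quality[, j], shelf_life)
  }, numeric(1))
  names(out) <- colnames(quality)
  if (anyNA(out))
    warning("zero-variance column(s) reported as NA: ",
            paste(names(out)[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

#' Decay deadline and remaining shelf life
#'
#' The decay deadline is the first timepoint whose grade reaches 3
#' (decayed); remaining shelf life at time t is `deadline - t`.
#'
#' @param time_hours Nondecreasing numeric vector of timepoints.
#' @param grades Integer grades in \code{1:3}, same length.
#' @return `decay_deadline()`: a single time (hours); errors if no
#'   timepoint is decayed. `remaining_shelf_life()`: numeric vector
#'   `deadline - time_hours`.
#' @export
decay_deadline <- function(time_hours, grades) {
  stopifnot(length(time_hours) == length(grades))
  i <- which(grades == 3L)
  if (!length(i)) stop("no timepoint reaches the decayed grade", call. = FALSE)
  time_hours[i[1]]
}

#' @rdname decay_deadline
#' @export
remaining_shelf_life <- function(time_hours, grades) {
  decay_deadline(time_hours, grades) - time_hours
}

#' Euclidean distance between two points
#'
#' The root of the summed squared coordinate differences,
#' \eqn{\rho(A,B) = \sqrt{\sum_i (a_i - b_i)^2}} — the distance used by the
#' quality-index cluster analysis.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Nonnegative scalar; zero iff `a == b`.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("'a' and 'b' must have equal length", call. = FALSE)
  sqrt(sum((a - b)^2))
}

#' Lloyd k-means clustering of quality indices
#'
#' Plain Lloyd iteration under the Euclidean distance: centers are
#' initialised by seeded random selection of `k` distinct points, points
#' are assigned to their nearest center, centers move to assignment means,
#' until assignments are stable or `max_iter` is reached. The within-cluster
#' sum of squares is recorded per iteration and is nonincreasing. An empty
#' cluster is reseeded with the point farthest from its center.
#'
#' @param points Numeric matrix or data frame (rows = points).
#' @param k Number of clusters, between 1 and the number of points.
#' @param seed Integer seed for the initial center selection.
#' @param max_iter Iteration cap.
#' @return Object of class `"enose_kmeans"`: `assignments`, `centers`
#'   (k x features), `n_iter`, `wss` (per-iteration objective trace),
#'   `tot_withinss`.
#' @export
cluster_quality <- function(points, k = 2, seed = 1, max_iter = 100) {
  points <- as_numeric_matrix(points, min_rows = 1)
  n <- nrow(points)
  if (k < 1 || k != round(k)) stop("'k' must be a positive integer", call. = FALSE)
  if (k > n) stop("'k' exceeds the number of points", call. = FALSE)
  set.seed(seed)
  centers <- points[sample.int(n, k), , drop = FALSE]
  assign_old <- rep(0L, n)
  wss_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    d2 <- point_center_dist2(points, centers)
    assignment <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(assignment == j)) {        # reseed empty cluster
        far <- which.max(d2[cbind(seq_len(n), assignment)])
        assignment[far] <- j
      }
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(points[assignment == j, , drop = FALSE])
    wss_trace <- c(wss_trace,
                   sum(point_center_dist2(points, centers)[
                     cbind(seq_len(n), assignment)]))
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
  }
  structure(list(assignments = assignment, centers = centers, n_iter = iter,
                 wss = wss_trace, tot_withinss = wss_trace[length(wss_trace)]),
            class = "enose_kmeans")
}

#' @export
print.enose_kmeans <- function(x, ...) {
  cat(sprintf("k-means (Euclidean): %d clusters, %d iterations, WSS %.4g\n",
              nrow(x$centers), x$n_iter, x$tot_withinss))
  print(table(cluster = x$assignments))
  invisible(x)
}

# squared distances, n x k
point_center_dist2 <- function(points, centers) {
  n <- nrow(points); k <- nrow(centers)
  d2 <- matrix(0, n, k)
  for (j in seq_len(k))
    d2[, j] <- rowSums(sweep(points, 2, centers[j, ])^2)
  d2
}

#' Pairwise relationship signs from a 2-component loading plot
#'
#' In a biplot of the first two principal components, an acute angle
#' between two variables' loading vectors indicates a positive
#' relationship and an obtuse angle a negative one. Following the standard
#' biplot convention, each loading vector is scaled by its component's
#' standard deviation before the angle is read, so the cosine approximates
#' the inter-variable correlation. The sign of the scaled dot product
#' encodes the relationship: nonnegative is reported as `"positive"`.
#'
#' @param model A fitted [fit_pca()] model with at least 2 components.
#' @return Character matrix (features x features) of `"positive"` /
#'   `"negative"`.
#' @export
loading_angle_signs <- function(model) {
  stopifnot(inherits(model, "enose_pca"))
  if (model$n_components < 2)
    stop("loading-angle analysis needs at least 2 components", call. = FALSE)
  l2 <- sweep(model$loadings[, 1:2, drop = FALSE], 2, model$sdev[1:2], "*")
  d <- l2 %*% t(l2)
  out <- ifelse(d >= 0, "positive", "negative")
  dimnames(out) <- list(rownames(model$loadings), rownames(model$loadings))
  out
}

# coerce to a finite numeric matrix, preserving column names
as_numeric_matrix <- function(x, min_rows = 1) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("input must be numeric", call. = FALSE)
  if (nrow(x) < min_rows)
    stop("input needs at least ", min_rows, " rows", call. = FALSE)
  if (any(!is.finite(x)))
    stop("input contains non-finite values", call. = FALSE)
  x
}
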