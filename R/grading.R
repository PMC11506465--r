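#' Grade freshness from total volatile basic nitrogen (TVB-N)
#'
#' Applies the three-level seafood freshness rule on TVB-N content:
#' below 15 mg/100 g is fresh (grade 1), 15--25 mg/100 g inclusive is
#' sub-fresh (grade 2), above 25 mg/100 g is decayed (grade 3). Both
#' boundary values fall in the sub-fresh class because the middle band
#' is a closed interval while the outer rules are strict inequalities.
#'
#' @param tvbn Numeric vector of TVB-N content in mg per 100 g; must be
#'   finite and nonnegative.
#' @return Integer vector of grades in \code{1:3} (1 = fresh,
#'   2 = sub-fresh, 3 = decayed).
#' @examples
#' classify_tvbn(c(10, 15, 25, 28.2))
#' @export
classify_tvbn <- function(tvbn) {
  check_index(tvbn, "tvbn")
  grade_by_thresholds(tvbn, lower = 15, upper = 25)
}

#' Grade freshness from total plate count (TPC)
#'
#' Three-level rule on the aerobic colony count: below 6.70 log CFU/g is
#' fresh, 6.70--7.70 log CFU/g inclusive is sub-fresh, above 7.70 log
#' CFU/g is decayed (thresholds follow GB 4789.2-2016 practice for
#' shellfish).
#'
#' @param tpc Numeric vector of total plate count in log10 CFU/g;
#'   finite and nonnegative.
#' @return Integer vector of grades in \code{1:3}.
#' @examples
#' classify_tpc(c(3.31, 6.70, 8.20))
#' @export
classify_tpc <- function(tpc) {
  check_index(tpc, "tpc")
  grade_by_thresholds(tpc, lower = 6.70, upper = 7.70)
}

#' Grade freshness from sensory sub-scores
#'
#' Averages the three 10-point panel sub-scores (color, odor, tissue
#' state) and grades the mean \eqn{s}: \eqn{s \ge 8} fresh,
#' \eqn{5 \le s < 8} sub-fresh, \eqn{s < 5} decayed. The mean is
#' unweighted.
#'
#' @param color,odor,tissue Numeric vectors of equal length with values
#'   in \code{[0, 10]}.
#' @return Integer vector of grades in \code{1:3}.
#' @examples
#' classify_sensory(9, 8, 8)
#' classify_sensory(c(5, 4), c(5, 4), c(5, 4))
#' @export
classify_sensory <- function(color, odor, tissue) {
  for (v in list(color = color, odor = odor, tissue = tissue)) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0 | v > 10))
      stop("sensory sub-scores must be finite values in [0, 10]", call. = FALSE)
  }
  if (length(color) != length(odor) || length(odor) != length(tissue))
    stop("sensory sub-score vectors must have equal length", call. = FALSE)
  s <- (color + odor + tissue) / 3
  ifelse(s >= 8, 1L, ifelse(s >= 5, 2L, 3L))
}

#' Internal-standard quantification of dimethyl sulfide
#'
#' Computes the sample concentration from GC-MS peak areas by the
#' internal-standard ratio \eqn{X_0 = X_{st} A_0 / A_{st}}, where
#' \eqn{X_{st}} is the standard concentration, \eqn{A_0} the sample
#' peak area and \eqn{A_{st}} the standard peak area. The result is
#' linear in \eqn{A_0} and equals \eqn{X_{st}} when the two areas
#' coincide. Full precision is returned; round only for display.
#'
#' @param xst Standard concentration (ppm), positive.
#' @param a0 Sample peak area (arbitrary area units), nonnegative.
#' @param ast Standard peak area (same units), strictly positive.
#' @return Concentration in ppm.
#' @examples
#' signif(quantify_dms(0.3821, 1900211.5, 18796229), 3)
#' @export
quantify_dms <- function(xst, a0, ast) {
  if (!is.numeric(xst) || any(!is.finite(xst)) || any(xst <= 0))
    stop("standard concentration 'xst' must be finite and positive", call. = FALSE)
  if (!is.numeric(a0) || any(!is.finite(a0)) || any(a0 < 0))
    stop("sample peak area 'a0' must be finite and nonnegative", call. = FALSE)
  if (!is.numeric(ast) || any(!is.finite(ast)) || any(ast <= 0))
    stop("standard peak area 'ast' must be finite and positive", call. = FALSE)
  xst * a0 / ast
}

#' Grade a quality-record series
#'
#' Applies one of the three grading rules element-wise to a table of
#' quality records as produced by [simulate_enose()] or
#' [read_enose_dataset()].
#'
#' @param records Data frame with columns \code{tvbn}, \code{tpc},
#'   \code{color}, \code{odor}, \code{tissue} (only the columns the
#'   chosen rule needs must be present).
#' @param rule One of \code{"tvbn"}, \code{"tpc"}, \code{"sensory"}.
#' @return Integer vector of grades, one per row of \code{records}.
#' @examples
#' grade_series(data.frame(tvbn = c(10, 20, 30)), "tvbn")
#' @export
grade_series <- function(records, rule = c("tvbn", "tpc", "sensory")) {
  rule <- match.arg(rule)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("'records' must be a nonempty data frame", call. = FALSE)
  need <- switch(rule, tvbn = "tvbn", tpc = "tpc",
                 sensory = c("color", "odor", "tissue"))
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  switch(rule,
    tvbn    = classify_tvbn(records$tvbn),
    tpc     = classify_tpc(records$tpc),
    sensory = classify_sensory(records$color, records$odor, records$tissue))
}

# shared validation for spoilage indices
check_index <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x < 0))
    stop("'", name, "' must be finite and nonnegative", call. = FALSE)
  invisible(x)
}

# strict below 'lower' -> 1, closed [lower, upper] -> 2, strict above -> 3
grade_by_thresholds <- function(x, lower, upper) {
  ifelse(x < lower, 1L, ifelse(x <= upper, 2L, 3L))
}
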