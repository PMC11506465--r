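#' Train/test split with optional class stratification
#'
#' Partitions sample indices into disjoint, exhaustive train and test sets.
#' With `stratified = TRUE` (default) each grade contributes `round(ratio *
#' n_class)` training samples, keeping class proportions within one sample
#' of the target ratio and preventing empty-class test folds.
#'
#' @param y Integer grade vector; only its length and class membership are
#'   used.
#' @param ratio Training fraction, strictly between 0 and 1.
#' @param seed Optional integer seed; fixed seed gives an identical split.
#' @param stratified Stratify by class (default) or split at random.
#' @return List with integer index vectors `train` and `test`.
#' @examples
#' s <- split_train_test(rep(1:3, c(60, 30, 10)), ratio = 0.8, seed = 1)
#' lengths(s)
#' @export
split_train_test <- function(y, ratio = 0.8, seed = NULL, stratified = TRUE) {
  if (ratio <= 0 || ratio >= 1)
    stop("'ratio' must be strictly between 0 and 1", call. = FALSE)
  n <- length(y)
  if (n < 2) stop("need at least two samples to split", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (stratified) {
    counts <- table(y)
    if (any(counts < 2))
      stop("every class needs at least 2 members for a stratified split",
           call. = FALSE)
    train <- integer(0)
    for (cls in names(counts)) {
      idx <- which(y == cls)
      n_train <- round(ratio * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_train))
    }
    train <- sort(train)
  } else {
    train <- sort(sample.int(n, round(ratio * n)))
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Three-class confusion matrix
#'
#' Cross-tabulates true against predicted grades; rows are true grades,
#' columns predictions, both over the full grade set `1:3` even when a
#' grade is absent.
#'
#' @param y_true,y_pred Integer grade vectors of equal, positive length
#'   with values in `1:3`.
#' @return A 3x3 integer matrix of class `"confusion3"` with dimnames
#'   `true`/`predicted` labelled fresh, sub-fresh, decayed.
#' @examples
#' confusion_matrix3(c(1, 2, 3, 3), c(1, 2, 3, 2))
#' @export
confusion_matrix3 <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred))
    stop("'y_true' and 'y_pred' must have equal positive length",
         call. = FALSE)
  for (v in list(y_true, y_pred))
    if (!all(v %in% 1:3))
      stop("grades must lie in 1:3", call. = FALSE)
  lv <- c("fresh", "sub-fresh", "decayed")
  cm <- table(true = factor(y_true, 1:3, lv),
              predicted = factor(y_pred, 1:3, lv))
  structure(unclass(as.matrix(cm)), class = "confusion3")
}

#' Overall and per-class accuracy of a confusion matrix
#'
#' `overall_accuracy()` is 100 times the trace over the total count.
#' `per_class_accuracy()` is each class's recall — the diagonal count over
#' the row total — as the per-class "accuracy rate"; classes with no true
#' samples are reported as `NA`. Values are returned at full precision;
#' display conventionally rounds the overall figure to 4 decimals and
#' per-class figures to 1.
#'
#' @param cm A 3x3 confusion matrix (any numeric matrix is accepted).
#' @return `overall_accuracy()`: scalar percentage; `per_class_accuracy()`:
#'   3 percentages named fresh/sub-fresh/decayed.
#' @examples
#' cm <- rbind(c(352, 0, 0), c(3, 108, 0), c(0, 1, 377))
#' round(overall_accuracy(cm), 4)
#' round(per_class_accuracy(cm), 1)
#' @export
overall_accuracy <- function(cm) {
  cm <- check_cm(cm)
  100 * sum(diag(cm)) / sum(cm)
}

#' @rdname overall_accuracy
#' @export
per_class_accuracy <- function(cm) {
  cm <- check_cm(cm)
  rs <- rowSums(cm)
  out <- ifelse(rs > 0, 100 * diag(cm) / ifelse(rs > 0, rs, 1), NA_real_)
  names(out) <- c("fresh", "sub-fresh", "decayed")
  out
}

check_cm <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (!is.numeric(cm) || !identical(dim(cm), c(3L, 3L)))
    stop("'cm' must be a numeric 3x3 matrix", call. = FALSE)
  if (any(cm < 0)) stop("'cm' must be nonnegative", call. = FALSE)
  if (sum(cm) == 0) stop("'cm' is empty", call. = FALSE)
  cm
}

#' @export
print.confusion3 <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted)\n")
  print(matrix(as.integer(x), 3, 3, dimnames = dimnames(x)))
  cat(sprintf("overall accuracy: %.4f%%\n", overall_accuracy(x)))
  pc <- per_class_accuracy(x)
  cat("per-class accuracy:",
      paste(sprintf("%s %.1f%%", names(pc), pc), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a fitted classifier on labelled test data
#'
#' Builds the confusion matrix and accuracy figures for a fitted [gabp()]
#' model on a held-out set, together with a configuration echo so the
#' report is self-describing and byte-reproducible under fixed seeds.
#'
#' @param model A fitted [gabp()] model.
#' @param x_test Feature matrix; `y_test` true grades.
#' @param y_test Integer grades in `1:3`.
#' @param label Optional condition tag (e.g. `"4C"`) carried in the report.
#' @return Object of class `"enose_report"`: `confusion`, `overall`
#'   (percent), `per_class` (percent), `n_test`, `label`, `model_summary`.
#' @export
evaluate_model <- function(model, x_test, y_test, label = NULL) {
  pred <- predict(model, x_test)
  cm <- confusion_matrix3(y_test, pred)
  structure(list(confusion = cm,
                 overall = overall_accuracy(cm),
                 per_class = per_class_accuracy(cm),
                 n_test = length(y_test), label = label,
                 model_summary = summary(model)),
            class = "enose_report")
}

#' @export
print.enose_report <- function(x, ...) {
  for (line in report_lines(x)) cat(line, "\n", sep = "")
  invisible(x)
}

#' Plain-text lines of an evaluation report
#'
#' A deterministic, human-readable rendering of an [evaluate_model()]
#' report (also convenient for writing to disk).
#'
#' @param report An `"enose_report"`.
#' @return Character vector of lines.
#' @export
report_lines <- function(report) {
  cm <- report$confusion
  pc <- report$per_class
  c(sprintf("Evaluation report%s",
            if (is.null(report$label)) "" else paste0(" [", report$label, "]")),
    sprintf("  test samples: %d", report$n_test),
    sprintf("  overall accuracy: %.4f%%", report$overall),
    sprintf("  per-class accuracy: %s",
            paste(sprintf("%s %.1f%%", names(pc), pc), collapse = ", ")),
    "  confusion matrix (true x predicted):",
    sprintf("    %5d %5d %5d", cm[, 1], cm[, 2], cm[, 3]))
}
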