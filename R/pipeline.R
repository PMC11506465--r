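#' Configuration for a full grading experiment
#'
#' Bundles the settings for [run_experiment()]: which storage temperatures
#' to simulate, the preprocessing (min-max normalisation, number of
#' principal components), the GA-BP settings and the evaluation split.
#' Per-temperature generator defaults come from [enose_config()].
#'
#' @param temperatures Storage temperatures to run (subset of
#'   `c(4, 12, 20, 28)`).
#' @param n_components Principal components kept as classifier features
#'   (at most 10, the number of gas channels).
#' @param n_hidden Hidden-layer size of the network.
#' @param ga A [ga_control()]; `bp` a [bp_control()].
#' @param bp A [bp_control()].
#' @param split_ratio Training fraction of the train/test split.
#' @param stratified Stratify the split by grade.
#' @param seed Master integer seed; all per-temperature generator, split
#'   and fitting seeds are derived from it.
#' @param n_rows Optional named or unnamed vector overriding the default
#'   dataset size per temperature (useful for quick runs).
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(temperatures = c(4, 12, 20, 28),
                              n_components = 3, n_hidden = 10,
                              ga = ga_control(), bp = bp_control(),
                              split_ratio = 0.8, stratified = TRUE,
                              seed = 1, n_rows = NULL) {
  if (!all(temperatures %in% c(4, 12, 20, 28)))
    stop("'temperatures' must be a subset of c(4, 12, 20, 28)", call. = FALSE)
  if (n_components < 1 || n_components > 10)
    stop("'n_components' must be between 1 and 10 (gas channels)",
         call. = FALSE)
  if (!is.null(n_rows) && length(n_rows) != length(temperatures))
    stop("'n_rows' must supply one size per temperature", call. = FALSE)
  structure(list(temperatures = temperatures, n_components = n_components,
                 n_hidden = n_hidden, ga = ga, bp = bp,
                 split_ratio = split_ratio, stratified = stratified,
                 seed = as.integer(seed), n_rows = n_rows),
            class = "experiment_config")
}

#' Run the end-to-end freshness-grading experiment
#'
#' For each configured storage temperature: simulate the e-nose trial,
#' take the TVB-N-derived grades as targets, min-max normalise the ten gas
#' channels, reduce them to `n_components` principal components, split
#' train/test, fit the GA-BP classifier on the training scores and
#' evaluate on the held-out scores. One model is fitted per temperature.
#' The whole run is reproducible from the config: every stage seed is
#' derived from `config$seed`.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Object of class `"enose_experiment"`: `reports` (one
#'   [evaluate_model()] report per temperature), `models`, `pca` (fitted
#'   PCA per temperature), `summary` (data frame: temperature, n_rows,
#'   n_test, pc3_variance_pct, test_accuracy_pct), `config`,
#'   `config_hash`.
#' @examples
#' \donttest{
#' cfg <- experiment_config(temperatures = 28, seed = 1,
#'                          n_rows = 600,
#'                          ga = ga_control(generations = 10),
#'                          bp = bp_control(epochs = 200))
#' ex <- run_experiment(cfg, quiet = TRUE)
#' ex$summary
#' }
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  reports <- list(); models <- list(); pcas <- list()
  rows <- integer(0); n_tests <- integer(0)
  pc_var <- numeric(0); accs <- numeric(0)
  for (i in seq_along(config$temperatures)) {
    temp <- config$temperatures[i]
    gen_cfg <- enose_config(temp,
                            n_rows = if (!is.null(config$n_rows))
                              config$n_rows[i] else NULL,
                            seed = config$seed + 1000L * i)
    dataset <- simulate_enose(gen_cfg)
    y <- dataset$labels$label
    say("[%g C] simulated %d rows; grades %s", temp, nrow(dataset$sensors),
        paste(table(y), collapse = "/"))
    volts <- as.matrix(dataset$sensors[, sensor_cols()])
    scaler <- fit_minmax(volts)
    pca <- fit_pca(scale_minmax(scaler, volts), config$n_components)
    scores <- pca_transform(pca, scale_minmax(scaler, volts))
    say("[%g C] first %d PCs explain %.1f%% of variance", temp,
        config$n_components,
        100 * cumulative_variance(pca, config$n_components))
    split <- split_train_test(y, config$split_ratio,
                              seed = config$seed + 1000L * i + 1L,
                              stratified = config$stratified)
    model <- gabp(scores[split$train, , drop = FALSE], y[split$train],
                  n_hidden = config$n_hidden, ga = config$ga, bp = config$bp,
                  seed = config$seed + 1000L * i + 2L)
    report <- evaluate_model(model, scores[split$test, , drop = FALSE],
                             y[split$test], label = paste0(temp, "C"))
    say("[%g C] held-out accuracy %.4f%%", temp, report$overall)
    key <- paste0(temp, "C")
    reports[[key]] <- report; models[[key]] <- model; pcas[[key]] <- pca
    rows <- c(rows, nrow(dataset$sensors))
    n_tests <- c(n_tests, report$n_test)
    pc_var <- c(pc_var, 100 * cumulative_variance(pca, config$n_components))
    accs <- c(accs, report$overall)
  }
  structure(list(reports = reports, models = models, pca = pcas,
                 summary = data.frame(temperature = config$temperatures,
                                      n_rows = rows, n_test = n_tests,
                                      pc_variance_pct = pc_var,
                                      test_accuracy_pct = accs),
                 config = config, config_hash = config_hash(config)),
            class = "enose_experiment")
}

#' @export
print.enose_experiment <- function(x, ...) {
  cat("E-nose freshness-grading experiment\n")
  cat(sprintf("  config hash: %s; master seed: %d\n",
              x$config_hash, x$config$seed))
  df <- x$summary
  df$pc_variance_pct <- round(df$pc_variance_pct, 1)
  df$test_accuracy_pct <- round(df$test_accuracy_pct, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

# stable 31-bit polynomial hash of the deparsed config (no external deps)
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
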