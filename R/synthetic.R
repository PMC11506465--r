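#' Configuration for the synthetic electronic-nose generator
#'
#' Builds the parameter set for [simulate_enose()]. Defaults reproduce the
#' storage-trial conditions the analysis assumes: four storage temperatures
#' with dataset sizes 4200 (4 \eqn{\degree}C), 4800 (12 \eqn{\degree}C),
#' 4200 (20 \eqn{\degree}C) and 7800 rows (28 \eqn{\degree}C), storage
#' horizons of 216/168/72/48 h, and fresh/sub-fresh/decayed phase boundaries
#' expressed as fractions of the horizon. Boundary defaults per temperature
#' match the class composition of the trials (e.g. roughly 42/13/45% of the
#' 4 \eqn{\degree}C horizon).
#'
#' @param temperature Storage temperature in Celsius; one of 4, 12, 20, 28.
#' @param n_rows Number of sensor rows to generate (default depends on
#'   temperature).
#' @param horizon Storage duration in hours (default depends on temperature).
#' @param class_boundaries Two increasing fractions in (0,1) splitting the
#'   horizon into fresh / sub-fresh / decayed phases.
#' @param noise_sd Per-reading Gaussian voltage noise, volts. Quality-index
#'   measurement noise scales with `noise_sd` so that `noise_sd = 0` yields
#'   exactly monotone quality trajectories.
#' @param drift_sd Magnitude (volts, over the full horizon) of the slow
#'   random-walk baseline drift per channel.
#' @param seed Integer RNG seed; identical config and seed give bit-identical
#'   datasets.
#' @return A list of class `"enose_config"`.
#' @examples
#' cfg <- enose_config(28, n_rows = 200, seed = 1)
#' @export
enose_config <- function(temperature = 4, n_rows = NULL, horizon = NULL,
                         class_boundaries = NULL, noise_sd = 0.02,
                         drift_sd = 0.01, seed = 1) {
  defaults <- condition_defaults()
  key <- as.character(temperature)
  if (!key %in% rownames(defaults))
    stop("'temperature' must be one of 4, 12, 20, 28", call. = FALSE)
  d <- defaults[key, ]
  if (is.null(n_rows)) n_rows <- d$n_rows
  if (is.null(horizon)) horizon <- d$horizon
  if (is.null(class_boundaries)) class_boundaries <- c(d$b1, d$b2)
  if (!is.numeric(n_rows) || length(n_rows) != 1 || n_rows < 1 ||
      n_rows != round(n_rows))
    stop("'n_rows' must be a positive integer", call. = FALSE)
  if (length(class_boundaries) != 2 ||
      !(0 < class_boundaries[1] && class_boundaries[1] < class_boundaries[2] &&
        class_boundaries[2] < 1))
    stop("'class_boundaries' must satisfy 0 < b1 < b2 < 1", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be nonnegative", call. = FALSE)
  if (!is.numeric(horizon) || horizon <= 0)
    stop("'horizon' must be positive (hours)", call. = FALSE)
  structure(list(temperature = temperature, n_rows = as.integer(n_rows),
                 horizon = horizon, class_boundaries = class_boundaries,
                 noise_sd = noise_sd, drift_sd = drift_sd,
                 tpc0 = d$tpc0, seed = as.integer(seed)),
            class = "enose_config")
}

# per-temperature study conditions: dataset size, storage duration (h),
# phase boundaries as horizon fractions, initial plate count (log CFU/g)
condition_defaults <- function() {
  data.frame(row.names = c("4", "12", "20", "28"),
             n_rows  = c(4200L, 4800L, 4200L, 7800L),
             horizon = c(216, 168, 72, 48),
             b1      = c(0.419, 0.257, 0.306, 0.467),
             b2      = c(0.551, 0.498, 0.721, 0.769),
             tpc0    = c(3.31, 3.08, 4.23, 4.11))
}

#' Noise-free sensor response curves
#'
#' Mean voltage of each of the ten gas channels as a function of normalised
#' storage time. Channel roles follow a typical MOS array for seafood
#' headspace: the alcohol-sensitive channel (S9) rises early in the fresh
#' phase; amine-sensitive channels (S1, S2, S5, S10) rise around the
#' sub-fresh/decayed boundary; a sulfide-linked response (S6, with a smaller
#' contribution on S2) appears only in the final phase of decay. Responses
#' are logistic (saturating) in time.
#'
#' @param u Numeric vector of normalised storage times (fraction of horizon,
#'   typically in \code{[0, 1]}).
#' @param class_boundaries The two phase-boundary fractions.
#' @return Matrix with `length(u)` rows and columns `S1`..`S10`, in volts.
#' @export
sensor_response_curves <- function(u, class_boundaries) {
  b1 <- class_boundaries[1]; b2 <- class_boundaries[2]
  bs <- (b2 + 1) / 2                       # sulfide onset, final phase
  p <- list(                               # base, amplitude, midpoint, scale
    S1  = c(0.55, 1.5, b2,          0.06),
    S2  = c(0.50, 1.4, b2 + 0.05,   0.07),
    S3  = c(0.60, 0.6, b1,          0.08),
    S4  = c(0.45, 0.1, 0.5,         0.30),
    S5  = c(0.40, 1.6, b2 + 0.02,   0.06),
    S6  = c(0.50, 1.3, bs,          0.05),
    S7  = c(0.55, 0.5, (b1 + b2)/2, 0.10),
    S8  = c(0.60, 0.5, 1.2 * b1,    0.12),
    S9  = c(0.45, 1.2, 0.55 * b1,   0.25 * b1),
    S10 = c(0.50, 1.0, b2 + 0.08,   0.08))
  v <- vapply(p, function(q) q[1] + q[2] * stats::plogis((u - q[3]) / q[4]),
              numeric(length(u)))
  v <- matrix(v, nrow = length(u), dimnames = list(NULL, names(p)))
  # secondary sulfide sensitivity of S2 in the final phase
  v[, "S2"] <- v[, "S2"] + 0.3 * stats::plogis((u - bs) / 0.05)
  v
}

# noise-free quality-index trajectories on normalised time; monotone by
# construction and crossing the grading thresholds at the phase boundaries
quality_mean_curves <- function(u, class_boundaries, tpc0) {
  b1 <- class_boundaries[1]; b2 <- class_boundaries[2]
  pl <- function(xs, ys) stats::approx(xs, ys, xout = u, rule = 2)$y
  data.frame(
    tvbn     = pl(c(0, b1, b2, 1), c(8, 15, 25, 42)),
    tpc      = pl(c(0, b1 + 0.03, b2 - 0.03, 1), c(tpc0, 6.70, 7.70, 9.6)),
    hardness = 4.5 * exp(-3.3 * pmin(u, 1)),
    color    = pl(c(0, b1, b2, 1), c(9.6, 8, 5, 2.5)),
    odor     = pl(c(0, b1, b2, 1), c(9.4, 8, 5, 1.8)),
    tissue   = pl(c(0, b1, b2, 1), c(9.5, 8, 5, 2.2)))
}

# map cumulative sampling time to clock time: 45-min cycles of 20 min
# chamber cleaning followed by five 5-min collection windows at 1 Hz
sampling_clock <- function(n_rows, horizon) {
  s_total <- horizon * 25 / 45            # hours actually spent sampling
  s <- (seq_len(n_rows) - 0.5) / n_rows * s_total
  k <- floor(s / (25 / 60))               # completed cycles
  k * 0.75 + 20 / 60 + (s - k * 25 / 60)
}

#' Simulate an electronic-nose storage trial
#'
#' Generates a complete synthetic dataset for one storage-temperature
#' condition: a 10-channel sensor time series, the parallel quality-index
#' trajectories (TVB-N, total plate count, hardness, three sensory
#' sub-scores) and ground-truth freshness grades. Sensor means follow
#' [sensor_response_curves()]; readings add i.i.d. Gaussian noise plus a
#' slow random-walk baseline drift per channel. Quality indices are monotone
#' in expectation (TVB-N and TPC nondecreasing, hardness and sensory scores
#' nonincreasing). Grades are derived from the noise-free TVB-N trajectory
#' through [classify_tvbn()], so the label boundaries fall exactly at the
#' configured phase boundaries.
#'
#' Row timestamps honour the acquisition protocol: 45-min cycles of 20 min
#' chamber cleaning followed by five 5-min collection windows, so
#' `time_hours` shows periodic gaps during cleaning.
#'
#' @param config An [enose_config()] object.
#' @return A list of class `"enose_dataset"` with elements `sensors` (data
#'   frame: `time_hours`, `S1`..`S10`, `chamber_temp`, `rh`, `condition`),
#'   `quality` (data frame: `time_hours`, `tvbn`, `tpc`, `hardness`,
#'   `color`, `odor`, `tissue`), `labels` (data frame: `time_hours`,
#'   `label`) and `config`.
#' @examples
#' d <- simulate_enose(enose_config(28, n_rows = 300, seed = 7))
#' table(d$labels$label)
#' @export
simulate_enose <- function(config) {
  if (!inherits(config, "enose_config"))
    stop("'config' must be an enose_config object", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_rows
  time_hours <- sampling_clock(n, config$horizon)
  u <- time_hours / config$horizon

  mu <- sensor_response_curves(u, config$class_boundaries)
  drift <- vapply(seq_len(10), function(j)
    cumsum(stats::rnorm(n, 0, config$drift_sd / sqrt(n))), numeric(n))
  volts <- mu + drift + matrix(stats::rnorm(n * 10, 0, config$noise_sd), n, 10)
  colnames(volts) <- colnames(mu)

  q_mu <- quality_mean_curves(u, config$class_boundaries, config$tpc0)
  qscale <- config$noise_sd / 0.02        # reference voltage noise 0.02 V
  qsd <- c(tvbn = 0.4, tpc = 0.08, hardness = 0.05,
           color = 0.15, odor = 0.15, tissue = 0.15) * qscale
  quality <- q_mu
  for (nm in names(qsd))
    quality[[nm]] <- q_mu[[nm]] + stats::rnorm(n, 0, qsd[[nm]])
  quality$tvbn <- pmax(quality$tvbn, 0)
  quality$tpc <- pmax(quality$tpc, 0)
  quality$hardness <- pmax(quality$hardness, 0)
  for (nm in c("color", "odor", "tissue"))
    quality[[nm]] <- pmin(pmax(quality[[nm]], 0), 10)

  sensors <- data.frame(time_hours = time_hours, volts,
                        chamber_temp = config$temperature +
                          stats::rnorm(n, 0, 0.1),
                        rh = pmin(pmax(85 + stats::rnorm(n, 0, 1), 0), 100),
                        condition = paste0(config$temperature, "C"))
  quality <- cbind(time_hours = time_hours, quality)
  labels <- data.frame(time_hours = time_hours,
                       label = classify_tvbn(q_mu$tvbn))
  structure(list(sensors = sensors, quality = quality, labels = labels,
                 config = config),
            class = "enose_dataset")
}

#' @export
print.enose_dataset <- function(x, ...) {
  cat(sprintf("Synthetic e-nose storage trial at %g °C\n",
              x$config$temperature))
  cat(sprintf("  %d sensor rows over %g h; grades: %s\n",
              nrow(x$sensors), x$config$horizon,
              paste(sprintf("%d×%s", table(x$labels$label),
                            c("fresh", "sub-fresh", "decayed")[
                              sort(unique(x$labels$label))]),
                    collapse = ", ")))
  invisible(x)
}

sensor_cols <- function() paste0("S", 1:10)

#' Write or read an e-nose dataset as delimited text
#'
#' `write_enose_dataset()` writes three CSV files (`sensors.csv`,
#' `quality.csv`, `labels.csv`) into a directory; `read_enose_dataset()`
#' reads them back, validating headers, column counts and numeric cells.
#' The round trip reproduces the dataset to within float-formatting
#' tolerance (better than 1e-9).
#'
#' @param dataset An `"enose_dataset"` (or a list with the same three data
#'   frames).
#' @param dir Directory to write to / read from; created if absent.
#' @return `write_enose_dataset()` returns `dir` invisibly;
#'   `read_enose_dataset()` returns a list of class `"enose_dataset"`
#'   (without the generator config).
#' @export
write_enose_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$sensors, file.path(dir, "sensors.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$quality, file.path(dir, "quality.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_enose_dataset
#' @export
read_enose_dataset <- function(dir) {
  sensors <- read_checked_csv(file.path(dir, "sensors.csv"),
                              c("time_hours", sensor_cols(),
                                "chamber_temp", "rh", "condition"),
                              character_cols = "condition")
  quality <- read_checked_csv(file.path(dir, "quality.csv"),
                              c("time_hours", "tvbn", "tpc", "hardness",
                                "color", "odor", "tissue"))
  labels <- read_checked_csv(file.path(dir, "labels.csv"),
                             c("time_hours", "label"))
  labels$label <- as.integer(labels$label)
  structure(list(sensors = sensors, quality = quality, labels = labels),
            class = "enose_dataset")
}

# strict CSV reader: exact header, numeric validation naming row and column
read_checked_csv <- function(path, expected_header, character_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0)
    stop("empty file: ", path, call. = FALSE)
  got <- strsplit(header, ",", fixed = TRUE)[[1]]
  if (length(got) != length(expected_header) || !all(got == expected_header))
    stop("malformed header in ", basename(path), ": expected '",
         paste(expected_header, collapse = ","), "', got '", header, "'",
         call. = FALSE)
  x <- utils::read.csv(path, colClasses = "character")
  if (nrow(x) == 0) stop("no data rows in ", path, call. = FALSE)
  for (nm in setdiff(expected_header, character_cols)) {
    num <- suppressWarnings(as.numeric(x[[nm]]))
    bad <- which(is.na(num) & !is.na(x[[nm]]))
    if (length(bad))
      stop(sprintf("non-numeric cell in %s: row %d, column '%s' ('%s')",
                   basename(path), bad[1], nm, x[[nm]][bad[1]]),
           call. = FALSE)
    x[[nm]] <- num
  }
  x
}
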