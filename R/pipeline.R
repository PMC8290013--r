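# Pipeline orchestration: simulate -> time-frequency features -> decoding ->
# statistics -> report, streaming subject by subject so memory stays bounded
# by one subject's epochs.

#' Per-subject theta features and ROI scalars
#'
#' Runs the wavelet decomposition on the midline sensors for one subject's
#' eight conditions and returns (i) per-condition scalar ERSP/ITC summaries
#' computed on trial-count-equalized data (ITC is biased by unequal n) and
#' (ii) per-condition single-trial theta power features on the decoding grid
#' computed from all trials (decoding does its own class equalization).
#'
#' @param epochs named list of 8 `epoch_set`s.
#' @param frequencies wavelet grid (default the 4-8 Hz theta bins; each bin
#'   is computed independently, so theta summaries equal those extracted
#'   from a wider grid).
#' @param sensors midline sensor labels.
#' @param band theta band (Hz).
#' @param window,baseline_window ROI and baseline windows (ms).
#' @param equalize whether to equalize trial counts before the scalar
#'   ERSP/ITC summaries.
#' @param seed seed for the equalizing subsample.
#' @return list: `scalars` (data.frame strategy, trial_type, theta_power,
#'   theta_itc, n_trials), `features` (per strategy: control/target arrays
#'   trial x sensor x grid point), `grid`.
#' @export
subject_features <- function(epochs, frequencies = 4:8,
                             sensors = MIDLINE_SENSORS, band = c(4, 8),
                             window = c(200, 450),
                             baseline_window = c(-500, -200),
                             equalize = TRUE, seed = 1L) {
  fam <- build_wavelets(frequencies, epochs[[1]]$fs)
  coefs <- lapply(epochs, convolve_epochs, family = fam, channels = sensors)
  grid <- decoding_grid(coefs[[1]]$times)

  counts <- vapply(epochs, n_trials, integer(1))
  no_op <- !equalize || length(unique(counts)) == 1
  eq <- if (no_op) epochs else subsample_equalize(epochs, seed = seed)
  scal <- list()
  for (nm in names(eq)) {
    co <- if (no_op) coefs[[nm]]
          else convolve_epochs(eq[[nm]], fam, channels = sensors)
    e <- ersp(co, baseline_window)
    it <- itc(co)
    scal[[nm]] <- data.frame(
      strategy = eq[[nm]]$strategy, trial_type = eq[[nm]]$trial_type,
      theta_power = extract_scalar(e, sensors, band, window),
      theta_itc = extract_scalar(it, sensors, band, window),
      n_trials = n_trials(eq[[nm]]), stringsAsFactors = FALSE)
  }
  scalars <- do.call(rbind, scal)
  rownames(scalars) <- NULL

  features <- list()
  for (s in STRATEGIES) {
    features[[s]] <- lapply(stats::setNames(TRIAL_TYPES, TRIAL_TYPES),
      function(tt) {
        tc <- theta_timecourses(coefs[[paste(s, tt, sep = ".")]], sensors,
                                band)
        tc$power[, , grid$index, drop = FALSE]
      })
  }
  list(scalars = scalars, features = features, grid = grid)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a study and executes the complete analysis chain:
#' per-subject wavelet decomposition and ROI summarization, the 16-way
#' cross-strategy decoding with group FDR inference, behavioral interference
#' statistics, theta rm-ANOVAs, and residualized individual-differences
#' correlations. Subjects are processed one at a time; epochs are written to
#' the container (if `path` is given) and dropped from memory.
#'
#' @param config `fmtheta_config` (ignored if `path` holds an existing
#'   study and `simulate = FALSE`).
#' @param path optional container directory for persisted epochs/results.
#' @param simulate if TRUE (default) generate the study from `config`.
#' @param frequencies wavelet grid for the theta features.
#' @param k,reps decoding folds and repetitions.
#' @param fdr_q FDR level for group decoding inference.
#' @param keep_epochs if FALSE and `path` is NULL, epochs are discarded
#'   after feature extraction.
#' @param progress print per-subject progress.
#' @return list of class `fmtheta_report`: `scalars`, `decoding`
#'   (per-subject curves array subject x train x test x timepoint), `group`
#'   (FDR-corrected group table), `behavior`, `interference`, `anova`
#'   (theta power + ITC two-way rm-ANOVAs), `correlations`, `grid`,
#'   `config`.
#' @export
run_pipeline <- function(config, path = NULL, simulate = TRUE,
                         frequencies = 4:8, k = 5, reps = 3, fdr_q = 0.05,
                         keep_epochs = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "fmtheta_config"))
  if (!is.null(path)) init_container(path, config)

  n <- config$n_subjects
  scal_rows <- vector("list", n)
  beh_rows <- vector("list", n)
  acc <- NULL
  grid <- NULL

  for (i in seq_len(n)) {
    if (progress) message("subject ", i, "/", n)
    if (simulate) {
      sub <- generate_subject(config, i)
      epochs <- sub$epochs
      beh_rows[[i]] <- sub$behavior
      if (!is.null(path)) write_subject_epochs(path, i, epochs)
    } else {
      epochs <- read_subject_epochs(path, i)
    }
    sf <- subject_features(epochs, frequencies = frequencies,
                           seed = derive_seed(config$seed, 23L, i))
    rm(epochs)
    grid <- sf$grid
    sf$scalars$subject <- i
    scal_rows[[i]] <- sf$scalars
    curves <- decode_subject(sf$features, k = k, reps = reps,
                             seed = derive_seed(config$seed, 29L, i))
    if (is.null(acc)) {
      acc <- array(NA_real_, dim = c(n, dim(curves)),
                   dimnames = c(list(NULL), dimnames(curves)))
    }
    acc[i, , , ] <- curves
  }

  scalars <- do.call(rbind, scal_rows)
  behavior <- if (simulate) do.call(rbind, beh_rows)
              else read_study(path)$behavior
  if (simulate && !is.null(path))
    utils::write.csv(behavior, file.path(path, "behavior.csv"),
                     row.names = FALSE)
  group <- group_inference(acc, q = fdr_q)

  intf <- interference(behavior)
  acc_mat <- do.call(cbind, lapply(STRATEGIES, function(s)
    intf$acc_interference[intf$strategy == s]))
  colnames(acc_mat) <- STRATEGIES
  rt_mat <- do.call(cbind, lapply(setdiff(STRATEGIES, "inhibitory"),
    function(s) intf$rt_interference[intf$strategy == s]))
  colnames(rt_mat) <- setdiff(STRATEGIES, "inhibitory")

  theta_aov <- list()
  for (measure in c("theta_power", "theta_itc")) {
    cube <- array(NA_real_, dim = c(n, 4, 2),
                  dimnames = list(NULL, STRATEGIES, TRIAL_TYPES))
    for (s in STRATEGIES) for (tt in TRIAL_TYPES) {
      v <- scalars[scalars$strategy == s & scalars$trial_type == tt, ]
      cube[v$subject, s, tt] <- v[[measure]]
    }
    theta_aov[[measure]] <-
      two_way_rm_anova(cube, c("strategy", "trial_type"))
  }

  theta_tbl <- scalars[, c("subject", "strategy", "trial_type",
                           "theta_power", "theta_itc")]
  correlations <- individual_differences(behavior, theta_tbl)

  report <- structure(list(
    scalars = scalars, decoding = acc, group = group, behavior = behavior,
    interference = intf,
    interference_anova = list(
      accuracy = one_way_rm_anova(acc_mat),
      rt = one_way_rm_anova(rt_mat)),
    anova = theta_aov, correlations = correlations, grid = grid,
    config = config
  ), class = "fmtheta_report")

  if (!is.null(path)) write_report(report, path)
  report
}

#' Persist derived pipeline results into a container
#' @param report an `fmtheta_report`.
#' @param path container directory.
#' @export
write_report <- function(report, path) {
  dd <- file.path(path, "derived")
  dir.create(dd, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$scalars, file.path(dd, "theta_scalars.csv"),
                   row.names = FALSE)
  utils::write.csv(report$group, file.path(dd, "decoding_group.csv"),
                   row.names = FALSE)
  utils::write.csv(report$interference, file.path(dd, "interference.csv"),
                   row.names = FALSE)
  utils::write.csv(report$correlations, file.path(dd, "correlations.csv"),
                   row.names = FALSE)
  saveRDS(report$decoding, file.path(dd, "decoding_curves.rds"))
  writeLines(format_report(report), file.path(path, "report.md"))
  invisible(path)
}

#' Plain-text summary report
#'
#' @param report an `fmtheta_report`.
#' @return character vector of markdown lines.
#' @export
format_report <- function(report) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c("# Frontal-midline theta analysis report", "")
  lines <- c(lines, "## Condition theta means", "")
  ag <- stats::aggregate(cbind(theta_power, theta_itc) ~ strategy + trial_type,
                         report$scalars, mean)
  lines <- c(lines, utils::capture.output(print(ag, row.names = FALSE)), "")
  lines <- c(lines, "## Theta rm-ANOVAs (Greenhouse-Geisser corrected)", "")
  for (m in names(report$anova)) {
    lines <- c(lines, paste0("### ", m),
               utils::capture.output(print(report$anova[[m]],
                                           row.names = FALSE)), "")
  }
  lines <- c(lines, "## Behavioral interference (mean per strategy)", "")
  ia <- stats::aggregate(
    cbind(acc_interference, rt_interference) ~ strategy, report$interference,
    function(v) mean(v, na.rm = TRUE), na.action = stats::na.pass)
  lines <- c(lines, utils::capture.output(print(ia, row.names = FALSE)), "")
  lines <- c(lines, "## Residualized correlations", "",
             utils::capture.output(print(report$correlations,
                                         row.names = FALSE)), "")
  gm <- mean(report$decoding)
  lines <- c(lines, "## Decoding (16 train/test pairs)", "",
             paste0("Grand-mean accuracy: ", fmt(gm, 4)), "")
  win <- decoding_window_accuracy(report)
  lines <- c(lines, "Group-mean accuracy in 200-450 ms per pair:",
             utils::capture.output(print(win, row.names = FALSE)), "",
             paste0("Timepoints significant after BH-FDR: ",
                    sum(report$group$significant), " / ",
                    nrow(report$group)))
  lines
}

#' Group-mean decoding accuracy in a post-stimulus window, per pair
#'
#' @param report an `fmtheta_report`.
#' @param window `c(start_ms, end_ms)` over the decoding grid.
#' @return data.frame: train, test, window_accuracy.
#' @export
decoding_window_accuracy <- function(report, window = c(200, 450)) {
  sel <- report$grid$actual_ms >= window[1] &
    report$grid$actual_ms <= window[2]
  out <- expand.grid(test = STRATEGIES, train = STRATEGIES,
                     stringsAsFactors = FALSE)[, c("train", "test")]
  out$window_accuracy <- NA_real_
  for (i in seq_len(nrow(out))) {
    out$window_accuracy[i] <-
      mean(report$decoding[, out$train[i], out$test[i], sel])
  }
  out
}
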