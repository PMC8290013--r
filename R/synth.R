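# Synthetic study generator: epoched EEG with 1/f background noise plus a
# stimulus-locked, midline-peaked theta burst whose amplitude and phase
# consistency differ between control and target trials, and a behavioral
# table optionally coupled to each subject's theta effect.

#' Default per-condition trial-count distribution
#'
#' Means and SDs of trial counts for the eight conditions (four cognitive
#' control strategies crossed with control/target trial types), patterned on
#' the heterogeneous counts typical of a multi-task cognitive control battery
#' (proactive and reactive control share a frequent low-control condition, so
#' control trials vastly outnumber targets for those strategies).
#'
#' @return data.frame with columns strategy, trial_type, mean, sd.
#' @export
default_trial_counts <- function() {
  data.frame(
    strategy = rep(STRATEGIES, each = 2),
    trial_type = rep(TRIAL_TYPES, 4),
    mean = c(285.8864, 68.2784, 266.8864, 20.2898,
             164.6023, 33.2216, 114.1705, 100.6818),
    sd = c(33.0369, 8.8393, 28.1471, 6.7672,
           14.6981, 8.2595, 19.0687, 18.6768),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Assembles and validates the full parameter set of the synthetic study.
#' Defaults describe a plausible frontal-midline theta experiment: 125 Hz
#' epochs from -2500 to +3000 ms, a 6 Hz Gaussian-windowed burst in
#' 200-450 ms that is larger and more phase-locked on target than on control
#' trials, pink (1/f) background noise, and behavioral accuracy/RT whose
#' target-condition residuals are correlated with the subject's theta effect
#' at strength `behavior_coupling`.
#'
#' @param n_subjects number of subjects.
#' @param fs sampling rate in Hz.
#' @param epoch_window `c(start_ms, end_ms)` of each epoch.
#' @param channel_labels channel names; must include Fz, FCz, Cz.
#' @param topography per-channel gain of the burst (midline-peaked), named or
#'   in `channel_labels` order.
#' @param trial_counts data.frame as [default_trial_counts()]; draws are
#'   rounded and clipped below at 10 (the inclusion floor).
#' @param burst list: `center_freq` (Hz), `onset_ms`, `offset_ms`,
#'   `amplitude_control`, `amplitude_target` (uV, peak envelope),
#'   `phase_jitter_control`, `phase_jitter_target` (SD in radians of the
#'   wrapped-normal per-trial phase offset), `subject_amp_sd` (SD of the
#'   multiplicative between-subject amplitude effect).
#' @param noise list: `one_over_f_exponent`, `amplitude` (uV SD).
#' @param behavior list of condition means/SDs for accuracy and RT (see
#'   [default_behavior_model()]).
#' @param behavior_coupling correlation strength in `[-1, 1]` between a
#'   subject's theta target-vs-control effect and the target-condition
#'   residuals of accuracy and RT.
#' @param seed master integer seed.
#' @return object of class `fmtheta_config`.
#' @export
simulation_config <- function(n_subjects = 176,
                              fs = 125,
                              epoch_window = c(-2500, 3000),
                              channel_labels = c("Fz", "FCz", "Cz", "Pz", "Oz"),
                              topography = c(Fz = 0.95, FCz = 1, Cz = 0.85,
                                             Pz = 0.3, Oz = 0.1),
                              trial_counts = default_trial_counts(),
                              burst = list(),
                              noise = list(),
                              behavior = default_behavior_model(),
                              behavior_coupling = 0.2,
                              seed = 1L) {
  burst_def <- list(center_freq = 6, onset_ms = 200, offset_ms = 450,
                    amplitude_control = 4, amplitude_target = 9.7,
                    phase_jitter_control = 1.2, phase_jitter_target = 0.7,
                    subject_amp_sd = 0.2)
  burst <- utils::modifyList(burst_def, burst)
  noise_def <- list(one_over_f_exponent = 1, amplitude = 10)
  noise <- utils::modifyList(noise_def, noise)

  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (fs <= 0) stop("fs must be positive")
  if (length(epoch_window) != 2 || epoch_window[1] >= epoch_window[2])
    stop("epoch_window must be c(start_ms, end_ms) with start < end")
  if (epoch_window[1] > -500 || epoch_window[2] < 1000)
    stop("epoch_window must cover the baseline (-500..-200 ms) and the ",
         "0..1000 ms analysis grid")
  if (!all(MIDLINE_SENSORS %in% channel_labels))
    stop("channel_labels must include ", paste(MIDLINE_SENSORS, collapse = ", "))
  if (anyDuplicated(channel_labels)) stop("channel_labels must be unique")
  if (is.null(names(topography))) names(topography) <- channel_labels
  if (!all(channel_labels %in% names(topography)))
    stop("topography must name every channel")
  if (any(trial_counts$mean < 10))
    stop("trial count means must be >= 10 (inclusion floor)")
  if (burst$amplitude_control < 0 || burst$amplitude_target < 0 ||
      noise$amplitude < 0)
    stop("amplitudes must be >= 0")
  if (burst$onset_ms >= burst$offset_ms) stop("burst onset must precede offset")
  if (abs(behavior_coupling) > 1) stop("behavior_coupling must lie in [-1, 1]")

  structure(list(
    n_subjects = as.integer(n_subjects), fs = fs,
    epoch_window = epoch_window, channel_labels = channel_labels,
    topography = topography[channel_labels], trial_counts = trial_counts,
    burst = burst, noise = noise, behavior = behavior,
    behavior_coupling = behavior_coupling, seed = as.integer(seed)
  ), class = "fmtheta_config")
}

#' Default behavioral model
#'
#' Condition means for accuracy (proportion) and reaction time (ms), loosely
#' patterned on typical go/nogo, AX-CPT and flanker-style performance:
#' large accuracy interference for reactive and inhibitory control, modest
#' for response conflict, small for proactive control; RT slowing on reactive
#' and conflict targets, speeding on proactive (cue-locked) targets; no RT
#' for inhibitory targets, where the correct response is no response.
#'
#' @return list with mean/SD components consumed by [generate_subject()].
#' @export
default_behavior_model <- function() {
  list(
    acc_control = c(proactive = 0.96, reactive = 0.96,
                    inhibitory = 0.98, conflict = 0.95),
    acc_target = c(proactive = 0.918, reactive = 0.555,
                   inhibitory = 0.591, conflict = 0.837),
    rt_control = c(proactive = 600, reactive = 600,
                   inhibitory = 450, conflict = 600),
    rt_target = c(proactive = 534.4, reactive = 739, inhibitory = NA,
                  conflict = 632.1),
    acc_sd_control = 0.03, acc_sd_target = 0.06,
    rt_sd_control = 80, rt_sd_target = 60
  )
}

# Pink-noise signals: shape white-noise spectra by f^(-exponent/2) in the
# frequency domain; the shaping vector is normalized so the output variance
# equals amplitude^2. Returns an nsamp x m matrix.
one_over_f_noise <- function(nsamp, m, fs, exponent, amplitude) {
  if (amplitude == 0 || m == 0) return(matrix(0, nsamp, m))
  k <- 0:(nsamp - 1)
  f <- pmin(k, nsamp - k) * fs / nsamp # two-sided frequency magnitude
  shape <- c(0, f[-1]^(-exponent / 2)) # kill DC
  shape <- shape / sqrt(mean(shape^2))
  w <- matrix(stats::rnorm(nsamp * m), nsamp, m)
  x <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / nsamp
  x * amplitude
}

# Gaussian burst envelope centered midway between onset and offset with
# SD = (offset - onset) / 4 (times in ms, envelope evaluated on `times`).
burst_envelope <- function(times, onset_ms, offset_ms) {
  t0 <- (onset_ms + offset_ms) / 2
  sdm <- (offset_ms - onset_ms) / 4
  exp(-(times - t0)^2 / (2 * sdm^2))
}

# One condition's epochs: channels x samples x trials.
make_condition_epochs <- function(config, amp, jitter, n_trials, times) {
  nch <- length(config$channel_labels)
  nsamp <- length(times)
  b <- config$burst
  env <- burst_envelope(times, b$onset_ms, b$offset_ms)
  t0 <- (b$onset_ms + b$offset_ms) / 2
  phase_arg <- 2 * pi * b$center_freq * (times - t0) / 1000
  gains <- config$topography
  noise <- one_over_f_noise(nsamp, nch * n_trials, config$fs,
                            config$noise$one_over_f_exponent,
                            config$noise$amplitude)
  phases <- stats::rnorm(n_trials, 0, jitter) %% (2 * pi)
  dat <- array(0, dim = c(nch, nsamp, n_trials))
  for (tr in seq_len(n_trials)) {
    sig <- amp * env * cos(phase_arg + phases[tr])
    for (ch in seq_len(nch)) {
      dat[ch, , tr] <- gains[ch] * sig + noise[, (tr - 1) * nch + ch]
    }
  }
  dimnames(dat) <- list(config$channel_labels, NULL, NULL)
  dat
}

new_epoch_set <- function(subject_id, strategy, trial_type, data, times, fs,
                          channel_labels) {
  structure(list(subject_id = subject_id, strategy = strategy,
                 trial_type = trial_type, data = data, times = times, fs = fs,
                 channel_labels = channel_labels),
            class = "epoch_set")
}

#' Number of trials in an epoch set
#' @param x an `epoch_set`.
#' @return integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[3]

#' Generate one subject's data
#'
#' Produces the eight condition [epoch sets][n_trials] (4 strategies x
#' control/target) plus one behavior row per condition. The subject's RNG
#' stream is derived from `config$seed` and the subject index, so any subject
#' can be regenerated bit-identically in isolation.
#'
#' The subject carries two latent effects: `u`, the theta target-effect used
#' both to modulate target burst amplitude and (at strength
#' `behavior_coupling`) the target-condition behavioral residuals; and an
#' independent control-amplitude effect. Behavioral scores follow
#' condition mean + subject effect + coupling x theta effect + noise.
#'
#' @param config an `fmtheta_config`.
#' @param subject_index integer subject identifier (1-based).
#' @param behavior_only if TRUE, skip EEG synthesis (trial counts, latent
#'   effects and behavior are still drawn identically).
#' @return list with `epochs` (named list of 8 `epoch_set`s, or NULL),
#'   `behavior` (8-row data.frame with accuracy, rt, true theta amplitude and
#'   trial counts).
#' @export
generate_subject <- function(config, subject_index, behavior_only = FALSE) {
  stopifnot(inherits(config, "fmtheta_config"))
  seed <- derive_seed(config$seed, 101L, subject_index)
  with_seed(seed, {
    b <- config$burst
    beh <- config$behavior
    rho <- config$behavior_coupling

    # latent subject effects
    u <- stats::rnorm(1)       # theta target effect (shared across strategies)
    w <- stats::rnorm(1)       # control-amplitude effect
    z_acc <- stats::rnorm(1)   # general accuracy level
    z_rt <- stats::rnorm(1)    # general speed

    amp_control <- b$amplitude_control * max(0, 1 + b$subject_amp_sd * w)
    amp_target <- b$amplitude_target * max(0, 1 + b$subject_amp_sd * u)

    tc <- config$trial_counts
    counts <- pmax(10L, as.integer(round(stats::rnorm(nrow(tc), tc$mean, tc$sd))))

    rows <- list()
    for (i in seq_len(nrow(tc))) {
      s <- tc$strategy[i]; tt <- tc$trial_type[i]
      is_target <- tt == "target"
      if (is_target) {
        eps <- stats::rnorm(1)
        resid <- rho * u + sqrt(1 - rho^2) * eps
        acc <- beh$acc_target[s] + beh$acc_sd_control * z_acc +
          beh$acc_sd_target * resid
        eps_rt <- stats::rnorm(1)
        resid_rt <- rho * u + sqrt(1 - rho^2) * eps_rt
        rt <- if (s == "inhibitory") NA_real_ else
          beh$rt_target[s] + beh$rt_sd_control * z_rt +
            beh$rt_sd_target * resid_rt
        amp <- amp_target
      } else {
        acc <- beh$acc_control[s] + beh$acc_sd_control * z_acc
        rt <- beh$rt_control[s] + beh$rt_sd_control * z_rt
        amp <- amp_control
      }
      rows[[i]] <- data.frame(
        subject = subject_index, strategy = s, trial_type = tt,
        accuracy = min(1, max(0, acc)),
        rt = if (is.na(rt)) NA_real_ else max(150, rt),
        theta_amp = amp, n_trials = counts[i], stringsAsFactors = FALSE
      )
    }
    behavior <- do.call(rbind, rows)

    epochs <- NULL
    if (!behavior_only) {
      nsamp <- floor((config$epoch_window[2] - config$epoch_window[1]) /
                       (1000 / config$fs)) + 1
      times <- config$epoch_window[1] + (0:(nsamp - 1)) * (1000 / config$fs)
      epochs <- list()
      for (i in seq_len(nrow(tc))) {
        s <- tc$strategy[i]; tt <- tc$trial_type[i]
        amp <- if (tt == "target") amp_target else amp_control
        jit <- if (tt == "target") b$phase_jitter_target else b$phase_jitter_control
        dat <- make_condition_epochs(config, amp, jit, counts[i], times)
        epochs[[paste(s, tt, sep = ".")]] <-
          new_epoch_set(subject_index, s, tt, dat, times, config$fs,
                        config$channel_labels)
      }
    }
    list(epochs = epochs, behavior = behavior)
  })
}

#' Generate a full synthetic study
#'
#' @param config an `fmtheta_config`.
#' @param behavior_only if TRUE, omit EEG arrays (fast; for behavioral and
#'   coupling-recovery analyses).
#' @return list of class `fmtheta_study`: `config`, `subjects` (list of
#'   per-subject epoch lists, or NULL), `behavior` (stacked table).
#' @export
generate_study <- function(config, behavior_only = FALSE) {
  subs <- lapply(seq_len(config$n_subjects), generate_subject,
                 config = config, behavior_only = behavior_only)
  structure(list(
    config = config,
    subjects = if (behavior_only) NULL else lapply(subs, `[[`, "epochs"),
    behavior = do.call(rbind, lapply(subs, `[[`, "behavior"))
  ), class = "fmtheta_study")
}

#' Null (no-effect) variant of a configuration
#'
#' Returns a config in which target trials are generated from exactly the
#' control distribution: same burst amplitude and phase jitter, no
#' between-subject amplitude modulation (it is drawn independently per trial
#' type, so leaving it on would induce a decodable within-subject class
#' difference even with equal mean amplitudes), and zero behavioral coupling.
#' Every downstream condition contrast is then null by construction.
#'
#' @param config an `fmtheta_config`.
#' @return modified `fmtheta_config`.
#' @export
null_config <- function(config) {
  config$burst$amplitude_target <- config$burst$amplitude_control
  config$burst$phase_jitter_target <- config$burst$phase_jitter_control
  config$burst$subject_amp_sd <- 0
  config$behavior_coupling <- 0
  config
}
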