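# Complex Morlet wavelet time-frequency decomposition, dB-baselined ERSP,
# inter-trial coherence, and trial-count-equalizing subsampling.

#' Adaptive cycle count for a wavelet frequency
#'
#' Cycles increase linearly from 3 at 1 Hz to 10 at 25 Hz, trading temporal
#' resolution at low frequencies against frequency resolution at high ones.
#'
#' @param f frequency in Hz, within `[1, 25]`.
#' @return cycle count(s).
#' @export
cycles_for_frequency <- function(f) {
  if (any(f < 1 | f > 25)) stop("frequency must lie in [1, 25] Hz")
  3 + (f - 1) * (10 - 3) / (25 - 1)
}

#' Build a complex Morlet wavelet family
#'
#' Each kernel is `exp(i 2 pi f t) * exp(-t^2 / (2 sigma^2))` with
#' `sigma = s / (2 pi f)` where `s` is the adaptive cycle count; kernels are
#' sampled at `fs` on a symmetric grid truncated at +/- 3 sigma and are not
#' amplitude-normalized (normalization cancels in the ERSP dB ratio and is
#' irrelevant to phase).
#'
#' @param frequencies Hz; default 25 linearly spaced bins from 1 to 25.
#' @param fs sampling rate (Hz); must exceed twice the highest frequency.
#' @return object of class `wavelet_family`.
#' @export
build_wavelets <- function(frequencies = 1:25, fs = 125) {
  if (any(diff(frequencies) <= 0) || any(frequencies <= 0))
    stop("frequencies must be strictly increasing and positive")
  if (fs <= 2 * max(frequencies))
    stop("sampling rate ", fs, " Hz violates the Nyquist limit for ",
         max(frequencies), " Hz")
  cycles <- cycles_for_frequency(frequencies)
  sigma <- cycles / (2 * pi * frequencies)
  kernels <- vector("list", length(frequencies))
  taxes <- vector("list", length(frequencies))
  for (i in seq_along(frequencies)) {
    h <- ceiling(3 * sigma[i] * fs)
    t <- (-h:h) / fs
    kernels[[i]] <- exp(1i * 2 * pi * frequencies[i] * t) *
      exp(-t^2 / (2 * sigma[i]^2))
    taxes[[i]] <- t
  }
  structure(list(frequencies = frequencies, cycles = cycles, sigma = sigma,
                 kernels = kernels, t = taxes, fs = fs),
            class = "wavelet_family")
}

# next power of two >= n
next_pow2 <- function(n) 2^ceiling(log2(n))

#' Convolve epoched EEG with a wavelet family
#'
#' FFT-based convolution with "same" alignment, returning per-trial complex
#' coefficients for every requested channel and frequency. Samples within
#' 3 sigma of the lowest frequency from either epoch boundary are flagged
#' invalid (`valid` attribute) rather than dropped, since edge artifacts
#' contaminate them.
#'
#' @param epochs an `epoch_set`.
#' @param family a `wavelet_family` sampled at the epoch's `fs`.
#' @param channels channel labels to decompose (default all).
#' @return object of class `tf_coefficients`: complex array
#'   channel x frequency x time x trial, plus `times`, `frequencies`,
#'   `channels`, `valid` (logical per time sample).
#' @export
convolve_epochs <- function(epochs, family, channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(family, "wavelet_family"))
  if (abs(family$fs - epochs$fs) > 1e-9)
    stop("wavelet family sampled at ", family$fs, " Hz but epochs at ",
         epochs$fs, " Hz")
  if (is.null(channels)) channels <- epochs$channel_labels
  missing_ch <- setdiff(channels, epochs$channel_labels)
  if (length(missing_ch))
    stop("channels not present: ", paste(missing_ch, collapse = ", "),
         "; available: ", paste(epochs$channel_labels, collapse = ", "))

  nsamp <- length(epochs$times)
  klen <- lengths(family$kernels)
  too_long <- klen > nsamp
  if (any(too_long))
    stop("epoch too short for wavelet at ",
         family$frequencies[which(too_long)[1]], " Hz (kernel ",
         klen[which(too_long)[1]], " samples, epoch ", nsamp, ")")

  nch <- length(channels)
  ntr <- dim(epochs$data)[3]
  nfreq <- length(family$frequencies)
  N <- next_pow2(nsamp + max(klen) - 1)

  # signals as columns: (channel varies fastest within trial)
  sig <- matrix(0, N, nch * ntr)
  dat <- epochs$data[channels, , , drop = FALSE]
  for (tr in seq_len(ntr)) {
    sig[1:nsamp, ((tr - 1) * nch + 1):(tr * nch)] <- t(dat[, , tr])
  }
  SIG <- stats::mvfft(sig)

  out <- array(complex(real = 0), dim = c(nch, nfreq, nsamp, ntr))
  for (fi in seq_len(nfreq)) {
    ker <- c(family$kernels[[fi]], rep(0, N - klen[fi]))
    conv <- stats::mvfft(SIG * stats::fft(ker), inverse = TRUE) / N
    h <- (klen[fi] - 1) / 2
    cs <- conv[(h + 1):(h + nsamp), , drop = FALSE]
    for (tr in seq_len(ntr)) {
      out[, fi, , tr] <- t(cs[, ((tr - 1) * nch + 1):(tr * nch), drop = FALSE])
    }
  }
  dimnames(out) <- list(channels, NULL, NULL, NULL)

  h_low <- (klen[1] - 1) / 2 # lowest frequency = widest kernel half-width (3 sigma)
  valid <- rep(TRUE, nsamp)
  if (h_low >= 1) valid[c(1:h_low, (nsamp - h_low + 1):nsamp)] <- FALSE

  structure(list(coef = out, times = epochs$times,
                 frequencies = family$frequencies, channels = channels,
                 valid = valid, fs = epochs$fs),
            class = "tf_coefficients")
}

#' Event-related spectral perturbation (dB power)
#'
#' Trial-mean power `Re(z)^2 + Im(z)^2` is divided by its own time-mean over
#' the pre-stimulus baseline window (per channel and frequency) and expressed
#' as `10 * log10(power(t) / power(baseline))`. Baselining uses the
#' trial-averaged power (divisive), then the log.
#'
#' @param coeffs `tf_coefficients`.
#' @param baseline_window `c(start_ms, end_ms)` pre-stimulus window.
#' @return object of class `ersp_map`: `db` array channel x frequency x time.
#' @export
ersp <- function(coeffs, baseline_window = c(-500, -200)) {
  stopifnot(inherits(coeffs, "tf_coefficients"))
  bidx <- which(coeffs$times >= baseline_window[1] &
                  coeffs$times <= baseline_window[2])
  if (!length(bidx)) stop("baseline window outside coefficient time axis")
  if (!all(coeffs$valid[bidx]))
    stop("baseline window overlaps edge-contaminated samples")
  pw <- Re(coeffs$coef)^2 + Im(coeffs$coef)^2
  power <- rowMeans(pw, dims = 3) # mean over trials
  base <- rowMeans(power[, , bidx, drop = FALSE], dims = 2)
  if (any(base <= 0))
    stop("zero baseline power: degenerate input")
  db <- 10 * log10(sweep(power, c(1, 2), base, "/"))
  dimnames(db)[[1]] <- coeffs$channels
  structure(list(db = db, times = coeffs$times,
                 frequencies = coeffs$frequencies, channels = coeffs$channels,
                 valid = coeffs$valid, baseline_window = baseline_window,
                 n_trials = dim(coeffs$coef)[4]),
            class = "ersp_map")
}

#' Inter-trial coherence
#'
#' The modulus of the across-trial mean unit phasor `|mean(z/|z|)|` at every
#' channel, frequency and time point. Points where a trial's coefficient is
#' exactly zero (phase undefined) are excluded from that point's mean, with
#' `n` reduced accordingly.
#'
#' @param coeffs `tf_coefficients`.
#' @return object of class `itc_map`: `itc` array channel x frequency x time
#'   with all values in `[0, 1]`.
#' @export
itc <- function(coeffs) {
  stopifnot(inherits(coeffs, "tf_coefficients"))
  modz <- Mod(coeffs$coef)
  phasor <- coeffs$coef / modz
  phasor[modz == 0] <- NA_complex_
  n_excluded <- sum(modz == 0)
  if (n_excluded > 0)
    message("itc: excluded ", n_excluded,
            " zero-amplitude points (phase undefined)")
  s <- rowSums(phasor, na.rm = TRUE, dims = 3)
  n_ok <- rowSums(!is.na(phasor), dims = 3)
  m <- Mod(s) / pmax(n_ok, 1)
  m[n_ok == 0] <- NA_real_
  m <- pmin(m, 1) # guard rounding
  dimnames(m)[[1]] <- coeffs$channels
  structure(list(itc = m, times = coeffs$times,
                 frequencies = coeffs$frequencies, channels = coeffs$channels,
                 valid = coeffs$valid, n_trials = dim(coeffs$coef)[4]),
            class = "itc_map")
}

#' Minimum trial count across a subject's eight conditions
#'
#' @param subject_epochs named list of 8 `epoch_set`s (strategy.trial_type).
#' @return integer minimum trial count.
#' @export
min_condition_count <- function(subject_epochs) {
  expected <- paste(rep(STRATEGIES, each = 2), TRIAL_TYPES, sep = ".")
  missing_c <- setdiff(expected, names(subject_epochs))
  if (length(missing_c))
    stop("missing conditions: ", paste(missing_c, collapse = ", "))
  min(vapply(subject_epochs[expected], n_trials, integer(1)))
}

#' Equalize trial counts across a subject's conditions by random subsampling
#'
#' Each condition is subsampled without replacement to `count` trials,
#' removing the trial-count bias that would otherwise confound ITC
#' comparisons. Subjects with any condition below 10 trials fail the
#' inclusion rule and raise an error.
#'
#' @param subject_epochs named list of 8 `epoch_set`s.
#' @param count target trial count (default: the minimum across conditions).
#' @param seed integer seed making the draw reproducible.
#' @return the epoch list with every condition at exactly `count` trials.
#' @export
subsample_equalize <- function(subject_epochs, count = NULL, seed = 1L) {
  counts <- vapply(subject_epochs, n_trials, integer(1))
  if (any(counts < 10))
    stop("subject excluded: condition(s) below the 10-trial inclusion floor: ",
         paste(names(counts)[counts < 10], collapse = ", "))
  if (is.null(count)) count <- min_condition_count(subject_epochs)
  if (count < 1) stop("count must be >= 1")
  if (any(counts < count))
    stop("cannot subsample to ", count, ": some conditions have fewer trials")
  with_seed(seed, {
    for (nm in names(subject_epochs)) {
      keep <- sort(sample.int(n_trials(subject_epochs[[nm]]), count))
      subject_epochs[[nm]]$data <-
        subject_epochs[[nm]]$data[, , keep, drop = FALSE]
    }
    subject_epochs
  })
}
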