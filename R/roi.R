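# Frontal-midline theta region-of-interest summaries: scalar ERSP/ITC means
# over {Fz, FCz, Cz} x 4-8 Hz x 200-450 ms, and per-trial theta power time
# courses used as decoding features.

#' Scalar ROI summary of an ERSP or ITC map
#'
#' Unweighted mean of the map over the requested sensors, frequency band and
#' time window. The default ROI is the frontal-midline theta index: Fz, FCz,
#' Cz; 4-8 Hz; 200-450 ms post-stimulus.
#'
#' @param map an `ersp_map` or `itc_map`.
#' @param sensors channel labels entering the mean.
#' @param band `c(low, high)` Hz, inclusive.
#' @param window `c(start_ms, end_ms)`, inclusive.
#' @return single numeric (dB for ERSP, coherence for ITC).
#' @export
extract_scalar <- function(map, sensors = MIDLINE_SENSORS, band = c(4, 8),
                           window = c(200, 450)) {
  vals <- if (inherits(map, "ersp_map")) map$db
          else if (inherits(map, "itc_map")) map$itc
          else stop("map must be an ersp_map or itc_map")
  missing_s <- setdiff(sensors, map$channels)
  if (length(missing_s))
    stop("sensor(s) not present: ", paste(missing_s, collapse = ", "),
         "; available: ", paste(map$channels, collapse = ", "))
  fidx <- which(map$frequencies >= band[1] & map$frequencies <= band[2])
  if (!length(fidx)) stop("no frequency bins inside band")
  tidx <- which(map$times >= window[1] & map$times <= window[2])
  if (!length(tidx)) stop("no time samples inside window")
  if (!all(map$valid[tidx]))
    stop("window overlaps edge-contaminated samples")
  mean(vals[sensors, fidx, tidx])
}

#' Per-trial theta power time courses at the midline sensors
#'
#' For each trial and sensor, single-trial power averaged over the theta
#' frequency bins, as a function of time, in linear units (no dB baseline:
#' these are single-trial classifier features, and the linear discriminant is
#' invariant to per-feature affine rescaling).
#'
#' @param coeffs `tf_coefficients` containing the requested sensors and band.
#' @param sensors sensor labels (default Fz, FCz, Cz).
#' @param band `c(low, high)` Hz.
#' @return object of class `theta_timecourses`: `power` array
#'   trial x sensor x time, plus `times`, `valid`, `sensors`.
#' @export
theta_timecourses <- function(coeffs, sensors = MIDLINE_SENSORS,
                              band = c(4, 8)) {
  stopifnot(inherits(coeffs, "tf_coefficients"))
  missing_s <- setdiff(sensors, coeffs$channels)
  if (length(missing_s))
    stop("sensor(s) not present: ", paste(missing_s, collapse = ", "),
         "; available: ", paste(coeffs$channels, collapse = ", "))
  fidx <- which(coeffs$frequencies >= band[1] & coeffs$frequencies <= band[2])
  if (!length(fidx)) stop("no frequency bins inside band")
  z <- coeffs$coef[sensors, fidx, , , drop = FALSE]
  pw <- Re(z)^2 + Im(z)^2
  # mean over frequency bins -> sensor x time x trial, then trial-first
  m <- colMeans(aperm(pw, c(2, 1, 3, 4)))
  out <- aperm(m, c(3, 1, 2))
  dimnames(out) <- list(NULL, sensors, NULL)
  structure(list(power = out, times = coeffs$times, valid = coeffs$valid,
                 sensors = sensors, band = band),
            class = "theta_timecourses")
}
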