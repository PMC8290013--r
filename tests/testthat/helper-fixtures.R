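# Shared fixtures: small, fast study configurations and hand-built epoch
# sets for oracle tests.

# Compact study: 3 midline channels only, short epochs (still covering the
# baseline and the 0-1000 ms grid with the theta-band edge margin), equal
# small trial counts.
small_config <- function(n_subjects = 2, n_trials = 14, seed = 11L, ...) {
  tc <- default_trial_counts()
  tc$mean <- n_trials
  tc$sd <- 0
  simulation_config(
    n_subjects = n_subjects,
    epoch_window = c(-1200, 1500),
    channel_labels = c("Fz", "FCz", "Cz"),
    topography = c(Fz = 0.95, FCz = 1, Cz = 0.85),
    trial_counts = tc,
    seed = seed,
    ...
  )
}

# Build an epoch_set directly from a channels x samples x trials array.
make_epoch_set <- function(data, fs = 125, t_start = -1200,
                           channel_labels = NULL) {
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(dim(data)[1]))
  dimnames(data) <- list(channel_labels, NULL, NULL)
  times <- t_start + (seq_len(dim(data)[2]) - 1) * (1000 / fs)
  structure(list(subject_id = 1L, strategy = "reactive",
                 trial_type = "control", data = data, times = times, fs = fs,
                 channel_labels = channel_labels),
            class = "epoch_set")
}

# Single-channel epoch set holding the same signal in every trial.
sine_epochs <- function(signal_fun, n_trials = 1, fs = 125, t_start = -1200,
                        t_end = 1500) {
  nsamp <- floor((t_end - t_start) / (1000 / fs)) + 1
  times <- t_start + (0:(nsamp - 1)) * (1000 / fs)
  dat <- array(0, dim = c(1, nsamp, n_trials))
  for (tr in seq_len(n_trials)) dat[1, , tr] <- signal_fun(times / 1000, tr)
  make_epoch_set(dat, fs = fs, t_start = t_start, channel_labels = "Fz")
}

# Reference implementation of Benjamini-Hochberg step-up: returns the
# logical rejection vector at level q.
bh_stepup_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- rep(FALSE, m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}
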