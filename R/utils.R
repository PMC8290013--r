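#' @keywords internal
"_PACKAGE"

STRATEGIES <- c("proactive", "reactive", "inhibitory", "conflict")
TRIAL_TYPES <- c("control", "target")
MIDLINE_SENSORS <- c("Fz", "FCz", "Cz")

#' Derive a child seed from a master seed and a stream of integer keys
#'
#' Deterministic Lehmer-style mixing so that every stage, subject, repetition
#' and pair gets its own reproducible RNG stream while staying inside the
#' 32-bit integer range `set.seed()` accepts.
#'
#' @param master integer master seed.
#' @param ... integer keys identifying the stream (stage, subject index, ...).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  keys <- c(master, ...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- 0
  for (k in keys) {
    s <- (s * 48271 + (as.numeric(k) %% m) + 11) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Index of the sample nearest to each requested time (ms); errors if outside.
nearest_time_index <- function(times, targets) {
  vapply(targets, function(tt) {
    if (tt < min(times) - 1e-9 || tt > max(times) + 1e-9) {
      stop("requested time ", tt, " ms outside epoch axis [",
           min(times), ", ", max(times), "]")
    }
    which.min(abs(times - tt))
  }, integer(1))
}
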