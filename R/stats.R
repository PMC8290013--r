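# Behavioral and theta statistics: interference scores, paired t-tests,
# repeated-measures ANOVA with Greenhouse-Geisser correction and partial
# eta^2, Bonferroni post-hocs, and residualized Pearson correlations for
# individual-differences analysis.

#' Behavioral interference scores
#'
#' Accuracy interference = control accuracy - target accuracy (percentage
#' points, positive = cost of control). RT interference = target RT -
#' control RT (ms, positive = slowing); absent for inhibitory control,
#' where targets require no response.
#'
#' @param behavior data.frame with subject, strategy, trial_type, accuracy,
#'   rt (as produced by [generate_study()]).
#' @return data.frame: subject, strategy, acc_interference, rt_interference.
#' @export
interference <- function(behavior) {
  need <- c("subject", "strategy", "trial_type", "accuracy", "rt")
  if (!all(need %in% names(behavior)))
    stop("behavior table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (s in unique(behavior$strategy)) {
    ctl <- behavior[behavior$strategy == s & behavior$trial_type == "control", ]
    tgt <- behavior[behavior$strategy == s & behavior$trial_type == "target", ]
    m <- merge(ctl, tgt, by = "subject", suffixes = c("_c", "_t"))
    out[[s]] <- data.frame(
      subject = m$subject, strategy = s,
      acc_interference = 100 * (m$accuracy_c - m$accuracy_t),
      rt_interference = m$rt_t - m$rt_c,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired t-test
#'
#' @param x,y paired numeric vectors.
#' @return list with `t`, `df`, `p`, `mean_difference` (x - y).
#' @export
paired_t <- function(x, y) {
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_difference = unname(ht$estimate))
}

# orthonormal contrast matrix for k levels (columns orthonormal, each
# orthogonal to the unit vector)
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Greenhouse-Geisser epsilon from the covariance of orthonormalized
# within-subject contrast scores (n x d matrix M = Y %*% C)
gg_epsilon <- function(M) {
  d <- ncol(M)
  if (d == 1) return(1)
  S <- stats::cov(M)
  if (sum(S^2) == 0) return(1) # degenerate (constant contrasts)
  eps <- sum(diag(S))^2 / (d * sum(S^2))
  min(1, max(1 / d, eps))
}

anova_row <- function(effect, ss_eff, df_eff, ss_err, df_err, eps) {
  if (ss_err <= 0) {
    if (ss_eff <= 0) {
      # completely flat data: no effect, by convention F = 0
      return(list(effect = effect, F = 0, df_num = df_eff, df_den = df_err,
                  epsilon = 1, p = 1, p_uncorrected = 1, partial_eta_sq = 0))
    }
    warning("zero error sum of squares for effect '", effect, "'; F undefined")
    return(list(effect = effect, F = NA_real_, df_num = NA_real_,
                df_den = NA_real_, epsilon = NA_real_, p = NA_real_,
                p_uncorrected = NA_real_, partial_eta_sq = NA_real_))
  }
  F <- (ss_eff / df_eff) / (ss_err / df_err)
  list(effect = effect, F = F, df_num = eps * df_eff, df_den = eps * df_err,
       epsilon = eps,
       p = stats::pf(F, eps * df_eff, eps * df_err, lower.tail = FALSE),
       p_uncorrected = stats::pf(F, df_eff, df_err, lower.tail = FALSE),
       partial_eta_sq = ss_eff / (ss_eff + ss_err))
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard within-subject decomposition; the sphericity correction
#' multiplies both degrees of freedom by the Greenhouse-Geisser epsilon
#' estimated from the sample covariance of orthonormalized contrasts.
#' Partial eta^2 = SS_effect / (SS_effect + SS_error).
#'
#' @param y numeric matrix, subjects x levels (complete cases only).
#' @return data.frame with effect, F, df_num, df_den, epsilon, p (GG),
#'   p_uncorrected, partial_eta_sq.
#' @export
one_way_rm_anova <- function(y) {
  y <- as.matrix(y)
  if (anyNA(y)) stop("complete cases only")
  n <- nrow(y); k <- ncol(y)
  if (n < 3) stop("at least 3 subjects required")
  grand <- mean(y)
  col_m <- colMeans(y); row_m <- rowMeans(y)
  ss_eff <- n * sum((col_m - grand)^2)
  resid <- y - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ss_err <- sum(resid^2)
  eps <- gg_epsilon(y %*% orthonormal_contrasts(k))
  as.data.frame(anova_row("level", ss_eff, k - 1, ss_err, (n - 1) * (k - 1),
                          eps))
}

#' Two-way repeated-measures ANOVA (both factors within) with GG correction
#'
#' Decomposes a subject x A x B cube into the two main effects and their
#' interaction, each tested against its own subject-by-effect error term,
#' with a separate Greenhouse-Geisser epsilon per effect (epsilon is
#' identically 1 for a 2-level factor).
#'
#' @param y numeric array, subjects x levels(A) x levels(B).
#' @param factor_names names of the two factors.
#' @return data.frame, one row per effect (A, B, A:B).
#' @export
two_way_rm_anova <- function(y, factor_names = c("A", "B")) {
  stopifnot(length(dim(y)) == 3)
  if (anyNA(y)) stop("complete cases only")
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  if (n < 3) stop("at least 3 subjects required")
  grand <- mean(y)
  m_i <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_ia <- apply(y, c(1, 2), mean)
  m_ib <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)

  ss_A <- n * b * sum((m_a - grand)^2)
  ss_AS <- b * sum((m_ia - outer(m_i, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_B <- n * a * sum((m_b - grand)^2)
  ss_BS <- a * sum((m_ib - outer(m_i, rep(1, b)) -
                      outer(rep(1, n), m_b) + grand)^2)
  ss_AB <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  resid <- y
  for (i in 1:n) for (j in 1:a) for (l in 1:b) {
    resid[i, j, l] <- y[i, j, l] - m_ia[i, j] - m_ib[i, l] - m_ab[j, l] +
      m_i[i] + m_a[j] + m_b[l] - grand
  }
  ss_ABS <- sum(resid^2)

  Yflat <- matrix(y, n, a * b) # cell (j,l) at column (l-1)*a + j
  Ca <- orthonormal_contrasts(a); Cb <- orthonormal_contrasts(b)
  one_a <- rep(1, a) / sqrt(a); one_b <- rep(1, b) / sqrt(b)
  C_A <- kronecker(one_b, Ca)
  C_B <- kronecker(Cb, one_a)
  C_AB <- kronecker(Cb, Ca)

  rows <- rbind(
    as.data.frame(anova_row(factor_names[1], ss_A, a - 1, ss_AS,
                            (n - 1) * (a - 1), gg_epsilon(Yflat %*% C_A))),
    as.data.frame(anova_row(factor_names[2], ss_B, b - 1, ss_BS,
                            (n - 1) * (b - 1), gg_epsilon(Yflat %*% C_B))),
    as.data.frame(anova_row(paste(factor_names, collapse = ":"), ss_AB,
                            (a - 1) * (b - 1), ss_ABS,
                            (n - 1) * (a - 1) * (b - 1),
                            gg_epsilon(Yflat %*% C_AB)))
  )
  rownames(rows) <- NULL
  rows
}

#' Bonferroni-corrected pairwise post-hoc comparisons
#'
#' All pairwise paired t-tests among the columns of `y`; p-values multiplied
#' by the family size (number of comparisons), capped at 1.
#'
#' @param y numeric matrix, subjects x levels, with column names.
#' @return data.frame: level_a, level_b, mean_difference, t, df, p_raw,
#'   p_adj, n_comparisons.
#' @export
bonferroni_posthoc <- function(y) {
  y <- as.matrix(y)
  k <- ncol(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("level", seq_len(k))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ht <- paired_t(y[, a], y[, b])
    rows[[i]] <- data.frame(
      level_a = colnames(y)[a], level_b = colnames(y)[b],
      mean_difference = ht$mean_difference, t = ht$t, df = ht$df,
      p_raw = ht$p, p_adj = min(1, ht$p * m), n_comparisons = m,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Residualize target-condition scores by their control-condition scores
#'
#' Ordinary least-squares residuals of target on control (intercept
#' included), isolating the control-related component without the
#' psychometric drawbacks of raw difference scores.
#'
#' @param target,control paired numeric vectors.
#' @return numeric residual vector.
#' @export
residualize <- function(target, control) {
  if (length(target) != length(control)) stop("vectors must be paired")
  ok <- stats::complete.cases(target, control)
  if (sum(ok) < 4) stop("need at least 4 complete pairs")
  res <- rep(NA_real_, length(target))
  if (stats::var(control[ok]) == 0) {
    message("residualize: zero-variance predictor; returning centered target")
    res[ok] <- target[ok] - mean(target[ok])
  } else {
    res[ok] <- stats::resid(stats::lm(target[ok] ~ control[ok]))
  }
  res
}

#' Pearson correlation with test
#'
#' @param x,y numeric vectors (pairwise complete).
#' @return list with `r`, `df` (n - 2), `p` (two-sided), `conf_int` (95%).
#' @export
correlate <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  ht <- stats::cor.test(x[ok], y[ok])
  list(r = unname(ht$estimate), df = unname(ht$parameter), p = ht$p.value,
       conf_int = as.numeric(ht$conf.int))
}

#' Residualized individual-differences correlation table
#'
#' For each strategy, residualizes target accuracy, RT, theta power and
#' theta ITC by their control-condition counterparts, then correlates the
#' residualized behavioral measures with the residualized theta measures
#' (RT omitted for inhibitory control).
#'
#' @param behavior behavior table (subject, strategy, trial_type, accuracy,
#'   rt).
#' @param theta data.frame: subject, strategy, trial_type, theta_power,
#'   theta_itc.
#' @return data.frame: strategy, theta_measure, behavioral_measure, r, df, p.
#' @export
individual_differences <- function(behavior, theta) {
  d <- merge(behavior, theta, by = c("subject", "strategy", "trial_type"))
  out <- list()
  for (s in unique(d$strategy)) {
    ctl <- d[d$strategy == s & d$trial_type == "control", ]
    tgt <- d[d$strategy == s & d$trial_type == "target", ]
    m <- merge(ctl, tgt, by = "subject", suffixes = c("_c", "_t"))
    rp <- residualize(m$theta_power_t, m$theta_power_c)
    ri <- residualize(m$theta_itc_t, m$theta_itc_c)
    ra <- residualize(m$accuracy_t, m$accuracy_c)
    rr <- if (s == "inhibitory") NULL else residualize(m$rt_t, m$rt_c)
    for (tm in c("theta_power", "theta_itc")) {
      rth <- if (tm == "theta_power") rp else ri
      ca <- correlate(rth, ra)
      out[[length(out) + 1]] <- data.frame(
        strategy = s, theta_measure = tm, behavioral_measure = "accuracy",
        r = ca$r, df = ca$df, p = ca$p, stringsAsFactors = FALSE)
      if (!is.null(rr)) {
        cr <- correlate(rth, rr)
        out[[length(out) + 1]] <- data.frame(
          strategy = s, theta_measure = tm, behavioral_measure = "rt",
          r = cr$r, df = cr$df, p = cr$p, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
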