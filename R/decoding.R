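# Cross-strategy single-trial decoding: control vs target trials classified
# by a regularized linear discriminant at each timepoint of a 0-1000 ms grid,
# with class-equalizing subsampling, fivefold cross-validation, repetition
# averaging, and group-level FDR-controlled inference over all 16
# train/test strategy pairs.

#' Balanced class index sets by random subsampling
#'
#' Both classes are subsampled without replacement to the smaller count, so
#' chance classification accuracy is exactly 0.5.
#'
#' @param n_control,n_target trial counts of the two classes.
#' @param seed integer seed.
#' @return list with integer index vectors `control` and `target`.
#' @export
equalize_classes <- function(n_control, n_target, seed = 1L) {
  if (n_control < 2 || n_target < 2)
    stop("both classes need at least 2 trials")
  m <- min(n_control, n_target)
  with_seed(seed, list(
    control = sort(sample.int(n_control, m)),
    target = sort(sample.int(n_target, m))
  ))
}

#' Fit a regularized linear discriminant
#'
#' Pooled within-class covariance shrunk toward its diagonal,
#' `S <- (1 - lambda) S + lambda diag(diag(S))`, with equal priors. The
#' decision rule is the usual linear discriminant; exact ties are broken
#' toward the label with lower sort order.
#'
#' @param x numeric matrix, trials x features.
#' @param y labels with exactly two levels.
#' @param shrinkage shrinkage coefficient lambda in `[0, 1]` (default 0.05).
#' @return object of class `lda_model`.
#' @export
lda_fit <- function(x, y, shrinkage = 0.05) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("exactly two classes required")
  i0 <- y == classes[1]; i1 <- y == classes[2]
  if (sum(i0) < 2 || sum(i1) < 2) stop("each class needs >= 2 trials")
  m0 <- colMeans(x[i0, , drop = FALSE])
  m1 <- colMeans(x[i1, , drop = FALSE])
  c0 <- sweep(x[i0, , drop = FALSE], 2, m0)
  c1 <- sweep(x[i1, , drop = FALSE], 2, m1)
  S <- (crossprod(c0) + crossprod(c1)) / (nrow(x) - 2)
  S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(x))
  # guard all-zero features
  dg <- diag(S)
  if (any(dg <= 0)) diag(S) <- dg + 1e-12
  w <- solve(S, m1 - m0)
  structure(list(classes = classes, means = rbind(m0, m1), w = w,
                 threshold = sum(w * (m0 + m1)) / 2, shrinkage = shrinkage),
            class = "lda_model")
}

#' Predict class labels from a fitted linear discriminant
#'
#' @param model an `lda_model`.
#' @param x matrix trials x features.
#' @return character vector of predicted labels.
#' @export
lda_predict <- function(model, x) {
  x <- as.matrix(x)
  score <- drop(x %*% model$w)
  ifelse(score > model$threshold, model$classes[2], model$classes[1])
}

#' Decoding timepoint grid
#'
#' Nominal grid 0-1000 ms in 20 ms steps (51 points) snapped to the nearest
#' recorded sample (no interpolation); at 125 Hz the 8 ms sample period does
#' not divide 20 ms.
#'
#' @param times epoch time axis (ms).
#' @param from,to,by nominal grid (ms).
#' @return list with `nominal_ms`, `index`, `actual_ms`.
#' @export
decoding_grid <- function(times, from = 0, to = 1000, by = 20) {
  nominal <- seq(from, to, by = by)
  idx <- nearest_time_index(times, nominal)
  list(nominal_ms = nominal, index = idx, actual_ms = times[idx])
}

# z-score features per sensor using pooled statistics over all trials and
# grid timepoints of the two classes (affine per-feature, so LDA decisions
# are unchanged; purely numerical conditioning).
zscore_features <- function(fc, ft) {
  for (s in seq_len(dim(fc)[2])) {
    v <- c(fc[, s, ], ft[, s, ])
    mu <- mean(v); sd <- stats::sd(v)
    if (!is.finite(sd) || sd == 0) sd <- 1
    fc[, s, ] <- (fc[, s, ] - mu) / sd
    ft[, s, ] <- (ft[, s, ] - mu) / sd
  }
  list(control = fc, target = ft)
}

# fold assignment: n trials into k folds, sizes as equal as possible, random
fold_assign <- function(n, k) sample(rep_len(seq_len(k), n))

#' Decode control vs target for one train/test strategy pair
#'
#' Per repetition: fresh class equalization and fold partitions. Fold `j`
#' trains a linear discriminant on the training strategy's folds `!= j` and
#' tests on the test strategy's fold `j` (for same-strategy decoding a single
#' partition guarantees train/test disjointness). Accuracy per timepoint is
#' averaged over `reps x k` fold evaluations.
#'
#' @param features_train,features_test lists with `control` and `target`
#'   arrays (trial x sensor x grid-timepoint), for the training and testing
#'   strategies; pass the same object for same-strategy decoding.
#' @param same_strategy logical; if TRUE the training and testing sets share
#'   one equalization and one fold partition.
#' @param k folds (default 5; reduced with a message if trials are too few).
#' @param reps repetitions (default 3).
#' @param seed integer seed.
#' @param shrinkage LDA shrinkage.
#' @return numeric vector of accuracies, one per grid timepoint.
#' @export
decode_pair <- function(features_train, features_test, same_strategy = FALSE,
                        k = 5, reps = 3, seed = 1L, shrinkage = 0.05) {
  ztr <- zscore_features(features_train$control, features_train$target)
  zte <- if (same_strategy) ztr
         else zscore_features(features_test$control, features_test$target)
  ntp <- dim(ztr$control)[3]
  acc <- matrix(0, reps, ntp)
  for (r in seq_len(reps)) {
    rs <- derive_seed(seed, 7L, r)
    with_seed(rs, {
      eq_tr <- equalize_classes(dim(ztr$control)[1], dim(ztr$target)[1],
                                seed = derive_seed(rs, 1L))
      m_tr <- length(eq_tr$control)
      kk <- min(k, m_tr)
      if (kk < k)
        message("decode_pair: folds reduced to ", kk, " (only ", m_tr,
                " trials per class)")
      folds_tr <- fold_assign(m_tr, kk)
      if (same_strategy) {
        eq_te <- eq_tr; folds_te <- folds_tr
      } else {
        eq_te <- equalize_classes(dim(zte$control)[1], dim(zte$target)[1],
                                  seed = derive_seed(rs, 2L))
        folds_te <- fold_assign(length(eq_te$control), kk)
      }
      a <- matrix(NA_real_, kk, ntp)
      for (j in seq_len(kk)) {
        itr_c <- eq_tr$control[folds_tr != j]
        itr_t <- eq_tr$target[folds_tr != j]
        ite_c <- eq_te$control[folds_te == j]
        ite_t <- eq_te$target[folds_te == j]
        y_tr <- rep(c("control", "target"), c(length(itr_c), length(itr_t)))
        y_te <- rep(c("control", "target"), c(length(ite_c), length(ite_t)))
        for (tp in seq_len(ntp)) {
          xtr <- rbind(ztr$control[itr_c, , tp, drop = FALSE][, , 1],
                       ztr$target[itr_t, , tp, drop = FALSE][, , 1])
          xte <- rbind(zte$control[ite_c, , tp, drop = FALSE][, , 1],
                       zte$target[ite_t, , tp, drop = FALSE][, , 1])
          fit <- lda_fit(xtr, y_tr, shrinkage = shrinkage)
          a[j, tp] <- mean(lda_predict(fit, xte) == y_te)
        }
      }
      acc[r, ] <- colMeans(a)
    })
  }
  colMeans(acc)
}

#' Decode all 16 train/test strategy pairs for one subject
#'
#' @param features named list (by strategy) of lists with `control`/`target`
#'   feature arrays (trial x sensor x grid-timepoint).
#' @param k,reps,seed,shrinkage passed to [decode_pair()]; per-pair seeds are
#'   derived from `seed` and the pair indices.
#' @return accuracy array `train x test x timepoint` with strategy dimnames.
#' @export
decode_subject <- function(features, k = 5, reps = 3, seed = 1L,
                           shrinkage = 0.05) {
  strategies <- names(features)
  ntp <- dim(features[[1]]$control)[3]
  out <- array(NA_real_, dim = c(length(strategies), length(strategies), ntp),
               dimnames = list(strategies, strategies, NULL))
  for (a in seq_along(strategies)) {
    for (b in seq_along(strategies)) {
      out[a, b, ] <- decode_pair(
        features[[a]], features[[b]], same_strategy = a == b,
        k = k, reps = reps, seed = derive_seed(seed, 11L, a, b),
        shrinkage = shrinkage)
    }
  }
  out
}

#' Group-level inference on decoding curves
#'
#' Per (train, test) pair and timepoint: two-sided one-sample t-test of the
#' subject accuracies against chance (0.5). Benjamini-Hochberg FDR applied
#' once to the concatenated p-values of all pairs and timepoints.
#'
#' @param acc array subject x train x test x timepoint (or a list of
#'   per-subject train x test x timepoint arrays).
#' @param q FDR level (default 0.05).
#' @param mu chance accuracy (default 0.5).
#' @return data.frame: train, test, timepoint, mean_accuracy, t, df, p,
#'   p_adj, significant.
#' @export
group_inference <- function(acc, q = 0.05, mu = 0.5) {
  if (is.list(acc)) {
    acc <- aperm(simplify2array(acc), c(4, 1, 2, 3))
  }
  ns <- dim(acc)[1]
  if (ns < 3) stop("at least 3 subjects required")
  strategies_tr <- dimnames(acc)[[2]]
  strategies_te <- dimnames(acc)[[3]]
  ntp <- dim(acc)[4]
  rows <- expand.grid(timepoint = seq_len(ntp), test = strategies_te,
                      train = strategies_tr, stringsAsFactors = FALSE)
  rows <- rows[, c("train", "test", "timepoint")]
  n <- nrow(rows)
  mean_acc <- tt <- pp <- numeric(n)
  for (i in seq_len(n)) {
    v <- acc[, rows$train[i], rows$test[i], rows$timepoint[i]]
    mean_acc[i] <- mean(v)
    s <- stats::sd(v)
    if (s == 0) {
      if (abs(mean_acc[i] - mu) < 1e-12) {
        tt[i] <- 0; pp[i] <- 1
      } else {
        warning("zero variance with mean != ", mu,
                " at one timepoint; p set to minimal")
        tt[i] <- sign(mean_acc[i] - mu) * Inf
        pp[i] <- .Machine$double.xmin
      }
    } else {
      ht <- stats::t.test(v, mu = mu)
      tt[i] <- unname(ht$statistic); pp[i] <- ht$p.value
    }
  }
  p_adj <- stats::p.adjust(pp, method = "BH")
  data.frame(rows, mean_accuracy = mean_acc, t = tt, df = ns - 1, p = pp,
             p_adj = p_adj, significant = p_adj <= q,
             stringsAsFactors = FALSE)
}
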