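test_that("class equalization subsamples to the smaller count, reproducibly", {
  eq <- equalize_classes(60, 20, seed = 5L)
  expect_length(eq$control, 20)
  expect_length(eq$target, 20)
  expect_true(all(eq$control %in% 1:60))
  expect_identical(eq, equalize_classes(60, 20, seed = 5L))
  eq2 <- equalize_classes(20, 20, seed = 5L)
  expect_length(eq2$control, 20)
  expect_identical(eq2$control, 1:20)
  expect_error(equalize_classes(1, 20), "at least 2")
})

test_that("linear discriminant separates, guesses at chance, and matches the Bayes rate", {
  set.seed(21)
  # well-separated 1-D classes -> perfect test accuracy
  x <- matrix(c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1)))
  y <- rep(c("control", "target"), each = 50)
  fit <- lda_fit(x, y)
  expect_equal(mean(lda_predict(fit, x) == y), 1)

  # identical class distributions -> chance
  x0 <- matrix(rnorm(8000 * 2), ncol = 2)
  y0 <- rep(c("control", "target"), 4000)
  f0 <- lda_fit(x0[1:4000, ], y0[1:4000])
  acc0 <- mean(lda_predict(f0, x0[4001:8000, ]) == y0[4001:8000])
  expect_equal(acc0, 0.5, tolerance = 0.05)

  # spherical Gaussians at +/- mu: accuracy -> Phi(||mu|| / sigma)
  mu <- c(0.4, 0.3)
  xtr <- rbind(matrix(rnorm(3000 * 2), ncol = 2) - rep(mu, each = 3000),
               matrix(rnorm(3000 * 2), ncol = 2) + rep(mu, each = 3000))
  ytr <- rep(c("control", "target"), each = 3000)
  xte <- rbind(matrix(rnorm(3000 * 2), ncol = 2) - rep(mu, each = 3000),
               matrix(rnorm(3000 * 2), ncol = 2) + rep(mu, each = 3000))
  f1 <- lda_fit(xtr, ytr, shrinkage = 0)
  acc <- mean(lda_predict(f1, xte) == ytr)
  bayes <- pnorm(sqrt(sum(mu^2)))
  expect_equal(acc, bayes, tolerance = 0.03)
})

test_that("discriminant agrees with the reference implementation when unregularized", {
  skip_if_not_installed("MASS")
  set.seed(8)
  x <- matrix(rnorm(200 * 3), ncol = 3)
  x[101:200, ] <- x[101:200, ] + 0.8
  y <- rep(c("control", "target"), each = 100)
  ours <- lda_predict(lda_fit(x, y, shrinkage = 0), x)
  ref <- as.character(predict(MASS::lda(x, grouping = y))$class)
  expect_equal(ours, ref)
})

test_that("per-timepoint decoding finds a deterministic separator and stays at chance under the null", {
  ntp <- 11
  mkfeat <- function(offset) {
    f <- list(control = array(rnorm(40 * 3 * ntp), dim = c(40, 3, ntp)),
              target = array(rnorm(40 * 3 * ntp), dim = c(40, 3, ntp)))
    # timepoint 6 perfectly separates the classes
    f$control[, , 6] <- f$control[, , 6] - 50 + offset
    f$target[, , 6] <- f$target[, , 6] + 50 + offset
    f
  }
  set.seed(13)
  f <- mkfeat(0)
  acc <- decode_pair(f, f, same_strategy = TRUE, seed = 2L)
  expect_length(acc, ntp)
  expect_true(all(acc >= 0 & acc <= 1))
  expect_equal(acc[6], 1)
  # other timepoints hover at chance
  expect_lt(max(abs(acc[-6] - 0.5)), 0.2)

  # cross-strategy generalization uses the training strategy's boundary
  g <- mkfeat(0)
  acc_x <- decode_pair(f, g, same_strategy = FALSE, seed = 3L)
  expect_equal(acc_x[6], 1)

  # pure-noise same-strategy decoding shows no leakage above chance
  nullf <- list(control = array(rnorm(60 * 3 * ntp), dim = c(60, 3, ntp)),
                target = array(rnorm(60 * 3 * ntp), dim = c(60, 3, ntp)))
  acc0 <- decode_pair(nullf, nullf, same_strategy = TRUE, reps = 6, seed = 4L)
  expect_equal(mean(acc0), 0.5, tolerance = 0.05)
})

test_that("fold count adapts to small trial counts with a message", {
  ntp <- 3
  f <- list(control = array(rnorm(4 * 3 * ntp), dim = c(4, 3, ntp)),
            target = array(rnorm(4 * 3 * ntp), dim = c(4, 3, ntp)))
  expect_message(decode_pair(f, f, same_strategy = TRUE, k = 5, seed = 1L),
                 "folds reduced")
})

test_that("decoding accuracy does not decrease with synthetic effect size", {
  accs <- sapply(c(4, 7, 10), function(amp_t) {
    cfg <- small_config(
      n_trials = 24, seed = 31L,
      burst = list(amplitude_target = amp_t, subject_amp_sd = 0))
    sub <- generate_subject(cfg, 1)
    sf <- subject_features(sub$epochs, seed = 1L)
    sel <- sf$grid$actual_ms >= 200 & sf$grid$actual_ms <= 450
    mean(decode_subject(sf$features, seed = 1L)[, , sel])
  })
  # monotone in effect size up to one Monte-Carlo SE (~0.02 here)
  expect_gte(accs[2], accs[1] - 0.02)
  expect_gte(accs[3], accs[2] - 0.02)
  expect_gt(accs[3], 0.55)
})

test_that("Benjamini-Hochberg flags match a brute-force step-up oracle", {
  q <- 0.05
  set.seed(77)
  for (i in 1:20) {
    m <- sample(3:50, 1)
    p <- runif(m)^sample(1:3, 1)
    rej <- p.adjust(p, method = "BH") <= q
    expect_identical(rej, bh_stepup_oracle(p, q))
  }
  # hand-run step-up: all four rejected at q = 0.05
  expect_identical(bh_stepup_oracle(c(0.01, 0.02, 0.03, 0.04), 0.05),
                   rep(TRUE, 4))
  expect_identical(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH") <= 0.05,
                   rep(TRUE, 4))
})

test_that("group inference handles null means, uniform significance and zero variance", {
  strategies <- c("proactive", "reactive")
  ntp <- 3
  acc <- array(0.5, dim = c(3, 2, 2, ntp),
               dimnames = list(NULL, strategies, strategies, NULL))
  acc[, 1, 1, 1] <- c(0.4, 0.5, 0.6) # mean exactly at chance
  acc[, 2, 2, ] <- rep(c(0.72, 0.74, 0.76), 3) # strong effect
  acc[, 2, 1, 1] <- 0.7 # zero variance away from chance
  expect_warning(g <- group_inference(acc), "zero variance")
  r11 <- g[g$train == "proactive" & g$test == "proactive" & g$timepoint == 1, ]
  expect_equal(r11$t, 0)
  expect_equal(r11$p, 1)
  r22 <- g[g$train == "reactive" & g$test == "reactive", ]
  expect_true(all(r22$significant))
  # zero-variance cells at exactly 0.5 get p = 1, not a warning-level p
  rflat <- g[g$train == "proactive" & g$test == "reactive", ]
  expect_true(all(rflat$p == 1))

  expect_error(group_inference(acc[1:2, , , , drop = FALSE]), "3 subjects")
})

test_that("cross-strategy decoding is symmetric for i.i.d. strategies", {
  set.seed(55)
  ntp <- 5
  mk <- function() list(
    control = array(rnorm(30 * 3 * ntp), dim = c(30, 3, ntp)),
    target = array(rnorm(30 * 3 * ntp, mean = 0.6), dim = c(30, 3, ntp)))
  ab <- ba <- numeric(8)
  for (i in 1:8) {
    A <- mk(); B <- mk()
    ab[i] <- mean(decode_pair(A, B, seed = i))
    ba[i] <- mean(decode_pair(B, A, seed = i + 100))
  }
  expect_equal(mean(ab), mean(ba), tolerance = 0.05)
  expect_gt(mean(ab), 0.6) # the common effect generalizes both ways
})
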