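# Random-intercept REML estimator, ICC, FDR, moderation, channel-wise
# analysis. The estimator is checked along two independent routes: a
# dense-matrix restricted-likelihood oracle and nlme::lme.

balanced_data <- function(n_sub = 6, n_per = 40, delta = 0.5, noise = 1,
                          seed = 1) {
  set.seed(seed)
  subject <- rep(sprintf("S%d", seq_len(n_sub)), each = n_per)
  code <- rep(c(-1, 1), length.out = n_sub * n_per)
  a <- rnorm(n_sub, 0, 0.8)
  y <- a[as.integer(factor(subject))] + (delta / 2) * code +
    rnorm(n_sub * n_per, 0, noise)
  data.frame(subject = subject, code = code, y = y)
}

test_that("effect-code contract: 2b equals the mean difference exactly when noiseless", {
  d <- balanced_data(delta = 0.84, noise = 0)
  f <- fit_random_intercept(d)
  expect_lt(abs(2 * coef(f)[["code"]] - 0.84), 1e-9)
  # and on any balanced data, 2b equals the raw condition mean difference
  d2 <- balanced_data(delta = 0.3, noise = 1, seed = 4)
  f2 <- fit_random_intercept(d2)
  raw_diff <- mean(d2$y[d2$code == 1]) - mean(d2$y[d2$code == -1])
  expect_lt(abs(2 * coef(f2)[["code"]] - raw_diff), 1e-9)
})

test_that("REML estimates match the dense restricted-likelihood oracle", {
  d <- balanced_data(n_sub = 4, n_per = 40, delta = 0.4, noise = 0.9, seed = 2)
  f <- fit_random_intercept(d)
  X <- cbind(1, d$code)
  # the package's lambda-hat minimizes the dense criterion...
  o_here <- oracle_reml_crit(f$lambda, d$y, X, d$subject)
  o_opt <- optimize(function(l) oracle_reml_crit(l, d$y, X, d$subject)$crit,
                    c(1e-8, 50), tol = 1e-12)
  expect_lt(o_here$crit - o_opt$objective, 1e-8)
  # ...and the coefficient / variance estimates agree at that optimum
  expect_lt(max(abs(o_here$beta - coef(f))), 1e-9)
  expect_lt(abs(o_here$s2 - f$sigma_e2), 1e-6)
  o_best <- oracle_reml_crit(o_opt$minimum, d$y, X, d$subject)
  expect_lt(max(abs(o_best$beta - coef(f))), 1e-6)
})

test_that("REML estimates agree with nlme::lme to 1e-6", {
  for (seed in c(3, 9)) {
    d <- balanced_data(n_sub = 7, n_per = 30, delta = 0.25, seed = seed)
    # unbalance it: drop a third of one subject's rows
    d <- d[-(1:10), ]
    f <- fit_random_intercept(d)
    m <- nlme::lme(y ~ code, random = ~ 1 | subject, data = d,
                   method = "REML")
    expect_equal(coef(f)[["code"]], nlme::fixef(m)[["code"]],
                 tolerance = 1e-6)
    expect_equal(f$coefficients$SE[2], sqrt(diag(stats::vcov(m)))[[2]],
                 tolerance = 1e-6)
    vc <- nlme::VarCorr(m)
    expect_equal(f$sigma_u2, as.numeric(vc[1, "Variance"]), tolerance = 1e-5)
    expect_equal(f$sigma_e2, as.numeric(vc[2, "Variance"]), tolerance = 1e-5)
  }
})

test_that("between-within degrees of freedom follow the partition rule", {
  d <- balanced_data(n_sub = 6, n_per = 40)
  f <- fit_random_intercept(d)
  expect_equal(f$coefficients$df,
                   c(6 - 1, 240 - 6 - 1))  # intercept between, code within
  # unbalanced data keep df = N - n - 1 for the level-1 effect
  d2 <- d[-(1:17), ]
  f2 <- fit_random_intercept(d2)
  expect_equal(f2$coefficients$df[2], nrow(d2) - 6 - 1)
})

test_that("permuted condition labels give a near-null coefficient", {
  set.seed(5)
  d <- balanced_data(n_sub = 10, n_per = 60, delta = 0.6)
  d$code <- sample(d$code)
  f <- fit_random_intercept(d)
  expect_lt(abs(coef(f)[["code"]]), 3 * f$coefficients$SE[2] + 0.05)
})

test_that("estimates are invariant to row order and subject relabeling", {
  d <- balanced_data(n_sub = 5, n_per = 30, seed = 6)
  f1 <- fit_random_intercept(d)
  d2 <- d[sample(nrow(d)), ]
  f2 <- fit_random_intercept(d2)
  d3 <- d
  d3$subject <- factor(d3$subject,
                       labels = sample(LETTERS[1:5]))
  f3 <- fit_random_intercept(d3)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_equal(f1$sigma_u2, f3$sigma_u2, tolerance = 1e-9)
  expect_equal(coef(f1)[["code"]], coef(f3)[["code"]], tolerance = 1e-9)
})

test_that("single-condition channels and tiny groups error clearly", {
  d <- balanced_data()
  d$code <- 1
  expect_error(fit_random_intercept(d), "single condition")
  d2 <- balanced_data(n_sub = 1)
  expect_error(fit_random_intercept(d2), "2 subjects")
})

test_that("ICC matches its defining variance ratio", {
  # between-subject variance equal to within -> ICC about 0.5
  set.seed(8)
  n_sub <- 60; n_per <- 80
  u <- rnorm(n_sub, 0, 1)
  d <- data.frame(subject = rep(seq_len(n_sub), each = n_per),
                  code = rep(c(-1, 1), length.out = n_sub * n_per))
  d$y <- u[d$subject] + rnorm(nrow(d), 0, 1)
  expect_equal(icc(d), 0.5, tolerance = 0.08)
  # no between-subject component -> ICC near zero
  d$y <- rnorm(nrow(d))
  expect_lt(icc(d), 0.03)
})

test_that("ICC recovers the generating value at study scale", {
  d <- simulate_null_long(n_subjects = 38, rows_per_subject = 1000,
                          n_channels = 1, icc = 0.15, seed = 30)
  expect_lt(abs(icc(d) - 0.15), 0.05)
})

test_that("BH adjustment equals the definitional oracle and preserves order", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(fdr_adjust(p), oracle_bh(p))
  expect_equal(fdr_adjust(p), rep(0.04, 4))  # step-up collapses this case
  set.seed(10)
  for (k in 1:25) {
    pv <- runif(16)^sample(1:3, 1)
    expect_equal(fdr_adjust(pv), oracle_bh(pv))
    expect_true(all(fdr_adjust(pv) >= pv))
  }
  same <- rep(0.2, 8)
  expect_equal(fdr_adjust(same), same)
  expect_error(fdr_adjust(c(0.5, 1.2)), "outside")
})

test_that("moderation: null interaction gives equal slopes; centering invariance", {
  m <- simulate_moderation_long(gamma = c(0, 0, 0.05, 0), seed = 12)
  f <- fit_moderation(m$data, m$traits, roi = 1)
  expect_lt(abs(f$coefficients$b[4]), 3 * f$coefficients$SE[4])
  expect_equal(f$slopes$slope[1], f$slopes$slope[2],
               tolerance = 3 * f$slopes$SE[1] / abs(f$slopes$slope[1] + 1e-9))
  # shifting every trait score leaves the interaction untouched
  m2 <- simulate_moderation_long(seed = 13)
  f2 <- fit_moderation(m2$data, m2$traits, roi = 1)
  tr_shift <- m2$traits
  tr_shift$deliberation_t <- tr_shift$deliberation_t + 25
  f3 <- fit_moderation(m2$data, tr_shift, roi = 1)
  expect_equal(f2$coefficients$b[4], f3$coefficients$b[4], tolerance = 1e-9)
  expect_equal(f2$slopes$slope, f3$slopes$slope, tolerance = 1e-9)
})

test_that("moderation recovers the crossing pattern and its df conventions", {
  m <- simulate_moderation_long(seed = 14)
  f <- fit_moderation(m$data, m$traits, roi = 1)
  # level-1 terms: N - n - 2; trait main effect: n - 2
  expect_equal(f$coefficients$df, c(36, 36, 15160, 15160))
  expect_equal(f$slopes$df, c(15160L, 15160L))
  expect_lt(f$slopes$p[1], 0.001)        # strong effect one SD below
  expect_gt(f$slopes$p[2], 0.05)         # none one SD above
  expect_lt(f$coefficients$t[4], -8)     # negative cross-level interaction
  # simple-slope identity: slope at D* = g10 + g11 * D*
  expect_equal(f$slopes$slope,
               f$coefficients$b[3] + f$coefficients$b[4] * f$slopes$d_offset,
               tolerance = 1e-12)
})

test_that("moderation requires trait scores for at least 3 subjects", {
  m <- simulate_moderation_long(n_subjects = 6, rows_per_subject = 20, seed = 15)
  tr <- m$traits
  tr$deliberation_t[1:4] <- NA
  expect_error(fit_moderation(m$data, tr, roi = 1), "fewer than 3")
})

test_that("channel-wise analysis labels directions and flags broken channels", {
  d <- simulate_null_long(n_subjects = 12, rows_per_subject = 60,
                          n_channels = 4, icc = 0.1, seed = 16)
  d$y <- d$y + ifelse(d$channel == 1, 0.4 * d$code,
                      ifelse(d$channel == 2, -0.4 * d$code, 0))
  # break channel 4: single condition only
  d <- d[!(d$channel == 4 & d$code == -1), ]
  cw <- as.data.frame(channelwise_analysis(d))
  expect_identical(nrow(cw), 4L)
  expect_identical(cw$label[1:2], c("activated", "deactivated"))
  expect_true(is.na(cw$b[4]) && !is.na(cw$note[4]))
  expect_true(all(cw$p_fdr >= cw$p, na.rm = TRUE))
})

test_that("the AR(1) option fits and reports an autocorrelation estimate", {
  set.seed(18)
  n_sub <- 6; n_per <- 80
  d <- data.frame(subject = rep(seq_len(n_sub), each = n_per),
                  code = rep(c(-1, 1), length.out = n_sub * n_per))
  eps <- unlist(lapply(seq_len(n_sub), function(i)
    as.numeric(arima.sim(list(ar = 0.6), n_per))))
  d$y <- 0.2 * d$code + eps
  f <- fit_random_intercept(d, ar1 = TRUE)
  expect_true(f$converged)
  expect_gt(f$phi, 0.3)
  expect_equal(f$coefficients$df[2], nrow(d) - n_sub - 1L)
})
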