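test_that("the Wald ratio follows the delta-method arithmetic", {
  h <- list(rsid = "rs1", beta_x = 0.1, beta_y = -0.05, se_x = 0.01,
            se_y = 0.02)
  w <- wald_ratio(h)
  expect_equal(w$theta, -0.5)
  expect_equal(w$se, 0.2)
  h0 <- h; h0$beta_y <- 0
  expect_equal(wald_ratio(h0)$theta, 0)
  expect_equal(wald_ratio(h0)$se, 0.2)
  # flipping both effects together leaves the ratio unchanged
  hf <- h; hf$beta_x <- -h$beta_x; hf$beta_y <- -h$beta_y
  expect_equal(wald_ratio(hf)$theta, w$theta)
  expect_equal(wald_ratio(hf)$se, w$se)
  hz <- h; hz$beta_x <- 0
  expect_error(wald_ratio(hz), "beta_x = 0")
  # second-order form adds the exposure-error term
  expect_gt(wald_ratio(h, second_order = TRUE)$se, w$se)
})

test_that("fixed-effect IVW matches the closed-form weighted mean", {
  hs <- data.frame(beta_x = c(0.1, 0.2), beta_y = c(0.05, 0.08),
                   se_y = c(0.01, 0.02), se_x = 0.01)
  iv <- ivw_fixed(hs)
  expect_equal(iv$theta, 0.45, tolerance = 1e-12)
  expect_equal(iv$se, 1 / sqrt(200), tolerance = 1e-12)
  # equal weights reduce to the plain mean of the two ratios
  hs2 <- data.frame(beta_x = c(0.1, 0.1), beta_y = c(0.01, 0.03),
                    se_y = c(0.02, 0.02), se_x = 0.01)
  expect_equal(ivw_fixed(hs2)$theta, mean(c(0.1, 0.3)), tolerance = 1e-12)
  expect_error(ivw_fixed(hs[0, ]), "no instruments")
})

test_that("IVW with one instrument reduces exactly to the Wald ratio", {
  hs <- toy_hs(1)
  iv <- ivw_fixed(hs)
  w <- wald_ratio(hs[1, ])
  expect_equal(iv$theta, w$theta, tolerance = 1e-12)
  expect_equal(iv$se, w$se, tolerance = 1e-12)
})

test_that("IVW agrees with an independent fixed-effect meta-analysis", {
  for (seed in c(2, 5, 9)) {
    hs <- toy_hs(7, seed)
    iv <- ivw_fixed(hs)
    or <- ivw_meta_oracle(hs)
    expect_equal(iv$theta, or$theta, tolerance = 1e-12)
    expect_equal(iv$se, or$se, tolerance = 1e-12)
    skip_if_not_installed("metafor")
    rma <- metafor::rma(yi = hs$beta_y / hs$beta_x,
                        sei = hs$se_y / abs(hs$beta_x), method = "FE")
    expect_equal(iv$theta, as.numeric(rma$beta), tolerance = 1e-10)
    expect_equal(iv$se, as.numeric(rma$se), tolerance = 1e-10)
  }
})

test_that("MR-Egger reproduces exact weighted least squares", {
  # collinear points through the origin: intercept 0, slope = common ratio
  hs <- data.frame(beta_x = c(0.1, 0.2, 0.4), se_x = 0.01,
                   beta_y = c(0.03, 0.06, 0.12), se_y = c(0.01, 0.01, 0.02))
  eg <- mr_egger(hs)
  expect_equal(eg$intercept, 0, tolerance = 1e-10)
  expect_equal(eg$theta, 0.3, tolerance = 1e-10)
  # noiseless intercept fixture recovers slope and intercept exactly
  bx <- c(0.05, 0.1, 0.2, 0.3)
  hs2 <- data.frame(beta_x = bx, se_x = 0.01, beta_y = 0.01 + 0.3 * bx,
                    se_y = 0.01)
  eg2 <- mr_egger(hs2)
  expect_equal(eg2$intercept, 0.01, tolerance = 1e-10)
  expect_equal(eg2$theta, 0.3, tolerance = 1e-10)
  # matches stats::lm on an over-determined noisy fixture
  hs3 <- toy_hs(8, 3)
  hs3$beta_x <- abs(hs3$beta_x)
  fit <- lm(beta_y ~ beta_x, data = hs3, weights = 1 / se_y^2)
  eg3 <- mr_egger(hs3)
  expect_equal(unname(coef(fit)), c(eg3$intercept, eg3$theta),
               tolerance = 1e-10)
  sm <- summary(fit)$coefficients[, "Std. Error"]
  disp <- summary(fit)$sigma
  infl <- max(1, disp) / disp  # dispersion floored at 1
  expect_equal(unname(sm * infl), c(eg3$intercept_se, eg3$se),
               tolerance = 1e-8)
  expect_null(mr_egger(toy_hs(2)))
})

test_that("Egger with the intercept constrained to zero is IVW", {
  hs <- toy_hs(6, 8)
  sgn <- ifelse(hs$beta_x < 0, -1, 1)
  slope0 <- unname(coef(lm(I(beta_y * sgn) ~ I(beta_x * sgn) - 1, data = hs,
                           weights = 1 / se_y^2)))
  expect_equal(slope0, ivw_fixed(hs)$theta, tolerance = 1e-12)
})

test_that("the weighted median interpolates the weighted quantile", {
  # equal weights, odd k: the middle order statistic
  hs <- data.frame(beta_x = 0.1, se_x = 0.01, se_y = 0.01,
                   beta_y = c(0.05, 0.01, 0.03))
  wm <- weighted_median_mr(hs, bootstrap_reps = 50, seed = 1)
  expect_equal(wm$theta, 0.3)
  # hand-computable interpolation case: theta (1,2,10), weights (.2,.5,.3)
  theta <- c(1, 2, 10)
  w <- c(0.2, 0.5, 0.3)
  got <- targetmr:::weighted_quantile_interp(theta, w)
  expect_equal(got, weighted_median_oracle(theta, w), tolerance = 1e-12)
  expect_equal(got, 3.0, tolerance = 1e-12)
  # random cases against the piecewise-CDF oracle
  set.seed(6)
  for (i in 1:25) {
    k <- sample(3:12, 1)
    th <- rnorm(k); ww <- runif(k)
    expect_equal(targetmr:::weighted_quantile_interp(th, ww),
                 weighted_median_oracle(th, ww), tolerance = 1e-12)
  }
  # identical ratios: that value, bootstrap se collapsing with precision
  hs3 <- data.frame(beta_x = c(0.1, 0.2, 0.4), se_x = 1e-8,
                    beta_y = c(0.02, 0.04, 0.08), se_y = 1e-8)
  wm3 <- weighted_median_mr(hs3, bootstrap_reps = 100, seed = 2)
  expect_equal(wm3$theta, 0.2, tolerance = 1e-6)
  expect_lt(wm3$se, 1e-5)
  expect_null(weighted_median_mr(toy_hs(2), 50, seed = 1))
})

test_that("the weighted mode finds the dominant ratio cluster", {
  hs <- data.frame(beta_x = 1, se_x = 0.01, se_y = 0.01,
                   beta_y = c(0.30, 0.31, 0.29, 2.0))
  wmo <- weighted_mode_mr(hs, bootstrap_reps = 50, seed = 3)
  expect_gt(wmo$theta, 0.25)
  expect_lt(wmo$theta, 0.35)
  # package KDE argmax equals the point-by-point oracle
  set.seed(12)
  for (i in 1:10) {
    th <- rnorm(8); ww <- runif(8)
    expect_equal(targetmr:::kde_mode(th, ww / sum(ww)),
                 kde_mode_oracle(th, ww), tolerance = 1e-12)
  }
  # scaling all weights by a constant changes nothing
  th <- rnorm(6); ww <- runif(6)
  expect_equal(targetmr:::kde_mode(th, ww / sum(ww)),
               targetmr:::kde_mode(th, 10 * ww / sum(10 * ww)))
  # degenerate: all ratios equal
  hs4 <- data.frame(beta_x = c(1, 2, 4), se_x = 0.01,
                    beta_y = c(0.1, 0.2, 0.4), se_y = 0.01)
  expect_equal(weighted_mode_mr(hs4, bootstrap_reps = 20, seed = 1)$theta,
               0.1, tolerance = 1e-9)
})

test_that("bootstrap standard errors are reproducible under a seed", {
  hs <- toy_hs(5)
  a <- weighted_median_mr(hs, bootstrap_reps = 200, seed = 99)
  b <- weighted_median_mr(hs, bootstrap_reps = 200, seed = 99)
  expect_identical(a$se, b$se)
  expect_error(weighted_median_mr(hs, 200, seed = NULL), "seed")
})

test_that("odds-ratio scaling matches the glucose-lowering convention", {
  s <- scale_estimate(0, 0.1)
  expect_equal(s$or, 1)
  expect_equal(scale_estimate(9.676, 0.5)$or, 0.38, tolerance = 0.005)
  # reciprocal factor gives the reciprocal OR, with mirrored CI
  up <- scale_estimate(2, 0.3, factor = 0.1)
  dn <- scale_estimate(2, 0.3, factor = -0.1)
  expect_equal(up$or, 1 / dn$or, tolerance = 1e-12)
  expect_equal(up$ci_low, 1 / dn$ci_high, tolerance = 1e-12)
  expect_lt(dn$ci_low, dn$or)
  expect_gt(dn$ci_high, dn$or)
})

test_that("normal-theory summaries invert printed results correctly", {
  w0 <- wald_summary(0, 1)
  expect_equal(w0$pval, 1)
  expect_equal(w0$or, 1)
  # boundary: estimate exactly 1.96 se from zero
  expect_equal(wald_summary(1.96 * 0.2, 0.2)$pval, 0.05, tolerance = 5e-4)
  # se implied by OR 0.38 at p = 0.004 reconstructs the reported CI
  se <- abs(log(0.38)) / qnorm(1 - 0.004 / 2)
  ci <- wald_summary(log(0.38), se)
  expect_equal(round(ci$ci_low, 2), 0.20)
  expect_equal(round(ci$ci_high, 2), 0.73)
})

test_that("the Bonferroni gate uses a strict 0.05/6 threshold", {
  expect_equal(round(0.05 / 6, 3), 0.008)
  expect_true(bonferroni_gate(0.004))
  expect_false(bonferroni_gate(0.009))
  expect_false(bonferroni_gate(0.05, n_tests = 1))  # strict inequality
  expect_true(bonferroni_gate(0.049, n_tests = 1))
  expect_error(bonferroni_gate(0.01, n_tests = 0), "n_tests")
})

test_that("mr_fit dispatches methods on the instrument count", {
  f1 <- mr_fit(toy_hs(1), seed = 1, bootstrap_reps = 50)
  expect_equal(f1$results$method, "wald")
  f2 <- mr_fit(toy_hs(2), seed = 1, bootstrap_reps = 50)
  expect_equal(f2$results$method, "ivw")
  f5 <- mr_fit(toy_hs(5), seed = 1, bootstrap_reps = 50)
  expect_setequal(f5$results$method,
                  c("ivw", "egger", "weighted_median", "weighted_mode"))
  f0 <- mr_fit(toy_hs(5)[0, ], seed = 1)
  expect_equal(f0$status, "no-instruments")
  expect_equal(nrow(f0$results), 0)
  # CI bounds bracket the scaled OR in every row
  expect_true(all(f5$results$ci_low < f5$results$or &
                  f5$results$or < f5$results$ci_high))
})

test_that("estimators are invariant under harmonization-consistent flips", {
  hs <- toy_hs(6, 15)
  flip <- c(2, 5)
  hs2 <- hs
  hs2$beta_x[flip] <- -hs2$beta_x[flip]
  hs2$beta_y[flip] <- -hs2$beta_y[flip]
  expect_equal(ivw_fixed(hs2)$theta, ivw_fixed(hs)$theta, tolerance = 1e-12)
  expect_equal(ivw_fixed(hs2)$se, ivw_fixed(hs)$se, tolerance = 1e-12)
  expect_equal(mr_egger(hs2)$theta, mr_egger(hs)$theta, tolerance = 1e-12)
  expect_equal(mr_egger(hs2)$intercept, mr_egger(hs)$intercept,
               tolerance = 1e-12)
  wm <- weighted_median_mr(hs, 100, seed = 4)
  wm2 <- weighted_median_mr(hs2, 100, seed = 4)
  expect_equal(wm2$theta, wm$theta, tolerance = 1e-12)
  mo <- weighted_mode_mr(hs, bootstrap_reps = 100, seed = 4)
  mo2 <- weighted_mode_mr(hs2, bootstrap_reps = 100, seed = 4)
  expect_equal(mo2$theta, mo$theta, tolerance = 1e-12)
})

test_that("mr_fit methods print, summarize and plot without error", {
  fit <- mr_fit(toy_hs(5), seed = 2, bootstrap_reps = 50)
  expect_output(print(fit), "ivw")
  expect_output(print(summary(fit)), "Egger intercept")
  expect_named(coef(fit))
  ci <- confint(fit)
  expect_equal(rownames(ci), fit$results$method)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
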