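test_that("ols_fit solves exact and noisy problems with classical inference", {
  x <- 1:10
  fit <- ols_fit(2 * x, cbind("(Intercept)" = 1, x = x))
  expect_equal(coef(fit), c("(Intercept)" = 0, x = 2), tolerance = 1e-10)
  expect_equal(fit$terms$std_error, c(0, 0), tolerance = 1e-10)

  # 8-row toy vs. direct minimization of the residual sum of squares
  set.seed(1)
  x8 <- rnorm(8); y8 <- 1 + 0.5 * x8 + rnorm(8)
  X8 <- cbind("(Intercept)" = 1, x = x8)
  fit8 <- ols_fit(y8, X8)
  rss <- function(b) sum((y8 - X8 %*% b)^2)
  expect_equal(unname(coef(fit8)), grid_minimize(rss, c(0, 0), c(5, 5)),
               tolerance = 1e-3)
  # agreement with lm's classical SEs
  lm8 <- lm(y8 ~ x8)
  expect_equal(unname(coef(fit8)), unname(coef(lm8)), tolerance = 1e-10)
  expect_equal(unname(fit8$terms$std_error),
               unname(summary(lm8)$coefficients[, 2]), tolerance = 1e-10)

  # consistency at n = 10^4
  set.seed(2)
  xn <- rnorm(1e4); yn <- 1 + 0.5 * xn + rnorm(1e4)
  fitn <- ols_fit(yn, cbind("(Intercept)" = 1, x = xn))
  expect_equal(coef(fitn)[["x"]], 0.5, tolerance = 0.05)

  # rank deficiency names the collinear column
  expect_error(ols_fit(y8, cbind("(Intercept)" = 1, a = x8, a_copy = x8)),
               "a_copy", class = "explor_rank_error")
})

test_that("huber_fit reduces to OLS on clean data and as c grows", {
  x <- 1:12
  y <- 3 + 2 * x
  X <- cbind("(Intercept)" = 1, x = x)
  expect_equal(coef(huber_fit(y, X)), coef(ols_fit(y, X)), tolerance = 1e-8)

  set.seed(7)
  yn <- 3 + 2 * x + rnorm(12)
  b_huge_c <- coef(huber_fit(yn, X, c = 1e6))
  expect_lt(max(abs(b_huge_c - coef(ols_fit(yn, X)))), 1e-6)
})

test_that("huber_fit minimizes the Huber objective and downweights an outlier", {
  set.seed(5)
  x <- seq(0, 5, length.out = 12)
  y <- 1 + 1.5 * x + rnorm(12, 0, 0.3)
  y[4] <- y[4] + 25   # gross outlier
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- huber_fit(y, X)
  expect_true(fit$converged)
  # oracle: grid minimization of the Huber objective at the converged scale
  obj <- function(b) huber_rho_obj(y, X, b, fit$scale)
  b_grid <- grid_minimize(obj, center = c(0, 0), width = c(10, 5))
  expect_equal(unname(coef(fit)), b_grid, tolerance = 1e-3)
  # robust slope stays near truth; OLS is dragged by the outlier
  expect_lt(abs(coef(fit)[["x"]] - 1.5), 0.35)
  expect_gt(abs(coef(ols_fit(y, X))[["x"]] - 1.5), 0.8)
  # cross-check against the reference IRLS implementation
  rl <- MASS::rlm(y ~ x, scale.est = "MAD", k2 = 1.345, maxit = 100,
                  acc = 1e-10)
  expect_equal(unname(coef(fit)), unname(coef(rl)), tolerance = 1e-4)
})

test_that("huber_fit recovers known effects under heavy-tailed noise at n = 36", {
  # the study design: index ~ sex + parity + age with t(3) noise
  truth <- c(0, -2.2, 2.7, -0.3)
  nrep <- 500
  est <- matrix(NA_real_, nrep, 3)
  set.seed(99)
  for (r in seq_len(nrep)) {
    male <- rbinom(36, 1, 0.5)
    multi <- rbinom(36, 1, 0.5)
    age <- runif(36, 0.5, 13)
    y <- truth[1] + truth[2] * male + truth[3] * multi + truth[4] * age +
      rt(36, df = 3)
    X <- cbind("(Intercept)" = 1, male = male, multi = multi, age = age)
    est[r, ] <- coef(huber_fit(y, X))[2:4]
  }
  med <- apply(est, 2, median)
  expect_lt(max(abs(med - truth[2:4])), 0.3)
  expect_gte(mean(est[, 1] < 0), 0.95)   # sex sign
  expect_gte(mean(est[, 2] > 0), 0.95)   # parity sign
})

test_that("mann_whitney_u matches its identities and the enumeration null", {
  # perfect separation at the study's group sizes
  res <- mann_whitney_u(101:109, 1:27)
  expect_equal(res$u_statistic, 243)
  expect_equal(res$u_min, 0)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$method, "normal_approx")  # 36 pooled exceeds the exact limit

  # identical samples: both orientations at n1*n2/2
  res2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$u_statistic, 4.5)
  expect_equal(res2$u_min, 4.5)

  # exact p equals full enumeration over all labelings (tie-free, n <= 10)
  set.seed(12)
  for (r in 1:5) {
    n1 <- sample(2:4, 1); n2 <- sample(3:6, 1)
    a <- rnorm(n1); b <- rnorm(n2, 0.5)
    res <- mann_whitney_u(a, b)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, enum_mw_p(a, b), tolerance = 1e-12)
    wt <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(res$p_value, wt$p.value, tolerance = 1e-12)
    expect_equal(res$u_a, unname(wt$statistic))
  }
})

test_that("mann_whitney_u normal approximation handles ties like the reference", {
  set.seed(3)
  a <- sample(1:8, 15, replace = TRUE)
  b <- sample(3:10, 18, replace = TRUE)
  res <- mann_whitney_u(a, b)
  expect_equal(res$method, "normal_approx")
  expect_true(res$tie_correction)
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(res$p_value, wt$p.value, tolerance = 1e-10)

  # invariance under monotone transformation of the pooled data
  res_t <- mann_whitney_u(exp(a / 3), exp(b / 3))
  expect_equal(res_t$u_statistic, res$u_statistic)
  expect_equal(res_t$p_value, res$p_value, tolerance = 1e-12)
})

test_that("icc_one_way recovers degenerate, null and known-variance structures", {
  # no within-group variance: all variance is maternal
  v <- rep(c(1, 5, 9), each = 4)
  g <- rep(letters[1:3], each = 4)
  res <- icc_one_way(v, g)
  expect_equal(res$icc, 1.0)
  expect_equal(res$sigma2_within, 0)

  # shuffled labels on pure noise: near-zero ICC
  set.seed(21)
  v0 <- rnorm(1000)
  g0 <- sample(rep(1:100, each = 10))
  expect_lt(icc_one_way(v0, g0)$icc, 0.05)

  # recovery of ICC = 0.10 (sigma2_b = 1, sigma2_w = 9), 200 groups of 5
  set.seed(22)
  iccs <- replicate(10, {
    gm <- rnorm(200, 0, 1)
    y <- rep(gm, each = 5) + rnorm(1000, 0, 3)
    icc_one_way(y, rep(1:200, each = 5))$icc
  })
  expect_lt(abs(mean(iccs) - 0.10), 0.03)

  expect_error(icc_one_way(rnorm(5), rep("a", 5)),
               class = "explor_domain_error")
})

test_that("REML agrees with ANOVA on balanced designs and with lmer when unbalanced", {
  set.seed(30)
  for (r in 1:5) {
    gm <- rnorm(12, 0, 1)
    y <- rep(gm, each = 4) + rnorm(48, 0, 2)
    g <- rep(1:12, each = 4)
    res <- icc_one_way(y, g)
    expect_lt(abs(res$reml$icc - res$anova$icc), 1e-6)
  }
  # unbalanced: cross-check the REML fit against lme4
  set.seed(31)
  sizes <- sample(1:6, 15, replace = TRUE, prob = 6:1)
  g <- rep(seq_along(sizes), sizes)
  y <- rep(rnorm(15, 0, 1.2), sizes) + rnorm(length(g), 0, 1)
  res <- icc_one_way(y, g)
  lf <- lme4::lmer(y ~ 1 + (1 | g),
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(lf))
  icc_lmer <- vc$vcov[1] / sum(vc$vcov)
  expect_equal(res$icc, icc_lmer, tolerance = 1e-4)
  expect_equal(res$sigma2_within, vc$vcov[2], tolerance = 1e-3)
})

test_that("model fits keep p-values in [0, 1] and CIs containing the estimate", {
  set.seed(40)
  x <- rnorm(25); y <- 1 + x + rnorm(25)
  X <- cbind("(Intercept)" = 1, x = x)
  for (fit in list(ols_fit(y, X), huber_fit(y, X),
                   logistic_fit(as.numeric(y > 1), X))) {
    tt <- fit$terms
    expect_true(all(tt$p_value >= 0 & tt$p_value <= 1))
    expect_true(all(tt$ci_low < tt$ci_high))
    expect_true(all(tt$ci_low <= tt$estimate & tt$estimate <= tt$ci_high))
    expect_equal(tt$z_value, tt$estimate / tt$std_error, tolerance = 1e-9)
  }
})
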