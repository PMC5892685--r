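test_that("random-intercept model matches OLS without grouping information", {
  set.seed(5)
  x <- rnorm(80); y <- 1 + 2 * x + rnorm(80)
  expect_warning(
    f <- fitRandomInterceptLM(y, data.frame(x = x), rep("b1", 80)),
    "single grouping")
  ols <- coef(lm(y ~ x))[["x"]]
  expect_equal(f$effects$estimate, ols, tolerance = 1e-8)
  expect_equal(unname(f$variance_components["tau2"]), 0)
})

test_that("random-intercept model recovers slope and variance components", {
  # with only 10 batches a single tau2 estimate is noisy; recovery is
  # asserted on the average over replicates
  set.seed(6)
  tau2 <- sig2 <- numeric(6)
  for (r in 1:6) {
    n <- 500; g <- sample(1:10, n, replace = TRUE)
    b <- rnorm(10, 0, 1)                     # sigma_b = 1
    x <- rnorm(n)
    y <- 2 * x + b[g] + rnorm(n)             # sigma_e = 1
    f <- fitRandomInterceptLM(y, data.frame(x = x), g)
    e <- f$effects[f$effects$term == "x", ]
    expect_lt(abs(e$estimate - 2), 3 * e$se)
    tau2[r] <- f$variance_components["tau2"]
    sig2[r] <- f$variance_components["sigma2"]
  }
  expect_lt(abs(mean(tau2) - 1), 0.5)
  expect_lt(abs(mean(sig2) - 1), 0.5)

  # truly equal intercepts: tau estimated at the boundary
  n <- 500; g <- sample(1:10, n, replace = TRUE); x <- rnorm(n)
  y0 <- 2 * x + rnorm(n)
  f0 <- fitRandomInterceptLM(y0, data.frame(x = x), g)
  expect_lt(f0$variance_components["tau2"], 0.05)

  expect_error(fitRandomInterceptLM(y0, data.frame(x = x, x2 = 2 * x), g),
               "collinear")
})

test_that("Rubin's rules pool estimates and variances as specified", {
  one <- data.frame(term = "b", estimate = 1.5, se = 0.2, n = 100)
  same <- rbind(one, one, one)
  p <- poolRubin(same)
  expect_equal(p$estimate, 1.5)
  expect_equal(p$se, 0.2)                    # B = 0
  # hand example: coefficients (1,2,3), variances (1,1,1), m = 3
  est <- data.frame(term = "b", estimate = c(1, 2, 3), se = 1, n = 10)
  p2 <- poolRubin(est)
  expect_equal(p2$estimate, 2)
  expect_equal(p2$se^2, 1 + (1 + 1 / 3) * 1)  # 2.3333...
  # total variance never below mean within-imputation variance
  expect_gte(p2$se^2, 1)
  expect_error(poolRubin(data.frame(term = c("a", "b"),
                                    estimate = 1:2, se = 1, n = 5)),
               "one term")
})

test_that("BH adjustment is the step-up procedure with discovery flags", {
  r <- bhAdjust(c(0.01, 0.02, 0.04, 0.05))
  expect_equal(r$p_adjusted, c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bhAdjust(0.03)$p_adjusted, 0.03)
  expect_equal(bhAdjust(rep(0.2, 5))$p_adjusted, rep(0.2, 5))
  # monotone in the order statistics and capped at 1
  set.seed(7)
  p <- runif(50)
  a1 <- bhAdjust(p)$p_adjusted
  expect_true(all(diff(a1[order(p)]) >= -1e-15))
  expect_true(all(a1 <= 1))
  expect_identical(r$discovery, r$p_adjusted <= 0.05)
})

test_that("DerSimonian-Laird pooling matches the hand computation", {
  two <- data.frame(term = "b", estimate = c(1.2, 1.2), se = c(0.3, 0.3),
                    n = c(50, 60))
  p <- dersimonianLaird(two)
  expect_equal(p$estimate, 1.2)
  expect_equal(p$tau2, 0)
  # hand case: estimates (0, 2), variances (1, 1) -> Q=2, C=1, tau2=1,
  # pooled 1 with variance 1
  h <- dersimonianLaird(data.frame(estimate = c(0, 2), se = c(1, 1)))
  expect_equal(h$estimate, 1)
  expect_equal(h$tau2, 1)
  expect_equal(h$q_statistic, 2)
  expect_equal(h$se, 1)
  # tau2 = 0 reproduces fixed-effect inverse-variance pooling
  fe <- dersimonianLaird(data.frame(estimate = c(1, 1.1), se = c(0.5, 0.25)))
  w <- c(1 / 0.25, 1 / 0.0625)
  expect_equal(fe$estimate, sum(w * c(1, 1.1)) / sum(w))
  # pooled estimate bounded by the inputs
  set.seed(8)
  for (i in 1:20) {
    est <- data.frame(estimate = rnorm(4), se = runif(4, 0.1, 1))
    d <- dersimonianLaird(est)
    expect_gte(d$estimate, min(est$estimate))
    expect_lte(d$estimate, max(est$estimate))
    expect_gte(d$tau2, 0)
  }
  expect_error(dersimonianLaird(two[1, ]), "at least 2")
})

test_that("Spearman matrices are symmetric, rank-invariant, NA for constants", {
  set.seed(9)
  d <- data.frame(a = rnorm(30), b = rnorm(30))
  d$c <- exp(d$a)                             # strictly monotone transform
  m <- spearmanMatrix(d)
  expect_equal(m["a", "c"], 1)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m, t(m))
  d$k <- 5
  expect_warning(m2 <- spearmanMatrix(d), "constant")
  expect_true(is.na(m2["k", "k"]))
})

test_that("indicator correlations on synthetic cohorts mirror the expected pattern", {
  x <- cached_cohort(5000, 1)
  fi <- frailtyIndex(trueParams(x)$complete_deficits)
  p <- suppressWarnings(buildScorePanel(x, fi = fi))
  m <- spearmanMatrix(p[, c("mrscore", "cont_mrscore", "age_acceleration", "fi")])
  expect_gt(m["mrscore", "cont_mrscore"], 0.6)
  expect_lt(abs(m["age_acceleration", "fi"]), 0.2)
})
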