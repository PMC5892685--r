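test_that("Cox fit maximizes the partial likelihood (analytic toy)", {
  f <- fitCoxModel(c(1, 2, 3), c(1, 1, 1), data.frame(x = c(1, 0, 1)))
  expect_equal(f$effects$estimate, -0.5 * log(2), tolerance = 1e-6)
  # partial likelihood at the optimum is at least the null value
  expect_gte(f$fit$loglik[2], f$fit$loglik[1])
  expect_error(fitCoxModel(c(1, 2), c(0, 0), data.frame(x = 1:2)), "no events")
})

test_that("null covariates give null Cox estimates", {
  set.seed(10)
  n <- 2000
  t <- rexp(n); e <- rbinom(n, 1, 0.7); x <- rnorm(n)
  f <- fitCoxModel(t, e, data.frame(x = x))
  expect_lt(abs(f$effects$estimate), 3 * f$effects$se)
})

test_that("unit weights match the unweighted fit; rescaled weights leave it", {
  x <- cached_cohort(300, 15)
  cd <- cohortData(x)
  f0 <- fitCoxModel(cd$time, cd$event, data.frame(age = cd$age))
  f1 <- fitCoxModel(cd$time, cd$event, data.frame(age = cd$age),
                    weights = rep(1, 300))
  expect_identical(f0$effects$estimate, f1$effects$estimate)
  w <- runif(300, 0.5, 2)
  fa <- fitCoxModel(cd$time, cd$event, data.frame(age = cd$age), weights = w)
  fb <- fitCoxModel(cd$time, cd$event, data.frame(age = cd$age), weights = 3 * w)
  expect_equal(fa$effects$estimate, fb$effects$estimate, tolerance = 1e-8)
})

test_that("case-cohort fit with full subcohort equals the plain Cox fit", {
  full <- cached_cohort(500, 16)
  cd <- cohortData(sampleCaseCohort(full, 1.0, seed = 1))
  df <- data.frame(time = cd$time, event = cd$event,
                   subcohort = cd$subcohort, age = cd$age,
                   dnam_age = cd$dnam_age)
  f1 <- fitCaseCohortCox(df, c("age", "dnam_age"), 1.0)
  cd0 <- cohortData(full)
  f0 <- fitCoxModel(cd0$time, cd0$event,
                    data.frame(age = cd0$age, dnam_age = cd0$dnam_age))
  expect_equal(f1$effects$estimate, f0$effects$estimate, tolerance = 1e-8)
})

test_that("case-cohort robust SE exceeds the naive SE on average", {
  rob <- naive <- numeric(8)
  for (r in 1:8) {
    full <- simulateCohort(simulationConfig(n_subjects = 1200, seed = 300 + r))
    cc <- sampleCaseCohort(full, 0.15, seed = 400 + r)
    cd <- cohortData(cc)
    z <- trueParams(cc)$true_indicators$cont_mrscore
    df <- data.frame(time = cd$time, event = cd$event,
                     subcohort = cd$subcohort, z = as.numeric(scale(z)))
    f <- fitCaseCohortCox(df, "z", 0.15)
    rob[r] <- f$effects$se
    naive[r] <- sqrt(diag(f$fit$naive.var))[1]
  }
  expect_gt(mean(rob), mean(naive))
})

test_that("logistic fits reproduce closed-form odds ratios", {
  y <- rep(c(1, 1, 0, 0), c(10, 10, 10, 10))
  x <- rep(c(1, 0, 1, 0), c(10, 10, 10, 10))
  f <- fitLogisticModel(y, data.frame(x = x))
  expect_equal(f$effects$estimate, 0, tolerance = 1e-8)
  # 2x2 counts (20,10 / 10,20): OR = 4
  y2 <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
  x2 <- rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
  f2 <- fitLogisticModel(y2, data.frame(x = x2))
  expect_equal(f2$effects$hr, 4, tolerance = 1e-6)
  expect_equal(f2$effects$estimate, log(4), tolerance = 1e-6)
  expect_error(fitLogisticModel(y2, data.frame(x = x2, xx = x2)), "collinear")
  sep <- c(rep(0, 20), rep(1, 20))
  expect_error(fitLogisticModel(sep, data.frame(x = seq_len(40))),
               "separation")
})

test_that("effect rescaling exponentiates by the unit ratio", {
  e <- data.frame(term = "s", estimate = log(2), se = 0.1,
                  ci_low = log(1.5), ci_high = log(2.5), p_value = 0.01, n = 100)
  r <- rescaleEffect(e, 0.5)
  expect_equal(r$hr, sqrt(2))
  expect_equal(r$hr_low, 1.5^0.5)
  e1 <- e; e1$estimate <- 0; e1$ci_low <- 0; e1$ci_high <- 0
  expect_equal(rescaleEffect(e1, 3.7)$hr, 1)
  expect_error(rescaleEffect(e, -1), "positive")
})

test_that("MRscore category hazards are monotone on synthetic cohorts", {
  x <- cached_cohort(4000, 17)
  cd <- cohortData(x)
  p <- suppressWarnings(
    buildScorePanel(x, fi = frailtyIndex(trueParams(x)$complete_deficits)))
  f <- fitCoxModel(cd$time, cd$event,
                   data.frame(cat = p$mrscore_category, age = cd$age,
                              sex = cd$sex))
  hr <- f$effects$hr[grepl("^cat", f$effects$term)]
  names(hr) <- sub("^cat", "", f$effects$term[grepl("^cat", f$effects$term)])
  expect_true(hr[">5"] > hr["2-5"] && hr["2-5"] > hr["1"])
})
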