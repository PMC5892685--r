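test_that("simulation is deterministic and structurally sound", {
  cfg <- simulationConfig(n_subjects = 300, seed = 42)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(betas(a), betas(b))
  expect_identical(deficits(a), deficits(b))
  expect_identical(cohortData(a), cohortData(b))

  bm <- betas(a)
  expect_true(all(bm > 0 & bm < 1))
  cd <- cohortData(a)
  expect_true(all(is.finite(cd$time)) && all(cd$time > 0))
  expect_true(all(cd$event %in% 0:1))
  # every subject appears exactly once in each component
  expect_identical(colnames(bm), cd$subject_id)
  expect_identical(rownames(deficits(a)), cd$subject_id)
  expect_identical(rownames(trueParams(a)$complete_deficits), cd$subject_id)
  expect_false(anyDuplicated(cd$subject_id) > 0)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(n_subjects = 1), "n_subjects")
  expect_error(simulationConfig(age_range = c(70, 50)), "age_range")
  expect_error(simulationConfig(dropout_rate = NaN), "non-finite")
  expect_error(simulateCohort(simulationConfig(
    n_subjects = 50, cpg_sds = setNames(rep(0, 10), mortalityWeights()$cpg_id),
    latent_risk_loading = setNames(rep(0, 10), mortalityWeights()$cpg_id),
    batch_shift_sd = 0)), "zero variance")
})

test_that("null indicator effects leave survival equal across score halves", {
  x <- simulateCohort(simulationConfig(n_subjects = 5000, seed = 5,
                                       log_hr_per_sd = c(0, 0, 0)))
  cd <- cohortData(x)
  sc <- trueParams(x)$true_indicators$cont_mrscore
  hi <- sc > median(sc)
  s10 <- vapply(c(TRUE, FALSE), function(h) {
    sf <- survival::survfit(survival::Surv(cd$time[hi == h], cd$event[hi == h]) ~ 1)
    summary(sf, times = 10)$surv
  }, numeric(1))
  expect_lt(abs(diff(s10)), 0.04)
})

test_that("stronger score effects shorten survival of the top quartile", {
  med_top <- vapply(c(0, log(3)), function(b) {
    x <- simulateCohort(simulationConfig(n_subjects = 5000, seed = 9,
                                         log_hr_per_sd = c(b, 0, 0)))
    tp <- trueParams(x)
    top <- tp$true_indicators$cont_mrscore >=
      quantile(tp$true_indicators$cont_mrscore, 0.75)
    median(tp$event_time[top])
  }, numeric(1))
  expect_lt(med_top[2], med_top[1])
})

test_that("default design yields enough deaths for inference", {
  x <- cached_cohort(2000, 1)
  expect_gt(mean(cohortData(x)$event), 0.15)
  expect_lt(mean(cohortData(x)$event), 0.45)
})

test_that("case-cohort sampling keeps all deaths and attaches Barlow weights", {
  full <- cached_cohort(1000, 3)
  cc <- sampleCaseCohort(full, 0.1, seed = 7)
  cd_full <- cohortData(full)
  cd <- cohortData(cc)
  # all deaths present
  expect_setequal(cd$subject_id[cd$event == 1],
                  cd_full$subject_id[cd_full$event == 1])
  # non-case subcohort members carry 1/alpha, cases carry 1
  expect_true(all(cd$weight[cd$event == 0] == 10))
  expect_true(all(cd$weight[cd$event == 1] == 1))
  expect_true(all(cd$event[!cd$subcohort] == 1))
  # subcohort size is Binomial(n, alpha): check a generous 4-sigma band
  n_sub <- sum(cd$subcohort)
  expect_true(abs(n_sub - 100) < 4 * sqrt(1000 * 0.1 * 0.9))
  # determinism
  expect_identical(cohortData(sampleCaseCohort(full, 0.1, seed = 7)), cd)

  # degenerate fraction = 1: everyone kept, all weights 1
  cc1 <- sampleCaseCohort(full, 1.0, seed = 7)
  expect_identical(colnames(cc1), colnames(full))
  expect_true(all(cohortData(cc1)$weight == 1))
})

test_that("nested case-control sampling produces the requested counts", {
  full <- cached_cohort(1000, 3)
  cd_full <- cohortData(full)
  n_case <- sum(cd_full$event)
  ncc <- sampleNestedCaseControl(full, control_ratio = 1, seed = 5)
  expect_equal(ncol(ncc), 2 * n_case)
  ncc2 <- sampleNestedCaseControl(full, control_ratio = 2, seed = 5)
  expect_equal(ncol(ncc2), 3 * n_case)
  expect_equal(sum(cohortData(ncc2)$case == 0), 2 * n_case)
  expect_identical(colnames(sampleNestedCaseControl(full, 1, seed = 5)),
                   colnames(ncc))
  expect_error(sampleNestedCaseControl(full, control_ratio = 50),
               "insufficient")
})

test_that("cohorts round-trip through plain-text files", {
  x <- cached_cohort(60, 8)
  dir <- tempfile()
  writeCohortFiles(x, dir)
  y <- readCohortFiles(dir)
  expect_equal(betas(y), betas(x), tolerance = 1e-12)
  expect_equal(deficits(y), deficits(x))
  expect_equal(cohortData(y)$time, cohortData(x)$time, tolerance = 1e-12)
})
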