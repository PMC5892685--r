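test_that("cont.MRscore is the weighted sum of the 10 beta values", {
  expect_equal(as.numeric(contMRscore(flat_betas(c(0, 0)))), c(0, 0))
  expect_equal(as.numeric(contMRscore(flat_betas(1))), -6.31557)
  # only the hypermethylated CpG set: 2.71749 * 0.5
  b <- flat_betas(0)
  b["cg08362785", ] <- 0.5
  expect_equal(as.numeric(contMRscore(b)), 1.358745)

  expect_error(contMRscore(b[-1, , drop = FALSE]), "cg01612140")
  # missing betas flag subjects instead of dropping them
  b2 <- flat_betas(c(0.5, 0.5))
  b2["cg05575921", 2] <- NA
  s <- contMRscore(b2)
  expect_true(is.na(s[2]) && !is.na(s[1]))
  expect_identical(attr(s, "incomplete"), "P2")
})

test_that("thresholds are direction-specific sample quartiles", {
  set.seed(1)
  b <- matrix(runif(10 * 40), nrow = 10,
              dimnames = list(mortalityWeights()$cpg_id, paste0("P", 1:40)))
  b["cg01612140", 1:4] <- c(0.1, 0.2, 0.3, 0.4)
  th <- deriveThresholds(b[, 1:4])
  # linear-interpolation (type 7) first quartile of (0.1, 0.2, 0.3, 0.4)
  expect_equal(th$cutoff[th$cpg_id == "cg01612140"], 0.175)
  expect_equal(th$cutoff[th$cpg_id == "cg08362785"],
               unname(quantile(b["cg08362785", 1:4], 0.75)))
  # cutoffs stay inside each column's range
  th_all <- deriveThresholds(b)
  rng <- t(apply(b, 1, range))
  expect_true(all(th_all$cutoff >= rng[th_all$cpg_id, 1] &
                  th_all$cutoff <= rng[th_all$cpg_id, 2]))
  # degenerate constant column: cutoff equals the constant, with a warning
  b["cg08362785", ] <- 0.5
  expect_warning(th2 <- deriveThresholds(b), "degenerate")
  expect_equal(th2$cutoff[th2$cpg_id == "cg08362785"], 0.5)
})

test_that("MRscore counts aberrant CpGs and maps to reporting categories", {
  wt <- mortalityWeights()
  th <- data.frame(cpg_id = wt$cpg_id, cutoff = 0.3, direction = wt$direction)
  # all betas above every hypo cutoff and below the hyper cutoff: score 0
  b <- flat_betas(c(0.6, 0.6))
  b["cg08362785", ] <- 0.2
  s <- mrScore(b, th)
  expect_equal(s$mrscore, c(0L, 0L))
  expect_equal(as.character(s$mrscore_category), c("0", "0"))
  # flip k hypo CpGs below cutoff
  flip <- function(k) {
    bb <- b[, 1, drop = FALSE]
    hypo <- wt$cpg_id[wt$direction == "hypo"]
    bb[hypo[seq_len(k)], 1] <- 0.1
    mrScore(bb, th)
  }
  expect_equal(as.character(flip(1)$mrscore_category), "1")
  expect_equal(as.character(flip(3)$mrscore_category), "2-5")
  expect_equal(as.character(flip(6)$mrscore_category), ">5")
  # all ten aberrant (inclusive boundaries)
  b10 <- flat_betas(0.3)
  expect_equal(mrScore(b10, th)$mrscore, 10L)
  expect_equal(as.character(mrscoreCategory(10L)), ">5")
})

test_that("age acceleration is the OLS residual of DNAm age on age", {
  # constant offset is absorbed by the intercept
  age <- c(51, 57, 63, 70, 75)
  expect_equal(unname(ageAcceleration(age + 5, age)), rep(0, 5))
  # closed-form three-point example
  expect_equal(unname(ageAcceleration(c(50, 60, 80), c(50, 60, 70))),
               c(5 / 3, -10 / 3, 5 / 3))
  # exact orthogonality to age, and shift invariance
  set.seed(2)
  a <- runif(200, 50, 75)
  d <- a + rnorm(200, 0, 5)
  aa <- ageAcceleration(d, a)
  expect_lt(abs(cor(aa, a)), 1e-10)
  expect_equal(ageAcceleration(d + 7.3, a), aa)
  expect_error(ageAcceleration(d, rep(60, 200)), "constant")
})

test_that("probe filtering applies detection, missingness and sex-chromosome rules", {
  ids <- c("cgA", "cgB", "cgC")
  b <- matrix(runif(60), nrow = 3, dimnames = list(ids, paste0("S", 1:20)))
  cmap <- data.frame(cpg_id = ids, chromosome = c("X", "1", "2"))
  # cgB: 15% missing; cgC: clean
  b["cgB", 1:3] <- NA
  out <- filterProbes(b, chromosome_map = cmap)
  expect_identical(rownames(out$betas), "cgC")
  expect_identical(out$exclusions$reason[out$exclusions$probe == "cgA"],
                   "sex chromosome")
  expect_identical(out$exclusions$reason[out$exclusions$probe == "cgB"],
                   "missingness")

  # detection failures are set missing before the missingness rule
  b2 <- matrix(runif(40), nrow = 2,
               dimnames = list(c("cgD", "cgE"), paste0("S", 1:20)))
  dp <- matrix(0, 2, 20, dimnames = dimnames(b2))
  dp["cgD", 1:5] <- 0.5                      # 25% detection failures
  cmap2 <- data.frame(cpg_id = c("cgD", "cgE"), chromosome = c("3", "4"))
  out2 <- filterProbes(b2, dp, cmap2)
  expect_identical(rownames(out2$betas), "cgE")
  # three-probe toy where one probe fails each rule: none survive
  b3 <- b
  b3["cgC", 1:4] <- NA
  dp3 <- matrix(0, 3, 20, dimnames = dimnames(b3))
  out3 <- filterProbes(b3, dp3, cmap)
  expect_equal(nrow(out3$betas), 0)
  expect_error(filterProbes(b, chromosome_map = cmap[-2, ]), "cgB")
})

test_that("count and continuous scores are strongly rank-correlated on synthetic data", {
  x <- cached_cohort(1000, 21)
  p <- suppressWarnings(buildScorePanel(x, fi = rep(0.2, 1000)))
  expect_gt(cor(p$mrscore, p$cont_mrscore, method = "spearman"), 0.6)
  # re-scoring the same input is bit-identical
  p2 <- suppressWarnings(buildScorePanel(x, fi = rep(0.2, 1000)))
  expect_identical(p, p2)
  # z-columns standardized within the sample
  for (cl in c("z_cont_mrscore", "z_age_acceleration"))
    expect_equal(c(mean(p[[cl]]), sd(p[[cl]])), c(0, 1), tolerance = 1e-12)
})
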