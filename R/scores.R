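# Mortality risk score construction.  Two forms: the count-based MRscore
# (number of CpGs, out of 10, with methylation in the mortality-associated
# extreme quartile) and the continuous cont.MRscore (weighted sum of the 10
# beta values with fixed published LASSO weights).

#' The 10-CpG mortality score weight table
#'
#' Fixed published weights of the continuous mortality risk score.  Nine
#' CpGs are hypomethylated with increasing mortality risk (negative
#' weights); cg08362785 is the single hypermethylated CpG (positive
#' weight).  The weights sum to -6.31557, so a subject with beta = 1 at all
#' 10 CpGs scores -6.31557 and one with beta = 0 scores 0.
#'
#' @return `data.frame` with columns `cpg_id`, `weight`, `direction`.
#' @export
mortalityWeights <- function() {
  out <- data.frame(
    cpg_id = c("cg01612140", "cg05575921", "cg06126421", "cg08362785",
               "cg10321156", "cg14975410", "cg19572487", "cg23665802",
               "cg24704287", "cg25983901"),
    weight = c(-0.38253, -0.92224, -1.70129, 2.71749, -0.02073,
               -0.04156, -0.28069, -0.89440, -2.98637, -1.80325),
    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$weight > 0, "hyper", "hypo")
  out
}

.check_weight_table <- function(weights) {
  .assert(is.data.frame(weights) &&
          all(c("cpg_id", "weight", "direction") %in% colnames(weights)),
          "weights must have columns cpg_id, weight, direction")
  .assert(all(weights$direction %in% c("hyper", "hypo")),
          "direction must be 'hyper' or 'hypo'")
  weights
}

.need_cpgs <- function(betas, cpgs) {
  missing <- setdiff(cpgs, rownames(betas))
  if (length(missing))
    stop("beta matrix lacks score CpG(s): ", paste(missing, collapse = ", "))
}

#' Filter methylation probes
#'
#' Standard pre-processing exclusions: probes with a detection p-value above
#' `p_cut` in any sample have those values set missing first; then probes
#' with more than `miss_cut` missing values, and probes on the X or Y
#' chromosome, are dropped.
#'
#' @param betas CpG x sample beta matrix.
#' @param detection_p optional matrix of detection p-values, same dimensions.
#' @param chromosome_map `data.frame` with columns `cpg_id`, `chromosome`
#'   covering every probe in `betas`.
#' @param p_cut detection p-value threshold (default 0.01).
#' @param miss_cut maximum tolerated missing proportion (default 0.10).
#' @return list with `betas` (filtered matrix, detection failures set `NA`)
#'   and `exclusions` (`data.frame` of probe, reason, statistic).
#' @export
filterProbes <- function(betas, detection_p = NULL, chromosome_map,
                         p_cut = 0.01, miss_cut = 0.10) {
  probes <- rownames(betas)
  .assert(!is.null(probes), "beta matrix needs CpG row names")
  unmapped <- setdiff(probes, chromosome_map$cpg_id)
  if (length(unmapped))
    stop("no chromosome annotation for probe(s): ",
         paste(unmapped, collapse = ", "))
  if (!is.null(detection_p)) {
    .assert(all(dim(detection_p) == dim(betas)),
            "detection_p must match the beta matrix dimensions")
    betas[detection_p[probes, , drop = FALSE] > p_cut] <- NA
  }
  chr <- chromosome_map$chromosome[match(probes, chromosome_map$cpg_id)]
  miss_frac <- rowMeans(is.na(betas))
  sex_chr <- chr %in% c("X", "Y", "chrX", "chrY")
  too_missing <- miss_frac > miss_cut
  excl <- rbind(
    if (any(sex_chr)) data.frame(probe = probes[sex_chr],
                                 reason = "sex chromosome",
                                 statistic = NA_real_),
    if (any(too_missing & !sex_chr))
      data.frame(probe = probes[too_missing & !sex_chr],
                 reason = "missingness",
                 statistic = miss_frac[too_missing & !sex_chr]))
  if (is.null(excl))
    excl <- data.frame(probe = character(), reason = character(),
                       statistic = numeric())
  keep <- !(sex_chr | too_missing)
  list(betas = betas[keep, , drop = FALSE], exclusions = excl)
}

#' Continuous mortality risk score
#'
#' Weighted sum of the 10 score-CpG beta values,
#' `sum_k weight_k * beta_k`, per subject.  Subjects with any missing score
#' CpG receive `NA` and are reported in the `incomplete` attribute rather
#' than silently dropped.
#'
#' @param betas CpG x subject beta matrix containing all weighted CpGs.
#' @param weights weight table as from [mortalityWeights()].
#' @return named numeric vector of scores; attribute `incomplete` lists
#'   subjects with missing score CpGs.
#' @examples
#' b <- matrix(1, 10, 2, dimnames = list(mortalityWeights()$cpg_id, c("a", "b")))
#' contMRscore(b)  # -6.31557 for both subjects
#' @export
contMRscore <- function(betas, weights = mortalityWeights()) {
  .check_weight_table(weights)
  .need_cpgs(betas, weights$cpg_id)
  b <- betas[weights$cpg_id, , drop = FALSE]
  score <- as.numeric(crossprod(b, weights$weight))
  names(score) <- colnames(betas)
  incomplete <- colnames(betas)[colSums(is.na(b)) > 0]
  score[colSums(is.na(b)) > 0] <- NA_real_
  attr(score, "incomplete") <- incomplete
  score
}

#' Derive aberrance thresholds from a sample
#'
#' The aberrant direction of each score CpG is the extreme quartile in the
#' direction associated with mortality: the lowest quartile (Q1) for
#' hypomethylated CpGs and the highest quartile (Q3) for the hypermethylated
#' CpG.  Quantiles use linear interpolation between order statistics
#' (`type = 7`), the convention fixed and documented for this package.
#'
#' @param betas CpG x subject beta matrix (>= 4 subjects).
#' @param weights weight table giving each CpG's direction.
#' @return `data.frame` with columns `cpg_id`, `cutoff`, `direction`.
#' @export
deriveThresholds <- function(betas, weights = mortalityWeights()) {
  .check_weight_table(weights)
  .need_cpgs(betas, weights$cpg_id)
  .assert(ncol(betas) >= 4, "need at least 4 subjects to derive quartiles")
  cutoff <- vapply(seq_len(nrow(weights)), function(k) {
    x <- betas[weights$cpg_id[k], ]
    x <- x[!is.na(x)]
    if (length(unique(x)) == 1L)
      warning("degenerate (constant) beta distribution for ",
              weights$cpg_id[k], "; cutoff equals the constant")
    q <- if (weights$direction[k] == "hyper") 0.75 else 0.25
    unname(quantile(x, q, type = 7))
  }, numeric(1))
  data.frame(cpg_id = weights$cpg_id, cutoff = cutoff,
             direction = weights$direction, stringsAsFactors = FALSE)
}

#' Count-based mortality risk score and category
#'
#' Counts score CpGs with aberrant methylation: beta at or below the cutoff
#' for hypomethylated CpGs, at or above the cutoff for the hypermethylated
#' CpG (inclusive boundaries, so all-tied degenerate distributions remain
#' well defined).  The score ranges 0-10 and is grouped into the reporting
#' categories 0, 1, 2-5 and >5.
#'
#' @param betas CpG x subject beta matrix.
#' @param thresholds a threshold table from [deriveThresholds()] or supplied
#'   externally (columns `cpg_id`, `cutoff`, `direction`).
#' @return `data.frame` with `subject_id`, `mrscore`, `mrscore_category`.
#' @export
mrScore <- function(betas, thresholds) {
  .assert(all(c("cpg_id", "cutoff", "direction") %in% colnames(thresholds)),
          "thresholds must have columns cpg_id, cutoff, direction")
  .need_cpgs(betas, thresholds$cpg_id)
  b <- betas[thresholds$cpg_id, , drop = FALSE]
  aberrant <- (thresholds$direction == "hypo") * (b <= thresholds$cutoff) +
    (thresholds$direction == "hyper") * (b >= thresholds$cutoff)
  score <- as.integer(colSums(aberrant))
  score[colSums(is.na(b)) > 0] <- NA_integer_
  data.frame(subject_id = colnames(betas), mrscore = score,
             mrscore_category = mrscoreCategory(score),
             stringsAsFactors = FALSE)
}

#' MRscore reporting category
#'
#' @param score integer scores 0-10.
#' @return factor with levels `"0"`, `"1"`, `"2-5"`, `">5"`.
#' @export
mrscoreCategory <- function(score) {
  .assert(all(is.na(score) | (score >= 0 & score <= 10)),
          "mrscore must lie in 0..10")
  cut(score, breaks = c(-0.5, 0.5, 1.5, 5.5, 10.5),
      labels = c("0", "1", "2-5", ">5"))
}

#' Epigenetic age acceleration
#'
#' Residuals of DNAm age regressed on chronological age by ordinary least
#' squares, computed within the analysis sample.  Positive values mean the
#' methylome looks older than expected for the subject's age.  Residuals
#' are exactly uncorrelated with age and invariant to adding a constant to
#' all DNAm ages.
#'
#' @param dnam_age numeric vector of DNAm ages (years).
#' @param age chronological ages (years), same length, non-constant.
#' @return numeric vector of residuals (years).
#' @export
ageAcceleration <- function(dnam_age, age) {
  .assert(length(dnam_age) == length(age), "length mismatch")
  ok <- complete.cases(dnam_age, age)
  .assert(sum(ok) >= 3, "need at least 3 complete subjects")
  .assert(sd(age[ok]) > 0, "chronological age is constant; slope undefined")
  out <- rep(NA_real_, length(age))
  out[ok] <- resid(lm(dnam_age[ok] ~ age[ok]))
  names(out) <- names(dnam_age)
  out
}

#' Assemble the per-subject score panel
#'
#' Computes every survival indicator for a cohort: MRscore (with category),
#' cont.MRscore, DNAm age, age acceleration, frailty index, and the
#' within-sample z-score of each continuous indicator (z-scores are
#' standardized within the analysis sample, so per-SD effects use the
#' sample's own SD).
#'
#' @param cohort a [MethylCohort-class].
#' @param thresholds optional externally supplied threshold table; by
#'   default thresholds are derived in-sample via [deriveThresholds()].
#' @param fi optional per-subject frailty index (e.g. pooled over
#'   imputations); by default computed from the complete rows of the
#'   cohort's deficit panel with [frailtyIndex()] on an imputed panel when
#'   the panel has missing values.
#' @param weights weight table for the continuous score.
#' @param impute_m,impute_seed imputation count and seed used when the
#'   deficit panel contains missing values and `fi` is not supplied.
#' @return `data.frame` (one row per subject): identifiers, indicators and
#'   `z_`-prefixed standardized versions.
#' @export
buildScorePanel <- function(cohort, thresholds = NULL, fi = NULL,
                            weights = mortalityWeights(),
                            impute_m = 5L, impute_seed = 1L) {
  cd <- cohortData(cohort)
  b <- betas(cohort)
  if (is.null(thresholds)) thresholds <- deriveThresholds(b, weights)
  ms <- mrScore(b, thresholds)
  cont <- contMRscore(b, weights)
  aa <- ageAcceleration(cd$dnam_age, cd$age)
  if (is.null(fi)) {
    def <- deficits(cohort)
    if (any(is.na(def))) {
      imp <- imputeDeficits(def, covariates = cd, m = impute_m,
                            seed = impute_seed)
      fi <- rowMeans(vapply(imp$panels, frailtyIndex,
                            numeric(nrow(def))))
    } else fi <- frailtyIndex(def)
  }
  zs <- function(x) {
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mean(x, na.rm = TRUE)) / s
  }
  data.frame(
    subject_id = cd$subject_id,
    mrscore = ms$mrscore, mrscore_category = ms$mrscore_category,
    cont_mrscore = unname(cont), dnam_age = cd$dnam_age,
    age_acceleration = unname(aa), fi = unname(fi),
    z_mrscore = zs(ms$mrscore), z_cont_mrscore = zs(unname(cont)),
    z_age_acceleration = zs(unname(aa)), z_fi = zs(unname(fi)),
    stringsAsFactors = FALSE)
}
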