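# Synthetic-cohort generator.  The generator is the package's testbed: it
# draws a shared latent risk factor that loads on the 10 score-CpG betas
# (logit scale) and on the deficit liability, so the methylation risk score
# and the frailty index are weakly positively coupled; DNAm age tracks
# chronological age with independent noise; survival is Weibull with
# log-hazard linear in the z-scores of the three indicators plus age.

# evaluate expr under a temporary RNG state so simulation functions are
# deterministic without clobbering the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a simulation configuration
#'
#' Returns a validated [SimulationConfig-class] whose defaults are calibrated
#' so that, at large n, the synthetic cohort reproduces the descriptive
#' anchors of the population it emulates: Spearman correlation of age with
#' DNAm age around 0.75, frailty index mean around 25% with SD around 15%,
#' ages uniform on 50-75 years, roughly 25-30% deaths over 14 years of
#' follow-up, and per-SD hazard ratios of about 2.0 (cont.MRscore), 1.4
#' (frailty index) and 1.16 (age acceleration).
#'
#' @param n_subjects cohort size.
#' @param seed integer RNG seed.
#' @param age_range uniform age range, years.
#' @param dnam_age_slope,dnam_age_intercept,dnam_age_noise_sd DNAm-age
#'   measurement model (years).
#' @param n_deficits number of deficits in the panel.
#' @param deficit_base_logit log-odds of a deficit at the youngest age for an
#'   average subject and average deficit.
#' @param deficit_age_gradient per-year increment of the deficit log-odds.
#' @param deficit_sd SD of per-deficit prevalence offsets (logit scale).
#' @param frailty_liability_sd SD of the subject-specific deficit liability.
#' @param frailty_latent_loading loading of the shared latent risk factor on
#'   the deficit liability.
#' @param cpg_means,cpg_sds logit-scale means and residual SDs of the 10
#'   score CpGs (named by probe ID).
#' @param latent_risk_loading magnitude of the latent-risk loading on each
#'   CpG; the sign is taken from the CpG's mortality direction
#'   (hypomethylated CpGs lose methylation as risk rises).
#' @param n_extra_cpgs,extra_cpg_loading additional simulated CpGs beyond
#'   the 10 score CpGs, and their (signed) latent loading.
#' @param log_hr_per_sd length-3 per-SD log hazard ratios for cont.MRscore,
#'   frailty index and age acceleration.
#' @param log_hr_age per-year log hazard ratio of chronological age.
#' @param baseline_hazard_shape,baseline_hazard_scale Weibull baseline
#'   hazard parameters (years).
#' @param admin_censor_years administrative censoring horizon.
#' @param dropout_rate per-year exponential dropout rate.
#' @param deficit_missing_rate MCAR missingness rate applied to the deficit
#'   panel (the complete panel is retained in `trueParams`).
#' @param n_batches,batch_shift_sd number of methylation batches and SD of
#'   the common logit-scale batch shift.
#' @param subcohort_fraction default subcohort sampling fraction for
#'   [sampleCaseCohort()].
#' @param control_ratio default controls-per-case ratio for
#'   [sampleNestedCaseControl()].
#' @return a `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(n_subjects = 200, seed = 1)
#' cohort <- simulateCohort(cfg)
#' cohort
#' @export
simulationConfig <- function(n_subjects = 5000L, seed = 1L,
                             age_range = c(50, 75),
                             dnam_age_slope = 1.0, dnam_age_intercept = 0.0,
                             dnam_age_noise_sd = 6.5,
                             n_deficits = 34L,
                             deficit_base_logit = -1.75,
                             deficit_age_gradient = 0.04,
                             deficit_sd = 0.4,
                             frailty_liability_sd = 0.6,
                             frailty_latent_loading = 0.25,
                             cpg_means = NULL, cpg_sds = NULL,
                             latent_risk_loading = 0.10,
                             n_extra_cpgs = 0L, extra_cpg_loading = -0.1,
                             log_hr_per_sd = c(log(2.0), log(1.4), log(1.16)),
                             log_hr_age = 0.07,
                             baseline_hazard_shape = 1.1,
                             baseline_hazard_scale = 50,
                             admin_censor_years = 14,
                             dropout_rate = 0.01,
                             deficit_missing_rate = 0.05,
                             n_batches = 4L, batch_shift_sd = 0.1,
                             subcohort_fraction = 0.1,
                             control_ratio = 1) {
  wt <- mortalityWeights()
  if (is.null(cpg_means)) {
    beta_means <- c(cg01612140 = 0.45, cg05575921 = 0.70, cg06126421 = 0.55,
                    cg08362785 = 0.25, cg10321156 = 0.50, cg14975410 = 0.45,
                    cg19572487 = 0.40, cg23665802 = 0.60, cg24704287 = 0.35,
                    cg25983901 = 0.55)
    cpg_means <- .logit(beta_means[wt$cpg_id])
  }
  if (is.null(cpg_sds)) cpg_sds <- setNames(rep(0.35, nrow(wt)), wt$cpg_id)
  if (length(latent_risk_loading) == 1L) {
    sign <- ifelse(wt$direction == "hyper", 1, -1)
    latent_risk_loading <- setNames(latent_risk_loading * sign, wt$cpg_id)
  }
  new("SimulationConfig",
      n_subjects = as.integer(n_subjects), seed = as.integer(seed),
      age_range = as.numeric(age_range),
      dnam_age_slope = dnam_age_slope, dnam_age_intercept = dnam_age_intercept,
      dnam_age_noise_sd = dnam_age_noise_sd,
      n_deficits = as.integer(n_deficits),
      deficit_base_logit = deficit_base_logit,
      deficit_age_gradient = deficit_age_gradient,
      deficit_sd = deficit_sd,
      frailty_liability_sd = frailty_liability_sd,
      frailty_latent_loading = frailty_latent_loading,
      cpg_means = cpg_means, cpg_sds = cpg_sds,
      latent_risk_loading = latent_risk_loading,
      n_extra_cpgs = as.integer(n_extra_cpgs),
      extra_cpg_loading = extra_cpg_loading,
      log_hr_per_sd = log_hr_per_sd, log_hr_age = log_hr_age,
      baseline_hazard_shape = baseline_hazard_shape,
      baseline_hazard_scale = baseline_hazard_scale,
      admin_censor_years = admin_censor_years,
      dropout_rate = dropout_rate,
      deficit_missing_rate = deficit_missing_rate,
      n_batches = as.integer(n_batches), batch_shift_sd = batch_shift_sd,
      subcohort_fraction = subcohort_fraction,
      control_ratio = control_ratio)
}

#' Simulate a full synthetic cohort
#'
#' Draws a complete cohort under the generative model described in
#' [simulationConfig()]: uniform ages; DNAm age linear in age with Gaussian
#' noise; a standard-normal latent risk factor loading on the score-CpG
#' betas (logit scale) and on the deficit liability; Bernoulli deficits with
#' an age gradient; Weibull survival with log-hazard linear in the z-scores
#' of the realized cont.MRscore, frailty index and age acceleration plus
#' chronological age; censoring at the administrative horizon or exponential
#' dropout, whichever comes first.
#'
#' @param config a [SimulationConfig-class] from [simulationConfig()].
#' @return a [MethylCohort-class] with design `"cohort"`.  `trueParams()`
#'   holds every generating value plus per-subject truths (latent risk,
#'   generating indicator values, uncensored event times, the complete
#'   deficit panel before missingness).
#' @export
simulateCohort <- function(config) {
  validObject(config)
  n <- config@n_subjects
  if (any(config@log_hr_per_sd != 0)) {
    if (all(config@cpg_sds == 0) && all(config@latent_risk_loading == 0) &&
        config@batch_shift_sd == 0 && config@log_hr_per_sd[1] != 0)
      stop("cont.MRscore has zero variance but a nonzero log-HR was requested")
  }
  wt <- mortalityWeights()
  .with_seed(config@seed, {
    ids <- sprintf("S%05d", seq_len(n))
    age <- runif(n, config@age_range[1], config@age_range[2])
    sex <- factor(sample(c("men", "women"), n, replace = TRUE),
                  levels = c("men", "women"))
    smoking <- factor(sample(c("never", "former", "current"), n,
                             replace = TRUE, prob = c(0.47, 0.33, 0.20)),
                      levels = c("never", "former", "current"))
    alcohol <- pmax(0, rnorm(n, 10, 8))              # g/day
    # leukocyte composition covariates (plain proportions, not estimated)
    cd8t <- pmin(pmax(rnorm(n, 0.08, 0.03), 0.001), 0.5)
    cd4t <- pmin(pmax(rnorm(n, 0.17, 0.05), 0.001), 0.6)
    gran <- pmin(pmax(rnorm(n, 0.55, 0.10), 0.05), 0.95)
    batch <- factor(sample(seq_len(config@n_batches), n, replace = TRUE))
    batch_shift <- rnorm(config@n_batches, 0, config@batch_shift_sd)

    latent <- rnorm(n)                               # shared risk factor

    dnam_age <- config@dnam_age_intercept + config@dnam_age_slope * age +
      rnorm(n, 0, config@dnam_age_noise_sd)

    # score CpGs (+ optional extra CpGs) on the logit scale
    p <- length(config@cpg_means)
    noise <- matrix(rnorm(p * n, 0, config@cpg_sds), nrow = p)
    logit_beta <- config@cpg_means + config@latent_risk_loading %o% latent +
      rep(batch_shift[as.integer(batch)], each = p) + noise
    beta_mat <- .invlogit(logit_beta)
    rownames(beta_mat) <- names(config@cpg_means)
    if (config@n_extra_cpgs > 0L) {
      k <- config@n_extra_cpgs
      extra_means <- rnorm(k, 0, 0.5)
      load <- rep_len(config@extra_cpg_loading, k)
      xnoise <- matrix(rnorm(k * n, 0, 0.35), nrow = k)
      extra <- .invlogit(extra_means + load %o% latent +
        rep(batch_shift[as.integer(batch)], each = k) + xnoise)
      rownames(extra) <- sprintf("cg9%07d", seq_len(k))
      beta_mat <- rbind(beta_mat, extra)
    }
    colnames(beta_mat) <- ids
    # keep betas strictly inside (0,1)
    beta_mat <- pmin(pmax(beta_mat, 1e-6), 1 - 1e-6)

    # deficit panel: Bernoulli with age gradient, per-deficit offset,
    # subject liability and latent-risk loading
    d <- config@n_deficits
    # centred so per-deficit heterogeneity never shifts the panel-average
    # prevalence (the FI calibration target) between realizations
    deficit_offset <- rnorm(d, 0, config@deficit_sd)
    deficit_offset <- deficit_offset - mean(deficit_offset)
    liability <- config@frailty_latent_loading * latent +
      rnorm(n, 0, config@frailty_liability_sd)
    eta <- config@deficit_base_logit +
      config@deficit_age_gradient * (age - config@age_range[1]) + liability
    pr <- .invlogit(outer(eta, deficit_offset, `+`))
    complete_deficits <- matrix(rbinom(n * d, 1L, pr), nrow = n)
    dimnames(complete_deficits) <- list(ids, sprintf("deficit_%02d", seq_len(d)))
    def <- complete_deficits
    if (config@deficit_missing_rate > 0) {
      mask <- matrix(runif(n * d) < config@deficit_missing_rate, nrow = n)
      def[mask] <- NA_integer_
    }

    # realized indicator values drive the hazard
    wvec <- setNames(wt$weight, wt$cpg_id)
    cont_score <- as.numeric(crossprod(beta_mat[wt$cpg_id, , drop = FALSE], wvec))
    fi_true <- rowMeans(complete_deficits)
    aa <- resid(lm(dnam_age ~ age))
    zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else {
      if (any(config@log_hr_per_sd != 0))
        stop("degenerate (zero-variance) indicator with nonzero log-HR")
      x * 0
    }
    lp <- config@log_hr_per_sd[1] * zs(cont_score) +
      config@log_hr_per_sd[2] * zs(fi_true) +
      config@log_hr_per_sd[3] * zs(aa) +
      config@log_hr_age * (age - mean(age))

    # Weibull event times: S(t|x) = exp(-(t/scale)^shape * e^lp)
    u <- runif(n)
    t_event <- config@baseline_hazard_scale *
      (-log(u) * exp(-lp))^(1 / config@baseline_hazard_shape)
    t_drop <- if (config@dropout_rate > 0) rexp(n, config@dropout_rate)
              else rep(Inf, n)
    t_cens <- pmin(config@admin_censor_years, t_drop)
    time <- pmax(pmin(t_event, t_cens), 1e-6)
    event <- as.integer(t_event <= t_cens)

    cd <- S4Vectors::DataFrame(
      age = age, sex = sex, smoking = smoking, alcohol = alcohol,
      cd8t = cd8t, cd4t = cd4t, gran = gran, batch = batch,
      dnam_age = dnam_age, time = time, event = event,
      row.names = ids)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(betas = beta_mat), colData = cd)
    tp <- list(
      config = config,
      latent_risk = setNames(latent, ids),
      linear_predictor = setNames(lp, ids),
      event_time = setNames(t_event, ids),
      complete_deficits = complete_deficits,
      true_indicators = data.frame(subject_id = ids,
                                   cont_mrscore = cont_score,
                                   fi = fi_true, aa = aa,
                                   row.names = ids))
    new("MethylCohort", se, deficits = def, design = "cohort",
        trueParams = tp)
  })
}

#' Draw a case-cohort sample
#'
#' Returns all deaths plus a Bernoulli-sampled subcohort of the stated
#' fraction, with Barlow design weights attached: subcohort non-cases carry
#' weight `1/fraction` (they stand in for the full cohort's risk sets),
#' cases carry weight 1 at their own failure.  Columns `subcohort` and
#' `weight` are added to the cohort data; the sampling fraction is recorded
#' in `trueParams()$sampling_fraction`.
#'
#' @param full a full-cohort [MethylCohort-class].
#' @param subcohort_fraction sampling fraction in (0, 1].
#' @param seed integer seed for the subcohort draw.
#' @return a [MethylCohort-class] with design `"casecohort"`.
#' @export
sampleCaseCohort <- function(full, subcohort_fraction = trueParams(full)$config@subcohort_fraction,
                             seed = 1L) {
  .assert(is(full, "MethylCohort"), "'full' must be a MethylCohort")
  .assert(subcohort_fraction > 0 && subcohort_fraction <= 1,
          "subcohort_fraction must be in (0, 1]")
  cd <- SummarizedExperiment::colData(full)
  .with_seed(seed, {
    sub <- runif(ncol(full)) < subcohort_fraction
    if (!any(sub)) stop("subcohort_fraction produced an empty subcohort")
    keep <- sub | cd$event == 1
    out <- full[, keep]
    cd2 <- SummarizedExperiment::colData(out)
    cd2$subcohort <- sub[keep]
    cd2$weight <- ifelse(cd2$event == 1, 1, 1 / subcohort_fraction)
    SummarizedExperiment::colData(out) <- cd2
    out@design <- "casecohort"
    out@trueParams <- c(out@trueParams,
                        list(sampling_fraction = subcohort_fraction))
    tp <- out@trueParams
    for (nm in c("latent_risk", "linear_predictor", "event_time"))
      if (!is.null(tp[[nm]])) tp[[nm]] <- tp[[nm]][colnames(out)]
    if (!is.null(tp$complete_deficits))
      tp$complete_deficits <- tp$complete_deficits[colnames(out), , drop = FALSE]
    if (!is.null(tp$true_indicators))
      tp$true_indicators <- tp$true_indicators[colnames(out), , drop = FALSE]
    out@trueParams <- tp
    out
  })
}

#' Draw a nested case-control sample
#'
#' Keeps every case (death) and samples `control_ratio` controls per case
#' without replacement from the non-cases; adds a binary `case` column used
#' as the outcome of logistic models.
#'
#' @param full a full-cohort [MethylCohort-class].
#' @param control_ratio controls per case.
#' @param seed integer seed for the control draw.
#' @return a [MethylCohort-class] with design `"ncc"`.
#' @export
sampleNestedCaseControl <- function(full, control_ratio = trueParams(full)$config@control_ratio,
                                    seed = 1L) {
  .assert(is(full, "MethylCohort"), "'full' must be a MethylCohort")
  cd <- SummarizedExperiment::colData(full)
  cases <- which(cd$event == 1)
  noncases <- which(cd$event == 0)
  n_controls <- round(control_ratio * length(cases))
  if (n_controls > length(noncases))
    stop("insufficient non-cases for the requested control ratio (need ",
         n_controls, ", have ", length(noncases), ")")
  .with_seed(seed, {
    controls <- sample(noncases, n_controls)
    keep <- sort(c(cases, controls))
    out <- full[, keep]
    cd2 <- SummarizedExperiment::colData(out)
    cd2$case <- as.integer(cd2$event == 1)
    SummarizedExperiment::colData(out) <- cd2
    out@design <- "ncc"
    tp <- out@trueParams
    for (nm in c("latent_risk", "linear_predictor", "event_time"))
      if (!is.null(tp[[nm]])) tp[[nm]] <- tp[[nm]][colnames(out)]
    if (!is.null(tp$complete_deficits))
      tp$complete_deficits <- tp$complete_deficits[colnames(out), , drop = FALSE]
    if (!is.null(tp$true_indicators))
      tp$true_indicators <- tp$true_indicators[colnames(out), , drop = FALSE]
    out@trueParams <- tp
    out
  })
}

#' Write a cohort to plain-text files
#'
#' Writes `cohort.tsv` (one row per subject), `betas.csv` (CpG rows x
#' subject columns) and `deficits.tsv` (0/1/NA) into `dir`.
#'
#' @param x a [MethylCohort-class].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeCohortFiles <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.tsv"),
             betas = file.path(dir, "betas.csv"),
             deficits = file.path(dir, "deficits.tsv"))
  write.table(cohortData(x), paths["cohort"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(data.frame(cpg_id = rownames(betas(x)), betas(x),
                       check.names = FALSE),
            paths["betas"], row.names = FALSE, quote = FALSE)
  write.table(data.frame(subject_id = rownames(deficits(x)), deficits(x),
                         check.names = FALSE),
              paths["deficits"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a cohort back from plain-text files
#'
#' Inverse of [writeCohortFiles()]; reconstructs a [MethylCohort-class]
#' (without generating truths).
#'
#' @param dir directory holding `cohort.tsv`, `betas.csv`, `deficits.tsv`.
#' @param design design label of the stored sample.
#' @return a [MethylCohort-class].
#' @export
readCohortFiles <- function(dir, design = "cohort") {
  cohort <- read.delim(file.path(dir, "cohort.tsv"), stringsAsFactors = TRUE)
  bet <- read.csv(file.path(dir, "betas.csv"), check.names = FALSE)
  bmat <- as.matrix(bet[, -1, drop = FALSE])
  rownames(bmat) <- bet$cpg_id
  defp <- file.path(dir, "deficits.tsv")
  def <- if (file.exists(defp)) {
    dd <- read.delim(defp, check.names = FALSE)
    m <- as.matrix(dd[, -1, drop = FALSE]); rownames(m) <- dd$subject_id
    storage.mode(m) <- "integer"; m
  } else matrix(integer(), 0, 0)
  ids <- cohort$subject_id
  cd <- S4Vectors::DataFrame(cohort[, setdiff(colnames(cohort), "subject_id"),
                                    drop = FALSE], row.names = ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(betas = bmat[, ids, drop = FALSE]), colData = cd)
  new("MethylCohort", se, deficits = def[ids, , drop = FALSE],
      design = design, trueParams = list())
}

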