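#' Simulation configuration for synthetic methylation cohorts
#'
#' An S4 container for every generating value of the synthetic-cohort model:
#' sample size, age range, the DNAm-age measurement model, the deficit panel
#' model, the 10 score-CpG beta distributions, the shared latent-risk
#' loadings that couple methylation to frailty, per-SD log hazard ratios of
#' the three survival indicators, Weibull baseline hazard, censoring, batch
#' structure and the two reduced sampling designs.
#'
#' Construct with [simulationConfig()], which supplies calibrated defaults.
#'
#' @slot n_subjects integer, cohort size.
#' @slot seed integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @slot age_range numeric length-2, uniform age range in years.
#' @slot dnam_age_slope,dnam_age_intercept,dnam_age_noise_sd DNAm age =
#'   intercept + slope * age + N(0, noise_sd) years.
#' @slot n_deficits integer, deficits in the panel.
#' @slot deficit_base_logit,deficit_age_gradient baseline log-odds of a
#'   deficit at the youngest age and its per-year increment.
#' @slot deficit_sd per-deficit prevalence heterogeneity (logit scale).
#' @slot frailty_liability_sd subject-level deficit liability SD (logit).
#' @slot frailty_latent_loading loading of the shared latent risk factor on
#'   the deficit liability.
#' @slot cpg_means,cpg_sds logit-scale mean and residual SD per score CpG.
#' @slot latent_risk_loading per-CpG loading (logit scale) of the latent
#'   risk factor; sign follows the mortality direction of each CpG.
#' @slot n_extra_cpgs,extra_cpg_loading optional additional simulated CpGs
#'   (for epigenome-scan style analyses) and their latent loading.
#' @slot log_hr_per_sd numeric length-3: per-SD log hazard ratios of
#'   cont.MRscore, frailty index and age acceleration.
#' @slot log_hr_age per-year log hazard ratio of chronological age.
#' @slot baseline_hazard_shape,baseline_hazard_scale Weibull baseline.
#' @slot admin_censor_years administrative censoring horizon (years).
#' @slot dropout_rate exponential dropout rate per year.
#' @slot deficit_missing_rate MCAR missingness rate of deficit entries.
#' @slot n_batches,batch_shift_sd methylation batch count and the SD of the
#'   common logit-scale batch shift.
#' @slot subcohort_fraction,control_ratio defaults for the case-cohort and
#'   nested case-control designs.
#' @export
setClass("SimulationConfig",
  representation(
    n_subjects = "integer", seed = "integer", age_range = "numeric",
    dnam_age_slope = "numeric", dnam_age_intercept = "numeric",
    dnam_age_noise_sd = "numeric",
    n_deficits = "integer", deficit_base_logit = "numeric",
    deficit_age_gradient = "numeric", deficit_sd = "numeric",
    frailty_liability_sd = "numeric", frailty_latent_loading = "numeric",
    cpg_means = "numeric", cpg_sds = "numeric",
    latent_risk_loading = "numeric",
    n_extra_cpgs = "integer", extra_cpg_loading = "numeric",
    log_hr_per_sd = "numeric", log_hr_age = "numeric",
    baseline_hazard_shape = "numeric", baseline_hazard_scale = "numeric",
    admin_censor_years = "numeric", dropout_rate = "numeric",
    deficit_missing_rate = "numeric",
    n_batches = "integer", batch_shift_sd = "numeric",
    subcohort_fraction = "numeric", control_ratio = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  num_slots <- slotNames(object)
  for (s in num_slots) {
    v <- slot(object, s)
    if (!all(is.finite(v))) msgs <- c(msgs, paste0("non-finite value in '", s, "'"))
  }
  if (length(msgs)) return(msgs)  # remaining checks assume finite values
  if (object@n_subjects < 2L) msgs <- c(msgs, "n_subjects must be >= 2")
  if (length(object@age_range) != 2L || diff(object@age_range) <= 0)
    msgs <- c(msgs, "age_range must be (low, high) with low < high")
  if (object@n_deficits < 1L) msgs <- c(msgs, "n_deficits must be >= 1")
  for (s in c("dropout_rate", "deficit_missing_rate"))
    if (any(slot(object, s) < 0)) msgs <- c(msgs, paste0(s, " must be >= 0"))
  for (s in c("subcohort_fraction", "control_ratio"))
    if (any(slot(object, s) <= 0)) msgs <- c(msgs, paste0(s, " must be > 0"))
  if (object@subcohort_fraction > 1) msgs <- c(msgs, "subcohort_fraction must be <= 1")
  if (object@deficit_missing_rate > 1) msgs <- c(msgs, "deficit_missing_rate must be <= 1")
  if (length(object@cpg_means) != length(object@cpg_sds) ||
      length(object@cpg_means) != length(object@latent_risk_loading))
    msgs <- c(msgs, "cpg_means, cpg_sds and latent_risk_loading must have equal length")
  if (length(object@log_hr_per_sd) != 3L)
    msgs <- c(msgs, "log_hr_per_sd must have length 3 (cont.MRscore, FI, AA)")
  if (object@baseline_hazard_shape <= 0 || object@baseline_hazard_scale <= 0)
    msgs <- c(msgs, "Weibull parameters must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic methylation cohort
#'
#' `MethylCohort` extends [SummarizedExperiment::SummarizedExperiment] with a
#' `"betas"` assay (CpG rows x subject columns, values strictly inside
#' (0,1)), per-subject cohort data in `colData` (age, sex, covariates, batch,
#' follow-up time, event indicator and, on reduced designs, design weights
#' and membership flags), a subject x deficit panel, and the list of true
#' generating parameters when simulated.
#'
#' @slot deficits integer matrix (subjects x deficits) of 0/1/NA indicators.
#' @slot design character; `"cohort"`, `"casecohort"` or `"ncc"`.
#' @slot trueParams named list of generating values (empty for real data).
#' @export
setClass("MethylCohort",
  contains = "SummarizedExperiment",
  representation(deficits = "matrix", design = "character",
                 trueParams = "list"),
  prototype(design = "cohort", trueParams = list())
)

setValidity("MethylCohort", function(object) {
  msgs <- character()
  b <- SummarizedExperiment::assay(object, "betas")
  if (!all(is.na(b) | (b > 0 & b < 1)))
    msgs <- c(msgs, "beta values must lie strictly inside (0, 1)")
  cd <- SummarizedExperiment::colData(object)
  need <- c("age", "time", "event")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msgs <- c(msgs, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (any(!is.finite(cd$time)) || any(cd$time <= 0))
      msgs <- c(msgs, "follow-up time must be finite and > 0")
    if (!all(cd$event %in% c(0, 1)))
      msgs <- c(msgs, "event indicator must be 0/1")
  }
  if (nrow(object@deficits) > 0 && nrow(object@deficits) != ncol(object))
    msgs <- c(msgs, "deficit panel rows must match the number of subjects")
  if (nrow(object@deficits) > 0 &&
      !all(object@deficits %in% c(0L, 1L, NA_integer_)))
    msgs <- c(msgs, "deficits must be 0/1/NA")
  if (!object@design %in% c("cohort", "casecohort", "ncc"))
    msgs <- c(msgs, "design must be 'cohort', 'casecohort' or 'ncc'")
  if (length(msgs)) msgs else TRUE
})
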