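# End-to-end orchestration over one or more study subsets: score panels,
# frailty-association models with meta-analysis, the per-CpG frailty scan
# with BH correction, design-specific mortality models, and the
# predictive-accuracy comparison.

.default_model_ladder <- function() list(
  model1 = c("age", "sex", "cd8t", "cd4t", "gran"),
  model2 = c("age", "sex", "cd8t", "cd4t", "gran", "smoking", "alcohol"))

#' Analysis configuration
#'
#' Bundles the knobs shared by the `run*` pipeline stages: the covariate
#' ladder per model (kept in configuration, never hard-coded), the FDR
#' threshold, the evaluation time grid, the imputation count used when
#' deficit panels contain missing values, and a seed.
#'
#' @param models named list of covariate vectors, one per adjustment model.
#' @param q FDR threshold for the CpG scan (default 0.05).
#' @param grid time grid (years) for Brier / AUC(t) curves.
#' @param impute_m imputations used inside [buildScorePanel()].
#' @param seed integer seed for imputation draws.
#' @return a list of class `methrisk_config`.
#' @export
analysisConfig <- function(models = .default_model_ladder(), q = 0.05,
                           grid = c(seq(2, 12, by = 2), 13.5), impute_m = 5L,
                           seed = 1L) {
  .assert(q > 0 && q < 1, "q must lie in (0, 1)")
  structure(list(models = models, q = q, grid = grid,
                 impute_m = as.integer(impute_m), seed = as.integer(seed)),
            class = "methrisk_config")
}

# score panel + cohort data joined, one call per subset
.subset_frame <- function(cohort, config) {
  panel <- buildScorePanel(cohort, impute_m = config$impute_m,
                           impute_seed = config$seed)
  cbind(cohortData(cohort), panel[, setdiff(colnames(panel), "subject_id")])
}

#' Frailty-association stage (mixed models + meta-analysis)
#'
#' For each subset fits random-intercept linear models of the frailty index
#' (in % units) on each methylomic indicator's z-score — Model 1 and
#' Model 2 covariate ladders, plus Model 3 entering the mortality score and
#' age acceleration jointly — with methylation batch as the random effect,
#' then pools each indicator/model across subsets by DerSimonian-Laird
#' random-effects meta-analysis.
#'
#' @param subsets named list of [MethylCohort-class] objects.
#' @param config an [analysisConfig()].
#' @return `data.frame` with columns `subset` (`"overall"` for the pooled
#'   rows), `model`, `term`, `estimate` (FI % units per SD), `se`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, and `tau2`/`k` on pooled rows.
#' @export
runFrailtyAssociation <- function(subsets, config = analysisConfig()) {
  frames <- lapply(names(subsets), function(nm) {
    tryCatch(.subset_frame(subsets[[nm]], config),
             error = function(e) stop("subset '", nm, "' failed: ",
                                      conditionMessage(e)))
  })
  names(frames) <- names(subsets)
  indicators <- c(mrscore = "z_mrscore", cont_mrscore = "z_cont_mrscore",
                  age_acceleration = "z_age_acceleration")
  rows <- list()
  for (nm in names(frames)) {
    df <- frames[[nm]]
    df$fi_pct <- df$fi * 100
    for (model in c("model1", "model2")) {
      covs <- config$models[[model]]
      for (ind in names(indicators)) {
        preds <- df[, c(indicators[[ind]], covs), drop = FALSE]
        f <- fitRandomInterceptLM(df$fi_pct, preds, df$batch)
        e <- f$effects[f$effects$term == indicators[[ind]], ]
        e$subset <- nm; e$model <- model; e$term <- ind
        rows[[length(rows) + 1L]] <- e
      }
    }
    # Model 3: mortality score and age acceleration entered jointly
    for (score_term in c("mrscore", "cont_mrscore")) {
      preds <- df[, c(indicators[[score_term]], "z_age_acceleration",
                      config$models$model2), drop = FALSE]
      f <- fitRandomInterceptLM(df$fi_pct, preds, df$batch)
      for (ind in c(score_term, "age_acceleration")) {
        e <- f$effects[f$effects$term == indicators[[ind]], ]
        e$subset <- nm
        e$model <- paste0("model3_", score_term)
        e$term <- ind
        rows[[length(rows) + 1L]] <- e
      }
    }
  }
  per_subset <- do.call(rbind, rows)
  pooled <- do.call(rbind, lapply(split(per_subset,
                                        list(per_subset$model, per_subset$term),
                                        drop = TRUE), function(g) {
    if (nrow(g) < 2) return(NULL)
    p <- dersimonianLaird(g)
    p$subset <- "overall"; p$model <- g$model[1]; p$term <- g$term[1]
    p
  }))
  common <- c("subset", "model", "term", "estimate", "se", "ci_low",
              "ci_high", "p_value", "n")
  out <- rbind(cbind(per_subset[common], tau2 = NA_real_, k = NA_integer_),
               cbind(pooled[common], tau2 = pooled$tau2, k = pooled$k))
  rownames(out) <- NULL
  out
}

#' Per-CpG frailty scan with FDR control
#'
#' For each listed CpG fits, per subset, a random-intercept model of the
#' frailty index (% units) on the CpG's methylation expressed per 10%-unit
#' *decrease* in beta (so positive coefficients mean frailty rises as
#' methylation falls), adjusted for the Model 1 covariates; pools subsets by
#' DerSimonian-Laird and applies Benjamini-Hochberg correction across the
#' CpG list at `config$q`.
#'
#' @param subsets named list of [MethylCohort-class] objects.
#' @param cpg_ids CpGs to scan; entries absent from the beta matrix are
#'   skipped and reported.
#' @param config an [analysisConfig()].
#' @return list with `results` (per-CpG pooled coefficient, CI, p,
#'   `p_adjusted`, `discovery`) and `skipped`.
#' @export
runCpgFrailtyScan <- function(subsets, cpg_ids, config = analysisConfig()) {
  if (!length(cpg_ids))
    return(list(results = data.frame(), skipped = character()))
  present <- Reduce(intersect, lapply(subsets, function(s) rownames(betas(s))))
  skipped <- setdiff(cpg_ids, present)
  cpg_ids <- intersect(cpg_ids, present)
  frames <- lapply(subsets, .subset_frame, config = config)
  covs <- config$models$model1
  results <- lapply(cpg_ids, function(cg) {
    per <- do.call(rbind, lapply(names(subsets), function(nm) {
      df <- frames[[nm]]
      x <- -betas(subsets[[nm]])[cg, ] / 0.10   # per 10%-unit decrease
      preds <- cbind(data.frame(meth_dec10 = as.numeric(x)),
                     df[, covs, drop = FALSE])
      f <- fitRandomInterceptLM(df$fi * 100, preds, df$batch)
      f$effects[f$effects$term == "meth_dec10", ]
    }))
    p <- dersimonianLaird(per)
    p$term <- cg
    p
  })
  res <- do.call(rbind, results)
  adj <- bhAdjust(res$p_value, q = config$q)
  res$p_adjusted <- adj$p_adjusted
  res$discovery <- adj$discovery
  names(res)[names(res) == "term"] <- "cpg_id"
  rownames(res) <- NULL
  list(results = res, skipped = skipped)
}

# indicator reporting conventions: per-unit columns and the per-SD ratio
.unit_specs <- function(df) list(
  cont_mrscore = list(col = "cont_mrscore", unit = 1,
                      sd_ratio = sd(df$cont_mrscore, na.rm = TRUE)),
  age_acceleration = list(col = "aa_per5", unit = 5,
                          sd_ratio = sd(df$age_acceleration, na.rm = TRUE) / 5),
  fi = list(col = "fi_per10", unit = 0.10,
            sd_ratio = sd(df$fi, na.rm = TRUE) / 0.10))

.fit_design <- function(df, terms, design, sampling_fraction) {
  if (design == "cohort")
    fitCoxModel(df$time, df$event, df[, terms, drop = FALSE])
  else if (design == "casecohort")
    fitCaseCohortCox(df, terms, sampling_fraction)
  else fitLogisticModel(df$case, df[, terms, drop = FALSE])
}

#' Mortality-association stage
#'
#' Per subset, dispatches on the sampling design — Cox PH for the full
#' cohort, Barlow-weighted Cox for the case-cohort sample, logistic
#' regression for the nested case-control sample — and reports, for Model 1
#' (one indicator + demographic covariates) and Model 2 (all three
#' indicators jointly): hazard/odds ratios per MRscore category, per
#' reporting unit (1 unit cont.MRscore, 5-year AA, 10% FI) and per subset
#' SD.  Per-SD rows are the per-unit fits rescaled by the subset's own SD.
#' Cohort-design subsets (full cohort and case-cohort) are pooled per term
#' by DerSimonian-Laird meta-analysis.
#'
#' @param subsets named list of [MethylCohort-class] objects (any mix of
#'   designs).
#' @param config an [analysisConfig()].
#' @param demographics covariates of the mortality Model 1/2 ladder
#'   (default age and sex).
#' @return `data.frame` with columns `subset`, `design`, `model`, `term`,
#'   `scale`, log-scale `estimate`/`se`/CI/p, `hr`, `hr_low`, `hr_high`,
#'   `n`, `n_events`.
#' @export
runMortalityAnalysis <- function(subsets, config = analysisConfig(),
                                 demographics = c("age", "sex")) {
  rows <- list()
  add <- function(e, subset, design, model, scale) {
    e$subset <- subset; e$design <- design; e$model <- model; e$scale <- scale
    rows[[length(rows) + 1L]] <<- e
  }
  for (nm in names(subsets)) {
    ch <- subsets[[nm]]
    design <- designType(ch)
    df <- .subset_frame(ch, config)
    df$aa_per5 <- df$age_acceleration / 5
    df$fi_per10 <- df$fi / 0.10
    alpha <- trueParams(ch)$sampling_fraction %||% 1
    specs <- .unit_specs(df)

    # categorized MRscore, Model 1
    fit <- .fit_design(df, c("mrscore_category", demographics), design, alpha)
    cat_rows <- fit$effects[grepl("^mrscore_category", fit$effects$term), ]
    cat_rows$term <- sub("^mrscore_category", "mrscore=", cat_rows$term)
    add(cat_rows, nm, design, "model1", "category")

    # each indicator alone (Model 1), on reporting units, then per SD
    for (ind in names(specs)) {
      sp <- specs[[ind]]
      fit <- .fit_design(df, c(sp$col, demographics), design, alpha)
      e <- fit$effects[fit$effects$term == sp$col, ]
      e$term <- ind
      add(e, nm, design, "model1", "unit")
      add(rescaleEffect(e, sp$sd_ratio), nm, design, "model1", "sd")
    }
    # all three indicators jointly (Model 2)
    joint_terms <- vapply(specs, `[[`, character(1), "col")
    fit <- .fit_design(df, c(joint_terms, demographics), design, alpha)
    for (ind in names(specs)) {
      sp <- specs[[ind]]
      e <- fit$effects[fit$effects$term == sp$col, ]
      e$term <- ind
      add(e, nm, design, "model2", "unit")
      add(rescaleEffect(e, sp$sd_ratio), nm, design, "model2", "sd")
    }
  }
  per_subset <- do.call(rbind, lapply(rows, function(e) {
    e[, c("subset", "design", "model", "term", "scale", "estimate", "se",
          "ci_low", "ci_high", "p_value", "hr", "hr_low", "hr_high",
          "n", "n_events")]
  }))
  # pool the survival-design subsets (full cohort + case-cohort)
  surv <- per_subset[per_subset$design %in% c("cohort", "casecohort") &
                     per_subset$scale %in% c("unit", "sd", "category"), ]
  pooled <- do.call(rbind, lapply(
    split(surv, list(surv$model, surv$term, surv$scale), drop = TRUE),
    function(g) {
      if (nrow(g) < 2) return(NULL)
      p <- dersimonianLaird(g)
      data.frame(subset = "meta", design = "meta", model = g$model[1],
                 term = g$term[1], scale = g$scale[1],
                 estimate = p$estimate, se = p$se, ci_low = p$ci_low,
                 ci_high = p$ci_high, p_value = p$p_value,
                 hr = exp(p$estimate), hr_low = exp(p$ci_low),
                 hr_high = exp(p$ci_high), n = sum(g$n),
                 n_events = sum(g$n_events))
    }))
  out <- rbind(per_subset, pooled)
  rownames(out) <- NULL
  out
}

#' Predictive-accuracy comparison
#'
#' For a survival-design subset, fits one Cox model per predictor set —
#' age, DNAm age, age acceleration, cont.MRscore and frailty index, alone
#' and in the pairwise/triple combinations reported by the association
#' stage — and computes Harrell's C with CI on each model's linear
#' predictor, IPCW Brier prediction-error curves from each model's
#' predicted survival, and time-dependent AUC on the grid.  For a nested
#' case-control subset the same predictor sets are ranked by the rank AUC
#' (C-index) of logistic fits.
#'
#' @param cohort a [MethylCohort-class].
#' @param config an [analysisConfig()].
#' @param predictor_sets named list of covariate-column vectors; the
#'   default reproduces the standard comparison ladder.
#' @return list with `cstats` (`data.frame`: predictor set, C, CI or binary
#'   AUC), `brier` and `auc` curve `data.frame`s (survival designs only).
#' @export
runAccuracyComparison <- function(cohort, config = analysisConfig(),
                                  predictor_sets = NULL) {
  df <- .subset_frame(cohort, config)
  if (is.null(predictor_sets))
    predictor_sets <- list(
      "age" = "age",
      "dnam_age" = "dnam_age",
      "dnam_age+age" = c("dnam_age", "age"),
      "aa" = "age_acceleration",
      "aa+age" = c("age_acceleration", "age"),
      "cont_mrscore" = "cont_mrscore",
      "cont_mrscore+age" = c("cont_mrscore", "age"),
      "fi" = "fi",
      "fi+age" = c("fi", "age"),
      "cont_mrscore+fi" = c("cont_mrscore", "fi"),
      "cont_mrscore+fi+age" = c("cont_mrscore", "fi", "age"))
  design <- designType(cohort)
  if (design == "ncc") {
    cst <- do.call(rbind, lapply(names(predictor_sets), function(nm) {
      fit <- fitLogisticModel(df$case, df[, predictor_sets[[nm]], drop = FALSE])
      pr <- predict(fit$fit, type = "response")
      data.frame(predictors = nm, c = binaryAUC(df$case[complete.cases(
        df[, c("case", predictor_sets[[nm]])])], pr),
        ci_low = NA_real_, ci_high = NA_real_, metric = "binary_auc")
    }))
    return(list(cstats = cst, brier = NULL, auc = NULL))
  }
  # case-cohort curves are computed within the subcohort (a random sample
  # of the full cohort); the full cohort uses everyone
  if (design == "casecohort") df <- df[df$subcohort, , drop = FALSE]
  grid <- config$grid[config$grid <= max(df$time)]
  cst <- list(); briers <- list(); aucs <- list()
  for (nm in names(predictor_sets)) {
    covs <- predictor_sets[[nm]]
    fit <- fitCoxModel(df$time, df$event, df[, covs, drop = FALSE])
    lp <- as.numeric(predict(fit$fit, type = "lp"))
    hc <- harrellC(df$time, df$event, lp)
    cst[[nm]] <- data.frame(predictors = nm, c = hc$c, ci_low = hc$ci_low,
                            ci_high = hc$ci_high, metric = "harrell_c")
    sp <- coxSurvivalProbs(fit, df[, covs, drop = FALSE], grid)
    b <- brierCurve(grid, df$time, df$event, sp)
    b$predictors <- nm
    briers[[nm]] <- b
    a <- timeDependentAUC(grid, df$time, df$event, lp)
    a$predictors <- nm
    aucs[[nm]] <- a
  }
  list(cstats = do.call(rbind, c(cst, list(make.row.names = FALSE))),
       brier = do.call(rbind, c(briers, list(make.row.names = FALSE))),
       auc = do.call(rbind, c(aucs, list(make.row.names = FALSE))))
}

#' Run the full analysis pipeline on simulated subsets
#'
#' Simulates a full-cohort subset, a case-cohort subset (drawn from its own
#' full cohort with oversampled deaths) and a nested case-control subset,
#' then runs the frailty-association, mortality and accuracy stages and
#' (optionally) writes every result table as TSV.  Byte-identical output
#' under a fixed config and seed.
#'
#' @param sim_config a [simulationConfig()] describing each subset's source
#'   cohort (subset-specific seeds are derived from its seed).
#' @param config an [analysisConfig()].
#' @param n_per_subset sizes of the three source cohorts.
#' @param out_dir optional output directory for TSV results.
#' @return list with `subsets`, `frailty_association`, `mortality`,
#'   `accuracy`.
#' @export
runPipeline <- function(sim_config = simulationConfig(),
                        config = analysisConfig(),
                        n_per_subset = c(1000L, 1500L, 800L),
                        out_dir = NULL) {
  base <- sim_config
  mk <- function(n, seed_off) {
    cfg <- base
    cfg@n_subjects <- as.integer(n)
    cfg@seed <- base@seed + as.integer(seed_off)
    simulateCohort(cfg)
  }
  subsetI <- mk(n_per_subset[1], 101L)
  fullII <- mk(n_per_subset[2], 202L)
  subsetII <- sampleCaseCohort(fullII, base@subcohort_fraction,
                               seed = base@seed + 2L)
  fullIII <- mk(n_per_subset[3], 303L)
  subsetIII <- sampleNestedCaseControl(fullIII, base@control_ratio,
                                       seed = base@seed + 3L)
  subsets <- list(I = subsetI, II = subsetII, III = subsetIII)
  message("subsets: ", paste(vapply(subsets, ncol, 1L), collapse = "/"),
          " subjects; events ",
          paste(vapply(subsets, function(s) sum(cohortData(s)$event), 1L),
                collapse = "/"))
  fa <- runFrailtyAssociation(subsets, config)
  mort <- runMortalityAnalysis(subsets, config)
  acc <- lapply(subsets, runAccuracyComparison, config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.table(fa, file.path(out_dir, "frailty_association.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(mort, file.path(out_dir, "mortality.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(acc))
      write.table(acc[[nm]]$cstats,
                  file.path(out_dir, paste0("accuracy_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(subsets = subsets, frailty_association = fa, mortality = mort,
       accuracy = acc)
}
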