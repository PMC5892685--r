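# Mortality models for the three sampling designs: standard Cox PH for a
# full cohort, Barlow-weighted Cox for a case-cohort sample (oversampled
# deaths), and logistic regression for a nested case-control sample, plus
# rescaling of effects to per-k-unit / per-SD reporting.

.check_full_rank <- function(mm) {
  q <- qr(mm)
  if (q$rank < ncol(mm))
    stop("singular design; collinear term(s): ",
         paste(colnames(mm)[q$pivot[-seq_len(q$rank)]], collapse = ", "))
}

.cox_effects <- function(fit, n, n_events, robust) {
  co <- coef(fit)
  se <- if (robust) sqrt(diag(fit$var)) else sqrt(diag(fit$naive.var %||% fit$var))
  est <- unname(co)
  eff <- .effect_row(names(co), est, unname(se),
                     2 * pnorm(-abs(est / se)), n)
  eff$hr <- exp(eff$estimate)
  eff$hr_low <- exp(eff$ci_low)
  eff$hr_high <- exp(eff$ci_high)
  eff$n_events <- n_events
  eff
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cox proportional hazards fit
#'
#' Wraps [survival::coxph()] with Efron tie handling (Breslow available).
#' With non-unit weights the robust (sandwich) variance is used for CIs.
#'
#' @param time follow-up times (> 0).
#' @param event 0/1 event indicators (>= 1 event).
#' @param covariates `data.frame` of covariates.
#' @param weights optional observation weights (default all 1).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list with `effects` (per-term rows including `hr`, `hr_low`,
#'   `hr_high`, `n_events`), `fit` (the `coxph` object), `n`, `n_events`.
#' @export
fitCoxModel <- function(time, event, covariates, weights = NULL,
                        ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .assert(all(time > 0), "follow-up times must be positive")
  .assert(sum(event) >= 1, "no events")
  dat <- data.frame(.t = time, .e = event, covariates, check.names = TRUE)
  ok <- complete.cases(dat)
  dat <- dat[ok, , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(dat)) else weights[ok]
  terms <- setdiff(colnames(dat), c(".t", ".e"))
  .check_full_rank(model.matrix(~ ., dat[, terms, drop = FALSE]))
  robust <- any(w != 1)
  fit <- survival::coxph(
    as.formula(paste("survival::Surv(.t, .e) ~", paste(terms, collapse = "+"))),
    data = dat, weights = w, ties = ties, robust = robust,
    control = survival::coxph.control(eps = 1e-10, iter.max = 50))
  if (!is.null(fit$info) && grepl("infinite", paste(fit$info, collapse = " ")))
    stop("Cox fit did not converge (possible monotone likelihood)")
  if (any(abs(coef(fit)) > 15))
    stop("Cox fit diverged: |coefficient| > 15 suggests perfect separation")
  out <- list(effects = .cox_effects(fit, nrow(dat), sum(dat$.e), robust),
              fit = fit, n = nrow(dat), n_events = sum(dat$.e),
              ties = ties, weighted = robust, type = "cox")
  class(out) <- "methrisk_fit"
  out
}

#' Barlow-weighted Cox fit for a case-cohort sample
#'
#' Implements the Barlow weighting scheme for case-cohort data via a
#' counting-process [survival::coxph()] fit: subcohort members contribute
#' person-time with weight `1/alpha` (the inverse subcohort sampling
#' fraction) up to just before failure, every case contributes its own
#' failure with weight 1, and cases outside the subcohort enter the risk
#' set only just before their failure time.  CIs use the robust sandwich
#' variance.
#'
#' @param data `data.frame` with columns `time`, `event`, `subcohort`
#'   (logical) and the covariates named in `terms`.
#' @param terms character vector of covariate column names.
#' @param sampling_fraction the subcohort sampling fraction alpha in (0, 1].
#' @param ties tie handling passed to [survival::coxph()].
#' @return same structure as [fitCoxModel()].
#' @export
fitCaseCohortCox <- function(data, terms, sampling_fraction,
                             ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .assert(sampling_fraction > 0 && sampling_fraction <= 1,
          "sampling_fraction must be in (0, 1]")
  .assert(all(c("time", "event", "subcohort") %in% colnames(data)),
          "data needs columns time, event, subcohort")
  .assert(all(terms %in% colnames(data)), "missing covariate column(s)")
  dat <- data[, c("time", "event", "subcohort", terms)]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  .check_full_rank(model.matrix(~ ., dat[, terms, drop = FALSE]))
  eps <- min(dat$time[dat$event == 1]) * 1e-6
  w_sub <- 1 / sampling_fraction
  dat$.id <- seq_len(nrow(dat))
  rows <- list()
  is_case <- dat$event == 1
  # subcohort members: pre-failure (or full) exposure at weight 1/alpha
  pre <- dat[dat$subcohort, , drop = FALSE]
  pre_stop <- ifelse(pre$event == 1, pre$time - eps, pre$time)
  keep <- pre_stop > 0
  rows$pre <- data.frame(start = 0, stop = pre_stop[keep], status = 0,
                         pre[keep, c(terms, ".id"), drop = FALSE],
                         .w = w_sub)
  # every case: its own failure at weight 1, entering just before failure
  cs <- dat[is_case, , drop = FALSE]
  rows$fail <- data.frame(start = pmax(cs$time - eps, 0), stop = cs$time,
                          status = 1, cs[, c(terms, ".id"), drop = FALSE],
                          .w = 1)
  long <- do.call(rbind, rows)
  fit <- survival::coxph(
    as.formula(paste("survival::Surv(start, stop, status) ~",
                     paste(terms, collapse = "+"),
                     "+ cluster(.id)")),
    data = long, weights = long$.w, ties = ties, robust = TRUE,
    control = survival::coxph.control(eps = 1e-10, iter.max = 50,
                                      timefix = FALSE))
  out <- list(effects = .cox_effects(fit, nrow(dat), sum(is_case),
                                     robust = TRUE),
              fit = fit, n = nrow(dat), n_events = sum(is_case),
              ties = ties, weighted = TRUE,
              sampling_fraction = sampling_fraction, type = "casecohort")
  class(out) <- "methrisk_fit"
  out
}

#' Logistic regression fit (nested case-control design)
#'
#' Maximum-likelihood logistic fit with Wald CIs; effects are reported on
#' the log-odds scale with odds ratios in the `hr` columns (shared layout
#' with the Cox fits).  Errors on separation or rank deficiency.
#'
#' @param outcome 0/1 outcome with both classes present.
#' @param covariates `data.frame` of covariates.
#' @return list with `effects`, `fit`, `n`, `n_events`.
#' @export
fitLogisticModel <- function(outcome, covariates) {
  .assert(length(unique(outcome[!is.na(outcome)])) == 2,
          "outcome must contain both classes")
  dat <- data.frame(.y = outcome, covariates, check.names = TRUE)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  terms <- setdiff(colnames(dat), ".y")
  .check_full_rank(model.matrix(~ ., dat[, terms, drop = FALSE]))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(as.formula(paste(".y ~", paste(terms, collapse = "+"))),
        data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || any(abs(coef(fit)[-1]) > 15))
    stop("logistic fit shows (quasi-)separation; coefficients unstable")
  sm <- summary(fit)$coefficients
  keep <- rownames(sm) != "(Intercept)"
  eff <- .effect_row(rownames(sm)[keep], unname(sm[keep, "Estimate"]),
                     unname(sm[keep, "Std. Error"]),
                     unname(sm[keep, "Pr(>|z|)"]), nrow(dat))
  eff$hr <- exp(eff$estimate); eff$hr_low <- exp(eff$ci_low)
  eff$hr_high <- exp(eff$ci_high); eff$n_events <- sum(dat$.y)
  out <- list(effects = eff, fit = fit, n = nrow(dat),
              n_events = sum(dat$.y), type = "logistic")
  class(out) <- "methrisk_fit"
  out
}

#' Rescale an effect to different predictor units
#'
#' Multiplies a log-hazard (or log-odds) coefficient and its CI bounds by
#' `ratio` before exponentiation, so `HR_new = HR_old^ratio`.  Use
#' `ratio = sd` to turn a per-unit effect into a per-SD effect, or
#' `ratio = k_new / k_old` between per-k-unit conventions (e.g. a per-5-year
#' effect to per-SD with SD 4.8 years: `ratio = 4.8 / 5`).
#'
#' @param effects effect rows (as produced by the fitting functions) with
#'   columns `estimate`, `se`, `ci_low`, `ci_high`.
#' @param ratio positive unit ratio, scalar or one per row.
#' @return rescaled effect rows (log-scale and `hr` columns both updated).
#' @examples
#' e <- data.frame(term = "cont_mrscore", estimate = log(7.29),
#'                 se = 0.1, ci_low = log(3.30), ci_high = log(16.10),
#'                 p_value = NA, n = 470)
#' rescaleEffect(e, ratio = 0.49)$hr  # 2.65: per-unit OR to per-SD
#' @export
rescaleEffect <- function(effects, ratio) {
  .assert(all(ratio > 0), "unit ratio must be positive")
  out <- effects
  for (cl in c("estimate", "se", "ci_low", "ci_high"))
    if (cl %in% colnames(out)) out[[cl]] <- out[[cl]] * ratio
  out$hr <- exp(out$estimate)
  if ("ci_low" %in% colnames(out)) {
    out$hr_low <- exp(out$ci_low); out$hr_high <- exp(out$ci_high)
  }
  out
}
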