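# Predictive-accuracy metrics: Harrell's C with an asymptotic CI, IPCW
# Brier prediction-error curves with Kaplan-Meier censoring weights,
# cumulative/dynamic time-dependent AUC, and the plain rank AUC used for
# the case-control design.

#' Harrell's concordance index for survival data
#'
#' A pair of subjects is comparable when the earlier follow-up time is an
#' event (including the tie case event-vs-censored at the same time); it is
#' concordant when the subject with the earlier event carries the higher
#' risk score, and risk ties count 1/2.  The 95% CI uses a Noether-type
#' asymptotic standard error over the pair indicators,
#' `sqrt(C (1 - C) / n_pairs)`, truncated to \[0, 1\].
#'
#' @param time follow-up times.
#' @param event 0/1 event indicator.
#' @param risk risk score (higher = shorter expected survival).
#' @return list with `c` (the index), `se`, `ci_low`, `ci_high`,
#'   `n_pairs` (comparable pairs), `concordant`, `tied`.
#' @export
harrellC <- function(time, event, risk) {
  ok <- complete.cases(time, event, risk)
  time <- time[ok]; event <- event[ok]; risk <- risk[ok]
  conc <- ties <- pairs <- 0
  for (i in which(event == 1)) {
    later <- (time > time[i]) | (time == time[i] & event == 0)
    if (!any(later)) next
    pairs <- pairs + sum(later)
    conc <- conc + sum(risk[i] > risk[later])
    ties <- ties + sum(risk[i] == risk[later])
  }
  if (pairs == 0) stop("no comparable pairs")
  C <- (conc + 0.5 * ties) / pairs
  se <- sqrt(C * (1 - C) / pairs)
  list(c = C, se = se,
       ci_low = max(0, C - qnorm(0.975) * se),
       ci_high = min(1, C + qnorm(0.975) * se),
       n_pairs = pairs, concordant = conc, tied = ties)
}

#' Rank-based AUC for a binary outcome
#'
#' Proportion of case/control pairs ranked correctly by the score, with
#' score ties counted 1/2; equals the C-index of a logistic model when the
#' score is the predicted probability.
#'
#' @param outcome 0/1 outcome with both classes present.
#' @param score numeric score (higher = more case-like).
#' @return AUC in \[0, 1\].
#' @export
binaryAUC <- function(outcome, score) {
  ok <- complete.cases(outcome, score)
  outcome <- outcome[ok]; score <- score[ok]
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  .assert(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(score)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Kaplan-Meier estimate of the censoring survival function G; returns
# right-continuous G(t) and the left limit G(t-)
.censor_km <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  st <- sf$time; ss <- sf$surv
  G <- function(t) {
    idx <- findInterval(t, st)
    ifelse(idx == 0, 1, ss[pmax(idx, 1)])
  }
  Gminus <- function(t) {
    idx <- findInterval(t, st, left.open = TRUE)
    ifelse(idx == 0, 1, ss[pmax(idx, 1)])
  }
  list(G = G, Gminus = Gminus)
}

#' IPCW Brier prediction-error curve
#'
#' Inverse-probability-of-censoring-weighted Brier score on a time grid:
#' subjects with an observed event by `t` contribute `S(t|x)^2` with weight
#' `1/G(T-)`, subjects still at risk past `t` contribute `(1 - S(t|x))^2`
#' with weight `1/G(t)`, and subjects censored before `t` contribute
#' nothing; `G` is the Kaplan-Meier estimate of the censoring survival
#' function.  Without censoring the weights collapse to 1 and the curve is
#' the plain mean squared error of `1{T > t}` against `S(t|x)`.
#'
#' @param grid evaluation times within the observed follow-up range.
#' @param time,event observed follow-up and 0/1 event indicator.
#' @param surv_prob matrix of predicted survival probabilities,
#'   subjects x grid times (or a vector when the grid has one point).
#' @return `data.frame` with columns `time`, `brier`; grid points where the
#'   censoring weight is undefined (`G(t) = 0`) are dropped with a warning.
#' @export
brierCurve <- function(grid, time, event, surv_prob) {
  n <- length(time)
  surv_prob <- matrix(surv_prob, nrow = n)
  .assert(ncol(surv_prob) == length(grid),
          "surv_prob must have one column per grid time")
  .assert(all(surv_prob >= 0 & surv_prob <= 1),
          "survival probabilities must lie in [0, 1]")
  km <- .censor_km(time, event)
  usable <- km$G(grid) > 0
  if (!all(usable))
    warning("grid truncated: censoring weight G(t) = 0 at ",
            sum(!usable), " grid point(s)")
  out <- vapply(which(usable), function(k) {
    t <- grid[k]; S <- surv_prob[, k]
    died <- time <= t & event == 1
    alive <- time > t
    w <- numeric(n)
    w[died] <- 1 / km$Gminus(time[died])
    w[alive] <- 1 / km$G(t)
    sum(w * ((as.numeric(alive) - S)^2)) / n
  }, numeric(1))
  data.frame(time = grid[usable], brier = out)
}

#' Time-dependent AUC (cumulative cases / dynamic controls, IPCW)
#'
#' At each grid time `t`, cases are subjects with an observed event by `t`
#' (weight `1/G(T-)`) and controls are subjects still at risk past `t`
#' (weight `1/G(t)`); the AUC is the weighted proportion of case-control
#' pairs ranked correctly by the risk score, ties counting 1/2.  Without
#' censoring this equals [binaryAUC()] on the indicator `1{T <= t}`.
#'
#' @param grid evaluation times.
#' @param time,event observed follow-up and 0/1 event indicator.
#' @param risk risk score (higher = earlier event).
#' @return `data.frame` with columns `time`, `auc`, `n_cases`, `n_controls`.
#' @export
timeDependentAUC <- function(grid, time, event, risk) {
  km <- .censor_km(time, event)
  rows <- lapply(grid, function(t) {
    case <- time <= t & event == 1
    ctrl <- time > t
    if (!any(case) || !any(ctrl))
      return(data.frame(time = t, auc = NA_real_,
                        n_cases = sum(case), n_controls = sum(ctrl)))
    wc <- 1 / km$Gminus(time[case])
    wk <- rep(1 / km$G(t), sum(ctrl))
    rc <- risk[case]; rk <- risk[ctrl]
    # weighted pair comparison; outer products stay small on desk-scale grids
    gt <- outer(rc, rk, `>`); eq <- outer(rc, rk, `==`)
    wmat <- outer(wc, wk)
    auc <- sum(wmat * (gt + 0.5 * eq)) / sum(wmat)
    data.frame(time = t, auc = auc, n_cases = sum(case),
               n_controls = sum(ctrl))
  })
  do.call(rbind, rows)
}

#' Predicted survival probabilities from a fitted Cox model
#'
#' Breslow-type baseline (via [survival::survfit()]) combined with the
#' fitted linear predictor to give `S(t|x)` for new subjects on a time grid.
#'
#' @param fit a fit from [fitCoxModel()].
#' @param covariates `data.frame` of new subjects' covariates (same columns
#'   as the fit).
#' @param grid evaluation times.
#' @return matrix of survival probabilities, subjects x grid times.
#' @export
coxSurvivalProbs <- function(fit, covariates, grid) {
  .assert(inherits(fit, "methrisk_fit") && fit$type %in% c("cox", "casecohort"),
          "fit must come from fitCoxModel or fitCaseCohortCox")
  nd <- data.frame(covariates, check.names = TRUE)
  sf <- survival::survfit(fit$fit, newdata = nd)
  sm <- summary(sf, times = grid, extend = TRUE)
  t(matrix(sm$surv, nrow = length(grid)))
}
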