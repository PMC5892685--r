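# Association-stage statistics: random-intercept linear models (methylation
# batch as random effect), Rubin's rules across imputations, BH false
# discovery control, DerSimonian-Laird random-effects meta-analysis, and
# Spearman correlation matrices.

#' Random-intercept linear model with batch as grouping factor
#'
#' REML fit of `outcome ~ predictors + (1 | group)` via [lme4::lmer()].
#' Fixed-effect coefficients are reported with Wald 95% CIs and normal
#' p-values.  With a single group (no grouping information) the function
#' falls back to OLS with a warning.
#'
#' @param outcome numeric response.
#' @param predictors `data.frame` of fixed-effect covariates (numeric or
#'   factor); must be full rank after expansion.
#' @param group grouping labels (e.g. methylation batch).
#' @return list with `effects` (one [effect-estimate row][poolRubin] per
#'   fixed term excluding the intercept), `variance_components`
#'   (`tau2` = group intercept variance, `sigma2` = residual) and `fit`.
#' @export
fitRandomInterceptLM <- function(outcome, predictors, group) {
  .assert(length(outcome) >= 2, "need at least 2 subjects")
  dat <- data.frame(.y = outcome, predictors, .g = factor(group),
                    check.names = TRUE)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  mm <- model.matrix(~ ., dat[, setdiff(colnames(dat), c(".y", ".g")),
                              drop = FALSE])
  if (qr(mm)$rank < ncol(mm)) {
    qr_mm <- qr(mm)
    bad <- colnames(mm)[qr_mm$pivot[-seq_len(qr_mm$rank)]]
    stop("singular fixed-effect design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  rhs <- paste(setdiff(colnames(dat), c(".y", ".g")), collapse = " + ")
  if (nlevels(dat$.g) < 2L) {
    warning("single grouping level; falling back to OLS")
    fit <- lm(as.formula(paste(".y ~", rhs)), data = dat)
    sm <- summary(fit)$coefficients
    vc <- c(tau2 = 0, sigma2 = summary(fit)$sigma^2)
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  } else {
    fit <- lme4::lmer(as.formula(paste(".y ~", rhs, "+ (1 | .g)")),
                      data = dat, REML = TRUE)
    sm <- as.data.frame(lme4::VarCorr(fit))
    vc <- c(tau2 = sm$vcov[sm$grp == ".g"],
            sigma2 = sm$vcov[sm$grp == "Residual"])
    co <- summary(fit)$coefficients
    est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  }
  keep <- names(est) != "(Intercept)"
  effects <- .effect_row(names(est)[keep], unname(est[keep]),
                         unname(se[keep]),
                         2 * pnorm(-abs(est[keep] / se[keep])), n)
  list(effects = effects, variance_components = vc, fit = fit)
}

#' Pool estimates across multiple imputations (Rubin's rules)
#'
#' Pooled coefficient is the mean across imputations; total variance is
#' `W + (1 + 1/m) B` with `W` the mean within-imputation variance and `B`
#' the between-imputation variance.  CIs and the p-value use Rubin's
#' small-sample t degrees of freedom
#' `(m - 1) (1 + W / ((1 + 1/m) B))^2` (infinite when `B = 0`).
#'
#' @param estimates `data.frame` of effect rows (columns `term`, `estimate`,
#'   `se`, `n`), one row per imputation, all for the same term.
#' @return a single pooled effect row with columns `term`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `n`, `m`, `df`.
#' @export
poolRubin <- function(estimates) {
  m <- nrow(estimates)
  .assert(m >= 2, "need at least 2 imputations")
  .assert(length(unique(estimates$term)) == 1L,
          "all estimates must share one term")
  qbar <- mean(estimates$estimate)
  W <- mean(estimates$se^2)
  B <- var(estimates$estimate)
  Tvar <- W + (1 + 1 / m) * B
  se <- sqrt(Tvar)
  if (B > 0) {
    df <- (m - 1) * (1 + W / ((1 + 1 / m) * B))^2
    tq <- stats::qt(0.975, df)
    p <- 2 * stats::pt(-abs(qbar / se), df)
  } else {
    df <- Inf; tq <- qnorm(0.975); p <- 2 * pnorm(-abs(qbar / se))
  }
  data.frame(term = estimates$term[1], estimate = qbar, se = se,
             ci_low = qbar - tq * se, ci_high = qbar + tq * se,
             p_value = p, n = max(estimates$n), m = m, df = df,
             row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values and discovery flags
#'
#' Step-up adjusted values via [stats::p.adjust()] with discovery flags at
#' the requested false discovery rate.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param q FDR threshold (default 0.05).
#' @return `data.frame` with `p`, `p_adjusted`, `discovery`.
#' @export
bhAdjust <- function(p, q = 0.05) {
  .assert(length(p) >= 1, "empty p-value list")
  .assert(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  data.frame(p = p, p_adjusted = adj, discovery = !is.na(adj) & adj <= q)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance: `Q` from the inverse-variance
#' fixed-effect fit, `tau2 = max(0, (Q - (k-1)) / C)` with
#' `C = sum(w) - sum(w^2)/sum(w)`, then inverse-variance pooling with
#' weights `1 / (v_i + tau2)` and a Wald CI.  Implemented through
#' [metafor::rma()] (`method = "DL"`).
#'
#' @param estimates `data.frame` with columns `estimate` and `se` (k >= 2
#'   rows) and optionally `term`, `n`.
#' @return one-row `data.frame`: `term`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, `tau2`, `q_statistic`, `k`, `n`.
#' @export
dersimonianLaird <- function(estimates) {
  k <- nrow(estimates)
  .assert(k >= 2, "meta-analysis needs at least 2 estimates")
  .assert(all(estimates$se > 0), "all standard errors must be positive")
  fit <- metafor::rma(yi = estimates$estimate, sei = estimates$se,
                      method = "DL", test = "z")
  term <- if ("term" %in% colnames(estimates)) estimates$term[1] else NA_character_
  data.frame(term = term, estimate = as.numeric(fit$beta),
             se = fit$se, ci_low = fit$ci.lb, ci_high = fit$ci.ub,
             p_value = fit$pval, tau2 = fit$tau2, q_statistic = fit$QE,
             k = k,
             n = if ("n" %in% colnames(estimates)) sum(estimates$n) else NA_integer_,
             row.names = NULL)
}

#' Spearman correlation matrix of survival indicators
#'
#' Pairwise-complete Spearman rank correlations with unit diagonal;
#' constant columns yield `NA` entries with a warning.
#'
#' @param x `data.frame` or matrix of numeric indicator columns (>= 3 rows).
#' @return symmetric correlation matrix.
#' @export
spearmanMatrix <- function(x) {
  x <- as.data.frame(x)
  .assert(nrow(x) >= 3, "need at least 3 subjects")
  const <- vapply(x, function(v) sd(v, na.rm = TRUE) == 0, logical(1))
  if (any(const))
    warning("constant column(s) give undefined correlations: ",
            paste(names(x)[const], collapse = ", "))
  m <- suppressWarnings(cor(x, method = "spearman",
                            use = "pairwise.complete.obs"))
  diag(m) <- ifelse(const, NA_real_, 1)
  m
}
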