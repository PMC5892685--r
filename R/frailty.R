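# Deficit-accumulation frailty index: eligibility screening of candidate
# deficits, the FI ratio itself, and chained-equation multiple imputation
# of missing deficit values.

#' Screen candidate deficits for frailty-index eligibility
#'
#' Retains deficits that (i) have overall prevalence above `min_prevalence`,
#' (ii) do not saturate early — prevalence at most `max_young_prevalence`
#' among subjects aged 50-60 years, and (iii) accumulate with age, tested as
#' a positive Spearman correlation between the deficit indicator and age
#' with p < `age_trend_alpha`.  Association with general health status is
#' not machine-checkable from the panel alone; supply `keep` to force-retain
#' externally vetted deficits.
#'
#' @param panel subject x deficit 0/1/NA matrix.
#' @param ages chronological ages aligned with the panel rows.
#' @param min_prevalence minimum overall prevalence (default 0.01).
#' @param max_young_prevalence maximum prevalence among ages 50-60
#'   (default 0.50).
#' @param young_range age window used for the saturation rule.
#' @param age_trend_alpha significance level of the age-trend test.
#' @param keep optional character vector of deficit names exempt from
#'   exclusion.
#' @return list with `panel` (eligible columns) and `report`
#'   (`data.frame`: deficit, rule, statistic for each exclusion).
#' @export
screenDeficits <- function(panel, ages, min_prevalence = 0.01,
                           max_young_prevalence = 0.50,
                           young_range = c(50, 60),
                           age_trend_alpha = 0.05, keep = character()) {
  .assert(nrow(panel) == length(ages), "ages must align with panel rows")
  young <- ages >= young_range[1] & ages <= young_range[2]
  if (!any(young))
    stop("no subjects in the ", young_range[1], "-", young_range[2],
         " age window; saturation rule cannot be evaluated")
  nm <- colnames(panel)
  rep_rows <- list()
  ok <- logical(ncol(panel))
  for (j in seq_len(ncol(panel))) {
    x <- panel[, j]
    prev <- mean(x, na.rm = TRUE)
    prev_young <- mean(x[young], na.rm = TRUE)
    ct <- suppressWarnings(stats::cor.test(x, ages, method = "spearman",
                                           exact = FALSE))
    if (nm[j] %in% keep) { ok[j] <- TRUE; next }
    if (!is.finite(prev) || prev <= min_prevalence) {
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(deficit = nm[j], rule = "prevalence <= 1%",
                   statistic = prev)
    } else if (is.finite(prev_young) && prev_young > max_young_prevalence) {
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(deficit = nm[j], rule = "early saturation",
                   statistic = prev_young)
    } else if (!(is.finite(ct$estimate) && ct$estimate > 0 &&
                 ct$p.value < age_trend_alpha)) {
      rep_rows[[length(rep_rows) + 1L]] <-
        data.frame(deficit = nm[j], rule = "no positive age trend",
                   statistic = unname(ct$estimate))
    } else ok[j] <- TRUE
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows)
            else data.frame(deficit = character(), rule = character(),
                            statistic = numeric())
  list(panel = panel[, ok, drop = FALSE], report = report)
}

#' Deficit-accumulation frailty index
#'
#' FI = (number of deficits present) / (number of deficits considered).
#' The default path expects a complete (imputed) panel and uses the full
#' column count as denominator.  With `denominator = "observed"` the ratio
#' is taken over each subject's observed deficits instead; subjects with no
#' observed deficit get `NA` with a warning.
#'
#' @param panel subject x deficit 0/1 matrix (NA allowed only on the
#'   observed-denominator path).
#' @param denominator `"all"` (default) or `"observed"`.
#' @return numeric vector of FI values in \[0, 1\], one per subject.
#' @examples
#' frailtyIndex(matrix(c(rep(1, 17), rep(0, 17)), nrow = 1))  # 0.5
#' @export
frailtyIndex <- function(panel, denominator = c("all", "observed")) {
  denominator <- match.arg(denominator)
  .assert(ncol(panel) >= 1, "deficit panel is empty")
  .assert(all(panel %in% c(0, 1) | is.na(panel)), "deficits must be 0/1/NA")
  if (denominator == "all") {
    if (any(is.na(panel)))
      stop("panel has missing values; impute first (imputeDeficits) or use ",
           "denominator = 'observed'")
    fi <- rowMeans(panel)
  } else {
    n_obs <- rowSums(!is.na(panel))
    fi <- rowSums(panel, na.rm = TRUE) / n_obs
    if (any(n_obs == 0)) {
      warning(sum(n_obs == 0), " subject(s) with zero observed deficits; FI set NA")
      fi[n_obs == 0] <- NA_real_
    }
  }
  setNames(as.numeric(fi), rownames(panel))
}

#' Multiple imputation of missing deficit values
#'
#' Chained-equation style imputation: each deficit with missing values is
#' modelled by logistic regression on age, sex and the mean of the
#' subject's other observed deficits; missing entries are replaced by
#' Bernoulli draws from the fitted probabilities, and the cycle is repeated
#' `n_cycles` times per imputation.  Deterministic under `seed`.
#'
#' @param panel subject x deficit 0/1/NA matrix.
#' @param covariates per-subject table containing `age` and `sex`.
#' @param m number of completed panels (default 20).
#' @param seed integer seed.
#' @param n_cycles chained-update cycles per imputation (default 3).
#' @return list with `panels` (list of m complete matrices), `m`, `seed`.
#' @export
imputeDeficits <- function(panel, covariates, m = 20L, seed = 1L,
                           n_cycles = 3L) {
  .assert(m >= 2, "m must be >= 2")
  .assert(all(c("age", "sex") %in% colnames(covariates)),
          "covariates must include age and sex")
  .assert(nrow(covariates) == nrow(panel),
          "covariates must align with panel rows")
  all_missing <- colnames(panel)[colSums(!is.na(panel)) == 0]
  if (length(all_missing))
    stop("deficit(s) entirely missing: ", paste(all_missing, collapse = ", "))
  storage.mode(panel) <- "integer"
  if (!any(is.na(panel)))
    return(list(panels = replicate(m, panel, simplify = FALSE),
                m = as.integer(m), seed = as.integer(seed)))
  age <- covariates$age
  sex01 <- as.numeric(as.factor(covariates$sex)) - 1
  miss_cols <- which(colSums(is.na(panel)) > 0)
  .with_seed(seed, {
    panels <- vector("list", m)
    for (i in seq_len(m)) {
      cur <- panel
      # initialize by marginal draws
      for (j in miss_cols) {
        na_j <- is.na(cur[, j])
        cur[na_j, j] <- rbinom(sum(na_j), 1L, mean(panel[, j], na.rm = TRUE))
      }
      for (cyc in seq_len(n_cycles)) {
        for (j in miss_cols) {
          na_j <- is.na(panel[, j])
          others <- rowMeans(cur[, -j, drop = FALSE])
          obs <- !na_j
          dat <- data.frame(y = cur[, j], age = age, sex = sex01,
                            others = others)
          fit <- suppressWarnings(
            glm(y ~ age + sex + others, data = dat[obs, ],
                family = binomial()))
          pr <- predict(fit, newdata = dat[na_j, , drop = FALSE],
                        type = "response")
          cur[na_j, j] <- rbinom(sum(na_j), 1L, pr)
        }
      }
      panels[[i]] <- cur
    }
    list(panels = panels, m = as.integer(m), seed = as.integer(seed))
  })
}
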