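#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats as.formula binomial coef cor glm lm median model.matrix
#'   p.adjust pnorm qnorm quantile rbinom resid residuals rexp rnorm runif
#'   rweibull sd setNames vcov complete.cases plogis qlogis predict var
#' @importFrom utils write.csv read.csv read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay colData colData<-
#'   SummarizedExperiment
#' @importFrom S4Vectors DataFrame
NULL

# inverse-logit / logit used throughout the generator (beta values live on
# the logit scale there)
.invlogit <- function(x) stats::plogis(x)
.logit <- function(p) stats::qlogis(p)

# Wald-style 95% interval helper
.wald_ci <- function(est, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  cbind(ci_low = est - z * se, ci_high = est + z * se)
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Effect-estimate rows are plain data.frames with a fixed column contract;
# every model-fitting function funnels through here.
.effect_row <- function(term, estimate, se, p, n, level = 0.95) {
  ci <- .wald_ci(estimate, se, level)
  data.frame(term = term, estimate = estimate, se = se,
             ci_low = ci[, 1], ci_high = ci[, 2], p_value = p, n = n,
             row.names = NULL)
}
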