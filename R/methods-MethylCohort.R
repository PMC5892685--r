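#' @describeIn MethylCohort the CpG x subject beta-value matrix.
#' @param x a `MethylCohort`.
#' @export
setMethod("betas", "MethylCohort", function(x)
  SummarizedExperiment::assay(x, "betas"))

#' @describeIn MethylCohort per-subject cohort table as a `data.frame`
#'   (one row per subject; includes survival columns and design flags).
#' @export
setMethod("cohortData", "MethylCohort", function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  df$subject_id <- colnames(x)
  df[, c("subject_id", setdiff(colnames(df), "subject_id")), drop = FALSE]
})

#' @describeIn MethylCohort subject x deficit 0/1/NA matrix.
#' @export
setMethod("deficits", "MethylCohort", function(x) x@deficits)

#' @describeIn MethylCohort sampling design of the object.
#' @export
setMethod("designType", "MethylCohort", function(x) x@design)

#' @describeIn MethylCohort list of generating parameter values (empty for
#'   non-simulated data).
#' @export
setMethod("trueParams", "MethylCohort", function(x) x@trueParams)

#' @describeIn MethylCohort compact display.
#' @param object a `MethylCohort`.
#' @export
setMethod("show", "MethylCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("MethylCohort (", object@design, " design)\n", sep = "")
  cat("  subjects: ", ncol(object), ";  CpGs: ", nrow(object),
      ";  deficits: ", ncol(object@deficits), "\n", sep = "")
  if (all(c("time", "event") %in% colnames(cd)))
    cat("  events: ", sum(cd$event), " of ", ncol(object),
        " over <=", round(max(cd$time), 1), " years\n", sep = "")
  if ("weight" %in% colnames(cd))
    cat("  design weights: ", paste(unique(round(cd$weight, 3)), collapse = ", "),
        "\n", sep = "")
})

# subsetting keeps the deficit panel aligned with the retained subjects
#' @export
#' @describeIn MethylCohort subset CpGs (i) and/or subjects (j).
#' @param i,j,...,drop standard matrix-style subset arguments.
setMethod("[", c("MethylCohort", "ANY", "ANY"), function(x, i, j, ..., drop = FALSE) {
  out <- callNextMethod()
  if (!missing(j) && nrow(x@deficits) > 0)
    out@deficits <- x@deficits[j, , drop = FALSE]
  out
})
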