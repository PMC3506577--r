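#' Accessors for FlexiFDR classes
#'
#' @param object a FlexiFDR S4 object.
#' @name accessors
NULL

#' @describeIn accessors the PSM table of a [PsmSet] (or of the augmented
#'   table inside an [FdrOutcome]).
#' @export
setGeneric("psmTable", function(object) standardGeneric("psmTable"))

#' @describeIn accessors search strategy (`"separate"`/`"concatenated"`).
#' @export
setGeneric("searchMode", function(object) standardGeneric("searchMode"))

#' @describeIn accessors orientation of the original score column.
#' @export
setGeneric("scoreDirection", function(object) standardGeneric("scoreDirection"))

#' @describeIn accessors metadata list of a [PsmSet].
#' @export
setGeneric("psmMetadata", function(object) standardGeneric("psmMetadata"))

#' @describeIn accessors per-charge regression line table of a
#'   [ChargeRegressionModel].
#' @export
setGeneric("regressionLines", function(object) standardGeneric("regressionLines"))

#' @describeIn accessors spectrum ids accepted by an [FdrOutcome].
#' @export
setGeneric("acceptedSpectra", function(object) standardGeneric("acceptedSpectra"))

#' @describeIn accessors I/L-normalized peptides accepted by an
#'   [FdrOutcome].
#' @export
setGeneric("acceptedPeptides", function(object) standardGeneric("acceptedPeptides"))

#' @describeIn accessors realised score threshold of an [FdrOutcome].
#' @export
setGeneric("scoreThreshold", function(object) standardGeneric("scoreThreshold"))

#' Entrapment-estimated false discovery proportion
#'
#' Fraction of labelled-false identifications among the labelled
#' identifications of an acceptance set (unlabelable identifications are
#' excluded from the denominator). This is the "actual FDR" readout of an
#' entrapment experiment: entrapment proteins sit in the target database,
#' so their identifications pass FDR control like any target, but the
#' evaluator knows they are wrong.
#'
#' @param accepted an [FdrOutcome] or a data.frame of identifications with
#'   columns `id` and `proteins` (semicolon-separated accessions).
#' @param labeler a [TruthLabeler].
#' @return a single proportion in \[0, 1\]; 0 with a warning when nothing
#'   is accepted.
#' @export
setGeneric("entrapmentFdp", function(accepted, labeler)
  standardGeneric("entrapmentFdp"))

setMethod("psmTable", "PsmSet", function(object) object@psm)
setMethod("psmTable", "FdrOutcome", function(object) object@psm)
setMethod("searchMode", "PsmSet", function(object) object@mode)
setMethod("searchMode", "FdrOutcome", function(object) object@mode)
setMethod("scoreDirection", "PsmSet", function(object) object@scoreDirection)
setMethod("psmMetadata", "PsmSet", function(object) object@metadata)
setMethod("regressionLines", "ChargeRegressionModel",
          function(object) object@lines)
setMethod("acceptedSpectra", "FdrOutcome", function(object) object@acceptedSpectra)
setMethod("acceptedPeptides", "FdrOutcome", function(object) object@acceptedPeptides)
setMethod("scoreThreshold", "FdrOutcome", function(object) object@threshold)

setMethod("show", "PsmSet", function(object) {
  p <- object@psm
  cat(sprintf("PsmSet: %d PSMs (%d target, %d decoy), %s search, charges {%s}\n",
              nrow(p), sum(!p$is_decoy), sum(p$is_decoy), object@mode,
              paste(sort(unique(p$charge)), collapse = ",")))
  invisible(NULL)
})

setMethod("show", "AccessionSets", function(object) {
  cat(sprintf("AccessionSets: %d true, %d entrapment accessions\n",
              length(object@trueSet), length(object@entrapmentSet)))
  invisible(NULL)
})

setMethod("show", "ChargeRegressionModel", function(object) {
  cat("ChargeRegressionModel (decoy score ~ mass, per charge)\n")
  l <- object@lines
  for (i in seq_len(nrow(l)))
    cat(sprintf("  z=%d: slope=%.6g score/Da, intercept=%.6g, n=%d, r=%s [%s]\n",
                l$charge[i], l$slope[i], l$intercept[i], l$n[i],
                ifelse(is.na(l$r[i]), "NA", sprintf("%.3f", l$r[i])),
                l$flag[i]))
  cat(sprintf("  pooled: slope=%.6g (nMin=%d)\n",
              object@pooledSlope, object@nMin))
  invisible(NULL)
})

setMethod("show", "FdrOutcome", function(object) {
  cat(sprintf(
    "FdrOutcome: alpha=%.4g (%s, %s), threshold=%.6g\n  %d accepted spectra, %d accepted peptides, %d decoys removed by I/L filter\n",
    object@alpha, object@mode, object@scoreColumn, object@threshold,
    length(object@acceptedSpectra), length(object@acceptedPeptides),
    object@decoysRemoved))
  invisible(NULL)
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (%s level, alpha=%.4g)\n",
              object@level, object@alpha))
  cat(sprintf("  common: %d   unlabelable uniques: %d\n",
              object@common, object@unlabelable))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d (method-unique identifications)\n",
              object@tp, object@fp, object@tn, object@fn))
  cat(sprintf("  net positive gain: %.3f%% of %d simple-FDR identifications\n",
              object@npgPercent, object@simpleTotal))
  cat(sprintf("  entrapment FDP: simple=%.4f flexi=%.4f\n",
              object@fdpSimple, object@fdpFlexi))
  invisible(NULL)
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    "GeneratorConfig: charges {%s}, n={%s}, slopes={%s} score/Da, mode=%s, seed=%d\n",
    paste(object@chargeStates, collapse = ","),
    paste(object@nSpectra, collapse = ","),
    paste(object@decoySlope, collapse = ","),
    object@mode, object@seed))
  invisible(NULL)
})
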