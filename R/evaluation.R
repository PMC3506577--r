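#' Construct a TruthLabeler
#'
#' @param sets an [AccessionSets] (or two character vectors via
#'   `trueSet`/`entrapmentSet`).
#' @param level identification unit: `"spectrum"` or `"peptide"`.
#' @return a [TruthLabeler].
#' @export
TruthLabeler <- function(sets, level = c("spectrum", "peptide")) {
  level <- match.arg(level)
  new("TruthLabeler", sets = sets, level = level)
}

#' Accepted identifications of an FDR outcome
#'
#' Collapses the accepted target PSMs of an [FdrOutcome] to the requested
#' identification unit. At the `spectrum` level the unit is the spectrum
#' id; at the `peptide` level it is the I/L-normalized peptide, with
#' protein accessions unioned over all accepted PSMs of that peptide.
#'
#' @param outcome an [FdrOutcome].
#' @param level `"spectrum"` or `"peptide"`.
#' @return data.frame with columns `id` and `proteins`
#'   (semicolon-separated).
#' @export
acceptedIdentifications <- function(outcome, level = c("spectrum", "peptide")) {
  stopifnot(is(outcome, "FdrOutcome"))
  level <- match.arg(level)
  p <- outcome@psm
  acc <- p[p$accepted, , drop = FALSE]
  if (nrow(acc) == 0L)
    return(data.frame(id = character(), proteins = character(),
                      stringsAsFactors = FALSE))
  id <- if (level == "spectrum") acc$spectrum_id
        else normalizePeptide(acc$peptide)
  prot <- split(acc$proteins, id)
  merged <- vapply(prot, function(ps) {
    paste(unique(unlist(strsplit(ps, ";", fixed = TRUE))), collapse = ";")
  }, character(1))
  data.frame(id = names(merged), proteins = unname(merged),
             stringsAsFactors = FALSE)
}

# one label per identification: "true" if any protein is in the true set,
# "false" only if all proteins are entrapment, else "unlabelable"
.labelOne <- function(proteins, trueSet, entrapSet) {
  accs <- unlist(strsplit(proteins, ";", fixed = TRUE))
  accs <- accs[nzchar(accs)]
  if (length(accs) == 0L) return("unlabelable")
  if (any(accs %in% trueSet)) return("true")
  if (all(accs %in% entrapSet)) return("false")
  "unlabelable"
}

#' Label accepted identifications as true, false or unlabelable
#'
#' Applies the entrapment-design rule: an identification sharing any
#' protein with the true set (standard-mix proteins or known
#' contaminants) is true; it is false only if all its proteins are
#' entrapment accessions; identifications hitting neither set are
#' unlabelable and excluded from confusion counts.
#'
#' @param identifications data.frame with columns `id` and `proteins`
#'   (semicolon-separated accessions), as produced by
#'   [acceptedIdentifications()].
#' @param labeler a [TruthLabeler].
#' @return list with character-vector elements `true`, `false` and
#'   `unlabelable` (identification ids).
#' @export
labelIdentifications <- function(identifications, labeler) {
  stopifnot(is(labeler, "TruthLabeler"))
  if (nrow(identifications) == 0L)
    return(list(true = character(), false = character(),
                unlabelable = character()))
  lab <- vapply(identifications$proteins, .labelOne,
                character(1), labeler@sets@trueSet,
                labeler@sets@entrapmentSet, USE.NAMES = FALSE)
  list(true = identifications$id[lab == "true"],
       false = identifications$id[lab == "false"],
       unlabelable = identifications$id[lab == "unlabelable"])
}

.fdpFromIds <- function(identifications, labeler) {
  if (nrow(identifications) == 0L) {
    warning("empty acceptance set: entrapment FDP reported as 0")
    return(0)
  }
  lab <- labelIdentifications(identifications, labeler)
  n_lab <- length(lab$true) + length(lab$false)
  if (n_lab == 0L) {
    warning("no labelable identifications: entrapment FDP reported as 0")
    return(0)
  }
  length(lab$false) / n_lab
}

#' @rdname entrapmentFdp
setMethod("entrapmentFdp", signature(accepted = "data.frame"),
          function(accepted, labeler) .fdpFromIds(accepted, labeler))

#' @rdname entrapmentFdp
setMethod("entrapmentFdp", signature(accepted = "FdrOutcome"),
          function(accepted, labeler) {
            .fdpFromIds(acceptedIdentifications(accepted, labeler@level),
                        labeler)
          })

# core of compareMethods, on identification data.frames
.compareIdentifications <- function(flexiIds, simpleIds, labeler,
                                    level, alpha) {
  uniqF <- flexiIds[!flexiIds$id %in% simpleIds$id, , drop = FALSE]
  uniqS <- simpleIds[!simpleIds$id %in% flexiIds$id, , drop = FALSE]
  common <- length(intersect(flexiIds$id, simpleIds$id))
  labF <- labelIdentifications(uniqF, labeler)
  labS <- labelIdentifications(uniqS, labeler)
  tp <- length(labF$true); fp <- length(labF$false)
  fn <- length(labS$true); tn <- length(labS$false)
  unlab <- length(labF$unlabelable) + length(labS$unlabelable)
  simpleTotal <- nrow(simpleIds)
  npg <- if (simpleTotal > 0)
    100 * ((tp - fp) - (fn - tn)) / simpleTotal else NA_real_
  new("EvaluationReport",
      tp = tp, fp = fp, tn = tn, fn = fn,
      common = as.integer(common), unlabelable = as.integer(unlab),
      level = level, alpha = alpha,
      simpleTotal = as.integer(simpleTotal),
      flexiTotal = as.integer(nrow(flexiIds)),
      npgPercent = npg,
      fdpSimple = .fdpFromIds(simpleIds, labeler),
      fdpFlexi = .fdpFromIds(flexiIds, labeler))
}

#' Compare FlexiFDR against simple FDR on method-unique identifications
#'
#' Both outcomes must have been computed at the same alpha and search
#' mode. Confusion counts follow the entrapment-design terminology:
#' TP/FP are the true/false identifications found only by the rescored
#' (flexi) method, TN/FN the false/true identifications found only by the
#' simple method; identifications shared by both are `common`.
#'
#' @param flexi,simple [FdrOutcome] objects (pass `runFlexiFdr(...)$outcome`
#'   for the rescored branch).
#' @param labeler a [TruthLabeler]; its `level` selects spectrum- or
#'   peptide-level comparison.
#' @return an [EvaluationReport].
#' @export
compareMethods <- function(flexi, simple, labeler) {
  stopifnot(is(flexi, "FdrOutcome"), is(simple, "FdrOutcome"),
            is(labeler, "TruthLabeler"))
  if (!isTRUE(all.equal(flexi@alpha, simple@alpha)))
    configError("outcomes were computed at different alpha levels")
  if (flexi@mode != simple@mode)
    configError("outcomes were computed under different search modes")
  level <- labeler@level
  .compareIdentifications(acceptedIdentifications(flexi, level),
                          acceptedIdentifications(simple, level),
                          labeler, level, flexi@alpha)
}

#' Net positive gain of the rescored method over the baseline
#'
#' Summarises an [EvaluationReport] as a single percentage: the net true
#' identifications gained, minus the net true identifications lost,
#' relative to the baseline acceptance count:
#' `100 * ((tp - fp) - (fn - tn)) / simpleTotal`.
#'
#' @param report an [EvaluationReport].
#' @param simpleTotal baseline acceptance count; defaults to the one
#'   recorded in the report.
#' @return percentage (may be negative).
#' @export
netPositiveGain <- function(report, simpleTotal = report@simpleTotal) {
  stopifnot(is(report, "EvaluationReport"))
  if (!(is.numeric(simpleTotal) && length(simpleTotal) == 1L &&
        simpleTotal > 0))
    configError("simpleTotal must be a positive count")
  100 * ((report@tp - report@fp) - (report@fn - report@tn)) / simpleTotal
}

#' Flatten an EvaluationReport to a named list (for JSON output)
#'
#' @param report an [EvaluationReport].
#' @return named list of all report fields.
#' @export
reportAsList <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  list(level = report@level, alpha = report@alpha,
       tp = report@tp, fp = report@fp, tn = report@tn, fn = report@fn,
       common = report@common, unlabelable = report@unlabelable,
       simple_total = report@simpleTotal, flexi_total = report@flexiTotal,
       net_positive_gain_percent = report@npgPercent,
       entrapment_fdp_simple = report@fdpSimple,
       entrapment_fdp_flexi = report@fdpFlexi)
}
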