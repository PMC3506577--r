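#' Normalize a peptide for sequence-identity comparison
#'
#' Removes bracketed modification text (e.g. `"M[+15.99]"` -> `"M"`),
#' uppercases, and replaces every isoleucine `I` by leucine `L`: the two
#' residues are isobaric and indistinguishable by mass, so peptides
#' differing only in I/L are treated as identical.
#'
#' @param peptide character vector of peptide strings.
#' @return character vector of normalized sequences.
#' @examples
#' normalizePeptide("M[+15.99]ILK")  # "MLLK"
#' @export
normalizePeptide <- function(peptide) {
  chartr("I", "L", toupper(gsub("\\[[^][]*\\]", "", peptide)))
}

#' Remove decoy PSMs whose peptide also occurs in the target database
#'
#' Decoy peptides identical (after I/L normalization and modification
#' stripping) to a target peptide are not valid draws from the null model
#' and are ignored during FDR estimation. By default the comparison set is
#' the normalized peptides of the target PSMs present in `result`; supply
#' `targetPeptides` to compare against an external (already normalized)
#' peptide universe instead.
#'
#' @param result a [PsmSet].
#' @param targetPeptides optional character vector of normalized target
#'   peptides.
#' @return a [PsmSet] without the matching decoys; the number removed is
#'   recorded in `psmMetadata(result)$decoys_removed` and the removed
#'   spectrum ids in `$removed_decoy_spectra`.
#' @export
filterDecoys <- function(result, targetPeptides = NULL) {
  stopifnot(is(result, "PsmSet"))
  p <- result@psm
  if (is.null(targetPeptides))
    targetPeptides <- unique(normalizePeptide(p$peptide[!p$is_decoy]))
  drop <- p$is_decoy & normalizePeptide(p$peptide) %in% targetPeptides
  md <- result@metadata
  md$decoys_removed <- sum(drop)
  md$removed_decoy_spectra <- p$spectrum_id[drop]
  initialize(result, psm = p[!drop, , drop = FALSE], metadata = md)
}

#' Target-decoy FDR at a score threshold
#'
#' With `T(t)` targets and `D(t)` decoys scoring at or above `t`, the
#' separate-search estimate is `D(t) / T(t)` and the concatenated-search
#' estimate is `2 D(t) / (T(t) + D(t))`. The value is 0 whenever
#' `D(t) = 0`, 1 when `T(t) = 0` with decoys remaining, and is clamped to
#' at most 1.
#'
#' @param targets,decoys numeric score vectors (higher is better).
#' @param t numeric vector of thresholds.
#' @param mode `"separate"` or `"concatenated"`.
#' @return numeric vector of FDR estimates, one per threshold.
#' @export
fdrAtThreshold <- function(targets, decoys,
                           t, mode = c("separate", "concatenated")) {
  mode <- match.arg(mode)
  st <- sort(targets)
  sd_ <- sort(decoys)
  # findInterval(x, v, left.open = TRUE) counts elements of v strictly < x
  Tt <- length(st) - findInterval(t, st, left.open = TRUE)
  Dt <- length(sd_) - findInterval(t, sd_, left.open = TRUE)
  fdr <- ifelse(Dt == 0, 0,
         ifelse(Tt == 0, 1,
                if (mode == "separate") Dt / Tt else 2 * Dt / (Tt + Dt)))
  pmin(fdr, 1)
}

#' q-values from target and decoy score lists
#'
#' Evaluates the FDR estimate at every distinct observed score taken as
#' the threshold, then monotonizes: the q-value of a score is the minimum
#' FDR over all thresholds at or below that score, i.e. the smallest FDR
#' at which a PSM with that score is accepted.
#'
#' @inheritParams fdrAtThreshold
#' @return data.frame with one row per distinct observed score (sorted
#'   decreasing): `score`, `fdr` (raw estimate at that threshold) and
#'   `qvalue` (monotonized).
#' @export
computeQvalues <- function(targets, decoys,
                           mode = c("separate", "concatenated")) {
  mode <- match.arg(mode)
  if (length(targets) == 0L)
    configError("computeQvalues needs at least one target score")
  thr <- sort(unique(c(targets, decoys)), decreasing = TRUE)
  if (length(decoys) == 0L) {
    warning("no decoy scores: FDR unestimable, all q-values set to 0")
    return(data.frame(score = thr, fdr = 0, qvalue = 0))
  }
  fdr <- fdrAtThreshold(targets, decoys, thr, mode)
  qvalue <- rev(cummin(rev(fdr)))
  data.frame(score = thr, fdr = fdr, qvalue = qvalue)
}

# q-value lookup for arbitrary scores: the q at the smallest observed
# threshold <= score is the minimal FDR at which that score is accepted.
qvalueAt <- function(scores, qtab) {
  asc <- qtab[order(qtab$score), , drop = FALSE]
  idx <- findInterval(scores, asc$score)
  out <- rep(1, length(scores))  # below every threshold: never accepted
  out[idx > 0] <- asc$qvalue[idx[idx > 0]]
  out
}

#' Accept target PSMs at an FDR level
#'
#' Computes q-values on the chosen score column and accepts exactly the
#' target PSMs with q-value at or below `alpha`. The reported threshold is
#' the minimum accepted score (ties at the threshold are accepted). Decoy
#' PSMs never enter the accepted sets; entrapment targets do (their
#' falseness is only known to the evaluator).
#'
#' @param result a [PsmSet] (decoy-filtered as appropriate).
#' @param alpha FDR level in (0, 1), e.g. 0.01.
#' @param mode search strategy; defaults to the set's own mode.
#' @param scoreColumn score column to threshold (`"score"` or
#'   `"flexiscore"`).
#' @return an [FdrOutcome]; its PSM table carries `q_value` and
#'   `accepted` columns for every PSM (decoys included, for audit).
#' @export
acceptAtAlpha <- function(result, alpha, mode = searchMode(result),
                          scoreColumn = "score") {
  stopifnot(is(result, "PsmSet"))
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    configError("alpha must lie strictly between 0 and 1")
  mode <- match.arg(mode, .SEARCH_MODES)
  p <- result@psm
  if (!scoreColumn %in% names(p))
    configError(sprintf("score column '%s' not present", scoreColumn))
  s <- p[[scoreColumn]]
  targets <- s[!p$is_decoy]
  decoys <- s[p$is_decoy]
  if (length(targets) == 0L)
    dataError("no target PSMs to accept")
  qtab <- computeQvalues(targets, decoys, mode)
  p$q_value <- qvalueAt(s, qtab)
  p$accepted <- !p$is_decoy & p$q_value <= alpha
  threshold <- if (any(p$accepted)) min(s[p$accepted]) else Inf
  new("FdrOutcome", alpha = alpha, mode = mode, scoreColumn = scoreColumn,
      threshold = threshold, psm = p,
      acceptedSpectra = unique(p$spectrum_id[p$accepted]),
      acceptedPeptides = unique(normalizePeptide(p$peptide[p$accepted])),
      decoysRemoved = as.integer(result@metadata$decoys_removed %||% 0L))
}

#' Classical target-decoy FDR pipeline
#'
#' Applies the I/L decoy filter, then accepts target PSMs at `alpha` on
#' the raw search score. This is the flat-threshold baseline the
#' regression rescoring of [runFlexiFdr()] is compared against.
#'
#' @inheritParams acceptAtAlpha
#' @return an [FdrOutcome].
#' @export
runSimpleFdr <- function(result, alpha = 0.01, mode = searchMode(result)) {
  acceptAtAlpha(filterDecoys(result), alpha, mode, scoreColumn = "score")
}
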