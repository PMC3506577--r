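#' @import methods
NULL

.PSM_REQUIRED_COLS <- c("spectrum_id", "peptide", "charge", "mass", "score",
                        "is_decoy", "proteins")

.SEARCH_MODES <- c("separate", "concatenated")
.SCORE_DIRECTIONS <- c("higher_is_better", "lower_is_better")
.EVAL_LEVELS <- c("spectrum", "peptide")

#' PsmSet: a collection of peptide-spectrum matches
#'
#' Container for one search result: one row per candidate peptide-spectrum
#' match (PSM), plus the search strategy under which target and decoy
#' databases were queried and the orientation of the search score. Scores
#' are always stored so that larger means better; `lower_is_better` inputs
#' (e-value-like scores) are negated on ingest by [readPsmTable()].
#'
#' @slot psm `data.frame` with at least the columns `spectrum_id`
#'   (character), `peptide` (character, modifications encoded as bracketed
#'   delta masses, e.g. `"M[+15.99]ILK"`), `charge` (integer, precursor
#'   charge state), `mass` (numeric, neutral peptide mass in Da), `score`
#'   (numeric), `is_decoy` (logical) and `proteins` (character,
#'   semicolon-separated accessions). Derived columns such as `flexiscore`,
#'   `q_value` and `accepted` may be appended by downstream steps.
#' @slot mode `"separate"` or `"concatenated"` target-decoy strategy.
#' @slot scoreDirection orientation of the *original* score column;
#'   internally scores are always higher-is-better.
#' @slot metadata free-form list (provenance, filter counts, generator
#'   configuration).
#'
#' @seealso [readPsmTable()], [selectBestPerSpectrum()], [filterDecoys()]
#' @export
setClass("PsmSet",
  slots = c(psm = "data.frame", mode = "character",
            scoreDirection = "character", metadata = "list"),
  prototype = prototype(mode = "separate",
                        scoreDirection = "higher_is_better",
                        metadata = list()))

setValidity("PsmSet", function(object) {
  p <- object@psm
  msgs <- character()
  missing <- setdiff(.PSM_REQUIRED_COLS, names(p))
  if (length(missing))
    return(sprintf("missing PSM columns: %s", paste(missing, collapse = ", ")))
  if (!(length(object@mode) == 1L && object@mode %in% .SEARCH_MODES))
    msgs <- c(msgs, "mode must be 'separate' or 'concatenated'")
  if (!(length(object@scoreDirection) == 1L &&
        object@scoreDirection %in% .SCORE_DIRECTIONS))
    msgs <- c(msgs, "invalid scoreDirection")
  if (nrow(p)) {
    if (!is.numeric(p$mass) || any(!is.finite(p$mass)) || any(p$mass <= 0))
      msgs <- c(msgs, "mass must be finite and > 0")
    if (any(!is.finite(p$charge)) || any(p$charge < 1))
      msgs <- c(msgs, "charge must be >= 1")
    if (!is.character(p$peptide) || any(!nzchar(p$peptide)))
      msgs <- c(msgs, "peptide must be non-empty")
    if (!is.logical(p$is_decoy) || any(is.na(p$is_decoy)))
      msgs <- c(msgs, "is_decoy must be TRUE/FALSE")
    if (any(!p$is_decoy & !nzchar(p$proteins)))
      msgs <- c(msgs, "target PSMs must carry at least one protein accession")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' AccessionSets: true vs entrapment protein accessions
#'
#' The evaluation database partition: accessions of proteins known to be
#' present in the sample (standard-mix proteins plus common contaminants)
#' and accessions of entrapment proteins from an unrelated organism, whose
#' identifications are false by construction. The two sets must be
#' disjoint.
#'
#' @slot trueSet character vector of true-protein accessions.
#' @slot entrapmentSet character vector of entrapment accessions.
#' @export
setClass("AccessionSets",
  slots = c(trueSet = "character", entrapmentSet = "character"))

setValidity("AccessionSets", function(object) {
  shared <- intersect(object@trueSet, object@entrapmentSet)
  if (length(shared))
    sprintf("true and entrapment sets overlap: %s",
            paste(utils::head(shared, 5L), collapse = ", "))
  else TRUE
})

#' ChargeRegressionModel: per-charge decoy score-vs-mass lines
#'
#' The decoy calibration model: for each precursor charge state, the
#' ordinary least-squares line of decoy score on peptide mass
#' (score = slope * mass + intercept), with the number of decoys used, the
#' Pearson correlation, and a flag recording whether the line was fitted
#' from that charge's own decoys (`fitted`), borrowed from the all-charge
#' pooled fit (`pooled_fallback`), or degenerated to slope zero
#' (`zero_fallback`).
#'
#' @slot lines `data.frame` with columns `charge`, `slope` (score per Da),
#'   `intercept` (score units), `n` (decoys used), `r` (Pearson
#'   correlation, `NA` for fallbacks) and `flag`.
#' @slot pooledSlope,pooledIntercept the all-charge fit (`NA` if too few
#'   decoys overall).
#' @slot nMin minimum decoys per charge required for a per-charge fit.
#' @seealso [fitDecoyRegression()], [flexiScore()]
#' @export
setClass("ChargeRegressionModel",
  slots = c(lines = "data.frame", pooledSlope = "numeric",
            pooledIntercept = "numeric", nMin = "integer"))

setValidity("ChargeRegressionModel", function(object) {
  l <- object@lines
  need <- c("charge", "slope", "intercept", "n", "r", "flag")
  missing <- setdiff(need, names(l))
  if (length(missing))
    return(sprintf("missing model columns: %s", paste(missing, collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(l$charge))
    msgs <- c(msgs, "duplicated charge entries")
  bad_flag <- setdiff(l$flag, c("fitted", "pooled_fallback", "zero_fallback"))
  if (length(bad_flag))
    msgs <- c(msgs, sprintf("unknown flag: %s", paste(bad_flag, collapse = ", ")))
  if (any(l$flag == "fitted" & l$n < object@nMin))
    msgs <- c(msgs, "charge flagged 'fitted' with fewer than nMin decoys")
  if (any(l$flag == "zero_fallback" & l$slope != 0))
    msgs <- c(msgs, "zero_fallback charge with nonzero slope")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' FdrOutcome: acceptance decision at a fixed FDR level
#'
#' The result of thresholding a [PsmSet] at an FDR level alpha: per-PSM
#' q-values, the score threshold actually realised, and the accepted
#' spectrum and peptide identification sets. Only target PSMs are ever
#' "identifications"; decoys never enter the accepted sets. Entrapment
#' targets *are* accepted when they pass -- their falseness is known only
#' to the evaluator.
#'
#' @slot alpha the FDR level in (0, 1).
#' @slot mode search strategy whose estimator was used.
#' @slot scoreColumn which score column the threshold applies to
#'   (`"score"` for classical FDR, `"flexiscore"` after rescoring).
#' @slot threshold minimum accepted score on that column (`Inf` when
#'   nothing is accepted).
#' @slot psm the input PSM table augmented with `q_value` and `accepted`.
#' @slot acceptedSpectra spectrum ids of accepted target PSMs.
#' @slot acceptedPeptides I/L-normalized peptides of accepted target PSMs.
#' @slot decoysRemoved decoys dropped by the I/L target-twin filter before
#'   FDR estimation.
#' @seealso [acceptAtAlpha()], [runSimpleFdr()], [runFlexiFdr()]
#' @export
setClass("FdrOutcome",
  slots = c(alpha = "numeric", mode = "character", scoreColumn = "character",
            threshold = "numeric", psm = "data.frame",
            acceptedSpectra = "character", acceptedPeptides = "character",
            decoysRemoved = "integer"))

setValidity("FdrOutcome", function(object) {
  msgs <- character()
  if (!(object@alpha > 0 && object@alpha < 1))
    msgs <- c(msgs, "alpha must lie in (0, 1)")
  if (!object@mode %in% .SEARCH_MODES)
    msgs <- c(msgs, "invalid mode")
  p <- object@psm
  if (all(c("q_value", "accepted") %in% names(p)) && nrow(p)) {
    acc <- p[p$accepted, , drop = FALSE]
    if (any(acc$is_decoy))
      msgs <- c(msgs, "decoy PSM marked accepted")
    if (nrow(acc) && any(acc$q_value > object@alpha))
      msgs <- c(msgs, "accepted PSM with q-value above alpha")
    if (nrow(acc) && any(acc[[object@scoreColumn]] < object@threshold))
      msgs <- c(msgs, "accepted PSM below threshold")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' TruthLabeler: ground-truth labelling by protein accession
#'
#' Labels accepted identifications as true or false using the entrapment
#' database design: an identification sharing any protein with the true
#' set is true; it is false only if *all* its proteins are entrapment
#' accessions; otherwise it cannot be labelled and is excluded from
#' confusion counts.
#'
#' @slot sets an [AccessionSets].
#' @slot level `"spectrum"` or `"peptide"`: the identification unit.
#' @seealso [labelIdentifications()], [compareMethods()], [entrapmentFdp()]
#' @export
setClass("TruthLabeler",
  slots = c(sets = "AccessionSets", level = "character"))

setValidity("TruthLabeler", function(object) {
  if (!(length(object@level) == 1L && object@level %in% .EVAL_LEVELS))
    "level must be 'spectrum' or 'peptide'"
  else TRUE
})

#' EvaluationReport: confusion counts on method-unique identifications
#'
#' Comparison of a rescored (FlexiFDR) acceptance against a classical
#' (simple) FDR acceptance at the same level and alpha. True/false
#' positives and negatives are defined on the identifications unique to
#' one method: TP = unique-to-FlexiFDR and true, FP = unique-to-FlexiFDR
#' and false, TN = unique-to-simple and false, FN = unique-to-simple and
#' true. Identifications shared by both methods are counted in `common`;
#' unlabelable unique identifications are excluded from the confusion
#' counts and reported separately.
#'
#' @slot tp,fp,tn,fn method-unique confusion counts.
#' @slot common identifications accepted by both methods.
#' @slot unlabelable unique identifications hitting neither accession set.
#' @slot level,alpha comparison unit and FDR level.
#' @slot simpleTotal,flexiTotal total accepted identifications per method.
#' @slot npgPercent net positive gain,
#'   `100 * ((tp - fp) - (fn - tn)) / simpleTotal`.
#' @slot fdpSimple,fdpFlexi entrapment-estimated false discovery
#'   proportions of the two full acceptance sets.
#' @seealso [compareMethods()], [netPositiveGain()]
#' @export
setClass("EvaluationReport",
  slots = c(tp = "integer", fp = "integer", tn = "integer", fn = "integer",
            common = "integer", unlabelable = "integer",
            level = "character", alpha = "numeric",
            simpleTotal = "integer", flexiTotal = "integer",
            npgPercent = "numeric", fdpSimple = "numeric",
            fdpFlexi = "numeric"))

setValidity("EvaluationReport", function(object) {
  counts <- c(object@tp, object@fp, object@tn, object@fn, object@common,
              object@unlabelable)
  if (any(counts < 0)) "confusion counts must be non-negative" else TRUE
})

#' GeneratorConfig: parameters of the synthetic PSM generator
#'
#' Describes a synthetic search result with the structure the rescoring
#' method assumes: per-charge decoy scores whose conditional mean is
#' linear in peptide mass, correct target PSMs boosted above the decoy
#' line, incorrect target PSMs drawn from the decoy (null) distribution,
#' and an entrapment fraction among the incorrect targets. Construct with
#' [generatorConfig()], which validates and applies the package defaults.
#'
#' @slot chargeStates integer charge states simulated.
#' @slot nSpectra spectra per charge state (parallel to `chargeStates`).
#' @slot massMeanlog,massSdlog lognormal law of peptide neutral mass (Da).
#' @slot massRange truncation bounds of the mass law (Da).
#' @slot decoySlope,decoyIntercept per-charge decoy line (score/Da, score).
#' @slot decoySd score s.d. around the decoy line.
#' @slot correctFraction fraction of spectra whose target PSM is correct.
#' @slot correctOffset mean score boost of correct PSMs above the decoy
#'   line at the same mass.
#' @slot correctSd score s.d. of correct PSMs.
#' @slot entrapmentFraction fraction of incorrect target PSMs assigned
#'   entrapment-only accessions.
#' @slot ilTwinFraction fraction of decoy peptides emitted as I/L twins of
#'   the same spectrum's target peptide (exercises the decoy filter).
#' @slot mode search strategy emulated (`"separate"` emits target and decoy
#'   PSMs per spectrum; `"concatenated"` emits the competition winner).
#' @slot nTrueProteins,nEntrapProteins sizes of the accession pools.
#' @slot seed integer RNG seed.
#' @slot rngKind RNG algorithm recorded for reproducibility.
#' @seealso [generatorConfig()], [generatePsmData()]
#' @export
setClass("GeneratorConfig",
  slots = c(chargeStates = "integer", nSpectra = "integer",
            massMeanlog = "numeric", massSdlog = "numeric",
            massRange = "numeric", decoySlope = "numeric",
            decoyIntercept = "numeric", decoySd = "numeric",
            correctFraction = "numeric", correctOffset = "numeric",
            correctSd = "numeric", entrapmentFraction = "numeric",
            ilTwinFraction = "numeric", mode = "character",
            nTrueProteins = "integer", nEntrapProteins = "integer",
            seed = "integer", rngKind = "character"))

setValidity("GeneratorConfig", function(object) {
  msgs <- character()
  k <- length(object@chargeStates)
  if (k == 0L || any(object@chargeStates < 1L))
    msgs <- c(msgs, "chargeStates must be positive integers")
  for (s in c("nSpectra", "decoySlope", "decoyIntercept"))
    if (length(slot(object, s)) != k)
      msgs <- c(msgs, sprintf("%s must have one entry per charge state", s))
  if (any(object@nSpectra < 1L))
    msgs <- c(msgs, "nSpectra must be >= 1")
  for (s in c("correctFraction", "entrapmentFraction", "ilTwinFraction")) {
    v <- slot(object, s)
    if (!(length(v) == 1L && is.finite(v) && v >= 0 && v <= 1))
      msgs <- c(msgs, sprintf("%s must lie in [0, 1]", s))
  }
  for (s in c("decoySd", "correctSd"))
    if (slot(object, s) <= 0)
      msgs <- c(msgs, sprintf("%s must be > 0", s))
  if (length(object@massRange) != 2L || object@massRange[1] <= 0 ||
      diff(object@massRange) <= 0)
    msgs <- c(msgs, "massRange must be an increasing positive pair")
  if (!object@mode %in% .SEARCH_MODES)
    msgs <- c(msgs, "mode must be 'separate' or 'concatenated'")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
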