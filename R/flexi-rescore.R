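#' Fit per-charge decoy score-vs-mass regression lines
#'
#' The calibration step of the rescoring method: for every precursor
#' charge state, the decoy PSMs are the null model and their score is
#' regressed on peptide mass by ordinary least squares (score = slope *
#' mass + intercept). Charges with fewer than `nMin` decoys -- or with no
#' mass spread -- fall back to the pooled all-charge line when the pooled
#' fit itself has at least `nMin` decoys, and to slope 0 otherwise (the
#' method then degenerates to classical FDR for that charge). Every charge
#' present among the PSMs, target or decoy, receives an entry so that all
#' PSMs can be rescored.
#'
#' Decoy filtering ([filterDecoys()]) should be applied first: decoys
#' identical to target peptides are not null draws and would bias the fit.
#'
#' @param result a decoy-filtered [PsmSet].
#' @param nMin minimum decoys per charge for a dedicated fit (>= 3;
#'   default 10).
#' @return a [ChargeRegressionModel].
#' @export
fitDecoyRegression <- function(result, nMin = 10L) {
  stopifnot(is(result, "PsmSet"))
  nMin <- as.integer(nMin)
  if (nMin < 3L)
    configError("nMin must be at least 3")
  p <- result@psm
  d <- p[p$is_decoy, , drop = FALSE]
  charges <- sort(unique(p$charge))
  if (nrow(d) == 0L)
    warning("no decoy PSMs: all slopes set to 0, rescoring degenerates to classical FDR")

  pooledSlope <- NA_real_
  pooledIntercept <- NA_real_
  if (nrow(d) >= nMin && stats::sd(d$mass) > 0) {
    pfit <- stats::lm(score ~ mass, data = d)
    pooledSlope <- unname(stats::coef(pfit)[2])
    pooledIntercept <- unname(stats::coef(pfit)[1])
  }

  rows <- lapply(charges, function(z) {
    dz <- d[d$charge == z, , drop = FALSE]
    nz <- nrow(dz)
    if (nz >= nMin && stats::sd(dz$mass) > 0) {
      fit <- stats::lm(score ~ mass, data = dz)
      data.frame(charge = z, slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]), n = nz,
                 r = stats::cor(dz$mass, dz$score), flag = "fitted",
                 stringsAsFactors = FALSE)
    } else if (!is.na(pooledSlope)) {
      data.frame(charge = z, slope = pooledSlope,
                 intercept = pooledIntercept, n = nz, r = NA_real_,
                 flag = "pooled_fallback", stringsAsFactors = FALSE)
    } else {
      intc <- if (nz > 0) mean(dz$score)
              else if (nrow(d) > 0) mean(d$score) else 0
      data.frame(charge = z, slope = 0, intercept = intc, n = nz,
                 r = NA_real_, flag = "zero_fallback",
                 stringsAsFactors = FALSE)
    }
  })
  new("ChargeRegressionModel", lines = do.call(rbind, rows),
      pooledSlope = pooledSlope, pooledIntercept = pooledIntercept,
      nMin = nMin)
}

#' FlexiScore: project a score along its charge's decoy line
#'
#' For a PSM with observed score y', peptide mass x and charge z, the
#' rescored value is the y-axis intercept of the line through (x, y')
#' parallel to charge z's decoy regression line: `c' = y' - m_z * x`.
#' Applied identically to targets and decoys, this removes the
#' mass-dependent drift of the null scores, so a flat threshold on the
#' FlexiScore scale is a mass-dependent, charge-specific threshold on the
#' raw scale. Works for positive, negative and mixed per-charge slopes.
#'
#' @param score,mass,charge equal-length vectors (or scalars).
#' @param model a [ChargeRegressionModel] with an entry (fitted or
#'   fallback) for every charge supplied.
#' @return numeric vector of FlexiScores.
#' @examples
#' m <- new("ChargeRegressionModel",
#'          lines = data.frame(charge = 2L, slope = 0.01, intercept = 5,
#'                             n = 10L, r = 1, flag = "fitted"),
#'          pooledSlope = 0.01, pooledIntercept = 5, nMin = 3L)
#' flexiScore(50, 1000, 2, m)  # 40
#' @export
flexiScore <- function(score, mass, charge, model) {
  stopifnot(is(model, "ChargeRegressionModel"))
  idx <- match(charge, model@lines$charge)
  if (anyNA(idx))
    configError(sprintf("no regression entry for charge state(s): %s",
                        paste(sort(unique(charge[is.na(idx)])),
                              collapse = ", ")))
  score - model@lines$slope[idx] * mass
}

#' Add a FlexiScore column to a PsmSet
#'
#' @param result a [PsmSet].
#' @param model a [ChargeRegressionModel] covering the set's charges.
#' @return the [PsmSet] with a `flexiscore` column appended.
#' @export
applyFlexiScore <- function(result, model) {
  stopifnot(is(result, "PsmSet"))
  p <- result@psm
  p$flexiscore <- flexiScore(p$score, p$mass, p$charge, model)
  initialize(result, psm = p)
}

#' The full FlexiFDR pipeline
#'
#' Runs the decoy-learned rescoring end to end: (1) remove decoys whose
#' I/L-normalized peptide also occurs among the targets, (2) fit the
#' per-charge decoy score-vs-mass lines, (3) transform every PSM score to
#' its FlexiScore `c' = y' - m_z * x`, (4) estimate q-values on the pooled
#' FlexiScores and accept targets at `alpha`. The acceptance region for
#' charge z in (mass, score) space is the half-plane above a line parallel
#' to that charge's decoy regression line.
#'
#' @inheritParams acceptAtAlpha
#' @param nMin minimum decoys per charge for a dedicated regression fit.
#' @return list with elements `outcome` (an [FdrOutcome] on the
#'   `flexiscore` column) and `model` (the [ChargeRegressionModel]).
#' @seealso [runSimpleFdr()] for the flat-threshold baseline.
#' @export
runFlexiFdr <- function(result, alpha = 0.01, mode = searchMode(result),
                        nMin = 10L) {
  filtered <- filterDecoys(result)
  model <- fitDecoyRegression(filtered, nMin = nMin)
  scored <- applyFlexiScore(filtered, model)
  outcome <- acceptAtAlpha(scored, alpha, mode, scoreColumn = "flexiscore")
  list(outcome = outcome, model = model)
}

#' Serialize a regression model to JSON
#'
#' @param model a [ChargeRegressionModel].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeRegressionModel <- function(model, path) {
  stopifnot(is(model, "ChargeRegressionModel"))
  jsonlite::write_json(
    list(lines = model@lines, pooled_slope = model@pooledSlope,
         pooled_intercept = model@pooledIntercept, n_min = model@nMin),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
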