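# Independent oracles and small builders shared across the test files.

# Brute-force q-values: evaluate the FDR estimate at every distinct
# observed score by direct counting, then take, for each score s, the
# minimum FDR over all thresholds at or below s. Independent of the
# package's vectorized implementation.
bruteForceQvalues <- function(targets, decoys, mode) {
  thr <- sort(unique(c(targets, decoys)), decreasing = TRUE)
  fdr <- vapply(thr, function(t) {
    Tt <- sum(targets >= t)
    Dt <- sum(decoys >= t)
    if (Dt == 0) return(0)
    if (Tt == 0) return(1)
    est <- if (mode == "separate") Dt / Tt else 2 * Dt / (Tt + Dt)
    min(est, 1)
  }, numeric(1))
  q <- vapply(seq_along(thr), function(i) min(fdr[thr <= thr[i]]),
              numeric(1))
  data.frame(score = thr, fdr = fdr, qvalue = q)
}

# Two-pass closed-form simple linear regression: slope = Sxy/Sxx about
# the means, intercept from the centroid.
twoPassOls <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(slope = slope, intercept = yb - slope * xb)
}

# Minimal PsmSet from score vectors (masses/charges/peptides defaulted).
makeScoreSet <- function(targetScores, decoyScores,
                         mode = "separate",
                         targetMass = 1000, decoyMass = 1000,
                         charge = 2L) {
  nt <- length(targetScores); nd <- length(decoyScores)
  psm <- data.frame(
    spectrum_id = sprintf("s%04d", seq_len(nt + nd)),
    peptide = c(strrep("A", 6 + seq_len(nt) %% 5 + 1),
                strrep("G", 6 + seq_len(nd) %% 5 + 1)),
    charge = charge,
    mass = c(rep_len(targetMass, nt), rep_len(decoyMass, nd)),
    score = c(targetScores, decoyScores),
    is_decoy = rep(c(FALSE, TRUE), c(nt, nd)),
    proteins = rep(c("TRUEP001", ""), c(nt, nd)),
    stringsAsFactors = FALSE)
  PsmSet(psm, mode = mode)
}

# One-row PSM builder for hand-assembled tables.
psmRow <- function(spectrum_id, peptide, charge, mass, score, is_decoy,
                   proteins = if (is_decoy) "" else "TRUEP001") {
  data.frame(spectrum_id = spectrum_id, peptide = peptide,
             charge = as.integer(charge), mass = mass, score = score,
             is_decoy = is_decoy, proteins = proteins,
             stringsAsFactors = FALSE)
}

# The committed default fixture, generated once per test run.
defaultFixture <- local({
  cache <- NULL
  function(mode = "separate") {
    key <- mode
    if (is.null(cache[[key]])) {
      cfg <- generatorConfig(mode = mode)
      cache[[key]] <<- generatePsmData(cfg)
    }
    cache[[key]]
  }
})
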