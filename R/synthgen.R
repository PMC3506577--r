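.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Create a synthetic-generator configuration
#'
#' Returns a validated [GeneratorConfig]. The defaults are the package's
#' canonical study conditions (also committed at
#' `inst/extdata/synthgen-default.yaml`): charges 2 and 3 with 2000
#' spectra each, decoy lines with slopes 0.008 and 0.012 score/Da and
#' intercepts 20 and 25, Gaussian score noise of 5 around the lines,
#' 50% of spectra correct with a mean score boost of 25 (s.d. 6) above
#' the decoy line at the same mass -- so the decoy drift across the mass
#' range is a substantial fraction of the target-decoy separation and
#' both methods accept a large common core while differing at the
#' borderline, 30% of incorrect targets carrying entrapment-only
#' accessions,
#' 5% of decoy peptides emitted as I/L twins of their spectrum's target
#' peptide, and a lognormal mass law (median 1400 Da, sdlog 0.3)
#' truncated to [600, 4600] Da.
#'
#' @param chargeStates integer vector of charge states.
#' @param nSpectra spectra per charge (recycled to the charge states).
#' @param decoySlope,decoyIntercept per-charge decoy line parameters
#'   (recycled).
#' @param massMeanlog,massSdlog,massRange lognormal mass law and bounds.
#' @param decoySd,correctFraction,correctOffset,correctSd,entrapmentFraction,ilTwinFraction
#'   see [GeneratorConfig].
#' @param mode search strategy to emulate.
#' @param nTrueProteins,nEntrapProteins accession pool sizes.
#' @param seed RNG seed.
#' @return a [GeneratorConfig].
#' @export
generatorConfig <- function(chargeStates = c(2L, 3L),
                            nSpectra = 2000L,
                            decoySlope = c(0.008, 0.012),
                            decoyIntercept = c(20, 25),
                            massMeanlog = log(1400), massSdlog = 0.3,
                            massRange = c(600, 4600),
                            decoySd = 5, correctFraction = 0.5,
                            correctOffset = 25, correctSd = 6,
                            entrapmentFraction = 0.3,
                            ilTwinFraction = 0.05,
                            mode = c("separate", "concatenated"),
                            nTrueProteins = 20L, nEntrapProteins = 50L,
                            seed = 42L) {
  mode <- match.arg(mode)
  k <- length(chargeStates)
  new("GeneratorConfig",
      chargeStates = as.integer(chargeStates),
      nSpectra = rep_len(as.integer(nSpectra), k),
      massMeanlog = massMeanlog, massSdlog = massSdlog,
      massRange = as.numeric(massRange),
      decoySlope = rep_len(as.numeric(decoySlope), k),
      decoyIntercept = rep_len(as.numeric(decoyIntercept), k),
      decoySd = decoySd, correctFraction = correctFraction,
      correctOffset = correctOffset, correctSd = correctSd,
      entrapmentFraction = entrapmentFraction,
      ilTwinFraction = ilTwinFraction, mode = mode,
      nTrueProteins = as.integer(nTrueProteins),
      nEntrapProteins = as.integer(nEntrapProteins),
      seed = as.integer(seed), rngKind = "Mersenne-Twister")
}

#' Read a generator configuration from YAML
#'
#' Keys are the snake_case forms of the [generatorConfig()] arguments
#' (e.g. `charge_states`, `decoy_slope`); absent keys keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return a [GeneratorConfig].
#' @export
readGeneratorConfig <- function(path) {
  if (!file.exists(path))
    configError(sprintf("generator config not found: %s", path))
  y <- yaml::read_yaml(path)
  camel <- function(s) gsub("_(\\w)", "\\U\\1", s, perl = TRUE)
  names(y) <- camel(names(y))
  known <- names(formals(generatorConfig))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    configError(sprintf("unknown generator config field(s): %s",
                        paste(unknown, collapse = ", ")))
  do.call(generatorConfig, y)
}

# vectorized random peptide strings of given lengths
.randomPeptides <- function(lengths) {
  tot <- sum(lengths)
  letters <- sample(.AA_ALPHABET, tot, replace = TRUE)
  vapply(split(letters, rep.int(seq_along(lengths), lengths)),
         paste0, character(1), collapse = "")
}

# lognormal masses truncated by rejection; deterministic under the seed
.randomMasses <- function(n, meanlog, sdlog, range) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (i in 1:100) {
    bad <- x < range[1] | x > range[2]
    if (!any(bad)) break
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  pmin(pmax(x, range[1]), range[2])
}

#' Generate a synthetic PSM dataset
#'
#' Emulates the statistical structure the rescoring method assumes. For
#' each spectrum of charge z with peptide mass x drawn from the truncated
#' lognormal law: the decoy PSM score is Normal(a_z + b_z x, decoySd);
#' the target PSM score is Normal(a_z + b_z x + correctOffset, correctSd)
#' when the spectrum is correct (probability `correctFraction`) and an
#' independent draw from the decoy (null) distribution otherwise.
#' Correct targets carry a true-set accession; incorrect targets carry an
#' entrapment accession with probability `entrapmentFraction`, otherwise
#' a true-set accession (the evaluator's unavoidable blind spot). A fixed
#' fraction of decoy peptides are emitted as I/L twins of their
#' spectrum's target peptide to exercise the decoy filter; all other
#' decoy peptides are guaranteed distinct (after I/L normalization) from
#' every target peptide. In `separate` mode both the target and the
#' decoy PSM of every spectrum are emitted; in `concatenated` mode only
#' the higher-scoring of the two.
#'
#' Output is bit-reproducible from the seed (Mersenne-Twister, inversion
#' normals).
#'
#' @param config a [GeneratorConfig].
#' @param seed overrides `config@seed` (used for replicate runs).
#' @return list with elements `result` ([PsmSet]), `sets`
#'   ([AccessionSets]), and `truth` (data.frame with one row per spectrum:
#'   `spectrum_id`, `charge`, `truth` in
#'   `{correct_true_protein, incorrect_entrapment,
#'   incorrect_true_protein_random}`, and `decoy_is_twin`).
#' @export
generatePsmData <- function(config, seed = config@seed) {
  stopifnot(is(config, "GeneratorConfig"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = config@rngKind,
           normal.kind = "Inversion", sample.kind = "Rejection")

  truePool <- sprintf("TRUEP%03d", seq_len(config@nTrueProteins))
  entrapPool <- sprintf("ENTRAPP%03d", seq_len(config@nEntrapProteins))

  per_charge <- lapply(seq_along(config@chargeStates), function(ci) {
    z <- config@chargeStates[ci]
    n <- config@nSpectra[ci]
    a <- config@decoyIntercept[ci]
    b <- config@decoySlope[ci]
    spectrum_id <- sprintf("spec_z%d_%05d", z, seq_len(n))
    mass <- .randomMasses(n, config@massMeanlog, config@massSdlog,
                          config@massRange)
    line <- a + b * mass
    correct <- stats::runif(n) < config@correctFraction
    target_score <- ifelse(correct,
                           stats::rnorm(n, line + config@correctOffset,
                                        config@correctSd),
                           stats::rnorm(n, line, config@decoySd))
    decoy_score <- stats::rnorm(n, line, config@decoySd)

    pep_len <- pmax(7L, as.integer(round(mass / 110)))
    target_pep <- .randomPeptides(pep_len)
    decoy_pep <- .randomPeptides(pep_len)
    n_twin <- round(config@ilTwinFraction * n)
    twin_idx <- if (n_twin > 0) sample.int(n, n_twin) else integer()
    decoy_pep[twin_idx] <- chartr("IL", "LI", target_pep[twin_idx])
    # non-twin decoys must not collide with any target peptide
    target_norm <- unique(normalizePeptide(target_pep))
    non_twin <- setdiff(seq_len(n), twin_idx)
    for (i in 1:20) {
      clash <- non_twin[normalizePeptide(decoy_pep[non_twin]) %in% target_norm]
      if (!length(clash)) break
      decoy_pep[clash] <- .randomPeptides(pep_len[clash])
    }

    entrap <- !correct & stats::runif(n) < config@entrapmentFraction
    target_prot <- ifelse(entrap,
                          sample(entrapPool, n, replace = TRUE),
                          sample(truePool, n, replace = TRUE))
    decoy_prot <- paste0("DECOY_", sample(truePool, n, replace = TRUE))
    truth <- ifelse(correct, "correct_true_protein",
                    ifelse(entrap, "incorrect_entrapment",
                           "incorrect_true_protein_random"))
    decoy_is_twin <- seq_len(n) %in% twin_idx

    target_rows <- data.frame(spectrum_id = spectrum_id,
                              peptide = target_pep, charge = z,
                              mass = mass, score = target_score,
                              is_decoy = FALSE, proteins = target_prot,
                              stringsAsFactors = FALSE)
    decoy_rows <- data.frame(spectrum_id = spectrum_id,
                             peptide = decoy_pep, charge = z,
                             mass = mass, score = decoy_score,
                             is_decoy = TRUE, proteins = decoy_prot,
                             stringsAsFactors = FALSE)
    if (config@mode == "concatenated") {
      keep_decoy <- decoy_score >= target_score  # tie goes to the decoy
      psm <- rbind(target_rows[!keep_decoy, , drop = FALSE],
                   decoy_rows[keep_decoy, , drop = FALSE])
    } else {
      psm <- rbind(target_rows, decoy_rows)
    }
    list(psm = psm,
         truth = data.frame(spectrum_id = spectrum_id, charge = z,
                            truth = truth, decoy_is_twin = decoy_is_twin,
                            stringsAsFactors = FALSE))
  })

  psm <- do.call(rbind, lapply(per_charge, `[[`, "psm"))
  psm <- psm[order(psm$spectrum_id, psm$is_decoy, method = "radix"), ,
             drop = FALSE]
  truth <- do.call(rbind, lapply(per_charge, `[[`, "truth"))
  rownames(psm) <- rownames(truth) <- NULL

  result <- PsmSet(psm, mode = config@mode,
                   metadata = list(generator = "FlexiFDR synthetic",
                                   seed = as.integer(seed),
                                   rng_kind = config@rngKind,
                                   charge_states = config@chargeStates,
                                   decoy_slope = config@decoySlope,
                                   decoy_intercept = config@decoyIntercept,
                                   il_twin_spectra =
                                     truth$spectrum_id[truth$decoy_is_twin]))
  list(result = result,
       sets = AccessionSets(truePool, entrapPool),
       truth = truth)
}

#' Build a TruthLabeler from generator ground truth
#'
#' The labeler uses the generator's own accession sets, so spectra of
#' kind `correct_true_protein` label true, `incorrect_entrapment` label
#' false, and `incorrect_true_protein_random` label true -- the latter is
#' the entrapment evaluator's documented blind spot (an incorrect match
#' that happens to hit a true protein is indistinguishable by accession).
#'
#' @param truth the generator's truth data.frame (retained for interface
#'   symmetry; labelling is purely accession-driven).
#' @param sets the generator's [AccessionSets].
#' @param level `"spectrum"` or `"peptide"`.
#' @return a [TruthLabeler].
#' @export
truthToLabeler <- function(truth, sets, level = c("spectrum", "peptide")) {
  TruthLabeler(sets, match.arg(level))
}
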