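.PROTON_MASS <- 1.007276  # Da, fixed for bit-exact mass derivation

#' Construct a PsmSet from a data.frame
#'
#' Low-level constructor; most users will call [readPsmTable()] or
#' [generatePsmData()] instead.
#'
#' @param psm data.frame with the columns documented in [PsmSet].
#' @param mode `"separate"` or `"concatenated"`.
#' @param scoreDirection orientation of the score column as supplied.
#'   Scores must already be higher-is-better in `psm`; this slot only
#'   records the original orientation.
#' @param metadata free-form provenance list.
#' @return a validated [PsmSet].
#' @export
PsmSet <- function(psm, mode = c("separate", "concatenated"),
                   scoreDirection = c("higher_is_better", "lower_is_better"),
                   metadata = list()) {
  mode <- match.arg(mode)
  scoreDirection <- match.arg(scoreDirection)
  psm$spectrum_id <- as.character(psm$spectrum_id)
  psm$peptide <- as.character(psm$peptide)
  psm$charge <- as.integer(psm$charge)
  psm$mass <- as.numeric(psm$mass)
  psm$score <- as.numeric(psm$score)
  psm$is_decoy <- as.logical(psm$is_decoy)
  psm$proteins <- as.character(psm$proteins)
  rownames(psm) <- NULL
  new("PsmSet", psm = psm, mode = mode, scoreDirection = scoreDirection,
      metadata = metadata)
}

#' Construct an AccessionSets
#'
#' @param trueSet accessions of sample proteins and known contaminants.
#' @param entrapmentSet accessions of entrapment (known-false) proteins.
#' @return a validated [AccessionSets].
#' @export
AccessionSets <- function(trueSet, entrapmentSet) {
  new("AccessionSets", trueSet = unique(as.character(trueSet)),
      entrapmentSet = unique(as.character(entrapmentSet)))
}

.CANONICAL_COLS <- c("spectrum_id", "peptide", "charge", "mz", "mass",
                     "score", "label", "proteins")

#' Read a delimited PSM table
#'
#' Reads one PSM per row from a tab-separated table with a header. Source
#' headers are mapped onto the canonical column names via `columnMap`.
#' Required columns: `spectrum_id`, `peptide`, `charge`, `score`, `label`
#' (values `target`/`decoy`) and `proteins` (semicolon-separated
#' accessions; may be empty for decoys), plus either `mass` (neutral
#' peptide mass, Da) or `mz` (precursor m/z). When only `mz` is present
#' the neutral mass is derived as `z * mz - z * 1.007276`; when a `mass`
#' column exists it is taken verbatim and `mz` is ignored.
#'
#' Rows whose required fields do not parse (non-numeric charge/score,
#' non-positive mass, unknown label, empty peptide, target without
#' proteins) are dropped with a warning listing their file line numbers.
#'
#' @param path path to the delimited file.
#' @param columnMap named character vector mapping canonical names to the
#'   file's headers, e.g. `c(spectrum_id = "SpecID", score = "IonScore")`.
#'   Canonical names absent from the map are looked up verbatim.
#' @param scoreDirection `"higher_is_better"` (default) or
#'   `"lower_is_better"`; the latter negates scores on ingest so that all
#'   downstream logic is higher-is-better.
#' @param sep field separator, tab by default.
#' @return a [PsmSet] in `separate` mode (re-tag with [PsmSet()] or select
#'   hits with [selectBestPerSpectrum()] as appropriate).
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("spectrum_id\tpeptide\tcharge\tmz\tscore\tlabel\tproteins",
#'              "s1\tPEPTIDEK\t2\t500.5\t41.2\ttarget\tsp|P1|A"), tsv)
#' psmTable(readPsmTable(tsv))$mass  # 2*500.5 - 2*1.007276
#' @export
readPsmTable <- function(path, columnMap = NULL,
                         scoreDirection = c("higher_is_better",
                                            "lower_is_better"),
                         sep = "\t") {
  scoreDirection <- match.arg(scoreDirection)
  if (!file.exists(path))
    configError(sprintf("PSM table not found: %s", path))
  raw <- tryCatch(
    utils::read.delim(path, sep = sep, header = TRUE, quote = "",
                      colClasses = "character", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) dataError(sprintf("cannot parse %s: %s", path,
                                          conditionMessage(e))))
  if (nrow(raw) == 0L)
    dataError(sprintf("empty PSM table: %s", path))

  lookup <- function(canon) {
    src <- if (!is.null(columnMap) && canon %in% names(columnMap))
      columnMap[[canon]] else canon
    if (src %in% names(raw)) raw[[src]] else NULL
  }
  required <- c("spectrum_id", "peptide", "charge", "score", "label",
                "proteins")
  for (canon in required)
    if (is.null(lookup(canon)))
      configError(sprintf("required column '%s' not found in %s", canon, path))
  mass_col <- lookup("mass")
  mz_col <- lookup("mz")
  if (is.null(mass_col) && is.null(mz_col))
    configError(sprintf("need a 'mass' or 'mz' column in %s", path))

  charge <- suppressWarnings(as.integer(lookup("charge")))
  score <- suppressWarnings(as.numeric(lookup("score")))
  label <- tolower(trimws(lookup("label")))
  peptide <- trimws(lookup("peptide"))
  proteins <- trimws(lookup("proteins"))
  spectrum_id <- trimws(lookup("spectrum_id"))

  if (!is.null(mass_col)) {
    mass <- suppressWarnings(as.numeric(mass_col))
  } else {
    mz <- suppressWarnings(as.numeric(mz_col))
    mass <- charge * mz - charge * .PROTON_MASS
  }

  is_decoy <- label == "decoy"
  bad <- is.na(charge) | charge < 1L | is.na(score) | !is.finite(mass) |
    is.na(mass) | mass <= 0 | !label %in% c("target", "decoy") |
    !nzchar(peptide) | !nzchar(spectrum_id) | (!is_decoy & !nzchar(proteins))
  if (any(bad)) {
    # +1 for the header line
    warning(sprintf("rejected %d unparseable PSM row(s) at file line(s): %s",
                    sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")))
  }
  keep <- !bad
  if (!any(keep))
    dataError(sprintf("no parseable PSM rows in %s", path))

  score_out <- if (scoreDirection == "lower_is_better") -score else score
  psm <- data.frame(spectrum_id = spectrum_id[keep], peptide = peptide[keep],
                    charge = charge[keep], mass = mass[keep],
                    score = score_out[keep], is_decoy = is_decoy[keep],
                    proteins = proteins[keep], stringsAsFactors = FALSE)
  PsmSet(psm, mode = "separate", scoreDirection = scoreDirection,
         metadata = list(source = path,
                         rejected_lines = which(bad) + 1L,
                         score_negated = scoreDirection == "lower_is_better"))
}

#' Write a PsmSet (or FDR outcome table) as a tab-separated table
#'
#' Writes the canonical dialect: `spectrum_id`, `peptide`, `charge`,
#' `mass`, `score`, `label`, `proteins`, followed by any derived columns
#' present (`flexiscore`, `q_value`, `accepted`). Numeric columns are
#' written with 17 significant digits so a read/write cycle is bit-exact.
#'
#' @param x a [PsmSet] or [FdrOutcome].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePsmTable <- function(x, path) {
  p <- psmTable(x)
  out <- data.frame(spectrum_id = p$spectrum_id, peptide = p$peptide,
                    charge = p$charge,
                    mass = formatNumeric(p$mass),
                    score = formatNumeric(p$score),
                    label = ifelse(p$is_decoy, "decoy", "target"),
                    proteins = p$proteins, stringsAsFactors = FALSE)
  for (extra in c("flexiscore", "q_value")) {
    if (extra %in% names(p)) out[[extra]] <- formatNumeric(p[[extra]])
  }
  if ("accepted" %in% names(p))
    out$accepted <- ifelse(p$accepted, "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Keep the best hit(s) per spectrum
#'
#' In `concatenated` mode target and decoy PSMs compete: the single
#' highest-scoring PSM per spectrum is retained, and an exact
#' target/decoy score tie is resolved in favour of the decoy (the
#' conservative choice for FDR estimation). In `separate` mode the best
#' target and the best decoy are retained independently per spectrum.
#' Output rows are ordered by spectrum id; the operation is idempotent.
#'
#' @param result a [PsmSet].
#' @return a [PsmSet] with at most one (concatenated) or two (separate)
#'   PSMs per spectrum.
#' @export
selectBestPerSpectrum <- function(result) {
  stopifnot(is(result, "PsmSet"))
  p <- result@psm
  if (nrow(p) == 0L) return(result)
  # decoys sort first on exact score ties (!is_decoy: FALSE < TRUE)
  o <- order(p$spectrum_id, -p$score, !p$is_decoy, p$peptide,
             method = "radix")
  p <- p[o, , drop = FALSE]
  key <- if (result@mode == "concatenated") p$spectrum_id
         else paste0(p$spectrum_id, "\r", p$is_decoy)
  p <- p[!duplicated(key), , drop = FALSE]
  p <- p[order(p$spectrum_id, p$is_decoy, method = "radix"), , drop = FALSE]
  rownames(p) <- NULL
  initialize(result, psm = p)
}

#' Read protein accessions from FASTA files
#'
#' The accession of a record is the first whitespace-delimited token of
#' its header line. Duplicates within and across files are collapsed.
#'
#' @param paths one or more FASTA file paths.
#' @return character vector of unique accessions (empty for empty files).
#' @export
readFastaAccessions <- function(paths) {
  accs <- character()
  for (path in paths) {
    if (!file.exists(path))
      configError(sprintf("FASTA file not found: %s", path))
    if (file.size(path) == 0L) next
    headers <- tryCatch(
      names(Biostrings::fasta.seqlengths(path)),
      error = function(e) {
        lines <- readLines(path, warn = FALSE)
        bad <- which(nzchar(trimws(lines)))[1]
        dataError(sprintf("not FASTA content in %s at line %d: '%s'",
                          path, bad, substr(lines[bad], 1, 40)))
      })
    accs <- c(accs, sub("\\s.*$", "", headers))
  }
  unique(accs)
}

#' Write an accession set as a FASTA file of placeholder sequences
#'
#' Used by the synthetic generator: the evaluation machinery only needs
#' accessions, so each record carries a short placeholder amino-acid
#' sequence.
#'
#' @param accessions character vector of accessions.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeAccessionFasta <- function(accessions, path) {
  seqs <- Biostrings::AAStringSet(rep("SYNTHETICPLACEHOLDER", length(accessions)))
  names(seqs) <- accessions
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
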