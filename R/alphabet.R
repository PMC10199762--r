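#' The 20 canonical amino-acid letters
#'
#' Single-letter codes, alphabetical. All descriptor tables in the package
#' (physicochemical classes, propensity scales, CTD groups, triplet scales)
#' are defined only over this alphabet; ambiguity codes (B, J, O, U, X, Z)
#' are rejected at read time.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

VALID_LABELS <- c("epitope", "non_epitope", "unknown")

#' @keywords internal
#' @noRd
check_sequence <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty string", call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L)
    stop("invalid character(s) ", paste(sQuote(bad), collapse = ", "),
         " in ", what, " ", sQuote(seq),
         " (only the 20 canonical amino-acid letters are accepted)",
         call. = FALSE)
  invisible(chars)
}

#' @keywords internal
#' @noRd
sequence_is_canonical <- function(seqs) {
  !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"), seqs) &
    nzchar(seqs) & !is.na(seqs)
}

#' Construct a validated table of peptide records
#'
#' A peptide record is one labeled peptide: the unit flowing through
#' curation, featurization and modeling. Records are stored as rows of a
#' plain `data.frame` with columns `id`, `sequence`, `label`,
#' `organism_class` and `evidence_count`.
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Uppercase peptide sequences over the 20 canonical letters.
#' @param label One of `"epitope"`, `"non_epitope"`, `"unknown"` (recycled).
#' @param organism_class A class from [taxonomy_vocabulary()] or `"unknown"`
#'   (recycled).
#' @param evidence_count Non-negative integer count of distinct confirming
#'   assays (recycled).
#' @param vocab Taxonomy vocabulary used to validate `organism_class`.
#' @return A `data.frame` of class `peptide_records`.
#' @examples
#' peptide_records("p1", "ACDEFG", label = "epitope", evidence_count = 2)
#' @export
peptide_records <- function(id, sequence, label = "unknown",
                            organism_class = "unknown", evidence_count = 0L,
                            vocab = taxonomy_vocabulary()) {
  n <- length(sequence)
  stopifnot(length(id) == n)
  sequence <- toupper(as.character(sequence))
  ok <- sequence_is_canonical(sequence)
  if (any(!ok))
    stop("non-canonical sequence(s) at row(s) ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  label <- rep_len(as.character(label), n)
  if (!all(label %in% VALID_LABELS))
    stop("labels must be one of ", paste(VALID_LABELS, collapse = ", "),
         call. = FALSE)
  organism_class <- rep_len(as.character(organism_class), n)
  bad_org <- setdiff(unique(organism_class), c(vocab$class, "unknown"))
  if (length(bad_org) > 0L)
    stop("organism class(es) not in the taxonomy vocabulary: ",
         paste(sQuote(bad_org), collapse = ", "), call. = FALSE)
  evidence_count <- rep_len(as.integer(evidence_count), n)
  if (any(is.na(evidence_count)) || any(evidence_count < 0L))
    stop("evidence_count must be a non-negative integer", call. = FALSE)
  out <- data.frame(id = as.character(id), sequence = sequence,
                    label = label, organism_class = organism_class,
                    evidence_count = evidence_count,
                    stringsAsFactors = FALSE)
  class(out) <- c("peptide_records", "data.frame")
  out
}

#' @keywords internal
#' @noRd
as_peptide_records <- function(df) {
  peptide_records(df$id, df$sequence, df$label, df$organism_class,
                  df$evidence_count)
}

#' @export
print.peptide_records <- function(x, ...) {
  cat(sprintf("<peptide_records> %d record(s): %d epitope, %d non_epitope, %d unknown\n",
              nrow(x), sum(x$label == "epitope"),
              sum(x$label == "non_epitope"), sum(x$label == "unknown")))
  NextMethod()
}

# evaluate expr under a temporary RNG state so callers' streams are untouched
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
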