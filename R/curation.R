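#' Curation configuration
#'
#' Parameters of the five-step benchmark curation procedure: keep peptides
#' confirmed by at least `min_evidence` distinct assays, with length in
#' `[min_length, max_length]` (both inclusive; essentially all linear
#' epitopes fall in 6..25), drop sequences observed in both classes,
#' optionally require organism metadata, remove sequence redundancy at a
#' global-identity threshold, and split train/test preserving the class
#' ratio.
#'
#' @param min_evidence Minimum number of distinct confirming assays
#'   (default 2, the "two or more assays" rule).
#' @param min_length,max_length Inclusive length bounds (defaults 6 and 25).
#' @param similarity_threshold Identity threshold in (0, 1] for redundancy
#'   removal (default 0.95; 0.90/0.80/0.70 probe stricter de-homologizing).
#' @param require_organism Drop records with `organism_class = "unknown"`
#'   (default `TRUE`).
#' @param test_fraction Fraction held out as blind test (default 0.20).
#' @param seed Integer seed for the stratified split.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(min_evidence = 2L, min_length = 6L,
                            max_length = 25L, similarity_threshold = 0.95,
                            require_organism = TRUE, test_fraction = 0.20,
                            seed = 1L) {
  stopifnot(min_length <= max_length,
            similarity_threshold > 0, similarity_threshold <= 1,
            test_fraction > 0, test_fraction < 1,
            min_evidence >= 0)
  structure(list(min_evidence = as.integer(min_evidence),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 similarity_threshold = similarity_threshold,
                 require_organism = isTRUE(require_organism),
                 test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "curation_config")
}

#' Keep records confirmed by enough assays
#'
#' Inclusive threshold: `evidence_count >= min_evidence`. Order preserved.
#'
#' @param records A `peptide_records` data frame.
#' @param min_evidence Minimum assay count.
#' @return Filtered records.
#' @export
filter_evidence <- function(records, min_evidence = 2L) {
  records[records$evidence_count >= min_evidence, , drop = FALSE]
}

#' Keep records within a length window
#'
#' Both bounds inclusive.
#'
#' @inheritParams filter_evidence
#' @param min_length,max_length Inclusive bounds on sequence length.
#' @return Filtered records.
#' @export
filter_length <- function(records, min_length = 6L, max_length = 25L) {
  len <- nchar(records$sequence)
  records[len >= min_length & len <= max_length, , drop = FALSE]
}

#' Remove sequences present in both classes
#'
#' A sequence string labeled both `epitope` and `non_epitope` is
#' contradictory evidence; every record carrying such a sequence is
#' removed. Duplicates within one class are untouched (that is the
#' redundancy step's job).
#'
#' @inheritParams filter_evidence
#' @return Filtered records; the number of conflicting sequence strings is
#'   attached as attribute `"removed_dual_class"`.
#' @export
remove_dual_class <- function(records) {
  epi <- unique(records$sequence[records$label == "epitope"])
  non <- unique(records$sequence[records$label == "non_epitope"])
  dual <- intersect(epi, non)
  out <- records[!(records$sequence %in% dual), , drop = FALSE]
  attr(out, "removed_dual_class") <- length(dual)
  out
}

#' Keep records with organism metadata
#'
#' @inheritParams filter_evidence
#' @return Records whose `organism_class` is not `"unknown"`.
#' @export
filter_organism <- function(records) {
  records[records$organism_class != "unknown", , drop = FALSE]
}

# identity between two sequences: matches / alignment length under global
# (end-gap-penalized) alignment; equal lengths reduce to Hamming matches/L
#' @keywords internal
#' @noRd
pair_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    return(sum(ca == cb) / length(ca))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = identity_submat(), gapOpening = 0, gapExtension = 1)
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / alen
}

#' @keywords internal
#' @noRd
identity_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
      diag(m) <- 1
      cache <<- m
    }
    cache
  }
})

#' Greedy redundancy removal at an identity threshold
#'
#' CD-HIT-like greedy clustering, run independently within each class
#' label: sequences are visited by (length descending, then
#' lexicographically, then input order); each joins the first existing
#' cluster whose representative has global pairwise identity at or above
#' the threshold, else founds a new cluster. One representative (the
#' longest, first-seen member) is kept per cluster. Identity is matches /
#' alignment length under end-gap-penalized global alignment, which for
#' equal-length sequences is the Hamming match fraction. Deterministic.
#'
#' @inheritParams filter_evidence
#' @param similarity_threshold Identity threshold in (0, 1].
#' @return Representative records in original input order, with attributes
#'   `"clusters_formed"` (integer) and `"engine"` (`"internal-greedy"`).
#' @export
remove_redundancy <- function(records, similarity_threshold = 0.95) {
  stopifnot(similarity_threshold > 0, similarity_threshold <= 1)
  keep_idx <- integer(0)
  n_clusters <- 0L
  for (lab in unique(records$label)) {
    pool <- which(records$label == lab)
    seqs <- records$sequence[pool]
    lens <- nchar(seqs)
    chars <- strsplit(seqs, "")
    # residue-composition vectors give an alignment-free upper bound on
    # matches (matches <= per-letter count overlap), pruning candidates
    comp <- t(vapply(chars, function(ch)
      tabulate(match(ch, AA_ALPHABET), 20L), integer(20)))
    ord <- order(-lens, seqs, seq_along(seqs))
    rep_idx <- integer(0)        # indices into the pool's local space
    for (j in ord) {
      L <- lens[j]
      assigned <- FALSE
      if (length(rep_idx) > 0L) {
        rl <- lens[rep_idx]
        # identity <= min lengths / max lengths: skip impossible lengths
        cand <- rep_idx[pmin(rl, L) / pmax(rl, L) >= similarity_threshold]
        if (length(cand) > 0L) {
          ub <- rowSums(pmin(comp[cand, , drop = FALSE],
                             rep(comp[j, ], each = length(cand))))
          cand <- cand[ub / pmax(lens[cand], L) >= similarity_threshold]
        }
        for (r in cand) {
          ident <- if (lens[r] == L)
            sum(chars[[r]] == chars[[j]]) / L
          else pair_identity(seqs[r], seqs[j])
          if (ident >= similarity_threshold) { assigned <- TRUE; break }
        }
      }
      if (!assigned) rep_idx <- c(rep_idx, j)
    }
    keep_idx <- c(keep_idx, pool[rep_idx])
    n_clusters <- n_clusters + length(rep_idx)
  }
  out <- records[sort(keep_idx), , drop = FALSE]
  attr(out, "clusters_formed") <- n_clusters
  attr(out, "engine") <- "internal-greedy"
  out
}

#' Stratified train/test split
#'
#' Randomly partitions records into train and test sets preserving the
#' per-class proportions to within one record per class; reproducible
#' under `seed`.
#'
#' @inheritParams filter_evidence
#' @param test_fraction Fraction of each class assigned to the test set.
#' @param seed Integer seed.
#' @return `list(train = , test = )` of `peptide_records`.
#' @export
stratified_split <- function(records, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  classes <- unique(records$label)
  test_rows <- integer(0)
  for (lab in classes) {
    rows <- which(records$label == lab)
    if (length(rows) < 2L)
      stop("cannot stratify: class ", sQuote(lab), " has fewer than 2 records",
           call. = FALSE)
    n_test <- max(1L, min(length(rows) - 1L,
                          round(length(rows) * test_fraction)))
    test_rows <- c(test_rows,
                   with_seed(seed + match(lab, classes),
                             sample(rows, n_test)))
  }
  list(train = records[-sort(test_rows), , drop = FALSE],
       test = records[sort(test_rows), , drop = FALSE])
}

#' Run the full curation pipeline
#'
#' Applies, in order: assay-evidence filter, length filter, dual-class
#' removal, organism requirement (if configured), redundancy removal, and
#' the stratified train/test split, recording survivor counts after each
#' step.
#'
#' @inheritParams filter_evidence
#' @param config A [curation_config()].
#' @return A list with `train`, `test` (both `peptide_records`) and
#'   `report`, a `curation_report` list with `counts_per_step` (named,
#'   non-increasing), `removed_dual_class` (conflicting sequence strings)
#'   and `clusters_formed`.
#' @export
curate <- function(records, config = curation_config()) {
  stopifnot(inherits(config, "curation_config"))
  counts <- c(input = nrow(records))
  r <- filter_evidence(records, config$min_evidence)
  counts["evidence"] <- nrow(r)
  r <- filter_length(r, config$min_length, config$max_length)
  counts["length"] <- nrow(r)
  r <- remove_dual_class(r)
  removed_dual <- attr(r, "removed_dual_class")
  counts["dual_class"] <- nrow(r)
  if (config$require_organism) r <- filter_organism(r)
  counts["organism"] <- nrow(r)
  r <- remove_redundancy(r, config$similarity_threshold)
  clusters <- attr(r, "clusters_formed")
  counts["redundancy"] <- nrow(r)
  report <- structure(list(counts_per_step = counts,
                           removed_dual_class = removed_dual,
                           clusters_formed = clusters,
                           engine = attr(r, "engine"),
                           config = unclass(config)),
                      class = "curation_report")
  if (nrow(r) == 0L)
    return(list(train = r, test = r, report = report))
  split <- stratified_split(r, config$test_fraction, config$seed)
  list(train = split$train, test = split$test, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n")
  cat("  survivors per step:",
      paste(names(x$counts_per_step), x$counts_per_step, sep = "=",
            collapse = " "), "\n")
  cat("  dual-class sequences removed:", x$removed_dual_class, "\n")
  cat("  clusters formed:", x$clusters_formed,
      sprintf("(engine: %s)\n", x$engine))
  invisible(x)
}
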