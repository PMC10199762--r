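#' Read peptides from a FASTA file
#'
#' Parses a (multi-line) FASTA file into peptide records. The header
#' convention `>id|organism_class` carries optional organism metadata;
#' a bare `>id` header yields `organism_class = "unknown"`. Labels are
#' always `"unknown"` (FASTA carries no assay information). Records whose
#' sequence contains ambiguity codes (B, J, O, U, X, Z) or any other
#' non-canonical character are excluded with a diagnostic naming them,
#' because every descriptor table is defined only over the 20 canonical
#' letters.
#'
#' @param path Path to a FASTA file.
#' @param vocab Taxonomy vocabulary for validating header-encoded classes.
#' @return A `peptide_records` data frame.
#' @export
read_fasta <- function(path, vocab = taxonomy_vocabulary()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L)
    stop("empty FASTA input: ", path, call. = FALSE)
  first <- nonempty[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA at line ", first,
         ": expected a '>' header, got ", sQuote(lines[first]),
         call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    stop("empty FASTA input: ", path, call. = FALSE)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  ids <- sub("\\|.*$", "", headers)
  orgs <- ifelse(grepl("\\|", headers), sub("^[^|]*\\|", "", headers),
                 "unknown")
  ok <- sequence_is_canonical(seqs)
  if (any(!ok)) {
    for (i in which(!ok)) {
      bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), AA_ALPHABET)
      warning("excluding record ", sQuote(ids[i]),
              ": non-canonical character(s) ",
              paste(sQuote(bad), collapse = ", "), call. = FALSE)
    }
    if (!any(ok)) stop("no canonical sequences in ", path, call. = FALSE)
  }
  peptide_records(ids[ok], seqs[ok], organism_class = orgs[ok],
                  vocab = vocab)
}

#' Write peptide records to FASTA
#'
#' Headers follow the `id|organism_class` convention used by
#' [read_fasta()]; records with `organism_class = "unknown"` get a bare id.
#'
#' @param records A `peptide_records` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- ifelse(records$organism_class == "unknown", records$id,
                    paste0(records$id, "|", records$organism_class))
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a labeled peptide table (IEDB-style export)
#'
#' Reads a delimited table of labeled peptides. The default dialect expects
#' columns `sequence`, `label`, `organism`, `assays`; a column-name map
#' adapts other export headers. Labels are normalized case-insensitively
#' (`positive`/`epitope` and `negative`/`non-epitope`/`non_epitope` are
#' accepted). Every row is either accepted or reported: rows with
#' non-canonical sequences or invalid labels are dropped with a warning
#' naming the row numbers; organisms outside the taxonomy vocabulary are
#' mapped to `"unknown"` with a warning count.
#'
#' @param path Path to a TSV (default for `.tsv`/`.txt`) or CSV file.
#' @param dialect Named character vector mapping the roles `sequence`,
#'   `label`, `organism`, `assays` to column names in the file. `organism`
#'   and `assays` columns are optional.
#' @param vocab Taxonomy vocabulary.
#' @return A `peptide_records` data frame. Row diagnostics are attached as
#'   attribute `"diagnostics"` (a character vector, possibly empty).
#' @export
read_peptide_table <- function(path,
                               dialect = c(sequence = "sequence",
                                           label = "label",
                                           organism = "organism",
                                           assays = "assays"),
                               vocab = taxonomy_vocabulary()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  for (role in c("sequence", "label")) {
    if (!dialect[[role]] %in% names(df))
      stop("missing mandatory column ", sQuote(dialect[[role]]),
           " (role: ", role, ") in ", path, call. = FALSE)
  }
  n <- nrow(df)
  seqs <- toupper(as.character(df[[dialect[["sequence"]]]]))
  labels <- normalize_labels(as.character(df[[dialect[["label"]]]]))
  orgs <- if (!is.na(dialect["organism"]) && dialect[["organism"]] %in% names(df))
    as.character(df[[dialect[["organism"]]]]) else rep("unknown", n)
  assays <- if (!is.na(dialect["assays"]) && dialect[["assays"]] %in% names(df))
    suppressWarnings(as.integer(df[[dialect[["assays"]]]])) else rep(0L, n)

  diagnostics <- character(0)
  bad_seq <- !sequence_is_canonical(seqs)
  if (any(bad_seq))
    diagnostics <- c(diagnostics,
                     paste0("row ", which(bad_seq), ": non-canonical sequence ",
                            sQuote(seqs[bad_seq])))
  bad_lab <- is.na(labels)
  if (any(bad_lab))
    diagnostics <- c(diagnostics,
                     paste0("row ", which(bad_lab), ": unrecognized label"))
  bad_ass <- is.na(assays) | assays < 0L
  if (any(bad_ass))
    diagnostics <- c(diagnostics,
                     paste0("row ", which(bad_ass),
                            ": invalid assay count, set to 0"))
  assays[bad_ass] <- 0L

  unknown_org <- !(orgs %in% c(vocab$class, "unknown"))
  if (any(unknown_org)) {
    warning(sum(unknown_org), " organism name(s) outside the taxonomy ",
            "vocabulary mapped to \"unknown\" (e.g. ",
            sQuote(orgs[which(unknown_org)[1L]]), ")", call. = FALSE)
    orgs[unknown_org] <- "unknown"
  }

  keep <- !bad_seq & !bad_lab
  if (length(diagnostics) > 0L)
    warning("dropped or repaired ", sum(!keep), " row(s); see ",
            "attr(, \"diagnostics\")", call. = FALSE)
  ids <- if ("id" %in% names(df)) as.character(df$id) else
    sprintf("pep%05d", seq_len(n))
  out <- peptide_records(ids[keep], seqs[keep], labels[keep], orgs[keep],
                         assays[keep], vocab = vocab)
  attr(out, "diagnostics") <- diagnostics
  out
}

#' @keywords internal
#' @noRd
normalize_labels <- function(x) {
  x <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("epitope", "positive", "pos", "1", "true")] <- "epitope"
  out[x %in% c("non_epitope", "non-epitope", "negative", "neg", "0",
               "false")] <- "non_epitope"
  out[x == "unknown"] <- "unknown"
  out
}

#' Write peptide records as a TSV table
#'
#' Columns `id`, `sequence`, `label`, `organism`, `assays` — the default
#' dialect of [read_peptide_table()], so write/read round trips.
#'
#' @param records A `peptide_records` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  df <- data.frame(id = records$id, sequence = records$sequence,
                   label = records$label, organism = records$organism_class,
                   assays = records$evidence_count)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a feature matrix as CSV
#'
#' CSV with a leading `id` column and one column per feature. The round
#' trip is lossless on ids and feature names and accurate to better than
#' 1e-12 on values (values are printed with 17 significant digits).
#'
#' @param m Numeric matrix with row names (peptide ids) and unique column
#'   names (feature names).
#' @param path Output path.
#' @return `path` invisibly for the writer; the matrix for the reader.
#' @export
write_feature_matrix <- function(m, path) {
  stopifnot(is.matrix(m), is.numeric(m) || ncol(m) == 0L)
  if (anyDuplicated(colnames(m)))
    stop("duplicate feature name(s): ",
         paste(sQuote(unique(colnames(m)[duplicated(colnames(m))])),
               collapse = ", "), call. = FALSE)
  header <- paste(c("id", colnames(m)), collapse = ",")
  body <- if (nrow(m) > 0L) {
    vals <- apply(m, 1L, function(r) paste(format(r, digits = 17,
                                                  scientific = TRUE,
                                                  trim = TRUE),
                                           collapse = ","))
    if (ncol(m) == 0L) rownames(m) else paste(rownames(m), vals, sep = ",")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param path Path to a CSV written by [write_feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "id")
    stop("feature matrix file must have a leading 'id' column", call. = FALSE)
  if (anyDuplicated(names(df)[-1L]))
    stop("duplicate feature name(s) in ", path, call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df$id)
  m
}

#' Save / load a trained model bundle
#'
#' Bundles (see [train_model()]) are serialized as versioned RDS files.
#'
#' @param bundle A `model_bundle`.
#' @param path Output path.
#' @return `path` invisibly for the writer; the bundle for the reader.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  saveRDS(list(format_version = 1L, bundle = bundle), path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format_version) ||
      !inherits(obj$bundle, "model_bundle"))
    stop("not a model bundle file: ", path, call. = FALSE)
  obj$bundle
}
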