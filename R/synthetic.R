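#' Specification for synthetic IEDB-like peptide tables
#'
#' The generator emulates the structure of a curated linear-epitope
#' export: peptides of length 6-25, an epitope:non-epitope ratio of 1:6,
#' organism classes drawn from the 20-class taxonomy vocabulary, assay
#' evidence counts that include values below the 2-assay curation
#' threshold, and an optional planted sequence signal — a 3-mer motif
#' inserted into epitopes at a controlled rate — that separates the two
#' classes. With a uniform background each of the 8000 triplets appears
#' by chance at rate 1/8000, so a motif planted at rate near 1 is
#' strongly overrepresented among epitopes and the fitted AAT scale must
#' score it positively.
#'
#' @param n_epitopes,n_non_epitopes Class sizes (defaults 300 and 1800,
#'   the 1:6 imbalance of real curated sets).
#' @param min_length,max_length Length range (defaults 6 and 25).
#' @param motif Planted 3-mer (default `"YWC"`); `NULL` disables planting.
#' @param motif_rate Probability an epitope carries the motif
#'   (default 0.9).
#' @param background Residue sampling weights (default uniform over the
#'   20 letters, which makes the planted-signal arithmetic exact).
#' @param organism_bias Optional named vector of per-class epitope
#'   sampling weights; default uniform organism assignment.
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_epitopes = 300L, n_non_epitopes = 1800L,
                           min_length = 6L, max_length = 25L,
                           motif = "YWC", motif_rate = 0.9,
                           background = NULL, organism_bias = NULL,
                           seed = 1L) {
  stopifnot(n_epitopes >= 1, n_non_epitopes >= 1,
            min_length >= 3, min_length <= max_length,
            motif_rate >= 0, motif_rate <= 1)
  if (!is.null(motif)) {
    if (nchar(motif) != 3L)
      stop("motif must be a 3-letter triplet", call. = FALSE)
    check_sequence(motif, "motif")
    if (nchar(motif) > min_length)
      stop("motif longer than the minimum peptide length", call. = FALSE)
  }
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  stopifnot(all(AA_ALPHABET %in% names(background)), all(background >= 0))
  structure(list(n_epitopes = as.integer(n_epitopes),
                 n_non_epitopes = as.integer(n_non_epitopes),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 motif = motif, motif_rate = motif_rate,
                 background = background[AA_ALPHABET],
                 organism_bias = organism_bias,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic labeled peptide table
#'
#' Reproducible under the spec's seed: the same spec yields a
#' byte-identical table. Epitopes carry the planted motif (overwriting a
#' random window) with probability `motif_rate`; non-epitopes are pure
#' background, so the motif occurs in them only at its chance rate.
#' Evidence counts are drawn from \{0..4\} with mass on values below 2 so
#' the assay-evidence filter is exercised.
#'
#' @param spec A [synthetic_spec()].
#' @return A `peptide_records` data frame of
#'   `n_epitopes + n_non_epitopes` rows.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  vocab <- taxonomy_vocabulary()
  n <- spec$n_epitopes + spec$n_non_epitopes
  with_seed(spec$seed, {
    lens <- sample(spec$min_length:spec$max_length, n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE,
                   prob = spec$background), collapse = ""),
      character(1))
    is_epi <- seq_len(n) <= spec$n_epitopes
    if (!is.null(spec$motif)) {
      plant <- is_epi & stats::runif(n) < spec$motif_rate
      for (i in which(plant)) {
        at <- sample.int(lens[i] - 2L, 1L)
        substr(seqs[i], at, at + 2L) <- spec$motif
      }
    }
    org_prob <- NULL
    if (!is.null(spec$organism_bias))
      org_prob <- spec$organism_bias[vocab$class]
    orgs <- sample(vocab$class, n, replace = TRUE, prob = org_prob)
    evid <- sample(0:4, n, replace = TRUE,
                   prob = c(0.15, 0.2, 0.3, 0.2, 0.15))
    peptide_records(sprintf("pep%05d", seq_len(n)), seqs,
                    ifelse(is_epi, "epitope", "non_epitope"),
                    orgs, evid)
  })
}

#' Generate a table with injected dual-class conflicts
#'
#' Appends `k` freshly generated sequences, disjoint from the base table,
#' each present twice — once as an epitope and once as a non-epitope, with
#' maximal evidence and in-range lengths — so the curation dual-class
#' filter must remove exactly `2k` records (`k` sequence strings).
#'
#' @param spec A [synthetic_spec()] for the clean base.
#' @param k Number of conflicting sequences to inject.
#' @return A `peptide_records` data frame of the base plus `2k` rows.
#' @export
generate_conflicts <- function(spec = synthetic_spec(), k = 1L) {
  stopifnot(k >= 0L)
  base <- generate_synthetic(spec)
  if (k == 0L) return(base)
  conflicts <- character(0)
  with_seed(spec$seed + 7919L, {
    while (length(conflicts) < k) {
      L <- sample(spec$min_length:spec$max_length, 1L)
      s <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
      if (!s %in% c(base$sequence, conflicts))
        conflicts <- c(conflicts, s)
    }
  })
  extra <- peptide_records(
    sprintf("conflict%03d_%s", rep(seq_len(k), each = 2L),
            rep(c("epi", "non"), k)),
    rep(conflicts, each = 2L),
    rep(c("epitope", "non_epitope"), k),
    organism_class = base$organism_class[1L],
    evidence_count = max(base$evidence_count))
  out <- rbind(base, extra)
  class(out) <- c("peptide_records", "data.frame")
  out
}
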