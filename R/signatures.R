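#' Residue labeling schemes for graph-based signatures
#'
#' A labeling scheme maps each of the 20 canonical residues to a
#' categorical node label. Two kinds exist: `categorical` schemes (a fixed
#' class table, e.g. the five physicochemical classes) and `scale_binary`
#' schemes, which binarize a continuous per-residue propensity scale into
#' `High`/`Low` at a threshold. Labels are kept in alphabetical order;
#' that order canonicalizes unordered pair names.
#'
#' @param name Scheme name (used in feature-name suffixes).
#' @param assign Named character vector: one label per canonical residue.
#' @param kind `"categorical"` or `"scale_binary"`.
#' @param suffix_names Whether feature names carry a `~name` suffix. Scale
#'   schemes always do (their `High`/`Low` labels are not self-describing);
#'   the physicochemical scheme does not, giving the bare names such as
#'   `Apolar:Aromatic-8`.
#' @return A list of class `labeling_scheme` with elements `name`, `kind`,
#'   `assign`, `labels` (sorted), `suffix_names`.
#' @export
labeling_scheme <- function(name, assign, kind = "categorical",
                            suffix_names = kind != "categorical") {
  stopifnot(kind %in% c("categorical", "scale_binary"))
  missing <- setdiff(AA_ALPHABET, names(assign))
  if (length(missing) > 0L)
    stop("labeling scheme ", sQuote(name), " is not total: no label for ",
         paste(missing, collapse = ", "), call. = FALSE)
  assign <- assign[AA_ALPHABET]
  structure(list(name = name, kind = kind, assign = assign,
                 labels = sort(unique(unname(assign))),
                 suffix_names = isTRUE(suffix_names)),
            class = "labeling_scheme")
}

#' Five-class physicochemical labeling scheme
#'
#' Apolar \{A,G,I,L,M,P,V\}, Aromatic \{F,W,Y\}, PolarNeutral \{C,N,Q,S,T\},
#' Acidic \{D,E\}, Basic \{H,K,R\} — the standard pharmacophore-style
#' classing. Signature names from this scheme are bare
#' (`Apolar:Aromatic-8`).
#'
#' @return A `labeling_scheme`.
#' @export
scheme_physchem <- function() {
  classes <- list(Apolar = c("A", "G", "I", "L", "M", "P", "V"),
                  Aromatic = c("F", "W", "Y"),
                  PolarNeutral = c("C", "N", "Q", "S", "T"),
                  Acidic = c("D", "E"),
                  Basic = c("H", "K", "R"))
  assign <- unlist(lapply(names(classes), function(cl)
    stats::setNames(rep(cl, length(classes[[cl]])), classes[[cl]])))
  labeling_scheme("physchem", assign, kind = "categorical")
}

#' Binary High/Low scheme from a propensity scale
#'
#' Residues with scale value strictly above the threshold are labeled
#' `High`, others `Low`. The default threshold is the unweighted mean of
#' the 20 per-residue values, a parameter-free midpoint.
#'
#' @param scale_name One of the packaged propensity scales (see
#'   [propensity_scales()]) or a custom named numeric vector via `values`.
#' @param threshold Binarization threshold; default mean of the values.
#' @param values Optional custom per-residue values overriding the packaged
#'   scale.
#' @return A `labeling_scheme` of kind `scale_binary`.
#' @export
scheme_scale_binary <- function(scale_name, threshold = NULL, values = NULL) {
  vals <- if (is.null(values)) get_propensity_scale(scale_name) else values
  missing <- setdiff(AA_ALPHABET, names(vals))
  if (length(missing) > 0L)
    stop("scale is missing residues ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(threshold)) threshold <- mean(vals[AA_ALPHABET])
  assign <- ifelse(vals[AA_ALPHABET] > threshold, "High", "Low")
  names(assign) <- AA_ALPHABET
  sch <- labeling_scheme(scale_name, assign, kind = "scale_binary")
  sch$threshold <- threshold
  sch
}

#' Assign node labels to a sequence
#'
#' @param sequence Canonical peptide sequence.
#' @param scheme A [labeling_scheme()].
#' @return Character vector of per-residue labels.
#' @examples
#' assign_labels("AFD", scheme_physchem())  # Apolar Aromatic Acidic
#' @export
assign_labels <- function(sequence, scheme) {
  chars <- check_sequence(sequence)
  unname(scheme$assign[chars])
}

#' @keywords internal
#' @noRd
canonical_pairs <- function(labels) {
  k <- length(labels)
  idx <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  paste(labels[idx[, "row"]], labels[idx[, "col"]], sep = ":")
}

#' Count labeled residue pairs at one sequence distance
#'
#' Counts pairs of positions `(i, i + d)` binned by their unordered label
#' pair. Every unordered pair of scheme labels gets an entry (zeros
#' included); `d >= length(sequence)` yields the all-zero map.
#'
#' @param labels Per-residue labels from [assign_labels()].
#' @param d Sequence distance (>= 1).
#' @param all_labels Ordered label set of the scheme (defines key order).
#' @return Named integer vector over unordered label pairs `"A:B"` with
#'   `A <= B` in label order.
#' @export
pair_counts <- function(labels, d, all_labels = sort(unique(labels))) {
  stopifnot(d >= 1)
  keys <- canonical_pairs(all_labels)
  out <- stats::setNames(integer(length(keys)), keys)
  L <- length(labels)
  if (d <= L - 1) {
    a <- labels[seq_len(L - d)]
    b <- labels[seq_len(L - d) + d]
    lo <- pmin(match(a, all_labels), match(b, all_labels))
    hi <- pmax(match(a, all_labels), match(b, all_labels))
    tab <- table(paste(all_labels[lo], all_labels[hi], sep = ":"))
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Signature configuration
#'
#' @param schemes List of [labeling_scheme()]s. Default: the
#'   physicochemical scheme plus the Parker hydrophilicity binary scheme —
#'   the two labelings with the strongest standing in linear-epitope work.
#' @param cutoffs Strictly increasing positive integer sequence distances.
#'   Default `1:24`: with peptides up to 25 residues the largest possible
#'   separation is 24, and full coverage is cheap at peptide scale.
#' @param mode `"cumulative"` (counts of pairs at distance <= d; the
#'   default vectorization), `"non_cumulative"` (pairs at exactly d) or
#'   `"both"`.
#' @return A list of class `signature_config`.
#' @export
signature_config <- function(schemes = list(scheme_physchem(),
                                            scheme_scale_binary("parker")),
                             cutoffs = 1:24,
                             mode = c("cumulative", "non_cumulative",
                                      "both")) {
  mode <- match.arg(mode)
  stopifnot(length(cutoffs) > 0, all(cutoffs >= 1),
            all(diff(cutoffs) > 0))
  for (s in schemes) stopifnot(inherits(s, "labeling_scheme"))
  structure(list(schemes = schemes, cutoffs = as.integer(cutoffs),
                 mode = mode),
            class = "signature_config")
}

#' @keywords internal
#' @noRd
signature_names_one <- function(scheme, cutoffs, mode_suffix = "") {
  keys <- canonical_pairs(scheme$labels)
  suffix <- if (scheme$suffix_names) paste0("~", scheme$name) else ""
  as.vector(t(outer(cutoffs, keys, function(d, k)
    paste0(k, "-", d, suffix, mode_suffix))))
}

#' Graph-based sequence signature of a peptide
#'
#' The signature models a peptide as a sequence graph: residues are nodes
#' carrying scheme labels, and each distance cutoff d induces edges between
#' residues separated by (up to) d positions. The feature vector counts
#' edges per unordered label pair at each cutoff — cumulative (distance
#' <= d) by default, non-cumulative (distance exactly d) optionally.
#' Feature names follow the grammar `LabelA:LabelB-d[~scheme][~nc]` with
#' `LabelA <= LabelB` in label order, e.g. `Apolar:Aromatic-8`.
#'
#' @param sequence Canonical peptide sequence, length >= 2.
#' @param config A [signature_config()].
#' @return Named numeric vector; order fixed by the config (schemes, then
#'   cutoffs within scheme, pairs within cutoff; for mode `"both"` the
#'   cumulative block precedes the non-cumulative block per scheme).
#' @export
signature <- function(sequence, config = signature_config()) {
  stopifnot(inherits(config, "signature_config"))
  if (nchar(sequence) < 2L)
    stop("sequence must have length >= 2 to form pairs", call. = FALSE)
  out <- numeric(0)
  for (scheme in config$schemes) {
    labels <- assign_labels(sequence, scheme)
    per_d <- vapply(seq_len(max(config$cutoffs)),
                    function(d) pair_counts(labels, d, scheme$labels),
                    numeric(length(canonical_pairs(scheme$labels))))
    per_d <- matrix(per_d, ncol = max(config$cutoffs))  # pairs x d
    cum <- per_d
    if (ncol(cum) > 1L)
      for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1L] + per_d[, j]
    if (config$mode %in% c("cumulative", "both")) {
      v <- as.vector(cum[, config$cutoffs, drop = FALSE])
      names(v) <- signature_names_one(scheme, config$cutoffs)
      out <- c(out, v)
    }
    if (config$mode %in% c("non_cumulative", "both")) {
      suffix <- if (config$mode == "both") "~nc" else ""
      v <- as.vector(per_d[, config$cutoffs, drop = FALSE])
      names(v) <- signature_names_one(scheme, config$cutoffs, suffix)
      out <- c(out, v)
    }
  }
  out
}
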