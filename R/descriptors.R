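#' Per-residue propensity scales
#'
#' The four classic linear-epitope propensity scales: Parker
#' hydrophilicity, Chou-Fasman beta-turn propensity, Emini surface
#' accessibility and Kolaskar-Tongaonkar antigenicity. Values are the
#' published per-residue constants; peptides are short, so no window
#' smoothing is applied anywhere in the package. CSV copies ship under
#' `inst/extdata/` for reference and external reuse.
#'
#' @return Named list of four named numeric vectors (one value per
#'   canonical residue).
#' @export
propensity_scales <- function() {
  list(
    parker = c(A = 2.1, C = 1.4, D = 10.0, E = 7.8, F = -9.2, G = 5.7,
               H = 2.1, I = -8.0, K = 5.7, L = -9.2, M = -4.2, N = 7.0,
               P = 2.1, Q = 6.0, R = 4.2, S = 6.5, T = 5.2, V = -3.7,
               W = -10.0, Y = -1.9),
    chou_fasman_turn = c(A = 0.66, C = 1.19, D = 1.46, E = 0.74, F = 0.60,
                         G = 1.56, H = 0.95, I = 0.47, K = 1.01, L = 0.59,
                         M = 0.60, N = 1.56, P = 1.52, Q = 0.98, R = 0.95,
                         S = 1.43, T = 0.96, V = 0.50, W = 0.96, Y = 1.14),
    emini = c(A = 0.49, C = 0.26, D = 0.81, E = 0.84, F = 0.42, G = 0.48,
              H = 0.66, I = 0.34, K = 0.97, L = 0.40, M = 0.48, N = 0.78,
              P = 0.75, Q = 0.84, R = 0.95, S = 0.65, T = 0.70, V = 0.36,
              W = 0.51, Y = 0.76),
    kolaskar = c(A = 1.064, C = 1.412, D = 0.866, E = 0.851, F = 1.091,
                 G = 0.874, H = 1.105, I = 1.152, K = 0.930, L = 1.250,
                 M = 0.826, N = 0.776, P = 1.064, Q = 1.015, R = 0.873,
                 S = 1.012, T = 0.909, V = 1.383, W = 0.893, Y = 1.161)
  )
}

#' @keywords internal
#' @noRd
get_propensity_scale <- function(name) {
  scales <- propensity_scales()
  if (!name %in% names(scales))
    stop("unknown scale ", sQuote(name), "; available: ",
         paste(names(scales), collapse = ", "), call. = FALSE)
  scales[[name]]
}

#' @keywords internal
#' @noRd
overlapping_triplets <- function(sequence) {
  L <- nchar(sequence)
  if (L < 3L) return(character(0))
  substring(sequence, 1:(L - 2L), 3:L)
}

#' Fit an amino-acid-triplet (AAT) antigenicity-ratio scale
#'
#' Scores every observed 3-mer by how overrepresented it is among epitopes
#' relative to non-epitopes. With overlapping triplet counts `c_e(t)`,
#' `c_n(t)` and class totals `N_e`, `N_n`, the score is the
#' frequency-normalized log-odds with additive pseudocount `p`:
#'
#' \deqn{s(t) = \ln\frac{c_e(t)+p}{c_n(t)+p} +
#'       \ln\frac{N_n + 8000p}{N_e + 8000p}}
#'
#' (8000 = number of possible triplets). Swapping the two classes negates
#' every score; identical classes give all-zero scores; scores shrink to 0
#' as `p` grows. Sequences shorter than 3 are skipped with a warning.
#'
#' @param epitope_seqs,non_epitope_seqs Character vectors of peptide
#'   sequences for the two classes (both non-empty).
#' @param pseudocount Positive additive pseudocount (default 1).
#' @return An object of class `aat_scale`: list with `scores` (named
#'   numeric over observed triplets), `pseudocount`, `default_score` (0,
#'   used for triplets unseen at fit time), and `fingerprint` (identifies
#'   the fitting data, for train/test hygiene checks).
#' @examples
#' sc <- fit_aat_scale("AAAA", "CCCC")
#' sc$scores[["AAA"]]  # log(3)
#' @export
fit_aat_scale <- function(epitope_seqs, non_epitope_seqs, pseudocount = 1) {
  stopifnot(length(epitope_seqs) > 0, length(non_epitope_seqs) > 0,
            pseudocount > 0)
  count_class <- function(seqs, what) {
    short <- nchar(seqs) < 3L
    if (any(short))
      warning("skipping ", sum(short), " ", what,
              " sequence(s) shorter than 3", call. = FALSE)
    trips <- unlist(lapply(seqs[!short], overlapping_triplets))
    table(trips)
  }
  tab_e <- count_class(epitope_seqs, "epitope")
  tab_n <- count_class(non_epitope_seqs, "non-epitope")
  all_t <- sort(union(names(tab_e), names(tab_n)))
  c_e <- stats::setNames(numeric(length(all_t)), all_t)
  c_n <- c_e
  c_e[names(tab_e)] <- as.numeric(tab_e)
  c_n[names(tab_n)] <- as.numeric(tab_n)
  N_e <- sum(c_e); N_n <- sum(c_n)
  scores <- log((c_e + pseudocount) / (c_n + pseudocount)) +
    log((N_n + pseudocount * 8000) / (N_e + pseudocount * 8000))
  structure(list(scores = scores, pseudocount = pseudocount,
                 default_score = 0,
                 fingerprint = sprintf("aat:%d+%d:%d:%.10g",
                                       length(epitope_seqs),
                                       length(non_epitope_seqs),
                                       length(scores), sum(scores))),
            class = "aat_scale")
}

#' @export
print.aat_scale <- function(x, ...) {
  cat(sprintf("<aat_scale> %d triplets, pseudocount %g, scores in [%.3f, %.3f]\n",
              length(x$scores), x$pseudocount,
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Summarize a peptide against an AAT scale
#'
#' Evaluates every overlapping triplet of the peptide against the fitted
#' scale (unseen triplets take the scale's `default_score`) and returns
#' `AAT_max`, `AAT_min`, `AAT_sum` and `AAT_mean`. `AAT_max`/`AAT_min` are
#' the headline summaries; the cumulative-sum reading of the triplet
#' profile is exposed separately as `AAT_sum`.
#'
#' @param sequence Peptide sequence, length >= 3.
#' @param scale A fitted [fit_aat_scale()] object.
#' @return Named numeric vector of the four summaries.
#' @export
aat_features <- function(sequence, scale) {
  stopifnot(inherits(scale, "aat_scale"))
  if (nchar(sequence) < 3L)
    stop("sequence must have length >= 3 for triplet features", call. = FALSE)
  trips <- overlapping_triplets(sequence)
  vals <- scale$scores[trips]
  vals[is.na(vals)] <- scale$default_score
  c(AAT_max = max(vals), AAT_min = min(vals), AAT_sum = sum(vals),
    AAT_mean = mean(vals))
}

#' CTD three-group property tables
#'
#' Standard 3-group residue partitions for the composition/transition/
#' distribution descriptors: hydrophobicity, normalized van der Waals
#' volume, polarity, charge, secondary structure, solvent accessibility
#' (enabled by default) and polarizability (available). Each property
#' partitions the 20 residues into groups G1/G2/G3 with the conventional
#' group meanings recorded in `group_labels`.
#'
#' @param properties Which property tables to return.
#' @return Named list; each element has `groups` (list of 3 character
#'   vectors) and `group_labels`.
#' @export
ctd_groupings <- function(properties = c("hydrophobicity", "vdw_volume",
                                         "polarity", "charge",
                                         "secondary_structure",
                                         "solvent_accessibility")) {
  all <- list(
    hydrophobicity = list(
      groups = list(G1 = c("R", "K", "E", "D", "Q", "N"),
                    G2 = c("G", "A", "S", "T", "P", "H", "Y"),
                    G3 = c("C", "L", "V", "I", "M", "F", "W")),
      group_labels = c(G1 = "Polar", G2 = "Neutral", G3 = "Hydrophobic")),
    vdw_volume = list(
      groups = list(G1 = c("G", "A", "S", "T", "P", "D", "C"),
                    G2 = c("N", "V", "E", "Q", "I", "L"),
                    G3 = c("M", "H", "K", "F", "R", "Y", "W")),
      group_labels = c(G1 = "Small", G2 = "Medium", G3 = "Large")),
    polarity = list(
      groups = list(G1 = c("L", "I", "F", "W", "C", "M", "V", "Y"),
                    G2 = c("P", "A", "T", "G", "S"),
                    G3 = c("H", "Q", "R", "K", "N", "E", "D")),
      group_labels = c(G1 = "Low", G2 = "Medium", G3 = "High")),
    polarizability = list(
      groups = list(G1 = c("G", "A", "S", "D", "T"),
                    G2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),
                    G3 = c("K", "M", "H", "F", "R", "Y", "W")),
      group_labels = c(G1 = "Low", G2 = "Medium", G3 = "High")),
    charge = list(
      groups = list(G1 = c("K", "R"),
                    G2 = c("A", "N", "C", "Q", "G", "H", "I", "L", "M",
                           "F", "P", "S", "T", "W", "Y", "V"),
                    G3 = c("D", "E")),
      group_labels = c(G1 = "Positive", G2 = "Neutral", G3 = "Negative")),
    secondary_structure = list(
      groups = list(G1 = c("E", "A", "L", "M", "Q", "K", "R", "H"),
                    G2 = c("V", "I", "Y", "C", "W", "F", "T"),
                    G3 = c("G", "N", "P", "S", "D")),
      group_labels = c(G1 = "Helix", G2 = "Strand", G3 = "Coil")),
    solvent_accessibility = list(
      groups = list(G1 = c("A", "L", "F", "C", "G", "I", "V", "W"),
                    G2 = c("R", "K", "Q", "E", "N", "D"),
                    G3 = c("M", "P", "S", "T", "H", "Y")),
      group_labels = c(G1 = "Buried", G2 = "Exposed", G3 = "Intermediate"))
  )
  bad <- setdiff(properties, names(all))
  if (length(bad) > 0L)
    stop("unknown CTD property: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  all[properties]
}

#' Composition/Transition/Distribution descriptors
#'
#' Per property: Composition = fraction of residues in each of the 3
#' groups (`prop.G1` .. `prop.G3`); Transition = fraction of adjacent
#' residue pairs whose members fall in different groups, per unordered
#' group pair (`prop.T.G1G2`, `prop.T.G1G3`, `prop.T.G2G3`, denominator
#' L-1); Distribution = positions, as percent of sequence length, of the
#' first, 25%, 50%, 75% and last occurrence of each group
#' (`prop.D.G1.P0` .. `prop.D.G1.P100`; ceiling index, groups absent from
#' the sequence yield all-zero positions so the vector length is fixed).
#'
#' @param sequence Peptide sequence, length >= 2.
#' @param groupings Property tables from [ctd_groupings()].
#' @return Named numeric vector, 21 values per property.
#' @export
ctd_features <- function(sequence, groupings = ctd_groupings()) {
  chars <- check_sequence(sequence)
  L <- length(chars)
  if (L < 2L)
    stop("sequence must have length >= 2 for transition features",
         call. = FALSE)
  out <- numeric(0)
  for (prop in names(groupings)) {
    g <- groupings[[prop]]$groups
    grp <- integer(L)
    for (k in 1:3) grp[chars %in% g[[k]]] <- k
    comp <- tabulate(grp, 3L) / L
    names(comp) <- paste0(prop, ".G", 1:3)
    a <- grp[-L]; b <- grp[-1L]
    lo <- pmin(a, b); hi <- pmax(a, b)
    trans <- c(sum(lo == 1 & hi == 2), sum(lo == 1 & hi == 3),
               sum(lo == 2 & hi == 3)) / (L - 1)
    names(trans) <- paste0(prop, ".T.", c("G1G2", "G1G3", "G2G3"))
    dist <- numeric(15)
    names(dist) <- paste0(prop, ".D.G", rep(1:3, each = 5), ".P",
                          rep(c(0, 25, 50, 75, 100), 3))
    for (k in 1:3) {
      pos <- which(grp == k)
      if (length(pos) > 0L) {
        qidx <- pmax(1L, ceiling(c(1, 0.25, 0.5, 0.75, 1) *
                                   c(1, rep(length(pos), 4))))
        picks <- pos[c(1L, qidx[2:5])]
        dist[(k - 1) * 5 + 1:5] <- picks / L * 100
      }
    }
    out <- c(out, comp, trans, dist)
  }
  out
}

#' Summary statistics of a per-residue propensity profile
#'
#' Mean, max and min of the residue-wise values of one propensity scale
#' over a peptide (no window smoothing; peptides are short).
#'
#' @param sequence Canonical peptide sequence.
#' @param scale_name A scale from [propensity_scales()].
#' @return Named numeric vector `<scale>.mean`, `<scale>.max`,
#'   `<scale>.min`.
#' @export
scale_profile_features <- function(sequence, scale_name) {
  vals <- get_propensity_scale(scale_name)[check_sequence(sequence)]
  stats::setNames(c(mean(vals), max(vals), min(vals)),
                  paste0(scale_name, c(".mean", ".max", ".min")))
}

#' Build the full feature matrix for a set of peptides
#'
#' Concatenates the enabled feature groups in fixed order — graph-based
#' signatures, AAT summaries, CTD descriptors, propensity-profile
#' statistics, taxonomy one-hot — so the same configuration always yields
#' the same columns for any input set. Pure function of its inputs:
#' repeated calls are identical.
#'
#' @param records A `peptide_records` data frame.
#' @param aat_scale A fitted [fit_aat_scale()] (required when the `"aat"`
#'   group is enabled). Fit it on training data only; the scale's
#'   fingerprint is stamped on the matrix and checked again at prediction
#'   time.
#' @param sig_config A [signature_config()].
#' @param groups Feature groups to enable, in any order (output order is
#'   fixed regardless).
#' @param groupings CTD property tables.
#' @param profile_scales Scales for the profile-statistics group.
#' @param vocab Taxonomy vocabulary.
#' @return Numeric matrix, rows = peptides (rownames = ids), columns =
#'   features; attributes `"provenance"` (group of each column) and
#'   `"aat_fingerprint"` (when AAT is enabled).
#' @export
featurize <- function(records, aat_scale = NULL,
                      sig_config = signature_config(),
                      groups = c("signatures", "aat", "ctd", "profiles",
                                 "taxonomy"),
                      groupings = ctd_groupings(),
                      profile_scales = names(propensity_scales()),
                      vocab = taxonomy_vocabulary()) {
  groups <- match.arg(groups, c("signatures", "aat", "ctd", "profiles",
                                "taxonomy"), several.ok = TRUE)
  if ("aat" %in% groups && !inherits(aat_scale, "aat_scale"))
    stop("the \"aat\" feature group needs a fitted aat_scale ",
         "(fit on training data only)", call. = FALSE)
  featurize_one <- function(i) {
    seq <- records$sequence[i]
    v <- numeric(0)
    tryCatch({
      if ("signatures" %in% groups) v <- c(v, signature(seq, sig_config))
      if ("aat" %in% groups) v <- c(v, aat_features(seq, aat_scale))
      if ("ctd" %in% groups) v <- c(v, ctd_features(seq, groupings))
      if ("profiles" %in% groups)
        for (sn in profile_scales)
          v <- c(v, scale_profile_features(seq, sn))
      if ("taxonomy" %in% groups)
        v <- c(v, taxonomy_onehot(records$organism_class[i], vocab))
      v
    }, error = function(e)
      stop("featurization failed for record ", sQuote(records$id[i]),
           " (row ", i, "): ", conditionMessage(e), call. = FALSE))
  }
  if (nrow(records) == 0L)
    stop("cannot featurize an empty record set", call. = FALSE)
  rows <- lapply(seq_len(nrow(records)), featurize_one)
  m <- do.call(rbind, rows)
  rownames(m) <- records$id
  colnames(m) <- names(rows[[1L]])
  if (anyDuplicated(colnames(m)))
    stop("internal error: duplicate feature names", call. = FALSE)
  prov <- character(ncol(m))
  prov[grepl(":", colnames(m))] <- "signatures"
  prov[startsWith(colnames(m), "AAT_")] <- "aat"
  prov[grepl("\\.(G[123]|T\\.|D\\.)", colnames(m)) &
         !startsWith(colnames(m), "AAT_")] <- "ctd"
  prov[grepl("\\.(mean|max|min)$", colnames(m))] <- "profiles"
  prov[startsWith(colnames(m), "taxon.")] <- "taxonomy"
  attr(m, "provenance") <- stats::setNames(prov, colnames(m))
  if ("aat" %in% groups)
    attr(m, "aat_fingerprint") <- aat_scale$fingerprint
  m
}
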