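# Independent brute-force oracles and constructed fixtures.

# Signature oracle: enumerate every index pair (i, j), bin by unordered
# label pair and separation, then threshold on the cutoff. Shares nothing
# with signature()'s per-distance vectorized counting.
brute_signature <- function(sequence, scheme, cutoffs, cumulative = TRUE) {
  labels <- assign_labels(sequence, scheme)
  L <- length(labels)
  all_labels <- scheme$labels
  keys <- character(0)
  for (a in seq_along(all_labels))
    for (b in a:length(all_labels))
      keys <- c(keys, paste(all_labels[a], all_labels[b], sep = ":"))
  out <- numeric(0)
  for (d in cutoffs) {
    counts <- setNames(numeric(length(keys)), keys)
    if (L >= 2) {
      for (i in 1:(L - 1)) {
        for (j in (i + 1):L) {
          sep <- j - i
          keep <- if (cumulative) sep <= d else sep == d
          if (keep) {
            pair <- sort(factor(c(labels[i], labels[j]),
                                levels = all_labels))
            key <- paste(as.character(pair), collapse = ":")
            counts[key] <- counts[key] + 1
          }
        }
      }
    }
    names(counts) <- paste0(keys, "-", d,
                            if (scheme$suffix_names)
                              paste0("~", scheme$name) else "")
    out <- c(out, counts)
  }
  out
}

# AUC oracle: exhaustive positive-negative pair counting, ties half.
brute_auc <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos)
    for (q in neg)
      total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# MCC oracle: the Pearson correlation of the binary prediction and truth
# vectors (phi coefficient), 0 for degenerate vectors.
brute_mcc <- function(y, pred) {
  if (length(unique(y)) < 2 || length(unique(pred)) < 2) return(0)
  stats::cor(pred, y)
}

# Greedy clustering oracle for small n: a literal, unoptimized re-run of
# the documented rule from a precomputed all-pairs identity matrix
# (Hamming for equal lengths; fixtures use equal-length pools).
brute_cluster_reps <- function(seqs, threshold) {
  id <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    stopifnot(length(ca) == length(cb))
    mean(ca == cb)
  }
  ord <- order(-nchar(seqs), seqs, seq_along(seqs))
  reps <- integer(0)
  for (j in ord) {
    hit <- FALSE
    for (r in reps) {
      if (nchar(seqs[r]) == nchar(seqs[j]) &&
          id(seqs[r], seqs[j]) >= threshold) { hit <- TRUE; break }
    }
    if (!hit) reps <- c(reps, j)
  }
  sort(reps)
}

random_peptide <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# 20-record curation fixture engineered so the steps remove, in order:
# 2 (evidence < 2), 2 (length outside 6..25), 2 (one dual-class sequence),
# 2 (unknown organism), 2 (exact within-class duplicates).
curation_fixture <- function() {
  base_seqs <- c("ACDEFGHIKL", "MNPQRSTVWY", "AAACCCDDDE", "FFFGGGHHHM",
                 "KKKLLLMMMN", "PPPQQQRRRS", "TTTVVVWWWY", "ACACACACAC",
                 "DEDEDEDEDE", "FGFGFGFGFG")
  base <- peptide_records(
    sprintf("base%02d", 1:10), base_seqs,
    rep(c("epitope", "non_epitope"), each = 5),
    organism_class = "Riboviria", evidence_count = 3L)
  dup <- peptide_records(c("dup1", "dup2"), base_seqs[c(1, 6)],
                         c("epitope", "non_epitope"),
                         organism_class = "Riboviria", evidence_count = 3L)
  low_ev <- peptide_records(c("ev1", "ev2"),
                            c("WYWYWYWYWY", "HIHIHIHIHI"),
                            c("epitope", "non_epitope"),
                            organism_class = "Riboviria",
                            evidence_count = 1L)
  bad_len <- peptide_records(c("len1", "len2"),
                             c("ACDEF", strrep("K", 26)),
                             c("epitope", "non_epitope"),
                             organism_class = "Riboviria",
                             evidence_count = 3L)
  dual <- peptide_records(c("dual1", "dual2"), rep("LYLYLYLYLY", 2),
                          c("epitope", "non_epitope"),
                          organism_class = "Riboviria",
                          evidence_count = 3L)
  no_org <- peptide_records(c("org1", "org2"),
                            c("MTMTMTMTMT", "SWSWSWSWSW"),
                            c("epitope", "non_epitope"),
                            organism_class = "unknown",
                            evidence_count = 3L)
  out <- rbind(base, dup, low_ev, bad_len, dual, no_org)
  class(out) <- c("peptide_records", "data.frame")
  out
}

# Separable toy matrix: one perfect predictor plus noise columns.
toy_selection_matrix <- function(n = 60, n_noise = 20, seed = 11) {
  set.seed(seed)
  y <- rep(c(1, 0), length.out = n)
  m <- cbind(signal = y + stats::rnorm(n, sd = 0.01),
             matrix(stats::rnorm(n * n_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(n_noise)))))
  rownames(m) <- sprintf("r%03d", seq_len(n))
  list(matrix = m, labels = y)
}
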