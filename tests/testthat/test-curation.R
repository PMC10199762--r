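test_that("evidence filter is inclusive at the threshold and idempotent", {
  recs <- peptide_records(paste0("p", 1:3), rep("ACDEFG", 3),
                          evidence_count = 1:3)
  kept <- filter_evidence(recs, 2)
  expect_equal(kept$evidence_count, c(2L, 3L))
  expect_equal(filter_evidence(recs, 0), recs)
  expect_equal(nrow(filter_evidence(recs, 4)), 0L)
  expect_equal(filter_evidence(kept, 2), kept)
})

test_that("length filter keeps both bounds inclusive", {
  recs <- peptide_records(paste0("p", 1:4),
                          c("ACDEF", "ACDEFG", strrep("K", 25),
                            strrep("K", 26)))
  kept <- filter_length(recs, 6, 25)
  expect_equal(nchar(kept$sequence), c(6L, 25L))
  one <- peptide_records("q", strrep("A", 10))
  expect_equal(nrow(filter_length(one, 10, 10)), 1L)
  expect_equal(nrow(filter_length(recs[0, ], 6, 25)), 0L)
})

test_that("dual-class removal drops all records of conflicting sequences only", {
  recs <- peptide_records(paste0("p", 1:4),
                          c("AAAAAA", "AAAAAA", "CCCCCC", "CCCCCC"),
                          c("epitope", "non_epitope", "epitope", "epitope"))
  out <- remove_dual_class(recs)
  expect_equal(out$sequence, c("CCCCCC", "CCCCCC"))
  expect_equal(attr(out, "removed_dual_class"), 1L)
  # same-label duplicates are untouched (the redundancy step's job)
  expect_equal(nrow(out), 2L)
  clean <- peptide_records(c("a", "b"), c("DDDDDD", "EEEEEE"),
                           c("epitope", "non_epitope"))
  expect_equal(remove_dual_class(clean)$sequence, clean$sequence)
})

test_that("redundancy removal merges by identity threshold", {
  recs <- peptide_records(c("a", "b"), rep("ACDEFGHIKL", 2), "epitope")
  expect_equal(nrow(remove_redundancy(recs, 0.95)), 1L)

  # 9/10 identity: kept apart at 0.95, merged at 0.80
  two <- peptide_records(c("a", "b"), c("AAAAAAAAAA", "AAAAAAAAAC"),
                         "epitope")
  expect_equal(nrow(remove_redundancy(two, 0.95)), 2L)
  expect_equal(nrow(remove_redundancy(two, 0.80)), 1L)
  # at threshold 1.0 only exact duplicates merge
  expect_equal(nrow(remove_redundancy(two, 1.0)), 2L)
})

test_that("redundancy removal clusters within class labels separately", {
  recs <- peptide_records(c("a", "b"), rep("ACDEFGHIKL", 2),
                          c("epitope", "non_epitope"))
  expect_equal(nrow(remove_redundancy(recs, 0.8)), 2L)
})

test_that("greedy clustering matches the brute-force oracle and is monotone in the threshold", {
  set.seed(42)
  for (rep in 1:5) {
    # low-complexity alphabet so near-duplicates actually occur
    seqs <- replicate(40, paste(sample(c("A", "C", "D"), 10, replace = TRUE,
                                       prob = c(0.7, 0.2, 0.1)),
                                collapse = ""))
    recs <- peptide_records(sprintf("s%02d", 1:40), seqs, "epitope")
    for (t in c(0.7, 0.8, 0.9, 1.0)) {
      mine <- remove_redundancy(recs, t)
      oracle <- brute_cluster_reps(seqs, t)
      expect_equal(which(recs$id %in% mine$id), oracle)
    }
    n_at <- vapply(c(0.7, 0.8, 0.9, 0.95, 1.0),
                   function(t) nrow(remove_redundancy(recs, t)), numeric(1))
    expect_true(all(diff(n_at) >= 0))
  }
})

test_that("unequal-length identity uses end-gap-penalized global alignment", {
  # "AAAAAAAAAA" vs "AAAAAAAAAAA": 10 matches over alignment length 11
  recs <- peptide_records(c("a", "b"),
                          c(strrep("A", 10), strrep("A", 11)), "epitope")
  expect_equal(nrow(remove_redundancy(recs, 0.90)), 1L)   # 10/11 = 0.909
  expect_equal(nrow(remove_redundancy(recs, 0.95)), 2L)
})

test_that("stratified split preserves class proportions, partitions, and is seed-stable", {
  recs <- peptide_records(
    sprintf("p%03d", 1:700),
    vapply(1:700, function(i) random_peptide(10), character(1)),
    rep(c("epitope", "non_epitope"), c(100, 600)))
  sp <- stratified_split(recs, 0.2, seed = 9)
  expect_equal(sum(sp$train$label == "epitope"), 80L)
  expect_equal(sum(sp$train$label == "non_epitope"), 480L)
  expect_equal(sum(sp$test$label == "epitope"), 20L)
  expect_equal(sum(sp$test$label == "non_epitope"), 120L)
  expect_setequal(c(sp$train$id, sp$test$id), recs$id)
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  sp2 <- stratified_split(recs, 0.2, seed = 9)
  expect_identical(sp$test$id, sp2$test$id)

  tiny <- peptide_records(paste0("t", 1:4), c("AAAAAA", "CCCCCC",
                                              "DDDDDD", "EEEEEE"),
                          rep(c("epitope", "non_epitope"), 2))
  sp3 <- stratified_split(tiny, 0.5, seed = 1)
  expect_equal(table(sp3$test$label)[["epitope"]], 1L)

  single <- peptide_records("x", "AAAAAA", "epitope")
  expect_error(stratified_split(rbind(single, tiny), 0.5), NA)
  expect_error(stratified_split(single, 0.5), "fewer than 2")
})

test_that("the composed curation pipeline records the designed survivor counts", {
  fix <- curation_fixture()
  out <- curate(fix, curation_config(seed = 4, test_fraction = 0.2))
  expect_equal(unname(out$report$counts_per_step),
               c(20L, 18L, 16L, 14L, 12L, 10L))
  expect_true(all(diff(out$report$counts_per_step) <= 0))
  expect_equal(out$report$removed_dual_class, 1L)
  expect_equal(nrow(out$train) + nrow(out$test), 10L)
})

test_that("curation with all filters disabled removes only duplicates and conflicts", {
  fix <- curation_fixture()
  cfg <- curation_config(min_evidence = 0, min_length = 1, max_length = 100,
                         similarity_threshold = 1.0,
                         require_organism = FALSE, seed = 2)
  out <- curate(fix, cfg)
  # 20 - 2 dual-class records - 2 exact duplicates
  expect_equal(unname(out$report$counts_per_step[["redundancy"]]), 16L)
})

test_that("curating an empty table yields empty outputs and zero counts", {
  empty <- curation_fixture()[0, ]
  out <- curate(empty, curation_config())
  expect_equal(nrow(out$train), 0L)
  expect_equal(nrow(out$test), 0L)
  expect_true(all(out$report$counts_per_step == 0L))
})
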