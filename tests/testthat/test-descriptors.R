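test_that("AAT scale reproduces the worked log-odds example", {
  sc <- fit_aat_scale("AAAA", "CCCC", pseudocount = 1)
  expect_equal(unname(sc$scores["AAA"]), log(3))
  expect_equal(unname(sc$scores["CCC"]), -log(3))
  f <- aat_features("AAAA", sc)
  expect_equal(unname(f["AAT_max"]), log(3))
  expect_equal(unname(f["AAT_min"]), log(3))
  expect_equal(unname(f["AAT_sum"]), 2 * log(3))
})

test_that("AAT scores are zero for identical classes and antisymmetric under swap", {
  seqs <- c("ACDEFG", "KLMNPQ", "WYWYWY")
  same <- fit_aat_scale(seqs, seqs)
  expect_true(all(abs(same$scores) < 1e-12))

  set.seed(12)
  for (i in 1:100) {
    a <- replicate(3, random_peptide(sample(6:12, 1)))
    b <- replicate(3, random_peptide(sample(6:12, 1)))
    fwd <- fit_aat_scale(a, b)
    rev <- fit_aat_scale(b, a)
    expect_equal(fwd$scores, -rev$scores[names(fwd$scores)])
  }
})

test_that("AAT scores shrink to zero as the pseudocount grows", {
  a <- c("AAAAAA", "AAACCC"); b <- c("DDDDDD", "EEEEEE")
  small <- fit_aat_scale(a, b, pseudocount = 1)
  big <- fit_aat_scale(a, b, pseudocount = 1e6)
  expect_true(max(abs(big$scores)) < max(abs(small$scores)) / 100)
  expect_true(max(abs(big$scores)) < 1e-3)
})

test_that("AAT featurization handles unseen triplets, short input and ordering", {
  sc <- fit_aat_scale("AAAA", "CCCC")
  f <- aat_features("DDDDD", sc)  # no triplet seen at fit time
  expect_true(all(f == 0))
  expect_error(aat_features("AC", sc), "length >= 3")
  set.seed(5)
  for (i in 1:20) {
    f <- aat_features(random_peptide(8), sc)
    expect_gte(f[["AAT_max"]], f[["AAT_min"]])
  }
  expect_warning(fit_aat_scale(c("AAAA", "AC"), "CCCC"), "shorter than 3")
})

test_that("CTD worked examples: homo-acidic and alternating charge", {
  g <- ctd_groupings("charge")
  f <- ctd_features("DDDD", g)
  expect_equal(unname(f[c("charge.G1", "charge.G2", "charge.G3")]),
               c(0, 0, 1))
  expect_true(all(f[grepl("charge.T.", names(f), fixed = TRUE)] == 0))
  f2 <- ctd_features("DKDK", g)
  expect_equal(unname(f2["charge.T.G1G3"]), 1)  # all 3 adjacent pairs cross
})

test_that("CTD invariants hold on random peptides", {
  set.seed(21)
  g <- ctd_groupings()
  for (i in 1:50) {
    f <- ctd_features(random_peptide(sample(6:25, 1)), g)
    for (prop in names(g)) {
      comp <- f[paste0(prop, ".G", 1:3)]
      expect_equal(sum(comp), 1, tolerance = 1e-12)
      trans <- f[paste0(prop, ".T.", c("G1G2", "G1G3", "G2G3"))]
      expect_true(all(trans >= 0 & trans <= 1))
      for (k in 1:3) {
        dist <- f[paste0(prop, ".D.G", k, ".P", c(0, 25, 50, 75, 100))]
        expect_true(all(diff(dist) >= 0))
        expect_true(all(dist >= 0 & dist <= 100))
      }
    }
  }
})

test_that("propensity profile statistics behave on homopolymers and under reversal", {
  vals <- propensity_scales()$parker
  f <- scale_profile_features("KKKK", "parker")
  expect_equal(unname(f), rep(unname(vals["K"]), 3))
  s <- "ACDEFGHIKL"
  r <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(scale_profile_features(s, "parker"),
               scale_profile_features(r, "parker"))
  f2 <- scale_profile_features(s, "kolaskar")
  expect_true(f2[["kolaskar.max"]] >= f2[["kolaskar.mean"]])
  expect_true(f2[["kolaskar.mean"]] >= f2[["kolaskar.min"]])
  expect_error(scale_profile_features(s, "nosuch"), "available")
})

test_that("taxonomy one-hot has a single positional 1 and an all-zero unknown", {
  vocab <- taxonomy_vocabulary()
  expect_equal(nrow(vocab), 20L)
  expect_equal(as.integer(table(vocab$superkingdom)[c("Virus", "Eukaryota",
                                                      "Bacteria")]),
               c(8L, 5L, 7L))
  v <- taxonomy_onehot("Riboviria")
  expect_equal(sum(v), 1)
  expect_equal(unname(v["taxon.Riboviria"]), 1)
  expect_true(all(taxonomy_onehot("unknown") == 0))
  for (cl in vocab$class) expect_equal(sum(taxonomy_onehot(cl)), 1)
  expect_error(taxonomy_onehot("Martian"), "vocabulary")
})

test_that("featurize is deterministic, group-toggleable and names the paper-grade features", {
  recs <- peptide_records(c("a", "b", "c"),
                          c("ACDEFGHIKL", "ACDEFGHIKL", "WYWYWYKKKK"),
                          c("epitope", "non_epitope", "epitope"),
                          organism_class = "Riboviria",
                          evidence_count = 2L)
  sc <- fit_aat_scale("ACDEFGHIKL", "WYWYWYKKKK")
  m1 <- featurize(recs, sc)
  m2 <- featurize(recs, sc)
  expect_identical(m1, m2)
  expect_identical(m1["a", ], m1["b", ])  # identical sequences, same organism
  expect_true(all(c("AAT_max", "Apolar:Aromatic-8", "charge.G3",
                    "taxon.Riboviria", "parker.mean") %in% colnames(m1)))
  expect_false(anyNA(m1))

  no_tax <- featurize(recs, sc, groups = c("signatures", "aat", "ctd",
                                           "profiles"))
  expect_equal(ncol(m1) - ncol(no_tax), 20L)
  prov <- attr(m1, "provenance")
  expect_setequal(unique(unname(prov)),
                  c("signatures", "aat", "ctd", "profiles", "taxonomy"))
  expect_error(featurize(recs, NULL), "aat_scale")
})

test_that("featurization errors carry the failing record id", {
  recs <- peptide_records(c("ok", "tooshort"), c("ACDEFG", "AC"))
  sc <- fit_aat_scale("AAAA", "CCCC")
  expect_error(featurize(recs, sc, groups = "aat"), "tooshort")
})
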