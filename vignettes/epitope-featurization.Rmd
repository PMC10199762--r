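---
title: "Featurizing and classifying linear B-cell epitopes with epitopr"
author: "epitopr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Featurizing and classifying linear B-cell epitopes with epitopr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitopr)
```

## The problem

Linear (continuous) B-cell epitopes are short stretches of an antigen's
sequence — overwhelmingly 6 to 25 residues — that antibodies recognize
directly, without requiring the folded protein. Predicting them from
sequence alone is a heavily imbalanced classification problem: curated
experimental collections contain roughly one confirmed epitope for every
six confirmed non-epitopes, and peptides vary in length, so fixed-window
encodings fit awkwardly. `epitopr` implements a featurization and
modeling stack built for exactly this setting: length-flexible sequence
descriptors, an imbalance-robust evaluation protocol, and interpretable
classifiers.

## Dataset curation

`curate()` reproduces the standard benchmark-construction discipline for
assay-derived peptide collections, in five steps applied in order:

1. **Assay evidence** — keep peptides confirmed in at least
   `min_evidence` distinct assays (default 2, inclusive). A single-assay
   observation is treated as unreplicated evidence.
2. **Length** — keep lengths in `[min_length, max_length]`, default
   `[6, 25]`, both bounds inclusive: essentially all linear epitopes fall
   in this window, and every descriptor in the package is well defined on
   it.
3. **Dual-class removal** — a sequence observed as both epitope and
   non-epitope is contradictory; all of its records are dropped.
4. **Organism requirement** — optionally keep only records with a known
   organism lineage class, since taxonomy is a feature group.
5. **Redundancy removal** — greedy representative-based clustering at a
   global-identity threshold (default 0.95; 0.90/0.80/0.70 are the
   conventional stricter settings), then one representative per cluster.

The identity used in step 5 is *matches / alignment length* under global,
end-gap-penalized alignment (Biostrings' Needleman–Wunsch with match
score 1, mismatch 0, gap cost 1 per position), which for equal-length
peptides reduces to the Hamming match fraction. This definition is chosen
over word-based screening heuristics because it is exactly reproducible
and directly testable against a brute-force oracle. Clustering visits
sequences by (length descending, lexicographic, input order) and assigns
each to the first representative within the threshold — fully
deterministic. It runs within each class label separately, so redundancy
removal can never silently resolve a class conflict; conflicts are the
dual-class filter's job, which runs first. A residue-composition upper
bound on the achievable match count prunes candidate pairs before any
alignment, which keeps the step fast at benchmark scale.

Two choices here were genuinely open. Whether clustering should pool the
classes is not dictated by the procedure itself; per-class pools were
chosen for the conflict-safety argument above, and the curation report
records which engine ran. And the evidence rule could count positive
assays only; `epitopr` counts whatever the `assays` column carries,
leaving assay-type semantics to the data provider.

`stratified_split()` holds out `test_fraction` (default 20%) of each
class, preserving the epitope:non-epitope ratio to within one record per
class. The 1:6 ratio is a property of the data, not enforced: the split
preserves whatever ratio exists.

## Graph-based sequence signatures

The package's central descriptor treats a peptide as a sequence graph:
residues are nodes carrying categorical labels, and each distance cutoff
`d` induces edges between residues separated by up to `d` positions
(cumulative mode, the default) or exactly `d` (non-cumulative). The
feature vector counts edges per unordered label pair at each cutoff, with
names like `Apolar:Aromatic-8` — the number of apolar/aromatic residue
pairs within sequence distance 8.

Two labelings are bundled by default:

* **Physicochemical classes** — Apolar \{A,G,I,L,M,P,V\}, Aromatic
  \{F,W,Y\}, PolarNeutral \{C,N,Q,S,T\}, Acidic \{D,E\}, Basic \{H,K,R\}.
  The class table is the standard pharmacophore-style assignment and is
  user-replaceable through `labeling_scheme()`.
* **Parker hydrophilicity, binarized** — residues above the scale's mean
  value are `High`, the rest `Low`. Binarizing at the unweighted mean of
  the 20 per-residue values is parameter-free; any threshold (or any of
  the other packaged scales: Chou–Fasman turn, Emini accessibility,
  Kolaskar–Tongaonkar antigenicity) can be substituted via
  `scheme_scale_binary()`.

The cutoff grid defaults to 1..24: peptides are at most 25 residues, so
24 is the largest possible separation, and full coverage is cheap at
peptide scale. Counts at cutoffs beyond `L - 1` are zero by definition,
not an error, so peptides of different lengths share one feature space.
Pair keys are unordered with labels sorted alphabetically
(`Acidic:Apolar`, never `Apolar:Acidic`), which also makes signatures
exactly invariant under sequence reversal.

```{r signature-example}
signature("AFD", signature_config(schemes = list(scheme_physchem()),
                                  cutoffs = 1:2))
```

## AAT antigenicity-ratio features

The amino-acid-triplet (AAT) scale scores each 3-mer by its
overrepresentation among epitopes. With overlapping triplet counts
$c_e(t)$, $c_n(t)$ and class totals $N_e$, $N_n$,

$$ s(t) \;=\; \ln\frac{c_e(t)+p}{c_n(t)+p}
        \;+\; \ln\frac{N_n + 8000\,p}{N_e + 8000\,p}, $$

a frequency-normalized log-odds with additive pseudocount $p$ (default
1; 8000 is the number of possible triplets). The form has the properties
a propensity scale needs: swapping the classes negates every score,
identical classes give zeros, and scores shrink to zero as $p$ grows.
Unseen triplets score 0 at prediction time — no evidence either way.

A peptide is summarized by `AAT_max`, `AAT_min`, `AAT_sum` and
`AAT_mean` over its triplets. The maximum and minimum are the headline
features; the sum is kept as the cumulative reading of the same profile
(the two summaries are sometimes conflated in the literature; `epitopr`
exposes both and lets feature selection arbitrate).

Because the scale is *fitted*, it is a leakage hazard: a scale estimated
on data that includes the evaluation peptides memorizes their triplets.
`epitopr` enforces hygiene twice. `featurize()` stamps the scale's
fingerprint on the matrix and `predict_scores()` refuses a matrix whose
fingerprint differs from the training one. And
`cross_validate_records()` refits the scale inside every fold from that
fold's training records only — the cross-validation to quote as
generalization evidence. The difference is not cosmetic: on synthetic
data with *no* planted signal, matrix-level CV over a scale fitted on
the full training set reports near-perfect AUC, while the fold-refit
protocol correctly reports chance (~0.5).

## CTD descriptors, profiles, taxonomy

`ctd_features()` computes composition/transition/distribution
descriptors over three-group residue partitions for hydrophobicity,
normalized van der Waals volume, polarity, charge, secondary structure
and solvent accessibility (polarizability is available but off by
default). Per property: 3 composition fractions, 3 cross-group adjacent
transition fractions (denominator `L - 1`), and 15 distribution values —
the positions, as percent of length, of the first, 25%, 50%, 75% and
last occurrence of each group, with absent groups reporting zeros so the
vector length is fixed. The group tables are the standard published
3-group partitions; the exact tables are exported in `ctd_groupings()`
and overridable.

`scale_profile_features()` adds mean/max/min of each propensity scale's
per-residue profile (no window smoothing — peptides are short), and
`taxonomy_onehot()` encodes the source organism over a fixed 20-class
lineage vocabulary (8 viral, 5 eukaryotic, 7 bacterial classes);
`"unknown"` encodes as all zeros rather than a fake class. How
sub-species map onto the 20 classes is data-provider territory: the
vocabulary is fixed, the mapping table is the user's.

With all groups enabled the default space has 594 features: 432
signature counts, 4 AAT summaries, 126 CTD values, 12 profile statistics
and 20 taxonomy slots.

## Modeling and evaluation

`train_model()` wraps five classifiers behind one interface: random
forest and extremely randomized trees (ranger, impurity importance
recorded at fit time), gradient boosting (xgboost, depth-3 trees),
*additive boosting* — xgboost restricted to depth-1 stumps, i.e. a
boosted generalized additive model whose per-feature response curves are
its exact shape functions — and an RBF SVM with probability outputs.
Random forest is the default: on this family of problems tree ensembles
and additive boosting perform equivalently, and the forest trains
fastest. All fits are seeded and single-threaded for bit-reproducibility;
hyperparameters default to library defaults and are recorded in the
returned bundle.

Metrics center on the Matthews correlation coefficient, the right
summary under 1:6 imbalance, plus ROC AUC (rank estimator, ties count
half), F1 and balanced accuracy. Numerical conventions: MCC is 0
whenever a denominator factor is 0 (so a majority-class predictor scores
exactly 0, not NA); AUC is NA — undefined, not 0.5 — when a class is
absent; F1 is 0 when its denominator is 0; the decision threshold
defaults to 0.5 on the predicted probability.

`greedy_forward_select()` implements forward stepwise selection on CV
MCC: starting empty (score 0, the MCC of any constant predictor), each
round adds the feature with the largest gain, stopping when no candidate
improves by more than `1e-4` for `patience` (default 1) consecutive
rounds. Ties break by gain then column order, so selection is
deterministic under a seed. Selection is run nested inside the
training data only; the non-nested variant is available by running it
once and passing the result to `train_model()` explicitly.

## The synthetic generator

`generate_synthetic()` produces IEDB-like labeled tables so the whole
pipeline is testable without downloads: lengths uniform on 6–25, an
epitope:non-epitope ratio of 1:6 (defaults 300:1800), organism classes
uniform over the 20-term vocabulary, evidence counts on \{0..4\} with
mass below the 2-assay threshold so the evidence filter actually does
something, and a planted 3-mer motif (`YWC` by default) inserted into
epitopes at rate 0.9. The background residue distribution is uniform,
which makes the planted-signal arithmetic exact: a background triplet
occurs at rate 1/8000, so the planted motif is overrepresented by
orders of magnitude and the fitted AAT scale must score it strongly
positive (about +5.6 at these rates).

What the generator deliberately does **not** emulate: real amino-acid
composition biases, homology structure within classes (beyond what the
redundancy filter removes), organism-dependent epitope rates (available
via `organism_bias` but off by default), and any true physicochemical
difference between epitopes and non-epitopes other than the planted
motif. Passing tests on this data therefore demonstrates that the
machinery recovers a known signal and refuses a null one — not that any
particular accuracy will transfer to experimental collections.

## Validation protocol and problem sizes

The test suite checks the descriptor layer against brute-force oracles
(exhaustive index-pair enumeration for signatures over all `{A,F,D}`
strings up to length 6; phi-coefficient MCC over every confusion matrix
with `n <= 8`; pair-counting AUC on random score vectors; a literal
re-run of the clustering rule on 40-sequence pools) and the modeling
layer on planted-signal synthetics at 2,000 records — large enough for
stable fold metrics, small enough to validate in seconds on one core.
At those conditions the leakage-free 5-fold CV reaches AUC above 0.9 and
MCC above 0.4, the blind test behaves comparably, and the no-signal
control sits at chance. `scripts/acceptance.R` recomputes exactly these
quantities from scratch at any seed.

## Known limitations

* The redundancy engine is a deterministic greedy clusterer, not a
  re-implementation of any specific external tool; at a given threshold
  its cluster count can differ slightly from word-filtered greedy
  clusterers on the same input. The report's `engine` field says what
  ran.
* Exact SHAP values are not computed; `feature_importance()` offers
  impurity (Gini) shares and seeded permutation importance, which agree
  with SHAP at the ranking level on planted-signal fixtures.
* Taxonomy covers exactly the fixed 20-class vocabulary; mapping raw
  species names to those classes is out of scope.
* Scores are probabilities under each library's calibration; no
  additional calibration step is applied.
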