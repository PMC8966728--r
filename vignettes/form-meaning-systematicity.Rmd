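---
title: "Measuring form–meaning systematicity in sign-language lexicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring form–meaning systematicity in sign-language lexicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formsem)
```

## The question and the model

Sign languages are rich in motivated form–meaning mappings, yet their
lexicons are also shaped by pressures toward phonological distinctiveness.
`formsem` asks a quantitative version of the question: across a whole
lexicon, how strongly does similarity in *form* track similarity in
*meaning*, and does the association concentrate inside semantically
coherent neighborhoods?

Each sign contributes two vectors.

**Phonological space.** A sign's form is described by categorical labels
over up to twelve annotation slots (`slot_schema`): handshape and location
of the dominant and non-dominant hand at the beginning and end of the
sign, and four movement slots (local movement, path movement, axis,
non-dominant-hand behavior). A *parameter scope* selects a slot subset —
`handshape`, `location`, `movement`, or `entire` (all twelve,
concatenated as one block rather than averaged per parameter; slots are
weighted equally). `build_onehot()` encodes the observed (slot, label)
pairs as a binary sign × feature matrix; `reduce_svd()` projects it onto
its top-*k* left-singular directions scaled by the singular values, giving
dense sign coordinates. Missing slots (one-handed signs have no
non-dominant labels) are all-zero blocks, not an "absent" feature level:
two signs are not made more similar merely because both lack a
non-dominant hand.

**Semantic space.** A sign's meaning is represented by the pre-trained
word embedding of its gloss (GloVe plain-text format, typically 100, 200,
or 300 dimensions). Glosses are normalized — lowercased, trimmed, internal
whitespace hyphenated — and matched to embedding tokens by exact string
equality; signs without a token are dropped by `align_lexicon()`. No
lemmatization or subword fallback is attempted, so the multi-word-gloss
policy is simply the hyphenation rule. Where a source lists several
variants of one sign, only the first listed variant is kept
(`dedup_first_variant()`), since repeated near-identical entries would
overweight those glosses in every pairwise statistic.

Similarity in both spaces is the cosine. The embedding-token filter is
the single inclusion criterion; the analysis inherits whatever cultural
and distributional assumptions the embedding corpus carries.

## The two analyses

**Lexicon-wide pairwise.** `run_pairwise()` enumerates all n(n−1)/2
unordered pairs, attaches semantic and per-scope phonological cosines, and
reports one Pearson correlation per scope with the t-transform test
(df = n_pairs − 2, two-sided, α = 0.001 by default). Pair similarities
are computed blockwise from normalized rows, so the full n × n cosine
matrix is never materialized.

**Within-cluster.** `ward_linkage()` clusters the semantic vectors at
their native embedding dimension (no SVD is applied to the semantic side)
with Ward's minimum-variance criterion on Euclidean distances — the
square-root form of the Ward cost, under which two singletons merge at
their Euclidean distance and merge heights are monotone. The tree is cut
at pruning heights expressed as a percentage of the maximum merge height
(`cut_at_percent()`); `run_sweep()` scans heights 1–100% at 1% steps by
default, scores each solution by its mean silhouette, pools the
within-cluster pairs (pairing never crosses cluster boundaries), and
computes one pooled correlation per scope — a single Pearson over the
pooled pairs, not an average of per-cluster coefficients, so large
clusters count in proportion to their pair counts. At 100% the pooled
pair set is the complete enumeration and the sweep row reproduces the
lexicon-wide result exactly; at 0% every sign is a singleton and the
correlation is undefined, which is why 0% is excluded from the default
grid (it remains available by passing `heights = 0:100`).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `svd_rank` | 50 (capped at the matrix rank) | retained phonological dimensions; `NULL` = full rank |
| `scopes` | all four | parameter scopes analyzed |
| `alpha` | 0.001 | per-record two-sided significance level |
| `heights` | 1–100 (%) | pruning heights, percent of max merge height |
| `bonferroni` | off | optional family-wise correction across the sweep grid |

The SVD rank trades compactness against fidelity; because any fixed
truncation makes similarities encoding-dependent, all calibration and
validation results in this package are computed in the full-rank limit,
where the reduced-space cosine provably equals the raw one-hot cosine
(the test suite bounds the difference at 1e-9). Significance is
per-record, matching the convention of reporting each height/scope cell
on its own; the Bonferroni option divides α by the number of grid
records.

## Numerical choices

- **SVD sign convention.** Each singular vector's sign is fixed so its
  largest-magnitude component is positive. Cosine similarity is invariant
  to these signs; the convention only makes outputs byte-reproducible.
- **Ward tie-breaking.** `ward_linkage()` delegates to
  `stats::hclust(method = "ward.D2")`, whose tie handling is
  deterministic; identical inputs always give identical trees. Ties are
  measure-zero for continuous embeddings.
- **Cluster labels** are numbered by first appearance in sign order, so
  labelings are stable under re-runs.
- **Silhouette convention.** Points in singleton clusters contribute 0;
  a solution with fewer than two clusters, or with every cluster a
  singleton, has an undefined score (recorded as missing). The score is
  computed from a distance object shared across the whole sweep.
- **Undefined similarities.** A sign with no annotation in a scope has a
  zero phonological vector and no direction; its pairs are flagged
  undefined and excluded listwise from that scope's correlation (counts
  are logged), rather than imputed.
- **Degenerate correlations.** Fewer than 3 pairs or zero variance in
  either similarity yields a flagged degenerate record (`r = NA`) instead
  of an error, so sweep grids stay rectangular.

## What the synthetic generator emulates

`generate_synthetic()` draws a lexicon whose semantic vectors form K
Gaussian clusters (centers with per-coordinate sd `sem_between_sd` = 1,
within-cluster noise `sem_within_sd` = 0.4, per-sign noise scale mixed by
a Gamma with shape 1 so each cluster has a prototypical core and a
periphery) and whose phonological labels are drawn per slot from a mixture
of the cluster's canonical label and the slot's global inventory.
Inventory sizes default to realistic annotation vocabularies: a few dozen
handshapes (30 per handshape slot), a couple dozen locations (20), and
around a dozen movement types (12/10/6/8 across the four movement slots).

Coupling is *prototypicality-graded*: a sign adopts its cluster's
canonical label at a coupled slot with probability
ρ · exp(−‖noise‖² / (2·d·`coupling_scale`²)), so semantically central
signs are also the most formationally canonical — the package's model of
a sign family, whose prototypical members share both meaning and form.
This gradient is what plants a *within*-cluster correlation between
semantic and phonological similarity; a flat per-sign adoption
probability would make the two similarities independent inside a cluster
and leave nothing for the within-cluster analysis to recover. At ρ = 0
every label is uniform and all correlations are null; as ρ → 1 with
vanishing semantic noise, all within-cluster similarities approach 1.
`coupled_scopes` confines the coupling to chosen parameters, giving the
uncoupled scopes a true null — the mechanism behind per-parameter
dissociations. Because the implied correlation has no convenient closed
form, the recovery target is estimated by Monte-Carlo
(`planted_effect()`): repeated generation, pairs within the *true*
clusters, phonological similarity from the label-match closed form —
deliberately independent of the clustering and SVD machinery under test.

What the generator does **not** emulate: real GloVe geometry (anisotropy,
hubness, frequency effects), real phonotactics (markedness, slot
dependencies, phonological neighborhoods), annotation noise, and
polysemous glosses. Passing recovery tests therefore shows the pipeline
measures what it claims on data with known structure — not that any
particular real lexicon has that structure.

## Validation problem sizes

The packaged checks use: kernel-oracle equivalence on random instances up
to n = 40 (Ward, against a naive O(n³) agglomerator) and n = 200
(silhouette, against the direct per-point formula); parameter recovery on
200 replicates per coupling level (n = 300 signs, K = 10 clusters,
ρ ∈ {0, 0.3, 0.6}), requiring the pipeline's mean pooled within-cluster r
at the generative granularity to sit within ±0.03 of the Monte-Carlo
target and the ρ = 0 null to reject in at most 1% of replicates at
α = 0.001; and a 1,950-sign, 60-cluster fixture with coupling 0.5
confined to location (`paper_shape_fixture()`) for the end-to-end
contrast. These sizes give Monte-Carlo standard errors comfortably below
the tolerances they are checked against.

## Known limitations

- Pearson over pair similarities treats pairs as independent although
  pairs sharing a sign are dependent; no Mantel-style permutation test is
  provided. For the label-mixture null this matters little (pairs sharing
  a sign are uncorrelated under uniform labels, and the measured
  false-positive rate is at or below nominal), but p-values on real data
  should be read with the dependence in mind.
- Phonological similarity is categorical: two different handshapes are
  equally dissimilar whatever their articulatory relationship. Gradient
  feature similarity is out of scope.
- Cross-language comparison is limited to running the pipeline per
  language; no cross-lingual embedding alignment is attempted.
- The silhouette profile of clean synthetic clusters peaks much higher
  (≈ 0.6) than is typical for real embedding spaces (≈ 0.1); only the
  *shape* of the profile — the interior maximum — transfers.
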