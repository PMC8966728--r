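# formsem

Vector-space analysis of form–meaning correspondence in sign-language
lexicons.

A long-standing question in sign-language linguistics is how far the
lexicon is *systematic*: whether signs that mean similar things also tend
to look similar. `formsem` quantifies this at lexicon scale. Each sign
gets two vector representations:

- a **phonological vector**: its categorical annotation labels —
  handshape, location, and movement, each annotated over several slots
  (dominant/non-dominant hand at the beginning and end of the sign; local
  movement, path movement, axis, non-dominant-hand behavior) — one-hot
  encoded into a binary sign × feature matrix and densified by truncated
  SVD;
- a **semantic vector**: the pre-trained word embedding (GloVe text
  format) of its gloss.

Similarity in both spaces is cosine. The package then measures the
form–meaning association two ways:

1. **Lexicon-wide pairwise analysis.** Over all n(n−1)/2 unordered sign
   pairs, the Pearson correlation r between semantic and phonological
   similarity, with the t-transform significance test
   (t = r·√(df/(1−r²)), df = n_pairs − 2).
2. **Within-cluster analysis.** The semantic vectors are clustered
   hierarchically (Ward's method on Euclidean distance); the dendrogram is
   cut at pruning heights 1–100% of the maximum merge height; each flat
   solution is scored by its mean silhouette; and the same Pearson
   correlation is computed over the pooled *within-cluster* pairs only —
   pairing never crosses cluster boundaries. This asks whether form–meaning
   correspondence concentrates inside semantically coherent neighborhoods
   (sign families) even when it is weak lexicon-wide.

A seeded synthetic-lexicon generator with planted cluster structure and a
tunable form–meaning coupling closes the loop: the pipeline's estimates
can be checked against the generator's known ground truth
(`planted_effect()` gives the Monte-Carlo recovery target).

The package is aimed at computational psycholinguists studying
systematicity and iconicity, and at anyone with a categorical feature
table plus an embedding file who wants a calibrated similarity-correlation
analysis.

## Worked example

A synthetic lexicon of 600 signs in 20 semantic clusters, with coupling
0.6 confined to the location parameter (handshape and movement labels are
drawn uniformly, so they carry a true null):

```r
library(formsem)

cfg <- synthetic_config(n_signs = 600, n_clusters = 20, coupling = 0.6,
                        coupled_scopes = "location", seed = 42)
syn <- generate_synthetic(cfg)
al  <- align_lexicon(dedup_first_variant(syn$lexicon), syn$embedding,
                     svd_rank = NULL)
run_pairwise(al)
#>       scope         r     df     p n_pairs significant degenerate
#> 1 handshape -0.000424 179698 0.857  179700       FALSE      FALSE
#> 2  location  0.260780 179698 0.000  179700        TRUE      FALSE
#> 3  movement  0.002622 179698 0.266  179700       FALSE      FALSE
#> 4    entire  0.146301 179698 0.000  179700        TRUE      FALSE
```

Lexicon-wide, semantic similarity correlates with phonological similarity
only in the coupled scope (r = 0.26) and, diluted, in the all-parameters
`entire` scope; the uncoupled scopes are flat. Now the height sweep:

```r
sw  <- run_sweep(al, heights = seq(2, 100, by = 2))
sil <- unique(sw[, c("height_percent", "n_clusters", "silhouette")])
sil[which.max(sil$silhouette), ]
#>    height_percent n_clusters silhouette
#> 33             18         20  0.6108051

sw[sw$height_percent == 18,
   c("scope", "n_clusters", "n_within_pairs", "r", "p", "significant")]
#>        scope n_clusters n_within_pairs       r         p significant
#> 33 handshape         20           8700 0.00352  7.43e-01       FALSE
#> 34  location         20           8700 0.37178 2.51e-283        TRUE
#> 35  movement         20           8700 0.01213  2.58e-01       FALSE
#> 36    entire         20           8700 0.29230 5.99e-171        TRUE
```

The silhouette profile peaks exactly at the planted granularity
(20 clusters), and restricting pairs to those clusters raises the
location-scope correlation from 0.26 to 0.37 while the uncoupled scopes
stay non-significant — the within-cluster vs lexicon-wide contrast the
method is designed to expose, confined to the parameter that actually
carries the signal.

Real data enter through `read_lexicon()` (TSV/CSV annotation table with a
`gloss` column and any subset of the twelve slots; see `slot_schema`) and
`load_embeddings()` (GloVe plain-text format), followed by
`dedup_first_variant()` and `align_lexicon()`, which drops glosses without
an embedding token.

A thin command-line front end wraps the same functions
(`formsem_cli_path()` returns its installed location):

```sh
Rscript $(Rscript -e 'cat(formsem::formsem_cli_path())') \
  sweep --lexicon lexicon.tsv --embeddings glove.txt \
  --heights 1:100 --alpha 0.001 --out results/
```

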