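# In-code fixtures shared across test files.

# A small fully annotated lexicon with known structure.
toy_lexicon_df <- function() {
  data.frame(
    gloss = c("tree", "mother", "think"),
    hs_dom_begin = c("flat", "five", "one"),
    hs_dom_end = c("flat", "five", "one"),
    hs_nondom_begin = c("flat", NA, NA),
    hs_nondom_end = c("flat", NA, NA),
    loc_dom_begin = c("neutral", "chin", "forehead"),
    loc_dom_end = c("neutral", "chin", "forehead"),
    loc_nondom_begin = c("neutral", NA, NA),
    loc_nondom_end = c("neutral", NA, NA),
    mov_local = c("twist", "none", "none"),
    mov_path = c("none", "none", "arc"),
    mov_axis = c("vertical", "none", "sagittal"),
    mov_nondom_behavior = c("static", NA, NA),
    stringsAsFactors = FALSE)
}

write_toy_lexicon <- function(path, df = toy_lexicon_df(), sep = "\t") {
  out <- df
  for (c in names(out)) out[[c]][is.na(out[[c]])] <- ""
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# GloVe-style embedding file for given tokens (deterministic vectors).
write_toy_embeddings <- function(path, tokens, d = 4, seed = 99) {
  set.seed(seed)
  lines <- vapply(tokens, function(tok) {
    paste(tok, paste(round(stats::rnorm(d), 6), collapse = " "))
  }, "")
  writeLines(lines, path)
  path
}

# A small aligned synthetic lexicon for pipeline-level tests.
small_aligned <- function(seed = 11, coupling = 0.5, n = 60, K = 4,
                          svd_rank = NULL, ...) {
  cfg <- synthetic_config(n_signs = n, n_clusters = K, coupling = coupling,
                          seed = seed, ...)
  syn <- generate_synthetic(cfg)
  al <- suppressMessages(
    align_lexicon(syn$lexicon, syn$embedding, svd_rank = svd_rank))
  list(cfg = cfg, syn = syn, al = al)
}
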