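#' Build a one-hot phonological vector space
#'
#' Encodes the categorical annotation labels of a lexicon, restricted to one
#' parameter scope, as a binary sign-by-feature matrix: one column per
#' observed (slot, label) pair, a 1 where the sign carries that label.
#' Missing slots contribute an all-zero block — absence is not itself a
#' feature level. The feature vocabulary is sorted by (slot, label) so the
#' encoding is order-independent.
#'
#' @param lex A deduplicated `sign_lexicon`.
#' @param scope A scope name or [parameter_scope] object.
#' @return A `phono_space`: list with `sign_index` (glosses), `feature_vocab`
#'   (data frame of slot/label), `onehot` (binary matrix), `scope`, and
#'   `reduced`/`svd_rank`/`singular_values` (unset until [reduce_svd]).
#' @export
build_onehot <- function(lex, scope = "entire") {
  scope <- as_scope(scope)
  slots <- intersect(scope$slots, names(lex))
  vocab_slot <- character(0)
  vocab_label <- character(0)
  for (s in slots) {
    labs <- sort(unique(lex[[s]][!is.na(lex[[s]]) & nzchar(lex[[s]])]))
    vocab_slot <- c(vocab_slot, rep(s, length(labs)))
    vocab_label <- c(vocab_label, labs)
  }
  if (length(vocab_label) == 0) {
    stop("empty feature space: no labels observed in scope '", scope$name,
         "'", call. = FALSE)
  }
  # keep slot blocks in schema order, labels sorted within slot
  ord <- order(match(vocab_slot, slot_schema), vocab_label)
  vocab <- data.frame(slot = vocab_slot[ord], label = vocab_label[ord],
                      stringsAsFactors = FALSE)
  n <- nrow(lex)
  m <- matrix(0L, nrow = n, ncol = nrow(vocab),
              dimnames = list(lex$gloss,
                              paste(vocab$slot, vocab$label, sep = "=")))
  for (k in seq_len(nrow(vocab))) {
    s <- vocab$slot[k]
    hit <- !is.na(lex[[s]]) & lex[[s]] == vocab$label[k]
    m[hit, k] <- 1L
  }
  structure(list(sign_index = lex$gloss, feature_vocab = vocab,
                 onehot = m, scope = scope, reduced = NULL,
                 svd_rank = NULL, singular_values = NULL),
            class = "phono_space")
}

#' Reduce a phonological space by truncated SVD
#'
#' Projects the one-hot matrix onto its top-`k` left-singular directions,
#' scaled by the singular values (`U_k %*% diag(d_k)`), giving each sign a
#' dense `k`-dimensional phonological coordinate. At `k` equal to the full
#' rank the pairwise cosine geometry of the one-hot rows is reproduced
#' exactly. Singular-vector signs are fixed so each component vector's
#' largest-magnitude entry is positive, making output deterministic.
#'
#' @param space A `phono_space` from [build_onehot].
#' @param k Retained rank, `1 <= k <= min(n_signs, n_features)`. The
#'   default keeps at most 50 dimensions.
#' @return The `phono_space` with `reduced`, `svd_rank`, and
#'   `singular_values` set.
#' @export
reduce_svd <- function(space, k = min(50L, dim(space$onehot))) {
  stopifnot(inherits(space, "phono_space"))
  kmax <- min(dim(space$onehot))
  if (length(k) != 1 || is.na(k) || k < 1 || k > kmax) {
    stop("SVD rank k must lie in [1, ", kmax, "], got ", k, call. = FALSE)
  }
  k <- as.integer(k)
  sv <- svd(space$onehot, nu = k, nv = k)
  u <- sv$u
  # deterministic sign convention per singular vector
  for (c in seq_len(k)) {
    piv <- which.max(abs(u[, c]))
    if (u[piv, c] < 0) u[, c] <- -u[, c]
  }
  space$reduced <- u %*% diag(sv$d[seq_len(k)], nrow = k)
  rownames(space$reduced) <- space$sign_index
  space$svd_rank <- k
  space$singular_values <- sv$d[seq_len(k)]
  space
}

#' Phonological cosine similarity between two signs
#'
#' Cosine of the SVD-reduced phonological vectors of signs `i` and `j`.
#' Undefined (`NA`) when either sign has no annotation in the scope (zero
#' vector); such pairs are excluded from downstream correlations.
#'
#' @param space A reduced `phono_space`.
#' @param i,j Sign indices (vectors allowed, recycled pairwise).
#' @return Cosine values in `[-1, 1]`, `NA` where undefined.
#' @export
phono_similarity <- function(space, i, j) {
  if (is.null(space$reduced)) {
    stop("phono_space has no reduced representation; call reduce_svd() first",
         call. = FALSE)
  }
  cosine_pairs(space$reduced, i, j)
}

#' Export a one-hot matrix as Matrix Market coordinates
#'
#' Writes the binary sign-by-feature matrix as a sparse coordinate triplet
#' file (MatrixMarket `coordinate integer general`) plus a sidecar CSV of
#' the feature vocabulary.
#'
#' @param space A `phono_space`.
#' @param mtx_path Output `.mtx` path.
#' @param vocab_path Output CSV path for the (slot, label) vocabulary.
#' @return `mtx_path`, invisibly.
#' @export
export_onehot_mtx <- function(space, mtx_path, vocab_path = NULL) {
  m <- space$onehot
  idx <- which(m != 0, arr.ind = TRUE)
  con <- file(mtx_path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), nrow(idx)), con)
  writeLines(sprintf("%d %d 1", idx[, 1], idx[, 2]), con)
  if (!is.null(vocab_path)) write_table(space$feature_vocab, vocab_path)
  invisible(mtx_path)
}
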