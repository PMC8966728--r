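#' Load word embeddings in GloVe text format
#'
#' Reads a plain-text embedding table: one line per token, the token
#' followed by `d` whitespace-separated floats, no header. Malformed lines
#' (wrong float count, unparseable numbers) are skipped with a warning;
#' duplicate tokens keep their first occurrence. Transparently reads
#' gzip-compressed files.
#'
#' @param path Embedding file path.
#' @param dimension Expected vector dimension (commonly 100, 200, or 300).
#'   When `NULL` the dimension of the first line is adopted; otherwise a
#'   mismatch with the first line is fatal.
#' @return An `embedding_table`: list with `vectors` (token-by-`d` matrix,
#'   rownames are tokens) and `dimension`.
#' @export
load_embeddings <- function(path, dimension = NULL) {
  if (!file.exists(path)) {
    stop("embedding file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty embedding file: ", path, call. = FALSE)
  parts <- strsplit(lines, "[ \t]+")
  d0 <- length(parts[[1]]) - 1L
  if (d0 < 1) stop("first embedding line has no vector components",
                   call. = FALSE)
  if (!is.null(dimension) && dimension != d0) {
    stop("embedding dimension mismatch: expected ", dimension,
         ", file has ", d0, call. = FALSE)
  }
  lens <- lengths(parts)
  good <- lens == d0 + 1L
  tokens <- vapply(parts[good], `[[`, "", 1L)
  vals <- suppressWarnings(
    as.numeric(unlist(lapply(parts[good], `[`, -1L), use.names = FALSE)))
  mat <- matrix(vals, ncol = d0, byrow = TRUE)
  bad_num <- rowSums(is.na(mat)) > 0
  n_skipped <- sum(!good) + sum(bad_num)
  if (n_skipped > 0) {
    warning("skipped ", n_skipped, " malformed embedding line(s)",
            call. = FALSE)
  }
  tokens <- tokens[!bad_num]
  mat <- mat[!bad_num, , drop = FALSE]
  dup <- duplicated(tokens)
  if (any(dup)) {
    warning("dropped ", sum(dup), " duplicate token line(s), keeping first",
            call. = FALSE)
    tokens <- tokens[!dup]
    mat <- mat[!dup, , drop = FALSE]
  }
  rownames(mat) <- tokens
  structure(list(vectors = mat, dimension = d0), class = "embedding_table")
}

#' Build an embedding table from a matrix
#'
#' @param vectors Numeric matrix with tokens as rownames.
#' @return An `embedding_table`.
#' @export
as_embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)),
            !anyDuplicated(rownames(vectors)))
  structure(list(vectors = vectors, dimension = ncol(vectors)),
            class = "embedding_table")
}

#' Write an embedding table in GloVe text format
#'
#' @param emb An `embedding_table`.
#' @param path Output path.
#' @param digits Significant digits per component.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path, digits = 12) {
  m <- emb$vectors
  rows <- apply(m, 1, function(v)
    paste(formatC(v, digits = digits, format = "g"), collapse = " "))
  writeLines(paste(rownames(m), rows), path)
  invisible(path)
}

#' Align a lexicon with an embedding table
#'
#' Retains exactly the signs whose normalized gloss has an embedding
#' vector, then builds one SVD-reduced phonological space per requested
#' scope over the retained entries, so that semantic vectors and every
#' phonological space share one sign order.
#'
#' @param lex A deduplicated `sign_lexicon`.
#' @param emb An `embedding_table`.
#' @param scopes Character vector of scope names (see [scope_names]).
#' @param svd_rank Retained SVD rank per scope; `NULL` keeps the full rank.
#'   Values above a scope's rank are capped.
#' @return An `aligned_lexicon`: list with `entries` (the retained
#'   `sign_lexicon`), `sem_vectors` (aligned embedding rows), `phono_spaces`
#'   (named list of reduced `phono_space`), `n`, and `dropped` (glosses with
#'   no embedding).
#' @export
align_lexicon <- function(lex, emb,
                          scopes = c("handshape", "location", "movement",
                                     "entire"),
                          svd_rank = 50L) {
  stopifnot(inherits(emb, "embedding_table"))
  scopes <- match.arg(scopes, scope_names(), several.ok = TRUE)
  hit <- lex$gloss %in% rownames(emb$vectors)
  if (!any(hit)) {
    stop("no overlap between lexicon glosses and embedding vocabulary",
         call. = FALSE)
  }
  entries <- lex[hit, , drop = FALSE]
  rownames(entries) <- NULL
  message("align_lexicon: ", sum(hit), " of ", nrow(lex),
          " signs have embedding vectors (", sum(!hit), " dropped)")
  sem <- emb$vectors[entries$gloss, , drop = FALSE]
  spaces <- lapply(scopes, function(sc) {
    sp <- build_onehot(entries, sc)
    k <- if (is.null(svd_rank)) min(dim(sp$onehot)) else
      min(as.integer(svd_rank), min(dim(sp$onehot)))
    reduce_svd(sp, k)
  })
  names(spaces) <- scopes
  structure(list(entries = entries, sem_vectors = sem,
                 phono_spaces = spaces, n = nrow(entries),
                 dropped = lex$gloss[!hit]),
            class = "aligned_lexicon")
}

#' Semantic cosine similarity between two signs
#'
#' Cosine of the embedding vectors of signs `i` and `j` of an aligned
#' lexicon. `NA` for zero vectors (same undefined-pair contract as
#' [phono_similarity]).
#'
#' @param al An `aligned_lexicon`.
#' @param i,j Sign indices (vectors allowed, recycled pairwise).
#' @return Cosine values in `[-1, 1]`.
#' @export
sem_similarity <- function(al, i, j) {
  cosine_pairs(al$sem_vectors, i, j)
}
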