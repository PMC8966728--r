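#' Enumerate all unordered sign pairs
#'
#' Lexicographic enumeration of the `n(n-1)/2` unordered index pairs
#' `(i, j)` with `i < j`.
#'
#' @param n Number of signs, or an `aligned_lexicon`.
#' @return A `pair_table`: data frame with integer columns `i`, `j` and an
#'   `n_signs` attribute.
#' @examples
#' nrow(enumerate_pairs(1946))  # 1892485
#' @export
enumerate_pairs <- function(n) {
  if (inherits(n, "aligned_lexicon")) n <- n$n
  n <- as.integer(n)
  if (is.na(n) || n < 2) {
    stop("need at least 2 signs to enumerate pairs, got ", n, call. = FALSE)
  }
  pt <- data.frame(i = rep.int(seq_len(n - 1L), times = (n - 1L):1L),
                   j = sequence((n - 1L):1L, from = 2:n))
  structure(pt, class = c("pair_table", "data.frame"), n_signs = n)
}

#' Attach semantic and phonological similarities to a pair table
#'
#' For every pair, computes the semantic cosine and one phonological cosine
#' per scope. Pairs with an undefined similarity in a scope (zero-norm
#' vector) carry `NA` in that column and are dropped listwise from that
#' scope's correlation downstream.
#'
#' @param pt A `pair_table` from [enumerate_pairs] (or any data frame with
#'   `i`, `j` columns).
#' @param al An `aligned_lexicon` whose spaces cover the requested scopes.
#' @param scopes Scope names; defaults to those built in `al`.
#' @return The pair table with columns `sem_sim` and `phono_<scope>` added.
#' @export
fill_similarities <- function(pt, al, scopes = names(al$phono_spaces)) {
  scopes <- match.arg(scopes, names(al$phono_spaces), several.ok = TRUE)
  full <- isTRUE(nrow(pt) == al$n * (al$n - 1) / 2)
  if (full) {
    # complete enumeration: blockwise upper-triangle kernels, no n x n matrix
    pt$sem_sim <- cosine_upper(al$sem_vectors)
    for (sc in scopes) {
      pt[[paste0("phono_", sc)]] <- cosine_upper(al$phono_spaces[[sc]]$reduced)
    }
  } else {
    pt$sem_sim <- sem_similarity(al, pt$i, pt$j)
    for (sc in scopes) {
      pt[[paste0("phono_", sc)]] <-
        phono_similarity(al$phono_spaces[[sc]], pt$i, pt$j)
    }
  }
  pt
}

#' Pearson correlation with t-based significance
#'
#' Sample Pearson coefficient with the usual t transform
#' `t = r * sqrt(df / (1 - r^2))`, `df = n - 2`, two-sided p-value. `NA`
#' pairs are dropped listwise. A zero-variance argument yields a degenerate
#' result (`r = NA`, `degenerate = TRUE`) rather than an error so sweep
#' grids can keep the record.
#'
#' @param x,y Numeric vectors of equal length.
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row data frame: `r`, `df`, `p`, `n_pairs`, `significant`,
#'   `degenerate`.
#' @export
pearson_cor <- function(x, y, alpha = 0.001) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  m <- length(x)
  degen <- m < 3 || stats::var(x) == 0 || stats::var(y) == 0
  if (degen) {
    return(data.frame(r = NA_real_, df = max(m - 2L, 0L), p = NA_real_,
                      n_pairs = m, significant = NA, degenerate = TRUE))
  }
  r <- stats::cor(x, y)
  df <- m - 2L
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  data.frame(r = r, df = df, p = p, n_pairs = m,
             significant = p < alpha, degenerate = FALSE)
}

#' Lexicon-wide pairwise correlation analysis
#'
#' Enumerates all unordered sign pairs of an aligned lexicon, fills in
#' semantic and per-scope phonological similarities, and reports one
#' Pearson correlation (with `df = n_pairs - 2`) per scope.
#'
#' @param al An `aligned_lexicon`.
#' @param scopes Scope names; defaults to those built in `al`.
#' @param alpha Significance level.
#' @param keep_pairs If `TRUE`, the filled pair table is attached as the
#'   `"pairs"` attribute of the result (large: `n(n-1)/2` rows).
#' @return Data frame with one row per scope: `scope`, `r`, `df`, `p`,
#'   `n_pairs`, `significant`, `degenerate`.
#' @export
run_pairwise <- function(al, scopes = names(al$phono_spaces), alpha = 0.001,
                         keep_pairs = FALSE) {
  pt <- enumerate_pairs(al)
  pt <- fill_similarities(pt, al, scopes)
  res <- do.call(rbind, lapply(scopes, function(sc) {
    cbind(scope = sc, pearson_cor(pt$sem_sim, pt[[paste0("phono_", sc)]],
                                  alpha = alpha))
  }))
  rownames(res) <- NULL
  n_undef <- sum(is.na(pt[setdiff(names(pt), c("i", "j"))]))
  if (n_undef > 0) {
    message("run_pairwise: ", n_undef,
            " undefined similarity value(s) excluded listwise")
  }
  if (keep_pairs) attr(res, "pairs") <- pt
  res
}
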