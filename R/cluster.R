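#' Ward hierarchical clustering of semantic vectors
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances (the `"ward.D2"` linkage, whose merge heights are the
#' square-root form of the Ward cost, so two singletons merge at their
#' Euclidean distance). Merge heights are non-decreasing.
#'
#' @param vectors Numeric matrix, one row per sign (typically the semantic
#'   vectors of an `aligned_lexicon` at their native embedding dimension).
#' @return A `linkage_tree`: list wrapping the `hclust` object with
#'   `n_leaves`, `heights` (sorted merge heights), and `max_height`.
#' @export
ward_linkage <- function(vectors) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, ncol = 1)
  n <- nrow(vectors)
  if (n < 2) stop("need at least 2 points to cluster", call. = FALSE)
  hc <- stats::hclust(stats::dist(vectors), method = "ward.D2")
  structure(list(hclust = hc, n_leaves = n, heights = hc$height,
                 max_height = max(hc$height)),
            class = "linkage_tree")
}

#' Cut a linkage tree at a percentage of its maximum merge height
#'
#' Flat clusters are the connected components left after removing all
#' merges above `height_percent / 100 * max_height`. At 0% (with distinct
#' points) every sign is its own cluster; at 100% there is a single
#' cluster. Cluster ids are numbered by first appearance in sign order.
#'
#' @param tree A `linkage_tree`.
#' @param height_percent Pruning height in `[0, 100]`.
#' @return A `cluster_solution`: list with `height_percent`, `cut_height`,
#'   `labels` (integer per sign), and `n_clusters`.
#' @export
cut_at_percent <- function(tree, height_percent) {
  stopifnot(inherits(tree, "linkage_tree"),
            height_percent >= 0, height_percent <= 100)
  h <- height_percent / 100 * tree$max_height
  labels <- stats::cutree(tree$hclust, h = h)
  structure(list(height_percent = height_percent, cut_height = h,
                 labels = as.integer(labels),
                 n_clusters = max(labels)),
            class = "cluster_solution")
}

#' Cut a linkage tree into exactly k clusters
#'
#' Convenience cut used when the target granularity (e.g. the number of
#' planted clusters of a synthetic lexicon) is known.
#'
#' @param tree A `linkage_tree`.
#' @param k Number of clusters.
#' @return A `cluster_solution`; `height_percent` is the smallest percent
#'   of `max_height` that yields `k` clusters.
#' @export
cut_at_k <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"), k >= 1, k <= tree$n_leaves)
  labels <- stats::cutree(tree$hclust, k = k)
  # height interval producing k clusters: between the (n-k)th and (n-k+1)th merge
  hs <- sort(tree$heights)
  n <- tree$n_leaves
  lo <- if (k == n) 0 else hs[n - k]
  structure(list(height_percent = 100 * lo / tree$max_height,
                 cut_height = lo, labels = as.integer(labels),
                 n_clusters = max(labels)),
            class = "cluster_solution")
}

#' Mean silhouette score of a clustering
#'
#' Per-point silhouette `(b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to the point's own cluster and `b` the smallest mean distance
#' to another cluster, averaged over all points; points in singleton
#' clusters contribute 0. Undefined (`NA`) when there are fewer than 2
#' clusters or every cluster is a singleton.
#'
#' @param vectors Numeric matrix of points, or `NULL` when `dists` is given.
#' @param labels Integer cluster labels.
#' @param dists Optional precomputed `dist` object (reused across a height
#'   sweep).
#' @return Mean silhouette in `[-1, 1]`, or `NA` when undefined.
#' @export
silhouette_score <- function(vectors, labels, dists = NULL) {
  k <- length(unique(labels))
  n <- length(labels)
  if (k < 2 || k == n) return(NA_real_)
  if (is.null(dists)) dists <- stats::dist(vectors)
  sil <- cluster::silhouette(labels, dists)
  mean(sil[, "sil_width"])
}

#' Unordered sign pairs that do not cross cluster boundaries
#'
#' The union over clusters of all within-cluster unordered pairs, in
#' lexicographic order. A solution of all singletons yields zero pairs.
#'
#' @param sol A `cluster_solution` (or a bare integer label vector).
#' @return A `pair_table` (data frame with `i`, `j`), possibly empty.
#' @export
within_cluster_pairs <- function(sol) {
  labels <- if (inherits(sol, "cluster_solution")) sol$labels else sol
  idx <- split(seq_along(labels), labels)
  idx <- idx[lengths(idx) >= 2]
  if (length(idx) == 0) {
    return(structure(data.frame(i = integer(0), j = integer(0)),
                     class = c("pair_table", "data.frame"),
                     n_signs = length(labels)))
  }
  ii <- unlist(lapply(idx, function(v) {
    s <- length(v)
    v[rep.int(seq_len(s - 1L), times = (s - 1L):1L)]
  }), use.names = FALSE)
  jj <- unlist(lapply(idx, function(v) {
    s <- length(v)
    v[sequence((s - 1L):1L, from = 2:s)]
  }), use.names = FALSE)
  ord <- order(ii, jj)
  structure(data.frame(i = ii[ord], j = jj[ord]),
            class = c("pair_table", "data.frame"),
            n_signs = length(labels))
}

#' Pruning-height sweep with silhouettes and within-cluster correlations
#'
#' For each requested embedding dimension and pruning height: cluster the
#' semantic vectors (Ward), record the cluster count and silhouette score,
#' pool all within-cluster sign pairs, and compute one pooled Pearson
#' correlation between semantic and phonological similarity per scope.
#' Heights yielding fewer than 3 within-cluster pairs keep their record
#' with the correlation marked undefined. At 100% the pooled pair set is
#' the complete enumeration, so the correlations equal the lexicon-wide
#' pairwise ones.
#'
#' All pairwise similarities are computed once per aligned lexicon and
#' indexed per height, so the sweep cost is dominated by a single
#' upper-triangle pass per similarity space.
#'
#' @param als An `aligned_lexicon`, or a named list of them (names are
#'   embedding dimensions, e.g. `list("100" = al100, "300" = al300)`).
#' @param heights Pruning-height percents; default `1:100` (0% is
#'   degenerate — all singletons — and excluded by default).
#' @param scopes Scope names; default those of the (first) aligned lexicon.
#' @param alpha Significance level per record (no family-wise correction;
#'   set `bonferroni = TRUE` to divide `alpha` by the number of records).
#' @param bonferroni Apply a Bonferroni correction across the grid.
#' @return A `sweep_result` data frame: one row per (dimension, height,
#'   scope) with `n_clusters`, `silhouette`, `n_within_pairs`, `r`, `df`,
#'   `p`, `significant`, `degenerate`.
#' @export
run_sweep <- function(als, heights = 1:100,
                      scopes = NULL, alpha = 0.001, bonferroni = FALSE) {
  if (inherits(als, "aligned_lexicon")) {
    als <- stats::setNames(list(als), ncol(als$sem_vectors))
  }
  stopifnot(all(heights >= 0), all(heights <= 100))
  if (is.null(scopes)) scopes <- names(als[[1]]$phono_spaces)
  n_records <- length(als) * length(heights) * length(scopes)
  a_eff <- if (bonferroni) alpha / n_records else alpha
  out <- vector("list", n_records)
  rec <- 0L
  for (dim_name in names(als)) {
    al <- als[[dim_name]]
    n <- al$n
    dists <- stats::dist(al$sem_vectors)
    tree <- ward_linkage(al$sem_vectors)
    sem_all <- cosine_upper(al$sem_vectors)
    phono_all <- lapply(scopes, function(sc)
      cosine_upper(al$phono_spaces[[sc]]$reduced))
    names(phono_all) <- scopes
    for (h in heights) {
      sol <- cut_at_percent(tree, h)
      silh <- silhouette_score(NULL, sol$labels, dists = dists)
      wp <- within_cluster_pairs(sol)
      pos <- pair_position(wp$i, wp$j, n)
      x <- sem_all[pos]
      for (sc in scopes) {
        res <- pearson_cor(x, phono_all[[sc]][pos], alpha = a_eff)
        rec <- rec + 1L
        out[[rec]] <- data.frame(
          dimension = as.integer(dim_name), height_percent = h, scope = sc,
          n_clusters = sol$n_clusters,
          silhouette = if (is.na(silh)) NA_real_ else silh,
          n_within_pairs = nrow(wp),
          r = res$r, df = res$df, p = res$p,
          significant = res$significant, degenerate = res$degenerate)
      }
    }
  }
  grid <- do.call(rbind, out)
  rownames(grid) <- NULL
  structure(grid, class = c("sweep_result", "data.frame"),
            alpha = alpha, bonferroni = bonferroni)
}

#' Extract the clusters containing given glosses
#'
#' Post-hoc inspection helper: returns every cluster of a solution that
#' contains at least one query gloss, together with its full membership
#' and its within-cluster pair similarities per scope.
#'
#' @param sol A `cluster_solution`.
#' @param al The `aligned_lexicon` the solution was computed on.
#' @param query_glosses Character vector of (raw or normalized) glosses.
#' @param scopes Scope names for the pair similarities.
#' @return List with `membership` (data frame gloss/cluster) and `pairs`
#'   (filled pair table restricted to the matched clusters, with gloss
#'   columns). Empty, with a warning, when no query gloss is found.
#' @export
extract_cluster <- function(sol, al, query_glosses,
                            scopes = names(al$phono_spaces)) {
  q <- normalize_gloss(query_glosses)
  hit <- match(q, al$entries$gloss)
  if (all(is.na(hit))) {
    warning("none of the query glosses are in the aligned lexicon",
            call. = FALSE)
    return(list(membership = data.frame(gloss = character(0),
                                        cluster = integer(0)),
                pairs = NULL))
  }
  clusters <- unique(sol$labels[hit[!is.na(hit)]])
  members <- which(sol$labels %in% clusters)
  membership <- data.frame(gloss = al$entries$gloss[members],
                           cluster = sol$labels[members])
  sub <- within_cluster_pairs(sol)
  sub <- sub[sol$labels[sub$i] %in% clusters, , drop = FALSE]
  sub <- fill_similarities(sub, al, scopes)
  sub$gloss_i <- al$entries$gloss[sub$i]
  sub$gloss_j <- al$entries$gloss[sub$j]
  list(membership = membership, pairs = sub)
}
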