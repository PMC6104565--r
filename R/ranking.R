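# PDS -> PDSz, subtype aggregation, top-k ranking, cross-dataset consensus,
# and clustering of subtype deregulation profiles.

#' Row-wise z-score transform of a PDS matrix
#'
#' Standardises each pathway row over all samples of the run (tumors and
#' controls together).  Rows with zero spread become all-zero and are
#' flagged degenerate.
#'
#' @param pds a `PDSMatrix`.
#' @return object of class `PDSzMatrix`: list with `scores` (standardised
#'   matrix) and `degenerate` (named logical per row).
#' @export
pdsz_transform <- function(pds) {
  stopifnot(inherits(pds, "PDSMatrix") || is.matrix(pds))
  m <- if (is.matrix(pds)) pds else pds$scores
  if (length(m) == 0) stop("empty PDS matrix", call. = FALSE)
  mu <- rowMeans(m)
  sd <- row_sds(m)
  degenerate <- sd < 1e-12
  z <- (m - mu) / ifelse(degenerate, 1, sd)
  z[degenerate, ] <- 0
  if (any(degenerate)) {
    warning(sprintf(
      "%d constant PDS row(s) set to zero: %s",
      sum(degenerate), paste(rownames(m)[degenerate], collapse = ", ")
    ), call. = FALSE)
  }
  structure(
    list(scores = z, degenerate = stats::setNames(degenerate, rownames(m))),
    class = "PDSzMatrix"
  )
}

#' Median PDSz per pathway for one tumor subtype
#'
#' Aggregates a PDSz matrix to one deregulation value per pathway by taking
#' the median over the subtype's tumor samples (controls are excluded).
#'
#' @param pdsz a `PDSzMatrix`.
#' @param annotation sample annotation (`sample_id`, `subtype`).
#' @param subtype subtype label to aggregate.
#' @return named numeric vector, pathway id -> median PDSz.
#' @export
median_pdsz_by_subtype <- function(pdsz, annotation, subtype) {
  stopifnot(inherits(pdsz, "PDSzMatrix"))
  ids <- annotation$sample_id[annotation$subtype == subtype]
  ids <- intersect(ids, colnames(pdsz$scores))
  if (length(ids) == 0) {
    stop(sprintf("subtype '%s' has no samples in the matrix", subtype), call. = FALSE)
  }
  apply(pdsz$scores[, ids, drop = FALSE], 1, stats::median)
}

#' Top-k most deregulated pathways
#'
#' @param ranking named numeric vector (pathway -> median PDSz).
#' @param k number of pathways to return (default 30).
#' @return character vector of pathway ids, descending score; ties broken
#'   lexicographically by pathway id.  If fewer than `k` pathways exist, all
#'   are returned with a warning.
#' @export
top_k_pathways <- function(ranking, k = 30) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  ord <- order(-ranking, names(ranking))
  ids <- names(ranking)[ord]
  if (length(ids) < k) {
    warning(sprintf(
      "only %d pathways available for top-%d selection", length(ids), k
    ), call. = FALSE)
    return(ids)
  }
  ids[seq_len(k)]
}

#' Cross-dataset consensus of top-k lists
#'
#' The consensus deregulated pathways of a subtype are those appearing in
#' the top-k lists of both datasets; reported ordered by the mean of the two
#' dataset ranks.
#'
#' @param top_a,top_b ordered pathway id vectors from the two datasets.
#' @return data.frame with `pathway`, `rank_a`, `rank_b`, `mean_rank`,
#'   ordered by `mean_rank` then pathway id.
#' @export
cross_dataset_intersection <- function(top_a, top_b) {
  ids <- intersect(top_a, top_b)
  res <- data.frame(
    pathway = ids,
    rank_a = match(ids, top_a),
    rank_b = match(ids, top_b),
    stringsAsFactors = FALSE
  )
  res$mean_rank <- (res$rank_a + res$rank_b) / 2
  res[order(res$mean_rank, res$pathway), , drop = FALSE]
}

#' Hierarchical clustering of subtype deregulation profiles
#'
#' Agglomerative clustering of median-PDSz profiles with correlation
#' distance (1 - Pearson) and average linkage, used to ask whether profiles
#' group by biological condition or by platform.
#'
#' @param profiles named list of named numeric vectors (pathway -> median
#'   PDSz), one per (subtype, dataset) profile, over a shared pathway
#'   universe.
#' @return an [stats::hclust] tree over the profiles.
#' @export
cluster_subtype_profiles <- function(profiles) {
  if (length(profiles) < 2) stop("need at least 2 profiles to cluster", call. = FALSE)
  shared <- Reduce(intersect, lapply(profiles, names))
  if (length(shared) < 2) stop("profiles share fewer than 2 pathways", call. = FALSE)
  m <- do.call(rbind, lapply(profiles, function(p) p[shared]))
  rownames(m) <- names(profiles)
  d <- profile_correlation_distance(m)
  stats::hclust(stats::as.dist(d), method = "average")
}

# 1 - Pearson correlation between profile rows, clipped at 0 for numerical
# noise; exported logic kept internal, tests reach it through the tree.
profile_correlation_distance <- function(m) {
  d <- 1 - stats::cor(t(m))
  d[d < 0] <- 0
  d
}
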