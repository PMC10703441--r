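# Redundancy reduction.  Significant gene sets that significantly share
# member genes (overlap ratio > 33% of the smaller set AND Bonferroni
# corrected one-tailed Fisher's exact test p < 5%) are merged into
# non-redundant supersets (connected components of the qualifying-overlap
# graph), re-tested for enrichment, and annotated with their top pathway
# labels by hypergeometric overlap.

#' One-tailed Fisher's exact (hypergeometric) overlap test
#'
#' Upper-tail probability `P(X >= n_shared)` for
#' `X ~ Hypergeometric(universe_size, |a|, |b|)`, plus the overlap ratio
#' `n_shared / min(|a|, |b|)`.
#'
#' @param a,b Character gene-id vectors.
#' @param universe_size Size of the gene universe (>= `|a U b|`).
#' @return List: `n_shared`, `ratio`, `fet_p`.
#' @export
fet_overlap <- function(a, b, universe_size) {
  a <- unique(a); b <- unique(b)
  nu <- length(union(a, b))
  if (universe_size < nu)
    stop(sprintf("universe_size (%d) smaller than |a U b| (%d)",
                 universe_size, nu), call. = FALSE)
  n_shared <- length(intersect(a, b))
  ratio <- if (min(length(a), length(b)) == 0L) 0 else
    n_shared / min(length(a), length(b))
  fet_p <- stats::phyper(n_shared - 1L, length(a),
                         universe_size - length(a), length(b),
                         lower.tail = FALSE)
  list(n_shared = n_shared, ratio = ratio, fet_p = fet_p)
}

#' Merge significantly overlapping gene sets into supersets
#'
#' All pairs among the input (MSEA-significant) sets are tested; an edge is
#' drawn when `ratio > ratio_min` AND the Bonferroni-adjusted FET p (over
#' the number of pairs tested in this round) is `< alpha`.  Supersets are
#' the connected components; their gene content is the union of member
#' sets.  Ids are assigned by decreasing component size, ties by the
#' lexicographically smallest member id, so the result is order-independent.
#'
#' @param sets Named list of gene-id vectors (the significant sets).
#' @param universe_size Gene-universe size for the FET.
#' @param ratio_min Overlap-ratio threshold (default 0.33; denominator is
#'   the smaller set).
#' @param alpha Significance level for the adjusted FET p (default 0.05).
#' @param adjust `"bonferroni"` (default) or `"none"` (raw p variant).
#' @return List of `superset` objects: `superset_id`, `member_sets`,
#'   `genes`.
#' @export
merge_supersets <- function(sets, universe_size, ratio_min = 0.33,
                            alpha = 0.05, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  if (length(sets) == 0L) return(list())
  ids <- sort(names(sets))
  sets <- lapply(sets[ids], unique)
  k <- length(ids)
  edges <- matrix(character(0), ncol = 2)
  if (k >= 2L) {
    pairs <- utils::combn(k, 2L)
    n_pairs <- ncol(pairs)
    qual <- logical(n_pairs)
    for (j in seq_len(n_pairs)) {
      ov <- fet_overlap(sets[[pairs[1L, j]]], sets[[pairs[2L, j]]],
                        universe_size)
      p_adj <- if (adjust == "bonferroni") min(1, ov$fet_p * n_pairs) else
        ov$fet_p
      qual[j] <- ov$ratio > ratio_min && p_adj < alpha
    }
    edges <- cbind(ids[pairs[1L, qual]], ids[pairs[2L, qual]])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = ids)
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[[`, character(1), 1L))
  groups <- groups[ord]
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    members <- groups[[i]]
    out[[i]] <- structure(
      list(superset_id = sprintf("SS%03d", i), member_sets = members,
           genes = sort(unique(unlist(sets[members], use.names = FALSE)))),
      class = "superset")
  }
  out
}

#' Re-test supersets for enrichment
#'
#' Each superset's union gene set is re-scored with [msea_test()]; the
#' result is stored in `$retest` and `$confirmed` flags FDR < `fdr_max`.
#' Failing supersets are retained in the output (flagged) but excluded from
#' downstream stages by default.
#'
#' @param supersets List of `superset` objects.
#' @param ctx An [msea_context()].
#' @param grid,n_perm,seed,kappa Passed to [msea_test()].
#' @param fdr_max Strict FDR threshold (default 0.05).
#' @return The supersets with `retest` (one-row data.frame) and `confirmed`
#'   fields added.
#' @export
confirm_supersets <- function(supersets, ctx, grid = make_grid(),
                              n_perm = 1000L, seed = 1L, kappa = 1,
                              fdr_max = 0.05) {
  if (length(supersets) == 0L) return(supersets)
  coll <- lapply(supersets, `[[`, "genes")
  names(coll) <- vapply(supersets, `[[`, character(1), "superset_id")
  res <- msea_test(coll, ctx, grid, n_perm, seed, kappa)
  for (i in seq_along(supersets)) {
    row <- res[res$SET_ID == supersets[[i]]$superset_id, , drop = FALSE]
    supersets[[i]]$retest <- row
    supersets[[i]]$confirmed <- isTRUE(!row$SKIPPED & !is.na(row$FDR) &
                                         row$FDR < fdr_max)
  }
  supersets
}

#' Annotate a gene set with its top overlapping pathway labels
#'
#' Hypergeometric upper-tail p per pathway, Bonferroni-corrected over the
#' pathway count; pathways with corrected p < `alpha` sharing >= `min_shared`
#' genes qualify, and the top `top_n` by p are reported.  If none qualify,
#' the fallback (raw p < `fallback_p`, >= `min_shared` shared genes) is used
#' and labels are suffixed with `*`.
#'
#' @param genes Gene-id vector (e.g. a superset's content).
#' @param pathways Named list of pathway gene-id vectors.
#' @param universe_size Gene-universe size.
#' @param top_n Number of labels to keep (default 5).
#' @param min_shared Minimum shared genes (default 5).
#' @param alpha Corrected-p threshold (default 0.05).
#' @param fallback_p Raw-p fallback threshold (default 5e-3).
#' @return data.frame `PATHWAY`, `N_SHARED`, `P`, `P_ADJ`, `FALLBACK`,
#'   at most `top_n` rows ordered by p.
#' @export
annotate_set <- function(genes, pathways, universe_size, top_n = 5L,
                         min_shared = 5L, alpha = 0.05, fallback_p = 5e-3) {
  stopifnot(length(pathways) > 0L)
  genes <- unique(genes)
  m <- length(pathways)
  p <- numeric(m); sh <- integer(m)
  for (i in seq_len(m)) {
    ov <- fet_overlap(genes, pathways[[i]], universe_size)
    p[i] <- ov$fet_p; sh[i] <- ov$n_shared
  }
  p_adj <- pmin(1, p * m)
  keep <- p_adj < alpha & sh >= min_shared
  fallback <- FALSE
  if (!any(keep)) {
    keep <- p < fallback_p & sh >= min_shared
    fallback <- TRUE
  }
  out <- data.frame(PATHWAY = names(pathways)[keep], N_SHARED = sh[keep],
                    P = p[keep], P_ADJ = p_adj[keep],
                    FALLBACK = rep(fallback, sum(keep)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$P, out$PATHWAY), , drop = FALSE]
  out <- utils::head(out, top_n)
  if (fallback && nrow(out) > 0L)
    out$PATHWAY <- paste0(out$PATHWAY, "*")
  rownames(out) <- NULL
  out
}
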