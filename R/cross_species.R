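# Cross-species superset comparison.  Supersets from two species are
# brought into a common identifier space through a 1:1 ortholog table and
# matched by gene overlap: a pair is a match when the adjusted
# hypergeometric (one-tailed FET) p is < 5% AND either the two-sided
# Jaccard index exceeds 50% or a one-sided overlap exceeds 90% (subset
# relationship).  A superset may match several counterparts, so the shared
# counts per species can legitimately differ.

#' Translate a gene set through a 1:1 ortholog table
#'
#' Unmappable genes are dropped (count reported via message); the mapped
#' core translates bijectively, so translate-then-back-translate is the
#' identity on mappable genes.
#'
#' @param genes Character gene-id vector.
#' @param table Ortholog data.frame (`GENE_A`, `GENE_B`), 1:1.
#' @param direction `"ab"` (A ids to B ids) or `"ba"`.
#' @return Character vector of translated ids (unique).
#' @export
translate_genes <- function(genes, table, direction = c("ab", "ba")) {
  direction <- match.arg(direction)
  if (is.null(table) || nrow(table) == 0L)
    stop("empty ortholog table", call. = FALSE)
  from <- if (direction == "ab") table$GENE_A else table$GENE_B
  to <- if (direction == "ab") table$GENE_B else table$GENE_A
  genes <- unique(as.character(genes))
  hit <- match(genes, from)
  n_drop <- sum(is.na(hit))
  if (n_drop > 0L)
    message(sprintf("translate_genes: dropped %d unmappable gene(s)", n_drop))
  out <- unique(to[hit[!is.na(hit)]])
  if (length(out) == 0L)
    warning("no genes could be translated", call. = FALSE)
  out
}

#' Jaccard index of two gene sets
#'
#' `|A n B| / |A u B| = n / (|A| + |B| - n)`; 0 for two empty sets by
#' convention.
#'
#' @param a,b Character gene-id vectors (common id space).
#' @return Fraction in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  n <- length(intersect(a, b))
  d <- length(a) + length(b) - n
  if (d == 0L) 0 else n / d
}

#' Match supersets across species and classify shared vs specific
#'
#' Each species-A superset is translated into species-B id space (via the
#' mappable ortholog core; unmappable genes are excluded from both
#' numerator and denominator) and tested against every species-B superset.
#' A pair matches when the adjusted FET p is < `alpha` AND either
#' `jaccard > jaccard_min` (rule `"two_sided"`) or
#' `max(one-sided overlaps) > one_sided_min` (rule `"one_sided"`; two-sided
#' takes precedence in reporting).  Adjustment is Bonferroni over all pairs
#' tested (BH via `adjust = "BH"`).  Classification: a superset is shared
#' if it has >= 1 match, otherwise species-specific.
#'
#' @param sets_a,sets_b Named lists of gene-id vectors (species A / B ids).
#' @param table 1:1 ortholog data.frame (`GENE_A`, `GENE_B`).
#' @param universe_size Hypergeometric universe; defaults to the
#'   ortholog-mappable gene count `nrow(table)`.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param jaccard_min Two-sided threshold (default 0.5).
#' @param one_sided_min One-sided threshold (default 0.9).
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return List with `matches` (data.frame `SET_A`, `SET_B`, `N_SHARED`,
#'   `JI`, `ONE_SIDED_A`, `ONE_SIDED_B`, `FET_P`, `FET_P_ADJ`, `MATCHED`,
#'   `RULE`) and `classification` (`shared_a`, `specific_a`, `shared_b`,
#'   `specific_b`).
#' @export
match_supersets <- function(sets_a, sets_b, table,
                            universe_size = nrow(table), alpha = 0.05,
                            jaccard_min = 0.5, one_sided_min = 0.9,
                            adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(sets_a) > 0L, length(sets_b) > 0L)
  trans_a <- lapply(sets_a, function(g)
    suppressMessages(translate_genes(g, table, "ab")))
  sets_b <- lapply(sets_b, function(g) unique(intersect(g, table$GENE_B)))
  ids_a <- names(sets_a); ids_b <- names(sets_b)
  grid_df <- expand.grid(ia = seq_along(ids_a), ib = seq_along(ids_b),
                         KEEP.OUT.ATTRS = FALSE)
  n_pairs <- nrow(grid_df)
  rows <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    a <- trans_a[[grid_df$ia[j]]]; b <- sets_b[[grid_df$ib[j]]]
    n_sh <- length(intersect(a, b))
    os_a <- if (length(a) == 0L) 0 else n_sh / length(a)
    os_b <- if (length(b) == 0L) 0 else n_sh / length(b)
    fet_p <- if (length(a) == 0L || length(b) == 0L) 1 else
      fet_overlap(a, b, universe_size)$fet_p
    rows[[j]] <- data.frame(
      SET_A = ids_a[grid_df$ia[j]], SET_B = ids_b[grid_df$ib[j]],
      N_SHARED = n_sh, JI = jaccard(a, b), ONE_SIDED_A = os_a,
      ONE_SIDED_B = os_b, FET_P = fet_p, stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, rows)
  m$FET_P_ADJ <- if (adjust == "bonferroni") pmin(1, m$FET_P * n_pairs) else
    stats::p.adjust(m$FET_P, "BH")
  two <- m$JI > jaccard_min
  one <- pmax(m$ONE_SIDED_A, m$ONE_SIDED_B) > one_sided_min
  m$MATCHED <- m$FET_P_ADJ < alpha & (two | one)
  m$RULE <- ifelse(!m$MATCHED, "none", ifelse(two, "two_sided", "one_sided"))
  shared_a <- sort(unique(m$SET_A[m$MATCHED]))
  shared_b <- sort(unique(m$SET_B[m$MATCHED]))
  list(matches = m,
       classification = list(
         shared_a = shared_a, specific_a = sort(setdiff(ids_a, shared_a)),
         shared_b = shared_b, specific_b = sort(setdiff(ids_b, shared_b))))
}
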