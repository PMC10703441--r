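# Marker-set enrichment analysis (MSEA).  Each gene set's LD-pruned eSNP
# set is scored for enrichment of strong GWAS signal across a grid of
# top-signal quantile cutoffs with the modified chi-square statistic
#   chi = sum_i (O_i - E_i) / sqrt(E_i + kappa),
# where O_i is the number of set markers ranking above the i-th cutoff in
# the GWAS p-value ranking of the pruned background, E_i = |set| * f_i is
# the expected count, and kappa (default 1) stabilizes small eSNP sets.
# Significance comes from a permutation null of size-matched random gene
# sets (Gaussian approximation by default), with Benjamini-Hochberg FDR
# across sets.

#' Quantile cutoff grid
#'
#' `n` top-signal fractions spaced from `f_top` down to `f_bottom`
#' (inclusive), log-spaced by default; defaults follow the top 50 percent to
#' top 99.9 percent (fraction 0.001) convention with 10 points.
#'
#' @param n Number of cutoffs (>= 2).
#' @param f_top,f_bottom Largest and smallest top fractions, with
#'   `0 < f_bottom < f_top < 1`.
#' @param spacing `"log"` (default) or `"linear"`.
#' @return A `quantile_grid` numeric vector (strictly decreasing).
#' @export
make_grid <- function(n = 10L, f_top = 0.5, f_bottom = 0.001,
                      spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (!is.numeric(n) || n < 2L) stop("n must be >= 2", call. = FALSE)
  if (!(0 < f_bottom && f_bottom < f_top && f_top < 1))
    stop("need 0 < f_bottom < f_top < 1", call. = FALSE)
  f <- if (spacing == "log") exp(seq(log(f_top), log(f_bottom), length.out = n))
       else seq(f_top, f_bottom, length.out = n)
  structure(f, class = "quantile_grid")
}

#' Observed and expected counts over the cutoff grid
#'
#' Background markers are ranked by ascending GWAS p-value (ties broken by
#' marker id).  For each fraction `f_i` the cutoff rank is
#' `ceiling(f_i * N)`; `O_i` is the number of set markers at or above that
#' rank and `E_i = |set| * f_i` is the continuous expectation.
#'
#' @param esnp An `esnp_set` (or character vector of markers).
#' @param gwas GWAS data.frame covering the background.
#' @param background Character vector: the pruned background universe.
#' @param grid A [make_grid()] object.
#' @return List with integer `O`, numeric `E`, and `skip` (TRUE for an empty
#'   set).
#' @export
count_oe <- function(esnp, gwas, background, grid) {
  markers <- if (inherits(esnp, "esnp_set")) esnp$markers else
    unique(as.character(esnp))
  N <- length(background)
  if (N == 0L) stop("empty background", call. = FALSE)
  if (length(markers) == 0L)
    return(list(O = integer(length(grid)), E = numeric(length(grid)),
                skip = TRUE))
  if (!all(markers %in% background))
    stop("eSNP set contains markers outside the background", call. = FALSE)
  p <- gwas$PVALUE[match(background, gwas$MARKER)]
  if (anyNA(p)) stop("background markers missing GWAS p-values", call. = FALSE)
  rank_of <- order(order(p, background))
  r <- sort(rank_of[match(markers, background)])
  cutoffs <- ceiling(as.numeric(grid) * N)
  O <- findInterval(cutoffs, r)
  E <- length(markers) * as.numeric(grid)
  list(O = as.integer(O), E = E, skip = FALSE)
}

#' Modified chi-square quantile statistic
#'
#' @param O Integer vector of observed counts per cutoff.
#' @param E Numeric vector of expected counts (same length).
#' @param kappa Stability parameter (>= 0, default 1).
#' @return `sum((O - E) / sqrt(E + kappa))`, unclipped.
#' @export
chi_statistic <- function(O, E, kappa = 1) {
  if (length(O) != length(E)) stop("length(O) != length(E)", call. = FALSE)
  if (!is.numeric(kappa) || kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  sum((O - E) / sqrt(E + kappa))
}

#' Build a reusable MSEA context
#'
#' Filters the eQTL table, prunes the global marker universe once, ranks the
#' background by GWAS p-value, and indexes each gene's surviving markers by
#' background rank.  The mappable gene universe (genes with >= 1 surviving
#' eQTL marker) is the population from which permutation null sets are
#' drawn.
#'
#' @param gwas GWAS data.frame.
#' @param eqtl Raw eQTL data.frame.
#' @param ld LD data.frame.
#' @param tissue Tissue to analyse.
#' @param eqtl_fdr Strict eQTL FDR threshold (default 0.05).
#' @param cis_only Restrict to cis eQTLs.
#' @param keep LD-pruning retention rule (see [prune_ld()]).
#' @return An `msea_context` environment with fields `background` (ranked
#'   marker ids), `gene_ranks` (gene -> integer rank vector), `universe`
#'   (mappable genes), `eqtl`, `gwas`, `ld`.
#' @export
msea_context <- function(gwas, eqtl, ld, tissue, eqtl_fdr = 0.05,
                         cis_only = FALSE, keep = "min_p") {
  eq <- filter_eqtls(eqtl, eqtl_fdr, tissue, cis_only)
  universe_markers <- intersect(unique(eq$MARKER), gwas$MARKER)
  n_dropped <- length(setdiff(unique(eq$MARKER), gwas$MARKER))
  if (n_dropped > 0L)
    message(sprintf("msea_context: dropped %d eQTL marker(s) absent from GWAS",
                    n_dropped))
  pruned <- prune_ld(universe_markers, gwas, ld, keep = keep)
  p <- gwas$PVALUE[match(pruned, gwas$MARKER)]
  background <- pruned[order(p, pruned)]   # background index == rank
  eq_bg <- eq[eq$MARKER %in% background, , drop = FALSE]
  idx <- match(eq_bg$MARKER, background)
  gene_ranks <- lapply(split(idx, eq_bg$GENE),
                       function(v) sort(unique(v)))
  ctx <- new.env(parent = emptyenv())
  ctx$background <- background
  ctx$gene_ranks <- gene_ranks
  ctx$universe <- names(gene_ranks)
  ctx$eqtl <- eq
  ctx$gwas <- gwas
  ctx$ld <- ld
  ctx$tissue <- tissue
  ctx$null_cache <- new.env(parent = emptyenv())
  class(ctx) <- c("msea_context", "environment")
  ctx
}

# Background ranks of a gene set's eSNPs within a context (sorted, unique).
set_ranks <- function(genes, ctx) {
  sort(unique(unlist(ctx$gene_ranks[intersect(genes, ctx$universe)],
                     use.names = FALSE)))
}

# chi for a sorted rank vector against precomputed cutoff ranks.
chi_from_ranks <- function(r, cutoffs, frac, kappa) {
  O <- findInterval(cutoffs, r)
  E <- length(r) * frac
  sum((O - E) / sqrt(E + kappa))
}

#' Permutation null for a given gene-set size
#'
#' Draws `n_perm` uniform random gene sets of the given size from the
#' mappable gene universe, maps each through the context's eQTL/LD
#' machinery, and computes the chi statistic for each.  Nulls are cached in
#' the context keyed by set size (sets of equal size share a null), with a
#' size-derived seed so the cache is call-order independent.
#'
#' @param set_size Number of genes in the sets to emulate.
#' @param ctx An [msea_context()].
#' @param grid A [make_grid()] object.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Master seed.
#' @param kappa Stability parameter.
#' @return List with `mean`, `sd` and the numeric `sample` of null chi
#'   values.
#' @export
null_distribution <- function(set_size, ctx, grid, n_perm = 1000L, seed = 1L,
                              kappa = 1) {
  stopifnot(inherits(ctx, "msea_context"))
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  n_universe <- length(ctx$universe)
  if (n_universe <= set_size)
    stop("gene universe must be larger than set_size", call. = FALSE)
  key <- sprintf("s%d_p%d_k%g_g%s", set_size, n_perm, kappa,
                 paste(signif(as.numeric(grid), 6), collapse = ","))
  cached <- ctx$null_cache[[key]]
  if (!is.null(cached) && identical(cached$seed, seed)) return(cached)
  set.seed(derive_seed(seed, paste0("null_", set_size)))
  N <- length(ctx$background)
  frac <- as.numeric(grid)
  cutoffs <- ceiling(frac * N)
  gr <- ctx$gene_ranks
  chis <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    g <- sample.int(n_universe, set_size)
    r <- unique(sort(unlist(gr[g], use.names = FALSE)))
    chis[b] <- if (length(r) == 0L) 0 else
      chi_from_ranks(r, cutoffs, frac, kappa)
  }
  s <- stats::sd(chis)
  if (!is.finite(s) || s == 0)
    stop("degenerate permutation null (sd = 0); increase n_perm or the gene universe",
         call. = FALSE)
  out <- list(mean = mean(chis), sd = s, sample = chis, seed = seed)
  ctx$null_cache[[key]] <- out
  out
}

#' Marker-set enrichment test over a gene-set collection
#'
#' For each set: map to its pruned eSNP set, compute the observed chi,
#' standardize against the size-matched permutation null
#' (`z = (chi - mean) / sd`), take the one-sided upper-tail p (Gaussian by
#' default, empirical via `null_model = "empirical"`), and control FDR by
#' Benjamini-Hochberg across all tested sets.  Sets with empty eSNP sets
#' are skipped and reported with `NA` statistics.
#'
#' @param collection Named list of gene-id vectors.
#' @param ctx An [msea_context()].
#' @param grid A [make_grid()] object.
#' @param n_perm Permutations per set size (default 1000).
#' @param seed Master seed.
#' @param kappa Stability parameter (default 1).
#' @param null_model `"gaussian"` (default) or `"empirical"`.
#' @return data.frame with columns `SET_ID`, `N_GENES`, `N_ESNPS`, `CHI`,
#'   `NULL_MEAN`, `NULL_SD`, `Z`, `P`, `FDR`, `SKIPPED`, sorted by FDR then
#'   descending chi.
#' @export
msea_test <- function(collection, ctx, grid = make_grid(), n_perm = 1000L,
                      seed = 1L, kappa = 1,
                      null_model = c("gaussian", "empirical")) {
  stopifnot(inherits(ctx, "msea_context"), length(collection) > 0L)
  null_model <- match.arg(null_model)
  N <- length(ctx$background)
  frac <- as.numeric(grid)
  cutoffs <- ceiling(frac * N)
  ids <- names(collection)
  n <- length(ids)
  res <- data.frame(SET_ID = ids, N_GENES = lengths(collection),
                    N_ESNPS = NA_integer_, CHI = NA_real_,
                    NULL_MEAN = NA_real_, NULL_SD = NA_real_, Z = NA_real_,
                    P = NA_real_, FDR = NA_real_, SKIPPED = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    genes <- unique(collection[[i]])
    r <- set_ranks(genes, ctx)
    res$N_ESNPS[i] <- length(r)
    if (length(r) == 0L) { res$SKIPPED[i] <- TRUE; next }
    res$CHI[i] <- chi_from_ranks(r, cutoffs, frac, kappa)
    nd <- null_distribution(length(genes), ctx, grid, n_perm, seed, kappa)
    res$NULL_MEAN[i] <- nd$mean
    res$NULL_SD[i] <- nd$sd
    res$Z[i] <- (res$CHI[i] - nd$mean) / nd$sd
    res$P[i] <- if (null_model == "gaussian")
      stats::pnorm(res$Z[i], lower.tail = FALSE)
    else
      (sum(nd$sample >= res$CHI[i]) + 1) / (length(nd$sample) + 1)
  }
  tested <- !res$SKIPPED
  res$FDR[tested] <- stats::p.adjust(res$P[tested], method = "BH")
  res <- res[order(res$FDR, -res$CHI, res$SET_ID), ]
  rownames(res) <- NULL
  attr(res, "n_perm") <- n_perm
  res
}
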