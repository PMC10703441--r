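# Weighted key driver analysis (wKDA).  Candidate nodes of a directed
# gene-regulatory network are scored for enrichment of a disease-associated
# superset within their network neighborhood using the same modified
# chi-square form as MSEA, reduced to a single membership bin:
#   score = (O_w - E_w) / sqrt(E_w + kappa),
# where O_w is the summed edge weight from the candidate to neighbors that
# are superset members and E_w = W_total * |S_net| / |nodes| is its
# expectation for a random gene set of the same size drawn from the network.
# Significance comes from a permutation null of random node sets, with BH
# FDR across all (candidate, superset) pairs.  Networks are typically DAGs
# (Bayesian networks) but none of the machinery assumes acyclicity.

#' Construct a regulatory network from an edge list
#'
#' Self-loops are dropped; parallel edges are collapsed keeping the maximum
#' weight; missing weights default to 1 and weights must be positive.
#'
#' @param edges data.frame with columns `SRC`, `DST` and optionally
#'   `WEIGHT`.
#' @return A `reg_network` list: `nodes` (sorted character), `edges`
#'   (cleaned data.frame).
#' @export
as_reg_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("SRC", "DST") %in% names(edges)))
  if (is.null(edges$WEIGHT)) edges$WEIGHT <- 1
  if (any(!is.finite(edges$WEIGHT)) || any(edges$WEIGHT <= 0))
    stop("edge weights must be positive", call. = FALSE)
  edges <- edges[edges$SRC != edges$DST, c("SRC", "DST", "WEIGHT")]
  edges <- edges[order(edges$SRC, edges$DST, -edges$WEIGHT), ]
  edges <- edges[!duplicated(edges[, c("SRC", "DST")]), ]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$SRC, edges$DST))),
                 edges = edges),
            class = "reg_network")
}

# Sparse weighted adjacency in the requested mode.  For "undirected",
# antiparallel edges are collapsed by maximum weight.
adjacency_matrix <- function(net, mode = c("undirected", "out", "in")) {
  mode <- match.arg(mode)
  n <- length(net$nodes)
  i <- match(net$edges$SRC, net$nodes)
  j <- match(net$edges$DST, net$nodes)
  W <- Matrix::sparseMatrix(i = i, j = j, x = net$edges$WEIGHT,
                            dims = c(n, n),
                            dimnames = list(net$nodes, net$nodes))
  switch(mode,
         out = W,
         `in` = Matrix::t(W),
         undirected = pmax(W, Matrix::t(W)))
}

# Row-indexed scoring matrix: depth 1 keeps edge weights; depth >= 2 uses
# unit weights on depth-neighborhood membership (no natural path weight).
scoring_matrix <- function(net, mode, depth) {
  W <- adjacency_matrix(net, mode)
  if (depth == 1L) return(W)
  B <- W
  B@x <- rep(1, length(B@x))
  R <- B
  for (d in seq_len(depth - 1L)) R <- ((R %*% B) + R)
  R <- (R > 0) * 1
  Matrix::diag(R) <- 0
  Matrix::drop0(R)
}

#' Network neighborhood of a node
#'
#' All nodes reachable within `depth` steps under the given edge mode,
#' excluding the node itself.
#'
#' @param node Node id.
#' @param net A [as_reg_network()] object.
#' @param depth Maximum number of steps (>= 1, default 1).
#' @param mode `"undirected"` (default), `"out"` or `"in"`.
#' @return Character vector of neighbor ids (sorted).
#' @export
neighborhood <- function(node, net, depth = 1L,
                         mode = c("undirected", "out", "in")) {
  mode <- match.arg(mode)
  stopifnot(depth >= 1L)
  if (!node %in% net$nodes)
    stop(sprintf("unknown node: %s", node), call. = FALSE)
  M <- scoring_matrix(net, mode, as.integer(depth))
  sort(net$nodes[M[node, ] > 0])
}

#' Key driver score of a single candidate node
#'
#' @param node Candidate node id.
#' @param genes Superset gene-id vector (intersected with network nodes).
#' @param net A [as_reg_network()] object.
#' @param kappa Stability parameter (default 1).
#' @param mode,depth Neighborhood definition (see [neighborhood()]).
#' @return List: `node`, `neighborhood_size`, `overlap_weight` (O_w),
#'   `expected_weight` (E_w), `score`.
#' @export
kd_score <- function(node, genes, net, kappa = 1,
                     mode = c("undirected", "out", "in"), depth = 1L) {
  mode <- match.arg(mode)
  if (!node %in% net$nodes)
    stop(sprintf("unknown node: %s", node), call. = FALSE)
  M <- scoring_matrix(net, mode, as.integer(depth))
  s_net <- intersect(unique(genes), net$nodes)
  w <- M[node, ]
  o_w <- sum(w[s_net])
  w_total <- sum(w)
  e_w <- w_total * length(s_net) / length(net$nodes)
  list(node = node, neighborhood_size = sum(w > 0), overlap_weight = o_w,
       expected_weight = e_w, score = (o_w - e_w) / sqrt(e_w + kappa))
}

#' Key driver analysis over one or more supersets
#'
#' Candidates are network nodes with neighborhood size >= `min_neighbors`.
#' For each (candidate, superset) pair the observed score is standardized
#' against `n_perm` random node sets of size `|S_net|` drawn uniformly from
#' the network (scores recomputed per draw; nulls shared across supersets
#' of equal mapped size), a one-sided Gaussian upper-tail p with a 0.5
#' continuity correction is taken (the overlap count is discrete; the raw
#' Gaussian tail undercovers it), and BH FDR is applied across all pairs.  KDs are pairs with FDR < `fdr_max`,
#' ranked within superset by FDR then descending score.
#'
#' @param supersets Named list of gene-id vectors.
#' @param net A [as_reg_network()] object.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Master seed.
#' @param min_neighbors Candidate filter (default 5).
#' @param kappa Stability parameter (default 1).
#' @param mode,depth Neighborhood definition.
#' @param fdr_max Strict KD FDR threshold (default 0.05).
#' @return data.frame `NODE`, `SUPERSET_ID`, `NEIGHBORHOOD_SIZE`, `O_W`,
#'   `E_W`, `SCORE`, `Z`, `P`, `FDR`, `IS_KD`, `RANK` (within superset).
#' @export
kda_test <- function(supersets, net, n_perm = 1000L, seed = 1L,
                     min_neighbors = 5L, kappa = 1,
                     mode = c("undirected", "out", "in"), depth = 1L,
                     fdr_max = 0.05) {
  mode <- match.arg(mode)
  stopifnot(length(supersets) > 0L, !is.null(names(supersets)))
  M <- scoring_matrix(net, mode, as.integer(depth))
  n <- length(net$nodes)
  nbr_size <- Matrix::rowSums(M > 0)
  w_total <- Matrix::rowSums(M)
  cand <- which(nbr_size >= min_neighbors)
  if (length(cand) == 0L)
    stop(sprintf("no candidate has >= %d neighbors", min_neighbors),
         call. = FALSE)
  Mc <- M[cand, , drop = FALSE]
  null_cache <- new.env(parent = emptyenv())
  perm_stats <- function(s) {
    key <- as.character(s)
    got <- null_cache[[key]]
    if (!is.null(got)) return(got)
    set.seed(derive_seed(seed, paste0("kda_null_", s)))
    mu <- numeric(length(cand)); m2 <- numeric(length(cand))
    done <- 0L
    chunk <- max(1L, min(n_perm, floor(5e7 / n)))
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      P <- matrix(0, n, b)
      idx <- vapply(seq_len(b), function(k) sample.int(n, s), integer(s))
      P[as.vector(idx) + rep((seq_len(b) - 1L) * n, each = s)] <- 1
      Onull <- as.matrix(Mc %*% P)
      mu <- mu + rowSums(Onull)
      m2 <- m2 + rowSums(Onull^2)
      done <- done + b
    }
    mean_o <- mu / n_perm
    sd_o <- sqrt(pmax(0, (m2 - n_perm * mean_o^2) / (n_perm - 1)))
    if (any(sd_o == 0))
      stop("degenerate permutation null (sd = 0) for some candidates; increase n_perm",
           call. = FALSE)
    out <- list(mean = mean_o, sd = sd_o)
    null_cache[[key]] <- out
    out
  }
  res_list <- vector("list", length(supersets))
  for (k in seq_along(supersets)) {
    s_net <- intersect(unique(supersets[[k]]), net$nodes)
    s <- length(s_net)
    if (s == 0L) next
    ind <- as.numeric(net$nodes %in% s_net)
    O <- as.numeric(Mc %*% ind)
    E <- w_total[cand] * s / n
    score <- (O - E) / sqrt(E + kappa)
    ns <- perm_stats(s)
    z <- (O - ns$mean) / ns$sd
    # O_w is a (near-)integer count in unweighted networks; the 0.5
    # continuity correction keeps the Gaussian upper tail from
    # undercovering the discrete permutation tail
    p <- stats::pnorm((O - 0.5 - ns$mean) / ns$sd, lower.tail = FALSE)
    res_list[[k]] <- data.frame(
      NODE = net$nodes[cand], SUPERSET_ID = names(supersets)[k],
      NEIGHBORHOOD_SIZE = as.integer(nbr_size[cand]), O_W = O, E_W = E,
      SCORE = score, Z = z, P = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res_list)
  if (is.null(res)) stop("no superset maps onto the network", call. = FALSE)
  res$FDR <- stats::p.adjust(res$P, method = "BH")
  res$IS_KD <- res$FDR < fdr_max
  # Z rather than SCORE as the tie-break keeps the ranking invariant under
  # uniform edge-weight scaling (Z is standardized; SCORE is not)
  res <- res[order(res$SUPERSET_ID, res$FDR, -res$Z, res$NODE), ]
  res$RANK <- stats::ave(seq_len(nrow(res)), res$SUPERSET_ID,
                         FUN = seq_along)
  rownames(res) <- NULL
  res
}

#' Extract the subnetwork around top key drivers
#'
#' Nodes are the given KDs plus their depth-neighborhoods; edges are the
#' induced edges of the network among these nodes.
#'
#' @param kds Character vector of KD node ids (length >= 1).
#' @param net A [as_reg_network()] object.
#' @param depth Neighborhood depth (default 1).
#' @param mode Neighborhood mode (default undirected).
#' @return A `subnetwork` list: `kd_nodes`, `member_nodes`, `edges`,
#'   `gwas_flags` (named character, all `"none"` initially).
#' @export
extract_subnetwork <- function(kds, net, depth = 1L,
                               mode = c("undirected", "out", "in")) {
  mode <- match.arg(mode)
  kds <- unique(as.character(kds))
  if (length(kds) == 0L) stop("need at least one key driver", call. = FALSE)
  missing <- setdiff(kds, net$nodes)
  if (length(missing) > 0L)
    stop(sprintf("unknown node(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  nbrs <- unique(unlist(lapply(kds, neighborhood, net = net, depth = depth,
                               mode = mode)))
  nodes <- sort(unique(c(kds, nbrs)))
  ed <- net$edges[net$edges$SRC %in% nodes & net$edges$DST %in% nodes, ,
                  drop = FALSE]
  rownames(ed) <- NULL
  structure(list(kd_nodes = sort(kds), member_nodes = nodes, edges = ed,
                 gwas_flags = stats::setNames(rep("none", length(nodes)),
                                              nodes)),
            class = "subnetwork")
}

#' Overlay GWAS hit flags on a subnetwork
#'
#' Nodes present in `recent_hits` are flagged `"recent_hit"`; otherwise
#' nodes in `prior_hits` are flagged `"prior_hit"`; the rest stay
#' `"none"`.  Recent takes precedence.
#'
#' @param sub A [extract_subnetwork()] object.
#' @param recent_hits,prior_hits Character gene-id vectors (may be empty).
#' @return The subnetwork with updated `gwas_flags`.
#' @export
flag_gwas_hits <- function(sub, recent_hits = character(),
                           prior_hits = character()) {
  stopifnot(inherits(sub, "subnetwork"))
  flags <- stats::setNames(rep("none", length(sub$member_nodes)),
                           sub$member_nodes)
  flags[names(flags) %in% prior_hits] <- "prior_hit"
  flags[names(flags) %in% recent_hits] <- "recent_hit"
  sub$gwas_flags <- flags
  sub
}

#' Correlate key driver expression with a clinical trait
#'
#' Pearson (or Spearman) correlation per KD gene with the trait vector;
#' zero-variance genes (or trait) yield `NA` with a flag rather than an
#' error.
#'
#' @param kds Character vector of gene ids (rows of `expr`).
#' @param expr Gene x sample expression matrix.
#' @param trait Numeric trait vector, same sample order as `expr` columns.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param sig_p Significance threshold for the flag (default 0.05).
#' @return data.frame `GENE`, `R`, `P`, `SIGNIFICANT`, `DIRECTION`.
#' @export
kd_trait_correlation <- function(kds, expr, trait,
                                 method = c("pearson", "spearman"),
                                 sig_p = 0.05) {
  method <- match.arg(method)
  if (length(trait) != ncol(expr))
    stop("expression and trait must share sample ordering", call. = FALSE)
  if (length(trait) < 4L) stop("need >= 4 samples", call. = FALSE)
  kds <- unique(as.character(kds))
  missing <- setdiff(kds, rownames(expr))
  if (length(missing) > 0L)
    stop(sprintf("gene(s) absent from expression matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  out <- data.frame(GENE = kds, R = NA_real_, P = NA_real_,
                    SIGNIFICANT = FALSE, DIRECTION = NA_character_,
                    stringsAsFactors = FALSE)
  trait_ok <- stats::sd(trait) > 0
  for (i in seq_along(kds)) {
    x <- expr[kds[i], ]
    if (!trait_ok || stats::sd(x) == 0) next
    ct <- suppressWarnings(stats::cor.test(x, trait, method = method))
    out$R[i] <- unname(ct$estimate)
    out$P[i] <- ct$p.value
    out$SIGNIFICANT[i] <- ct$p.value < sig_p
    out$DIRECTION[i] <- if (ct$estimate >= 0) "positive" else "negative"
  }
  out
}
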