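# Independent brute-force oracles.  These deliberately re-derive each
# statistic with explicit loops / enumeration, never calling the package's
# own computational path.

oracle_chi <- function(O, E, kappa) {
  total <- 0
  for (i in seq_along(O)) total <- total + (O[i] - E[i]) / sqrt(E[i] + kappa)
  total
}

# Double loop over markers x cutoffs; ranking by (p, id) done by explicit
# pairwise comparison counting.
oracle_count_oe <- function(set_markers, background, pvals, grid) {
  N <- length(background)
  rank_of <- integer(N)
  for (i in seq_len(N)) {
    r <- 1L
    for (j in seq_len(N)) {
      if (j == i) next
      if (pvals[j] < pvals[i] ||
          (pvals[j] == pvals[i] && background[j] < background[i]))
        r <- r + 1L
    }
    rank_of[i] <- r
  }
  O <- integer(length(grid)); E <- numeric(length(grid))
  for (k in seq_along(grid)) {
    cutoff <- ceiling(grid[k] * N)
    for (m in set_markers) {
      idx <- which(background == m)
      if (rank_of[idx] <= cutoff) O[k] <- O[k] + 1L
    }
    E[k] <- length(set_markers) * grid[k]
  }
  list(O = O, E = E)
}

# Hypergeometric upper tail by explicit pmf enumeration with choose().
oracle_fet <- function(n_shared, size_a, size_b, universe) {
  total <- 0
  for (k in n_shared:min(size_a, size_b)) {
    total <- total + choose(size_a, k) * choose(universe - size_a, size_b - k) /
      choose(universe, size_b)
  }
  total
}

oracle_jaccard <- function(a, b) {
  n <- 0
  for (g in unique(a)) if (g %in% b) n <- n + 1
  u <- length(unique(c(a, b)))
  if (u == 0) 0 else n / u
}

# Explicit loop over the edge list; undirected neighbors collapse
# antiparallel edges by max weight.
oracle_kd_score <- function(node, genes, edges, nodes, kappa = 1,
                            mode = "undirected") {
  w_to <- numeric(0)
  for (r in seq_len(nrow(edges))) {
    src <- edges$SRC[r]; dst <- edges$DST[r]; w <- edges$WEIGHT[r]
    nb <- NULL
    if (mode %in% c("undirected", "out") && src == node) nb <- dst
    if (mode %in% c("undirected", "in") && dst == node) nb <- src
    if (is.null(nb)) next
    if (is.na(w_to[nb]) || is.null(w_to[nb]) || !(nb %in% names(w_to)))
      w_to[nb] <- w
    else
      w_to[nb] <- max(w_to[nb], w)
  }
  s_net <- intersect(unique(genes), nodes)
  o_w <- 0
  for (nb in names(w_to)) if (nb %in% s_net) o_w <- o_w + w_to[[nb]]
  e_w <- sum(w_to) * length(s_net) / length(nodes)
  list(o_w = o_w, e_w = e_w, score = (o_w - e_w) / sqrt(e_w + kappa))
}
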