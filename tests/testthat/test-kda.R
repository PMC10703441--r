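# Key driver analysis: neighborhoods, scores, permutation test,
# subnetworks, GWAS flags and trait correlation.

star_net <- function(k = 10L) {
  as_reg_network(data.frame(SRC = "hub", DST = sprintf("n%02d", 1:k),
                            WEIGHT = 1, stringsAsFactors = FALSE))
}

test_that("neighborhood respects depth and mode", {
  net <- star_net(10L)
  expect_length(neighborhood("hub", net), 10L)
  chain <- as_reg_network(data.frame(SRC = c("a", "b"), DST = c("b", "c"),
                                     WEIGHT = 1))
  expect_setequal(neighborhood("a", chain, depth = 2, mode = "out"),
                  c("b", "c"))
  expect_setequal(neighborhood("a", chain, depth = 1, mode = "out"), "b")
  expect_setequal(neighborhood("c", chain, depth = 2, mode = "in"),
                  c("a", "b"))
  # isolated node: self-loops are dropped at load
  iso <- as_reg_network(data.frame(SRC = c("a", "z"), DST = c("b", "z"),
                                   WEIGHT = 1))
  expect_length(neighborhood("a", iso), 1L)
  expect_error(neighborhood("missing", net), "missing")
})

test_that("kd_score matches the hand-computed examples", {
  # hub with 10 unit-weight neighbors, 8 in S_net; |S_net|=20, |nodes|=100
  edges <- data.frame(SRC = "hub", DST = sprintf("v%03d", 1:10), WEIGHT = 1)
  fill <- data.frame(SRC = sprintf("v%03d", 11:98), DST = "v099", WEIGHT = 1)
  net <- as_reg_network(rbind(edges, fill))
  expect_length(net$nodes, 100L)
  s_net <- c(sprintf("v%03d", 1:8), sprintf("v%03d", 21:32))  # 20 genes
  ks <- kd_score("hub", s_net, net)
  expect_equal(ks$overlap_weight, 8)
  expect_equal(ks$expected_weight, 2)
  expect_equal(ks$score, 6 / sqrt(3))
  # zero overlap, E = 2
  ks0 <- kd_score("hub", sprintf("v%03d", 41:60), net)
  expect_equal(ks0$score, -2 / sqrt(3))
  # saturation: S_net = all nodes implies score 0
  expect_equal(kd_score("hub", net$nodes, net)$score, 0)
})

test_that("kd_score equals the brute-force edge-loop oracle", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(10:50, 1)
    nodes <- sprintf("nd%02d", seq_len(n))
    m <- sample(15:60, 1)
    edges <- data.frame(SRC = sample(nodes, m, replace = TRUE),
                        DST = sample(nodes, m, replace = TRUE),
                        WEIGHT = sample(c(1, 1, 2, 0.5), m, replace = TRUE),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$SRC != edges$DST, ]
    if (nrow(edges) == 0L) next
    net <- as_reg_network(edges)
    node <- sample(net$nodes, 1)
    genes <- sample(net$nodes, sample.int(length(net$nodes), 1))
    for (mode in c("undirected", "out", "in")) {
      got <- kd_score(node, genes, net, mode = mode)
      want <- oracle_kd_score(node, genes, net$edges, net$nodes, mode = mode)
      expect_equal(got$overlap_weight, want$o_w)
      expect_equal(got$expected_weight, want$e_w)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("candidate ranking is invariant under uniform weight scaling", {
  cfg <- tiny_config(n_genes = 200L, seed = 61L)
  ps <- planted_set("p1", gene_ids(cfg)[1:50], planted_kd = gene_ids(cfg)[190])
  cfg$planted_sets <- list(ps)
  edges <- gen_network(cfg)
  net1 <- as_reg_network(edges)
  edges2 <- edges; edges2$WEIGHT <- edges2$WEIGHT * 7
  net2 <- as_reg_network(edges2)
  r1 <- kda_test(list(p1 = ps$member_genes), net1, n_perm = 200L, seed = 5L)
  r2 <- kda_test(list(p1 = ps$member_genes), net2, n_perm = 200L, seed = 5L)
  expect_identical(r1$NODE, r2$NODE)      # identical ordering
  expect_identical(r1$RANK, r2$RANK)
})

test_that("kda_test recovers a planted driver deterministically", {
  cfg <- tiny_config(n_genes = 500L, seed = 71L)
  ps <- planted_set("p1", gene_ids(cfg)[1:60], planted_kd = gene_ids(cfg)[400])
  cfg$planted_sets <- list(ps)
  net <- as_reg_network(gen_network(cfg))
  res <- kda_test(list(p1 = ps$member_genes), net, n_perm = 500L, seed = 5L)
  expect_equal(res$NODE[1], ps$planted_kd)
  expect_lt(res$FDR[1], 0.05)
  res2 <- kda_test(list(p1 = ps$member_genes), net, n_perm = 500L, seed = 5L)
  expect_identical(res, res2)
})

test_that("extract_subnetwork induces exactly the restricted edge set", {
  net <- star_net(10L)
  sub <- extract_subnetwork("hub", net)
  expect_length(sub$member_nodes, 11L)
  expect_equal(nrow(sub$edges), 10L)
  # two drivers sharing a neighbor: node appears once
  net2 <- as_reg_network(data.frame(
    SRC = c("k1", "k2", "x", "y"), DST = c("s", "s", "y", "z"), WEIGHT = 1))
  sub2 <- extract_subnetwork(c("k1", "k2"), net2)
  expect_equal(sum(sub2$member_nodes == "s"), 1L)
  # oracle: induced edges equal the filter of the full edge list
  cfg <- tiny_config(n_genes = 150L, seed = 81L)
  net3 <- as_reg_network(gen_network(cfg))
  kds <- net3$nodes[1:3]
  sub3 <- extract_subnetwork(kds, net3)
  manual <- net3$edges[net3$edges$SRC %in% sub3$member_nodes &
                         net3$edges$DST %in% sub3$member_nodes, ]
  rownames(manual) <- NULL
  expect_identical(sub3$edges, manual)
  expect_error(extract_subnetwork(character(), net), "at least one")
})

test_that("flag_gwas_hits gives recent hits precedence", {
  sub <- extract_subnetwork("hub", star_net(5L))
  flagged <- flag_gwas_hits(sub, recent_hits = c("n01", "n02"),
                            prior_hits = c("n02", "n03"))
  expect_equal(unname(flagged$gwas_flags[c("n01", "n02", "n03", "n04")]),
               c("recent_hit", "recent_hit", "prior_hit", "none"))
  # empty lists leave everything unflagged; absent hits create no entries
  f2 <- flag_gwas_hits(sub)
  expect_true(all(f2$gwas_flags == "none"))
  f3 <- flag_gwas_hits(sub, recent_hits = "not_in_subnet")
  expect_true(all(names(f3$gwas_flags) %in% sub$member_nodes))
})

test_that("kd_trait_correlation reports r, p and degenerate cases", {
  genes <- sprintf("G%03d", 1:40)
  et <- gen_expression_trait(genes[1:3], genes, r_target = 0.8,
                             n_samples = 200L, seed = 6L)
  res <- kd_trait_correlation(genes[1:3], et$expression, et$trait)
  expect_true(all(res$R > 0.6 & res$R < 0.95))
  expect_true(all(res$P < 0.05))
  expect_true(all(res$SIGNIFICANT))
  expect_true(all(res$DIRECTION == "positive"))
  # perfect linear relation
  expr <- et$expression
  expr["G010", ] <- 2 * et$trait
  res1 <- kd_trait_correlation("G010", expr, et$trait)
  expect_equal(res1$R, 1)
  expect_lt(res1$P, 1e-100)
  # zero-variance gene reported as missing, not an error
  expr["G011", ] <- 5
  res2 <- kd_trait_correlation("G011", expr, et$trait)
  expect_true(is.na(res2$R))
  expect_false(res2$SIGNIFICANT)
  expect_error(kd_trait_correlation("G001", et$expression, et$trait[1:10]),
               "sample")
})
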