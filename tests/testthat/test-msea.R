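# The modified chi-square quantile statistic and its permutation null.

test_that("make_grid spans top 50% to top 99.9% with log spacing", {
  g <- make_grid()
  expect_length(g, 10L)
  expect_equal(g[1], 0.5)
  expect_equal(g[10], 0.001)
  expect_true(all(diff(as.numeric(g)) < 0))
  # closed-form second point of the log spacing
  expect_equal(g[2], 0.5 * (0.001 / 0.5)^(1 / 9), tolerance = 1e-12)
  expect_equal(as.numeric(make_grid(2)), c(0.5, 0.001))
  lin <- make_grid(5, spacing = "linear")
  expect_equal(diff(as.numeric(lin)), rep(-0.12475, 4))
  expect_error(make_grid(1), "n")
  expect_error(make_grid(10, f_top = 0.001, f_bottom = 0.5), "f_bottom")
})

test_that("count_oe follows the rank-cutoff definition", {
  # |set| = 4 of N = 8 background markers with p ranks {1,2,7,8}, f = 0.5
  bg <- sprintf("m%d", 1:8)
  gwas <- data.frame(MARKER = bg, PVALUE = (1:8) / 10)
  oe <- count_oe(bg[c(1, 2, 7, 8)], gwas, bg, structure(0.5, class = "quantile_grid"))
  expect_equal(oe$O, 2L)
  expect_equal(oe$E, 2)
  # saturation: set == background
  grid <- make_grid()
  oe2 <- count_oe(bg, gwas, bg, grid)
  expect_equal(oe2$O, as.integer(ceiling(as.numeric(grid) * 8)))
  expect_equal(oe2$E, 8 * as.numeric(grid))
  # set carrying the largest p-values scores zero at the top half
  gwas3 <- data.frame(MARKER = sprintf("m%d", 1:1000),
                      PVALUE = (1:1000) / 1000)
  oe3 <- count_oe(sprintf("m%d", 991:1000), gwas3, gwas3$MARKER,
                  structure(0.5, class = "quantile_grid"))
  expect_equal(oe3$O, 0L)
  expect_equal(oe3$E, 5)
  # empty set is a skip, empty background an error
  expect_true(count_oe(character(), gwas, bg, grid)$skip)
  expect_error(count_oe("m1", gwas, character(), grid), "background")
})

test_that("chi_statistic matches hand evaluation", {
  expect_equal(chi_statistic(c(5L, 3L), c(5, 3)), 0)
  expect_equal(chi_statistic(c(5L, 3L), c(2, 1), kappa = 1),
               3 / sqrt(3) + 2 / sqrt(2))
  expect_equal(chi_statistic(0L, 4, kappa = 1), -4 / sqrt(5))
  expect_error(chi_statistic(1:3, 1:2), "length")
  expect_error(chi_statistic(1L, 1, kappa = -1), "kappa")
})

test_that("count_oe and chi match the brute-force oracle exactly", {
  set.seed(7)
  for (rep in 1:100) {
    N <- sample(5:20, 1)
    bg <- sample(sprintf("mk%02d", 1:30), N)
    pv <- round(stats::runif(N), 1)          # heavy ties exercise tie-break
    gwas <- data.frame(MARKER = bg, PVALUE = pv)
    k <- sample.int(N, 1)
    set_m <- sample(bg, k)
    grid <- make_grid(sample(2:6, 1), 0.6, 0.05)
    got <- count_oe(set_m, gwas, bg, grid)
    want <- oracle_count_oe(set_m, bg, pv, as.numeric(grid))
    expect_identical(got$O, as.integer(want$O))
    expect_equal(got$E, want$E)
    kap <- sample(c(0, 1, 2.5), 1)
    expect_equal(chi_statistic(got$O, got$E, kap),
                 oracle_chi(want$O, want$E, kap))
  }
})

test_that("permutation nulls are deterministic, centered and cached", {
  # a reasonably large pruned background keeps the ceiling-cutoff bias of
  # E[O_i] - E_i negligible, so the null is centered near zero
  cfg <- tiny_config(n_genes = 600L, n_markers = 10000L, cis_per_gene = 3L,
                     seed = 31L)
  b <- gen_bundle(cfg)
  ctx <- suppressMessages(msea_context(b$gwas, b$eqtl, b$ld, "aorta"))
  grid <- make_grid()
  n1 <- null_distribution(20L, ctx, grid, n_perm = 500L, seed = 5L)
  ctx2 <- suppressMessages(msea_context(b$gwas, b$eqtl, b$ld, "aorta"))
  n2 <- null_distribution(20L, ctx2, grid, n_perm = 500L, seed = 5L)
  expect_identical(n1$sample, n2$sample)
  # statistic is centered by construction under a null GWAS
  expect_lt(abs(n1$mean), 3 * n1$sd / sqrt(500))
  # cache hit returns the same object
  expect_identical(null_distribution(20L, ctx, grid, 500L, 5L)$sample,
                   n1$sample)
  # observed chi of random sets falls inside the null envelope
  set.seed(8)
  inside <- 0L
  for (r in 1:50) {
    g <- sample(ctx$universe, 20)
    r_set <- msekda:::set_ranks(g, ctx)
    chi <- msekda:::chi_from_ranks(
      r_set, ceiling(as.numeric(grid) * length(ctx$background)),
      as.numeric(grid), 1)
    if (chi >= min(n1$sample) && chi <= max(n1$sample)) inside <- inside + 1L
  }
  expect_gte(inside, 45L)
  expect_error(null_distribution(5000L, ctx, grid, 500L, 5L), "universe")
})

test_that("msea_test recovers a planted set and applies BH correctly", {
  cfg <- tiny_config(n_genes = 300L, n_markers = 6000L, n_sets = 20L,
                     set_size_range = c(20L, 60L), seed = 17L)
  cfg$planted_sets <- list(planted_set("planted1", gene_ids(cfg)[1:60],
                                       enrichment_alpha = 0.2))
  b <- gen_bundle(cfg)
  ctx <- suppressMessages(msea_context(b$gwas, b$eqtl, b$ld, "aorta"))
  res <- msea_test(b$sets, ctx, n_perm = 500L, seed = 3L)
  expect_equal(res$SET_ID[1], "planted1")
  expect_lt(res$FDR[1], 0.05)
  # results ordered by FDR then descending chi
  expect_true(!is.unsorted(res$FDR[!res$SKIPPED]))
  # hand BH: p = (.01,.02,.03,.04) -> all adjusted to 0.04
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  # empirical null model agrees with the gaussian one on the top hit
  res_e <- msea_test(b$sets, ctx, n_perm = 500L, seed = 3L,
                     null_model = "empirical")
  expect_equal(res_e$SET_ID[1], "planted1")
  expect_lte(res_e$P[res_e$SET_ID == "planted1"], 1 / 500 + 1e-9)
})

test_that("power is monotone in the enrichment strength", {
  z_at <- function(alpha) {
    zs <- numeric(3)
    for (s in 1:3) {
      cfg <- tiny_config(n_genes = 300L, n_markers = 6000L, n_sets = 5L,
                         seed = 40L + s)
      cfg$planted_sets <- list(planted_set("pl", gene_ids(cfg)[1:60],
                                           enrichment_alpha = alpha))
      b <- gen_bundle(cfg)
      ctx <- suppressMessages(msea_context(b$gwas, b$eqtl, b$ld, "aorta"))
      res <- msea_test(b$sets, ctx, n_perm = 300L, seed = 3L)
      zs[s] <- res$Z[res$SET_ID == "pl"]
    }
    mean(zs)
  }
  z1 <- z_at(0.1); z3 <- z_at(0.3); z6 <- z_at(0.6)
  expect_gt(z1, z3)
  expect_gt(z3, z6)
})

test_that("top-hit ranking is stable across permutation counts", {
  cfg <- tiny_config(n_genes = 300L, n_markers = 6000L, n_sets = 20L,
                     seed = 23L)
  cfg$planted_sets <- list(planted_set("planted1", gene_ids(cfg)[1:60],
                                       enrichment_alpha = 0.2))
  b <- gen_bundle(cfg)
  ctx <- suppressMessages(msea_context(b$gwas, b$eqtl, b$ld, "aorta"))
  r500 <- msea_test(b$sets, ctx, n_perm = 500L, seed = 3L)
  r2000 <- msea_test(b$sets, ctx, n_perm = 2000L, seed = 3L)
  expect_equal(r500$SET_ID[1], "planted1")
  expect_equal(r2000$SET_ID[1], "planted1")
})
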