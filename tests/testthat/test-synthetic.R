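# Synthetic-data generators: determinism, forced counts, planted
# distributional structure, network contracts, species pairing.

test_that("gen_genome partitions markers into blocks and honors counts", {
  cfg <- tiny_config(n_markers = 100L, block_size = 5L, n_genes = 50L,
                     cis_per_gene = 2L, trans_fraction = 0)
  g <- gen_genome(cfg)
  expect_length(unique(g$ld$BLOCK), 20L)            # ceiling(100 / 5)
  expect_equal(nrow(g$eqtl), 100L)                  # 50 genes x 2 cis, no trans
  expect_true(all(table(g$ld$MARKER) == 1L))
  expect_true(all(table(g$eqtl$GENE) == 2L))
  # last block may be smaller
  g2 <- gen_genome(tiny_config(n_markers = 101L, block_size = 5L))
  expect_length(unique(g2$ld$BLOCK), 21L)
})

test_that("generators are pure functions of the config seed", {
  cfg <- tiny_config(seed = 42L)
  a <- gen_genome(cfg); b <- gen_genome(cfg)
  expect_identical(a, b)
  expect_identical(gen_gwas(a$eqtl, list(), cfg), gen_gwas(b$eqtl, list(), cfg))
  expect_identical(gen_gene_sets(cfg), gen_gene_sets(cfg))
  expect_identical(gen_network(cfg), gen_network(cfg))
  # GMT serialization identical byte-for-byte
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_gmt(gen_gene_sets(cfg), f1); write_gmt(gen_gene_sets(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed changes output
  expect_false(identical(a$eqtl, gen_genome(tiny_config(seed = 43L))$eqtl))
})

test_that("gen_gwas plants Beta(a,1) signal and leaves the rest uniform", {
  cfg <- tiny_config(n_genes = 2000L, n_markers = 60000L, cis_per_gene = 8L,
                     trans_fraction = 0, seed = 7L,
                     set_size_range = c(10L, 20L))
  g <- gen_genome(cfg)
  ps <- planted_set("p1", gene_ids(cfg)[1:1500], enrichment_alpha = 0.2)
  gwas <- gen_gwas(g$eqtl, list(ps), cfg)
  hit <- unique(g$eqtl$MARKER[g$eqtl$GENE %in% ps$member_genes])
  expect_gte(length(hit), 10000L)
  p_hit <- gwas$PVALUE[match(hit, gwas$MARKER)]
  # closed-form Beta(a,1) mean a/(a+1) within Monte-Carlo error
  expect_equal(mean(p_hit), 0.2 / 1.2, tolerance = 0.05)
  # goodness of fit of planted p-values against Beta(0.2, 1)
  ks_hit <- stats::ks.test(p_hit, function(q) stats::pbeta(q, 0.2, 1))
  expect_gt(ks_hit$p.value, 0.001)
  # null markers remain uniform
  p_null <- gwas$PVALUE[!gwas$MARKER %in% hit]
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.001)
  # alpha = 1 is indistinguishable from uniform
  ps1 <- planted_set("p1", ps$member_genes, enrichment_alpha = 1)
  gwas1 <- gen_gwas(g$eqtl, list(ps1), cfg)
  p1 <- gwas1$PVALUE[match(hit, gwas1$MARKER)]
  expect_gt(stats::ks.test(p1, "punif")$p.value, 0.01)
  # markers hit by several planted sets take the smallest alpha
  ps_weak <- planted_set("p2", ps$member_genes[1:50], enrichment_alpha = 0.9)
  gwas2 <- gen_gwas(g$eqtl, list(ps_weak, ps), cfg)
  expect_identical(gwas2, gen_gwas(g$eqtl, list(ps, ps_weak), cfg))
  # unknown planted genes are reported by id
  bad <- planted_set("p3", "NOPE1")
  expect_error(sim_config(planted_sets = list(bad)), "NOPE1")
})

test_that("gen_gene_sets builds requested overlaps and includes planted sets", {
  cfg <- tiny_config(
    n_sets = 30L, n_genes = 200L,
    engineered_overlaps = list(list(size_a = 40L, size_b = 40L,
                                    fraction = 0.5)))
  cfg$planted_sets <- list(tiny_planted(cfg))
  sets <- gen_gene_sets(cfg)
  expect_length(sets, 30L + 2L + 1L)
  expect_length(intersect(sets[["ovl01a"]], sets[["ovl01b"]]), 20L)
  expect_identical(sort(sets[["planted1"]]),
                   sort(cfg$planted_sets[[1]]$member_genes))
  expect_error(
    tiny_config(engineered_overlaps = list(list(size_a = 10L, size_b = 10L,
                                                fraction = 1.5))),
    "fraction")
})

test_that("gen_network yields a DAG with planted driver neighborhoods", {
  cfg <- tiny_config(n_genes = 300L, seed = 11L)
  ps <- planted_set("p1", gene_ids(cfg)[10:80], enrichment_alpha = 0.2,
                    planted_kd = gene_ids(cfg)[200])
  cfg$planted_sets <- list(ps)
  net <- gen_network(cfg, kd_out_degree = 10L, kd_member_fraction = 0.6)
  g <- igraph::graph_from_data_frame(net[, c("SRC", "DST")])
  expect_true(igraph::is_dag(g))
  out_nb <- net$DST[net$SRC == ps$planted_kd]
  expect_gte(length(out_nb), 10L)
  expect_gte(sum(out_nb %in% ps$member_genes) / length(out_nb), 0.6)
  expect_identical(net, gen_network(cfg, kd_out_degree = 10L,
                                    kd_member_fraction = 0.6))
  # infeasible enrichment request errors
  small <- planted_set("p2", gene_ids(cfg)[1:3], planted_kd = gene_ids(cfg)[5])
  cfg2 <- tiny_config(n_genes = 300L)
  cfg2$planted_sets <- list(small)
  expect_error(gen_network(cfg2, kd_out_degree = 10L), "too small")
})

test_that("gen_expression_trait hits the target correlation", {
  genes <- sprintf("G%03d", 1:60)
  et <- gen_expression_trait(genes[1:5], genes, r_target = 0.99,
                             n_samples = 500L, seed = 3L)
  r_kd <- apply(et$expression[1:5, ], 1, stats::cor, y = et$trait)
  expect_true(all(r_kd >= 0.95 & r_kd <= 1.0))
  # r_target = 0: nominal type-I error for non-driver genes
  et0 <- gen_expression_trait(genes[1], genes, r_target = 0,
                              n_samples = 200L, seed = 4L)
  pvals <- apply(et0$expression[-1, ], 1, function(x)
    stats::cor.test(x, et0$trait)$p.value)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.08)
  # zero noise, one driver: exact correlation
  et1 <- gen_expression_trait(genes[1], genes, r_target = 0.7,
                              n_samples = 50L, seed = 5L, noise_sd = 0)
  expect_equal(stats::cor(et1$expression[1, ], et1$trait), 1)
  expect_error(gen_expression_trait(genes[1], genes, 1.0, 50L), "r_target")
  expect_error(gen_expression_trait(genes[1], genes, 0.5, 3L), "n_samples")
})

test_that("gen_species_pair plants ortholog-identical shared sets", {
  cfg_a <- tiny_config(n_genes = 400L, species_tag = "human", seed = 9L)
  cfg_b <- tiny_config(n_genes = 400L, species_tag = "mouse", seed = 10L)
  pair <- gen_species_pair(cfg_a, cfg_b,
                           list(n_shared = 2L, n_specific_a = 1L,
                                n_specific_b = 1L, set_size = 30L))
  expect_setequal(pair$truth$shared, c("shared01", "shared02"))
  expect_setequal(pair$truth$specific_a, "onlyA01")
  expect_setequal(pair$truth$specific_b, "onlyB01")
  # shared sets translate exactly across the ortholog table
  for (id in pair$truth$shared) {
    a <- pair$species_a$sets[[id]]
    b <- pair$species_b$sets[[id]]
    expect_setequal(translate_genes(a, pair$ortholog_table, "ab"), b)
  }
  # every ortholog pair maps existing genes in both species
  expect_true(all(pair$ortholog_table$GENE_A %in% gene_ids(cfg_a)))
  expect_true(all(pair$ortholog_table$GENE_B %in% gene_ids(cfg_b)))
  # truth ids all resolvable in their bundles
  expect_true(all(c(pair$truth$shared, pair$truth$specific_a) %in%
                    names(pair$species_a$sets)))
  expect_true(all(c(pair$truth$shared, pair$truth$specific_b) %in%
                    names(pair$species_b$sets)))
})

test_that("full bundles are hash-stable under a fixed seed", {
  cfg <- tiny_config(seed = 21L)
  cfg$planted_sets <- list(tiny_planted(cfg, kd = gene_ids(cfg)[90]))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(gen_bundle(cfg), d1)
  write_bundle(gen_bundle(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})
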