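# Small in-code fixtures shared across test files.

tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_genes = 100L, n_markers = 2000L, block_size = 5L,
         cis_per_gene = 2L, trans_fraction = 0.1, n_sets = 10L,
         set_size_range = c(10L, 30L), seed = seed),
    list(...))
  do.call(sim_config, args)
}

tiny_planted <- function(cfg, alpha = 0.2, n = 30L, kd = NULL,
                         id = "planted1") {
  planted_set(id, gene_ids(cfg)[seq_len(n)], enrichment_alpha = alpha,
              planted_kd = kd)
}

# A fixed 6-marker toy GWAS / LD used by mapping tests.
toy_gwas <- function() {
  data.frame(MARKER = sprintf("m%d", 1:6),
             PVALUE = c(0.01, 0.5, 0.2, 0.3, 0.3, 0.9),
             stringsAsFactors = FALSE)
}

toy_ld <- function() {
  data.frame(MARKER = sprintf("m%d", 1:6),
             BLOCK = c("B1", "B1", "B2", "B3", "B3", "B4"),
             stringsAsFactors = FALSE)
}
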