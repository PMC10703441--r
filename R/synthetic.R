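# Synthetic-data generators.  Every pipeline input (GWAS summary statistics,
# tissue eQTL maps, LD blocks, gene-set collections, directed regulatory
# networks, ortholog tables, expression + trait data) can be generated with
# controllable planted structure: gene sets whose eSNPs carry
# Beta-distributed (enriched) GWAS p-values, hub nodes whose network
# neighborhoods are enriched for a planted set, and paired species sharing a
# 1:1 ortholog core.  Genomic coordinates are abstracted away: LD blocks are
# index partitions and cis/trans is a label, because downstream stages only
# use block membership and gene-marker links.

#' Simulation configuration
#'
#' @param n_genes Number of genes in the universe.
#' @param n_markers Number of GWAS markers.
#' @param block_size Markers per LD block (contiguous index blocks; the last
#'   block may be smaller).
#' @param cis_per_gene Number of dedicated cis markers per gene.
#' @param trans_fraction Fraction in `[0,1]`; `floor(trans_fraction * n_genes)`
#'   random gene-marker trans pairs are added.
#' @param n_sets Number of random background gene sets.
#' @param set_size_range Length-2 integer vector `(min, max)` of set sizes.
#' @param planted_sets List of [planted_set()] objects.
#' @param engineered_overlaps Optional list of
#'   `list(size_a=, size_b=, fraction=)` describing pairs of sets sharing a
#'   forced fraction of genes (exercises superset merging).
#' @param seed Master integer seed; fixed seed implies fully reproducible
#'   output.
#' @param species_tag `"human"` (upper-case gene symbols) or `"mouse"`
#'   (title-case symbols).
#' @param tissue Tissue label stamped on generated eQTL records.
#' @param n_samples Samples for the expression/trait component.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 500L, n_markers = 10000L, block_size = 5L,
                       cis_per_gene = 2L, trans_fraction = 0.1,
                       n_sets = 50L, set_size_range = c(20L, 100L),
                       planted_sets = list(), engineered_overlaps = list(),
                       seed = 1L, species_tag = c("human", "mouse"),
                       tissue = "aorta", n_samples = 100L) {
  species_tag <- match.arg(species_tag)
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_markers = check_count(n_markers, "n_markers"),
    block_size = check_count(block_size, "block_size"),
    cis_per_gene = check_count(cis_per_gene, "cis_per_gene"),
    trans_fraction = check_fraction(trans_fraction, "trans_fraction"),
    n_sets = check_count(n_sets, "n_sets"),
    set_size_range = set_size_range,
    planted_sets = planted_sets,
    engineered_overlaps = engineered_overlaps,
    seed = check_count(abs(seed) + 1L, "seed") - 1L,
    species_tag = species_tag,
    tissue = tissue,
    n_samples = check_count(n_samples, "n_samples")
  )
  if (cfg$n_markers < cfg$block_size)
    stop_field("n_markers", "must be >= block_size")
  if (length(set_size_range) != 2L || set_size_range[1] < 2 ||
      set_size_range[2] > cfg$n_genes || set_size_range[1] > set_size_range[2])
    stop_field("set_size_range", "must be (min, max) within [2, n_genes]")
  for (ps in planted_sets) {
    if (!inherits(ps, "planted_set"))
      stop_field("planted_sets", "entries must be planted_set objects")
    bad <- setdiff(ps$member_genes, gene_ids(cfg))
    if (length(bad) > 0L)
      stop(sprintf("planted set '%s' has genes outside the universe: %s",
                   ps$set_id, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
  }
  for (ov in engineered_overlaps) {
    f <- ov$fraction
    if (!is.numeric(f) || f < 0 || f > 1)
      stop_field("engineered_overlaps", "overlap fraction must lie in [0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' A planted (truth-known) gene set
#'
#' @param set_id Set label.
#' @param member_genes Non-empty character vector of member gene ids.
#' @param enrichment_alpha Beta shape `a` in `(0, 1]` for the GWAS p-values of
#'   the set's eSNPs; `a = 1` is the null (uniform).
#' @param shared_across_species Logical flag used by [gen_species_pair()].
#' @param planted_kd Optional gene id to wire as a hub key driver of this set.
#' @return A `planted_set` object.
#' @export
planted_set <- function(set_id, member_genes, enrichment_alpha = 1,
                        shared_across_species = FALSE, planted_kd = NULL) {
  stopifnot(length(member_genes) >= 1L)
  if (!is.numeric(enrichment_alpha) || enrichment_alpha <= 0 ||
      enrichment_alpha > 1)
    stop_field("enrichment_alpha", "must lie in (0, 1]")
  structure(list(set_id = as.character(set_id),
                 member_genes = unique(as.character(member_genes)),
                 enrichment_alpha = enrichment_alpha,
                 shared_across_species = isTRUE(shared_across_species),
                 planted_kd = planted_kd),
            class = "planted_set")
}

#' Gene and marker identifier conventions
#'
#' Human gene symbols are upper-case (`GENE00001`), mouse symbols title-case
#' (`Gene00001`), mirroring real symbol conventions so that the ortholog
#' translation step is exercised.  Markers carry a species initial.
#'
#' @param config A [sim_config()].
#' @return Character vector of ids.
#' @export
gene_ids <- function(config) {
  stem <- if (config$species_tag == "human") "GENE" else "Gene"
  sprintf("%s%05d", stem, seq_len(config$n_genes))
}

#' @rdname gene_ids
#' @export
marker_ids <- function(config) {
  sprintf("%ssnp%06d", substr(config$species_tag, 1L, 1L),
          seq_len(config$n_markers))
}

#' Generate markers, LD blocks and an eQTL map
#'
#' Markers are partitioned into contiguous LD blocks of `block_size`; each
#' gene receives `cis_per_gene` distinct cis markers drawn uniformly from the
#' marker pool, plus `floor(trans_fraction * n_genes)` random trans
#' gene-marker pairs.  eQTL FDR values are drawn below 5% so that default
#' filtering retains them.
#'
#' @param config A [sim_config()].
#' @return List with `markers` (character), `ld` (MARKER/BLOCK data.frame) and
#'   `eqtl` (MARKER/GENE/TISSUE/CIS_TRANS/FDR data.frame).
#' @export
gen_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  markers <- marker_ids(config)
  genes <- gene_ids(config)
  ld <- data.frame(
    MARKER = markers,
    BLOCK = sprintf("blk%05d", ceiling(seq_along(markers) / config$block_size)),
    stringsAsFactors = FALSE)
  n_cis <- config$n_genes * config$cis_per_gene
  if (n_cis <= config$n_markers) {
    # dedicated cis markers: no two genes share a cis marker
    cis_marker <- markers[sample.int(config$n_markers, n_cis)]
  } else {
    cis_marker <- unlist(lapply(genes, function(g)
      markers[sample.int(config$n_markers, config$cis_per_gene)]),
      use.names = FALSE)
  }
  eqtl <- data.frame(
    MARKER = cis_marker,
    GENE = rep(genes, each = config$cis_per_gene),
    TISSUE = config$tissue,
    CIS_TRANS = "cis",
    stringsAsFactors = FALSE)
  n_trans <- floor(config$trans_fraction * config$n_genes)
  if (n_trans > 0L) {
    trans <- data.frame(
      MARKER = markers[sample.int(config$n_markers, n_trans, replace = TRUE)],
      GENE = genes[sample.int(config$n_genes, n_trans, replace = TRUE)],
      TISSUE = config$tissue,
      CIS_TRANS = "trans",
      stringsAsFactors = FALSE)
    eqtl <- rbind(eqtl, trans)
    eqtl <- eqtl[!duplicated(eqtl[, c("MARKER", "GENE", "TISSUE")]), ]
  }
  eqtl$FDR <- stats::runif(nrow(eqtl), 0, 0.049)
  rownames(eqtl) <- NULL
  list(markers = markers, ld = ld, eqtl = eqtl)
}

#' Generate GWAS summary statistics with planted eSNP enrichment
#'
#' Every marker reachable through the eQTL map from a planted set with
#' Beta shape `a < 1` receives `p ~ Beta(a, 1)` (smaller `a` means stronger
#' enrichment; the Beta(a,1) mean is `a/(a+1)`); markers hit by several
#' planted sets use the smallest `a`; all other markers are `Uniform(0, 1)`
#' null.
#'
#' @param eqtl eQTL data.frame (as from [gen_genome()]).
#' @param planted List of [planted_set()] objects.
#' @param config A [sim_config()].
#' @return data.frame with columns `MARKER`, `PVALUE`.
#' @export
gen_gwas <- function(eqtl, planted, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "gwas"))
  markers <- marker_ids(config)
  known <- unique(eqtl$GENE)
  bad <- setdiff(unlist(lapply(planted, `[[`, "member_genes")), known)
  if (length(bad) > 0L)
    stop(sprintf("planted gene(s) absent from the eQTL gene universe: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  p <- stats::runif(config$n_markers)
  alpha <- rep(Inf, config$n_markers)
  for (ps in planted) {
    if (ps$enrichment_alpha >= 1) next
    hit <- unique(eqtl$MARKER[eqtl$GENE %in% ps$member_genes])
    idx <- match(hit, markers)
    idx <- idx[!is.na(idx)]
    alpha[idx] <- pmin(alpha[idx], ps$enrichment_alpha)
  }
  enriched <- which(is.finite(alpha))
  if (length(enriched) > 0L)
    p[enriched] <- stats::rbeta(length(enriched), alpha[enriched], 1)
  data.frame(MARKER = markers, PVALUE = p, stringsAsFactors = FALSE)
}

#' Generate an overlapping gene-set collection
#'
#' `n_sets` random background sets with sizes uniform in `set_size_range`,
#' plus any engineered overlap pairs (sharing a forced fraction of genes)
#' and all planted sets verbatim.  Background sets are drawn from the
#' non-causal part of the universe (genes outside every planted set), so
#' they are genuinely null rather than partially causal; with no planted
#' sets this is the whole universe.
#'
#' @param config A [sim_config()].
#' @return Named list of gene-id vectors with a `descriptions` attribute
#'   (GMT-compatible, see [write_gmt()]).
#' @export
gen_gene_sets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "sets"))
  genes <- gene_ids(config)
  rng <- config$set_size_range
  sizes <- sample.int(rng[2] - rng[1] + 1L, config$n_sets, replace = TRUE) +
    rng[1] - 1L
  planted_genes <- unique(unlist(lapply(config$planted_sets, `[[`,
                                        "member_genes")))
  null_pool <- setdiff(genes, planted_genes)
  if (length(null_pool) < rng[2]) null_pool <- genes
  sets <- lapply(sizes, function(s)
    null_pool[sample.int(length(null_pool), s)])
  names(sets) <- sprintf("set%04d", seq_len(config$n_sets))
  desc <- stats::setNames(rep("random background set", config$n_sets),
                          names(sets))
  for (i in seq_along(config$engineered_overlaps)) {
    ov <- config$engineered_overlaps[[i]]
    n_sh <- round(ov$fraction * min(ov$size_a, ov$size_b))
    pool <- genes[sample.int(config$n_genes, ov$size_a + ov$size_b - n_sh)]
    a <- pool[seq_len(ov$size_a)]
    b <- c(a[seq_len(n_sh)], pool[ov$size_a + seq_len(ov$size_b - n_sh)])
    ida <- sprintf("ovl%02da", i); idb <- sprintf("ovl%02db", i)
    sets[[ida]] <- a; sets[[idb]] <- b
    desc[ida] <- desc[idb] <- sprintf("engineered overlap %.2f", ov$fraction)
  }
  for (ps in config$planted_sets) {
    sets[[ps$set_id]] <- ps$member_genes
    desc[ps$set_id] <- sprintf("planted set (alpha=%g)", ps$enrichment_alpha)
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Generate a directed acyclic regulatory network with planted hub drivers
#'
#' A DAG over the gene universe is grown by preferential attachment along a
#' topological order (every edge points from an earlier to a later node, so
#' acyclicity is structural).  For each planted set carrying a `planted_kd`,
#' the driver node is given `kd_out_degree` out-edges of which at least
#' `ceiling(kd_member_fraction * kd_out_degree)` land on member genes of its
#' set.  Planted drivers are excluded as preferential-attachment parents so
#' their out-neighborhoods stay at the requested composition.
#'
#' @param config A [sim_config()].
#' @param planted List of [planted_set()] objects (defaults to the config's).
#' @param pa_edges Preferential-attachment edges per node.
#' @param kd_out_degree Out-degree wired for each planted driver.
#' @param kd_member_fraction Minimum fraction of driver out-neighbors that are
#'   set members (default 0.6).
#' @return Edge-list data.frame with columns `SRC`, `DST`, `WEIGHT`.
#' @export
gen_network <- function(config, planted = config$planted_sets, pa_edges = 2L,
                        kd_out_degree = 20L, kd_member_fraction = 0.6) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "network"))
  genes <- gene_ids(config)
  kd_of <- list()
  for (ps in planted) {
    if (is.null(ps$planted_kd)) next
    if (!ps$planted_kd %in% genes)
      stop(sprintf("planted_kd '%s' is not in the gene universe",
                   ps$planted_kd), call. = FALSE)
    kd_of[[ps$planted_kd]] <- ps
  }
  kds <- names(kd_of)
  n_mem_req <- ceiling(kd_member_fraction * kd_out_degree)
  for (kd in kds) {
    cand <- setdiff(kd_of[[kd]]$member_genes, c(kds, kd))
    if (length(cand) < n_mem_req)
      stop(sprintf(
        "planted set '%s' too small for driver '%s': need %d non-driver members, have %d",
        kd_of[[kd]]$set_id, kd, n_mem_req, length(cand)), call. = FALSE)
  }
  members_all <- unique(unlist(lapply(kd_of, `[[`, "member_genes")))
  root_pool <- setdiff(genes, c(kds, members_all))
  n_roots <- min(max(pa_edges, 5L), length(root_pool))
  roots <- if (n_roots > 0L) sample(root_pool, n_roots) else character()
  rest <- setdiff(genes, c(roots, kds))
  ord <- c(roots, sample(kds), sample(rest))
  n <- length(ord)
  is_kd_pos <- ord %in% kds
  deg <- rep(0L, n)
  src <- character(0); dst <- character(0)
  # preferential attachment: node i picks parents among earlier non-driver
  # nodes with probability proportional to degree + 1
  for (i in 2:n) {
    elig <- which(!is_kd_pos[seq_len(i - 1L)])
    if (length(elig) == 0L) elig <- seq_len(i - 1L)
    m <- min(pa_edges, length(elig))
    par <- if (length(elig) == 1L) elig else
      sample(elig, m, prob = deg[elig] + 1)
    src <- c(src, ord[par]); dst <- c(dst, rep(ord[i], m))
    deg[par] <- deg[par] + 1L
    deg[i] <- deg[i] + m
  }
  for (kd in kds) {
    ps <- kd_of[[kd]]
    mem_cand <- setdiff(ps$member_genes, c(kds, kd, roots))
    targ_mem <- sample(mem_cand, min(n_mem_req, length(mem_cand)))
    rand_pool <- setdiff(rest, c(ps$member_genes, kd))
    n_rand <- kd_out_degree - length(targ_mem)
    targ_rand <- sample(rand_pool, min(n_rand, length(rand_pool)))
    targ <- c(targ_mem, targ_rand)
    src <- c(src, rep(kd, length(targ))); dst <- c(dst, targ)
  }
  net <- data.frame(SRC = src, DST = dst, WEIGHT = 1, stringsAsFactors = FALSE)
  net <- net[!duplicated(net[, c("SRC", "DST")]), ]
  net <- net[order(net$SRC, net$DST), ]
  rownames(net) <- NULL
  net
}

#' Generate an expression matrix and a correlated clinical trait
#'
#' The trait is a latent factor `z`; each driver gene's expression is
#' `r_target * z + noise_sd * e` with `noise_sd = sqrt(1 - r_target^2)` by
#' default, so the population Pearson correlation between the trait and every
#' driver gene equals `r_target`.  Non-driver genes are independent standard
#' Gaussian noise.
#'
#' @param kd_genes Gene ids to correlate with the trait.
#' @param genes Full gene universe (rows of the matrix).
#' @param r_target Target correlation in `(-1, 1)`.
#' @param n_samples Number of samples (>= 4).
#' @param seed Integer seed.
#' @param noise_sd Optional override of the driver-gene noise scale; `0`
#'   makes the sample correlation exactly +/-1.
#' @return List with `expression` (genes x samples matrix) and `trait`
#'   (named numeric vector).
#' @export
gen_expression_trait <- function(kd_genes, genes, r_target, n_samples,
                                 seed = 1L, noise_sd = NULL) {
  if (!is.numeric(r_target) || abs(r_target) >= 1)
    stop("r_target must lie strictly inside (-1, 1)", call. = FALSE)
  if (n_samples < 4L) stop("n_samples must be >= 4", call. = FALSE)
  stopifnot(all(kd_genes %in% genes))
  set.seed(derive_seed(seed, "expression"))
  sd_e <- noise_sd %||% sqrt(1 - r_target^2)
  z <- stats::rnorm(n_samples)
  expr <- matrix(stats::rnorm(length(genes) * n_samples), nrow = length(genes),
                 dimnames = list(genes, sprintf("s%04d", seq_len(n_samples))))
  for (g in kd_genes)
    expr[g, ] <- r_target * z + sd_e * stats::rnorm(n_samples)
  trait <- stats::setNames(z, colnames(expr))
  list(expression = expr, trait = trait)
}

#' Generate one complete single-species input bundle
#'
#' Runs [gen_genome()], [gen_gwas()], [gen_gene_sets()], [gen_network()] and
#' [gen_expression_trait()] under the config's master seed and assembles the
#' truth record of planted structure.
#'
#' @param config A [sim_config()].
#' @param r_target Driver-trait correlation for the expression component.
#' @return A `sim_bundle` list: `config`, `markers`, `ld`, `eqtl`, `gwas`,
#'   `sets`, `network`, `expression`, `trait`, `truth`.
#' @export
gen_bundle <- function(config, r_target = 0.6) {
  genome <- gen_genome(config)
  gwas <- gen_gwas(genome$eqtl, config$planted_sets, config)
  sets <- gen_gene_sets(config)
  network <- gen_network(config)
  kds <- unlist(lapply(config$planted_sets, function(ps)
    stats::setNames(list(ps$planted_kd), ps$set_id)), recursive = FALSE)
  kds <- Filter(Negate(is.null), kds)
  et <- gen_expression_trait(unique(unlist(kds)), gene_ids(config), r_target,
                             config$n_samples, seed = config$seed)
  truth <- list(
    planted_sets = lapply(config$planted_sets, function(ps)
      list(set_id = ps$set_id, n_genes = length(ps$member_genes),
           enrichment_alpha = ps$enrichment_alpha,
           shared_across_species = ps$shared_across_species,
           planted_kd = ps$planted_kd)),
    planted_kds = kds,
    species_tag = config$species_tag, seed = config$seed)
  structure(list(config = config, markers = genome$markers, ld = genome$ld,
                 eqtl = genome$eqtl, gwas = gwas, sets = sets,
                 network = network, expression = et$expression,
                 trait = et$trait, truth = truth),
            class = "sim_bundle")
}

#' Generate a paired-species bundle with a shared ortholog core
#'
#' Shared planted sets are ortholog-identical gene lists (same universe
#' indices under each species' id convention); species-specific planted sets
#' have no counterpart.  The ortholog table maps the common index core 1:1.
#'
#' @param config_a,config_b [sim_config()]s for the two species (typically
#'   `species_tag = "human"` and `"mouse"`); any pre-existing `planted_sets`
#'   are replaced by the share plan.
#' @param share_plan List with `n_shared`, `n_specific_a`, `n_specific_b`,
#'   `set_size`, `enrichment_alpha` and `with_kd` (logical: wire a planted
#'   driver per planted set).
#' @return A `species_pair` list: `species_a`, `species_b` (sim_bundles),
#'   `ortholog_table`, `truth`.
#' @export
gen_species_pair <- function(config_a, config_b, share_plan) {
  stopifnot(inherits(config_a, "sim_config"), inherits(config_b, "sim_config"))
  sp <- utils::modifyList(list(n_shared = 3L, n_specific_a = 2L,
                               n_specific_b = 2L, set_size = 50L,
                               enrichment_alpha = 0.2, with_kd = FALSE),
                          share_plan)
  ids_a <- gene_ids(config_a); ids_b <- gene_ids(config_b)
  if (length(intersect(ids_a, ids_b)) > 0L)
    stop("gene id collision across species conventions", call. = FALSE)
  core <- seq_len(min(config_a$n_genes, config_b$n_genes))
  set.seed(derive_seed(config_a$seed, "species_pair"))
  draw_idx <- function(pool, n) pool[sample.int(length(pool), n)]
  need_kd <- isTRUE(sp$with_kd)
  mk_sets <- function(n, prefix, idx_pool, shared) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      k <- sp$set_size + if (need_kd) 1L else 0L
      idx <- draw_idx(idx_pool, k)
      out[[i]] <- list(id = sprintf("%s%02d", prefix, i),
                       member_idx = idx[seq_len(sp$set_size)],
                       kd_idx = if (need_kd) idx[k] else NULL,
                       shared = shared)
    }
    out
  }
  plan_shared <- mk_sets(sp$n_shared, "shared", core, TRUE)
  plan_a <- mk_sets(sp$n_specific_a, "onlyA", seq_len(config_a$n_genes), FALSE)
  plan_b <- mk_sets(sp$n_specific_b, "onlyB", seq_len(config_b$n_genes), FALSE)
  as_planted <- function(plan, ids) {
    lapply(plan, function(pl)
      planted_set(pl$id, ids[pl$member_idx],
                  enrichment_alpha = sp$enrichment_alpha,
                  shared_across_species = pl$shared,
                  planted_kd = if (!is.null(pl$kd_idx)) ids[pl$kd_idx]))
  }
  config_a$planted_sets <- c(as_planted(plan_shared, ids_a),
                             as_planted(plan_a, ids_a))
  config_b$planted_sets <- c(as_planted(plan_shared, ids_b),
                             as_planted(plan_b, ids_b))
  bundle_a <- gen_bundle(config_a)
  bundle_b <- gen_bundle(config_b)
  truth <- list(
    shared = vapply(plan_shared, `[[`, character(1), "id"),
    specific_a = vapply(plan_a, `[[`, character(1), "id"),
    specific_b = vapply(plan_b, `[[`, character(1), "id"),
    kds_a = bundle_a$truth$planted_kds,
    kds_b = bundle_b$truth$planted_kds)
  structure(list(species_a = bundle_a, species_b = bundle_b,
                 ortholog_table = data.frame(GENE_A = ids_a[core],
                                             GENE_B = ids_b[core],
                                             stringsAsFactors = FALSE),
                 truth = truth),
            class = "species_pair")
}

#' Write a simulated bundle to a directory in the standard formats
#'
#' @param bundle A `sim_bundle` (or `species_pair`, which writes `a/`, `b/`,
#'   `orthologs.tsv` and a pair-level `truth.json`).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(bundle, "species_pair")) {
    write_bundle(bundle$species_a, file.path(dir, "a"))
    write_bundle(bundle$species_b, file.path(dir, "b"))
    write_orthologs(bundle$ortholog_table, file.path(dir, "orthologs.tsv"))
    jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(dir))
  }
  write_gwas(bundle$gwas, file.path(dir, "gwas.tsv"))
  write_eqtl(bundle$eqtl, file.path(dir, "eqtl.tsv"))
  write_ld(bundle$ld, file.path(dir, "ld.tsv"))
  write_gmt(bundle$sets, file.path(dir, "genesets.gmt"))
  write_network(bundle$network, file.path(dir, "network.tsv"))
  write_expression(bundle$expression, file.path(dir, "expression.tsv"))
  write_trait(bundle$trait, file.path(dir, "trait.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
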