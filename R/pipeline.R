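# End-to-end pipeline and command-line entry point.  Stage order follows
# the study design: map gene sets to eSNPs -> MSEA -> merge supersets
# (+ confirm, + annotate) -> cross-species matching -> KDA (+ subnetworks,
# + GWAS-hit flags, + trait correlations).  One master seed governs every
# stochastic stage through stage-keyed derivation; a run manifest records
# config hash, seed, versions and output hashes so that identical configs
# reproduce byte-identical outputs.

#' Assemble and validate a pipeline configuration
#'
#' @param species Named list (one entry per species) of input paths:
#'   `gwas`, `eqtl`, `ld`, `gmt`, `network`, `tissue`, and optionally
#'   `expression`, `trait`, `recent_hits`, `prior_hits`.
#' @param orthologs Path to the ortholog TSV (required when two species are
#'   configured).
#' @param thresholds Named overrides of the default thresholds:
#'   `eqtl_fdr = 0.05`, `msea_fdr = 0.05`, `merge_ratio = 0.33`,
#'   `merge_alpha = 0.05`, `match_jaccard = 0.5`, `match_one_sided = 0.9`,
#'   `kda_fdr = 0.05`, `corr_p = 0.05`.
#' @param grid_n,grid_top,grid_bottom Quantile grid (default 10 points,
#'   0.5 down to 0.001).
#' @param kappa Stability parameter (default 1).
#' @param n_perm Permutations (default 1000).
#' @param seed Master seed (default 1).
#' @param top_kds Top key drivers per superset for subnetwork extraction
#'   (default 3).
#' @param min_neighbors KDA candidate filter (default 5).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(species, orthologs = NULL, thresholds = list(),
                            grid_n = 10L, grid_top = 0.5,
                            grid_bottom = 0.001, kappa = 1, n_perm = 1000L,
                            seed = 1L, top_kds = 3L, min_neighbors = 5L) {
  defaults <- list(eqtl_fdr = 0.05, msea_fdr = 0.05, merge_ratio = 0.33,
                   merge_alpha = 0.05, match_jaccard = 0.5,
                   match_one_sided = 0.9, kda_fdr = 0.05, corr_p = 0.05)
  th <- utils::modifyList(defaults, thresholds)
  for (nm in names(th))
    if (!is.numeric(th[[nm]]) || th[[nm]] <= 0 || th[[nm]] > 1)
      stop_field(nm, "thresholds must lie in (0, 1]")
  stopifnot(is.list(species), length(species) >= 1L,
            !is.null(names(species)))
  for (sp in names(species)) {
    s <- species[[sp]]
    for (f in c("gwas", "eqtl", "ld", "gmt", "network")) {
      if (is.null(s[[f]]))
        stop(sprintf("species '%s': missing input path '%s'", sp, f),
             call. = FALSE)
      if (!file.exists(s[[f]]))
        stop(sprintf("species '%s': %s file not readable: %s", sp, f,
                     s[[f]]), call. = FALSE)
    }
    if (is.null(s$tissue))
      stop(sprintf("species '%s': missing tissue label", sp), call. = FALSE)
  }
  if (length(species) >= 2L) {
    if (is.null(orthologs))
      stop("cross-species stage enabled but no ortholog file configured",
           call. = FALSE)
    if (!file.exists(orthologs))
      stop(sprintf("ortholog file not readable: %s", orthologs),
           call. = FALSE)
  }
  structure(list(species = species, orthologs = orthologs, thresholds = th,
                 grid_n = as.integer(grid_n), grid_top = grid_top,
                 grid_bottom = grid_bottom, kappa = kappa,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 top_kds = as.integer(top_kds),
                 min_neighbors = as.integer(min_neighbors)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with keys `species`, `orthologs`, `thresholds` and
#'   the scalar settings of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("species", "orthologs", "thresholds",
                                  "grid_n", "grid_top", "grid_bottom",
                                  "kappa", "n_perm", "seed", "top_kds",
                                  "min_neighbors"))]
  args$thresholds <- args$thresholds %||% list()
  do.call(pipeline_config, args)
}

write_stage <- function(obj, path) {
  if (is.data.frame(obj)) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, force = TRUE)
  }
  path
}

run_species <- function(sp, cfg, out_sp, grid) {
  s <- cfg$species[[sp]]
  th <- cfg$thresholds
  gwas <- read_gwas(s$gwas)
  eqtl <- read_eqtl(s$eqtl)
  ld <- read_ld(s$ld)
  sets <- read_gmt(s$gmt)
  net <- as_reg_network(read_network(s$network))
  ctx <- suppressMessages(
    msea_context(gwas, eqtl, ld, s$tissue, eqtl_fdr = th$eqtl_fdr))
  seed_sp <- derive_seed(cfg$seed, paste0("species_", sp))
  msea <- msea_test(sets, ctx, grid, cfg$n_perm, seed_sp, cfg$kappa)
  write_stage(msea, file.path(out_sp, "msea.tsv"))
  sig_ids <- msea$SET_ID[!msea$SKIPPED & !is.na(msea$FDR) &
                           msea$FDR < th$msea_fdr]
  universe_size <- length(ctx$universe)
  ss <- merge_supersets(sets[sig_ids], universe_size,
                        ratio_min = th$merge_ratio, alpha = th$merge_alpha)
  ss <- confirm_supersets(ss, ctx, grid, cfg$n_perm, seed_sp, cfg$kappa,
                          fdr_max = th$msea_fdr)
  for (i in seq_along(ss))
    ss[[i]]$annotation <- annotate_set(ss[[i]]$genes, sets, universe_size)
  write_stage(lapply(ss, function(x)
    list(superset_id = x$superset_id, member_sets = x$member_sets,
         genes = x$genes, confirmed = x$confirmed,
         annotation = x$annotation, retest = x$retest)),
    file.path(out_sp, "supersets.json"))
  confirmed <- Filter(function(x) isTRUE(x$confirmed), ss)
  ss_sets <- lapply(confirmed, `[[`, "genes")
  names(ss_sets) <- vapply(confirmed, `[[`, character(1), "superset_id")
  kda <- NULL
  if (length(ss_sets) > 0L) {
    kda <- kda_test(ss_sets, net, n_perm = cfg$n_perm, seed = seed_sp,
                    min_neighbors = cfg$min_neighbors, kappa = cfg$kappa,
                    fdr_max = th$kda_fdr)
    write_stage(kda, file.path(out_sp, "kda.tsv"))
    top <- kda[kda$IS_KD & kda$RANK <= cfg$top_kds, ]
    if (nrow(top) > 0L) {
      sub <- extract_subnetwork(unique(top$NODE), net)
      recent <- if (!is.null(s$recent_hits)) readLines(s$recent_hits) else
        character()
      prior <- if (!is.null(s$prior_hits)) readLines(s$prior_hits) else
        character()
      sub <- flag_gwas_hits(sub, recent, prior)
      write_stage(list(kd_nodes = sub$kd_nodes,
                       member_nodes = sub$member_nodes,
                       gwas_flags = as.list(sub$gwas_flags)),
                  file.path(out_sp, "subnetwork.json"))
      write_stage(sub$edges, file.path(out_sp, "subnetwork_edges.tsv"))
      write_stage(data.frame(NODE = sub$member_nodes,
                             IS_KD = sub$member_nodes %in% sub$kd_nodes,
                             GWAS_FLAG = unname(sub$gwas_flags),
                             stringsAsFactors = FALSE),
                  file.path(out_sp, "subnetwork_nodes.tsv"))
      if (!is.null(s$expression) && !is.null(s$trait)) {
        expr <- read_expression(s$expression)
        trait <- read_trait(s$trait)
        corr <- kd_trait_correlation(intersect(unique(top$NODE),
                                               rownames(expr)),
                                     expr, trait, sig_p = th$corr_p)
        write_stage(corr, file.path(out_sp, "kd_trait_correlation.tsv"))
      }
    }
  }
  list(ctx = ctx, msea = msea, supersets = ss, confirmed_sets = ss_sets,
       kda = kda, universe_size = universe_size)
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @param out_dir Output directory; every stage writes its TSV/JSON there,
#'   plus `manifest.json`.
#' @return Invisibly, a list with the per-species stage results and the
#'   cross-species matches (if configured).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- make_grid(config$grid_n, config$grid_top, config$grid_bottom)
  results <- list()
  stage <- "setup"
  tryCatch({
    for (sp in names(config$species)) {
      stage <- paste0("species:", sp)
      out_sp <- file.path(out_dir, sp)
      dir.create(out_sp, showWarnings = FALSE)
      results[[sp]] <- run_species(sp, config, out_sp, grid)
    }
    if (length(config$species) >= 2L) {
      stage <- "cross_species"
      sp_names <- names(config$species)[1:2]
      orth <- read_orthologs(config$orthologs)
      a <- results[[sp_names[1]]]$confirmed_sets
      b <- results[[sp_names[2]]]$confirmed_sets
      if (length(a) > 0L && length(b) > 0L) {
        mt <- match_supersets(a, b, orth,
                              alpha = config$thresholds$merge_alpha,
                              jaccard_min = config$thresholds$match_jaccard,
                              one_sided_min = config$thresholds$match_one_sided)
        write_stage(mt$matches, file.path(out_dir, "matches.tsv"))
        write_stage(mt$classification,
                    file.path(out_dir, "classification.json"))
        results$cross_species <- mt
      }
    }
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
                 stage, conditionMessage(e), out_dir), call. = FALSE)
  })
  stage_files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                              "manifest.json"))
  cfg_for_hash <- config
  manifest <- list(
    config = unclass(cfg_for_hash),
    config_hash = digest_config(cfg_for_hash),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("msekda")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    outputs = lapply(stats::setNames(stage_files, stage_files),
                     function(f) list(md5 = file_md5(file.path(out_dir, f)),
                                      bytes = file.size(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

# Stable hash of a configuration (serialize to canonical JSON, then md5).
digest_config <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  file_md5(tmp)
}
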