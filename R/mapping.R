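# Gene-set -> eSNP-set mapping.  Gene sets are bridged into GWAS marker
# space through tissue-specific eQTLs (FDR-filtered), then trimmed so that
# each LD block contributes a single representative marker.  Pruning is done
# ONCE on the global eQTL-marker universe per species/tissue and every
# per-set eSNP set is intersected with that pruned universe, guaranteeing a
# single consistent background for observed/expected computation.

#' Filter an eQTL table by tissue and FDR
#'
#' Retains records of the requested tissue with `FDR < fdr_max` (strict, per
#' the FDR < 5 percent convention).  Duplicate (marker, gene, tissue) records
#' are collapsed keeping the smallest FDR.
#'
#' @param eqtl eQTL data.frame (`MARKER`, `GENE`, `TISSUE`, `CIS_TRANS`,
#'   `FDR`).
#' @param fdr_max Strict FDR threshold in `(0, 1]` (default 0.05).
#' @param tissue Tissue label to retain.
#' @param cis_only If `TRUE`, keep cis records only (default pools cis and
#'   trans).
#' @return Filtered eQTL data.frame (possibly empty).
#' @export
filter_eqtls <- function(eqtl, fdr_max = 0.05, tissue, cis_only = FALSE) {
  stopifnot(is.numeric(fdr_max), fdr_max > 0, fdr_max <= 1)
  avail <- unique(eqtl$TISSUE)
  if (!tissue %in% avail)
    stop(sprintf("tissue '%s' not present; available: %s", tissue,
                 paste(avail, collapse = ", ")), call. = FALSE)
  out <- eqtl[eqtl$TISSUE == tissue & eqtl$FDR < fdr_max, , drop = FALSE]
  if (cis_only) out <- out[out$CIS_TRANS == "cis", , drop = FALSE]
  out <- out[order(out$FDR), , drop = FALSE]
  out <- out[!duplicated(out[, c("MARKER", "GENE", "TISSUE")]), , drop = FALSE]
  out <- out[order(out$MARKER, out$GENE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prune markers to one representative per LD block
#'
#' Keeps, for each LD block represented in `markers`, the marker with the
#' smallest GWAS p-value (`keep = "min_p"`, ties broken by lexicographically
#' smallest marker id) or the lexicographically first marker
#' (`keep = "first"`).  Idempotent.
#'
#' @param markers Character vector of marker ids.
#' @param gwas GWAS data.frame (`MARKER`, `PVALUE`).
#' @param ld LD data.frame (`MARKER`, `BLOCK`).
#' @param keep Retention rule, `"min_p"` (default) or `"first"`.
#' @return Character vector of retained marker ids (sorted).
#' @export
prune_ld <- function(markers, gwas, ld, keep = c("min_p", "first")) {
  keep <- match.arg(keep)
  markers <- unique(as.character(markers))
  if (length(markers) == 0L) return(character())
  block <- ld$BLOCK[match(markers, ld$MARKER)]
  if (anyNA(block))
    stop(sprintf("marker(s) missing from LD blocks: %s",
                 paste(utils::head(markers[is.na(block)], 5), collapse = ", ")),
         call. = FALSE)
  if (keep == "min_p") {
    p <- gwas$PVALUE[match(markers, gwas$MARKER)]
    if (anyNA(p))
      stop(sprintf("marker(s) missing from GWAS: %s",
                   paste(utils::head(markers[is.na(p)], 5), collapse = ", ")),
           call. = FALSE)
    o <- order(block, p, markers)
  } else {
    o <- order(block, markers)
  }
  kept <- markers[o][!duplicated(block[o])]
  sort(kept)
}

#' Map a gene set to its LD-pruned eSNP set
#'
#' The set's markers are the union of its member genes' eQTL markers,
#' intersected with the globally pruned background (markers must also carry
#' a GWAS p-value).  `n_unmapped` counts member genes contributing no
#' surviving marker; an entirely unmappable set yields an empty, skip-flagged
#' eSNP set rather than an error.
#'
#' @param genes Non-empty character vector of member gene ids.
#' @param eqtl FDR-filtered eQTL data.frame.
#' @param gwas GWAS data.frame.
#' @param ld LD data.frame.
#' @param background Optional pre-computed pruned background (character
#'   vector); computed from the full eQTL marker universe when `NULL`.
#' @param set_id Label carried into the result.
#' @return An `esnp_set` list: `set_id`, `markers`, `source_genes`,
#'   `n_unmapped`.
#' @export
map_set_to_esnps <- function(genes, eqtl, gwas, ld, background = NULL,
                             set_id = "set") {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("empty gene set", call. = FALSE)
  if (is.null(background)) {
    universe <- intersect(unique(eqtl$MARKER), gwas$MARKER)
    background <- prune_ld(universe, gwas, ld)
  }
  rec <- eqtl[eqtl$GENE %in% genes, c("MARKER", "GENE"), drop = FALSE]
  rec <- rec[rec$MARKER %in% background, , drop = FALSE]
  markers <- sort(unique(rec$MARKER))
  structure(list(set_id = set_id, markers = markers, source_genes = genes,
                 n_unmapped = length(setdiff(genes, unique(rec$GENE)))),
            class = "esnp_set")
}
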