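# Readers and writers for the plain-text interchange formats used by the
# pipeline: GWAS TSV, eQTL TSV, LD-block TSV, GMT gene sets, network edge
# lists, ortholog tables, expression matrices and trait vectors.

#' Read a tab-separated table against a required-column schema
#'
#' Header matching is order- and case-insensitive; extra columns are kept
#' but ignored downstream. Numeric columns are parsed including scientific
#' notation; rows failing a type check are dropped with a message.
#'
#' @param path File path.
#' @param required Character vector of required column names (canonical,
#'   upper-case).
#' @param numeric_cols Subset of `required` to coerce to numeric.
#' @return A data.frame with canonical upper-case column names.
#' @export
read_tabular <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  names(df) <- toupper(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  extra <- setdiff(names(df), required)
  if (length(extra) > 0L)
    message(sprintf("%s: ignoring %d extra column(s): %s", basename(path),
                    length(extra), paste(extra, collapse = ", ")))
  df <- df[, required, drop = FALSE]
  bad <- rep(FALSE, nrow(df))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- bad | (is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    df[[col]] <- v
  }
  if (any(bad)) {
    message(sprintf("%s: dropped %d row(s) failing numeric type checks",
                    basename(path), sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read GWAS summary statistics (`MARKER<TAB>PVALUE`)
#'
#' @param path File path.
#' @return data.frame with columns `MARKER`, `PVALUE`.
#' @export
read_gwas <- function(path) {
  df <- read_tabular(path, c("MARKER", "PVALUE"), "PVALUE")
  if (anyDuplicated(df$MARKER))
    stop(sprintf("%s: duplicated marker id(s), e.g. %s", path,
                 df$MARKER[duplicated(df$MARKER)][1L]), call. = FALSE)
  df
}

#' @rdname read_gwas
#' @param gwas data.frame with columns `MARKER`, `PVALUE`.
#' @export
write_gwas <- function(gwas, path) {
  utils::write.table(gwas[, c("MARKER", "PVALUE")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an eQTL table (`MARKER GENE TISSUE CIS_TRANS FDR`)
#'
#' @param path File path.
#' @return data.frame with columns `MARKER`, `GENE`, `TISSUE`, `CIS_TRANS`,
#'   `FDR`.
#' @export
read_eqtl <- function(path) {
  read_tabular(path, c("MARKER", "GENE", "TISSUE", "CIS_TRANS", "FDR"), "FDR")
}

#' @rdname read_eqtl
#' @param eqtl eQTL data.frame.
#' @export
write_eqtl <- function(eqtl, path) {
  utils::write.table(eqtl[, c("MARKER", "GENE", "TISSUE", "CIS_TRANS", "FDR")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read LD block assignments (`MARKER<TAB>BLOCK`)
#'
#' Every marker must appear in exactly one block.
#'
#' @param path File path.
#' @return data.frame with columns `MARKER`, `BLOCK`.
#' @export
read_ld <- function(path) {
  df <- read_tabular(path, c("MARKER", "BLOCK"))
  if (anyDuplicated(df$MARKER))
    stop(sprintf("%s: marker assigned to more than one LD block: %s", path,
                 df$MARKER[duplicated(df$MARKER)][1L]), call. = FALSE)
  df
}

#' @rdname read_ld
#' @param ld LD data.frame.
#' @export
write_ld <- function(ld, path) {
  utils::write.table(ld[, c("MARKER", "BLOCK")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: `id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a line are collapsed; duplicate set ids are an error.
#'
#' @param path File path.
#' @return Named list of character gene-id vectors, with a `descriptions`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("%s: malformed GMT line %d (fewer than 3 tab fields)",
                   path, i), call. = FALSE)
    ids[i] <- f[1L]
    desc[i] <- f[2L]
    sets[[i]] <- unique(f[-(1:2)])
  }
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate set id(s): %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  names(sets) <- ids
  names(desc) <- ids
  attr(sets, "descriptions") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene-id vectors (optional `descriptions`
#'   attribute).
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]] %||% "na", sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a directed network edge list (`SRC DST WEIGHT`)
#'
#' A missing `WEIGHT` column defaults to unit weights.
#'
#' @param path File path.
#' @return data.frame with columns `SRC`, `DST`, `WEIGHT`.
#' @export
read_network <- function(path) {
  first <- toupper(strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]])
  if ("WEIGHT" %in% first) {
    read_tabular(path, c("SRC", "DST", "WEIGHT"), "WEIGHT")
  } else {
    df <- read_tabular(path, c("SRC", "DST"))
    df$WEIGHT <- 1
    df
  }
}

#' @rdname read_network
#' @param net Edge-list data.frame.
#' @export
write_network <- function(net, path) {
  utils::write.table(net[, c("SRC", "DST", "WEIGHT")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog table (`GENE_A<TAB>GENE_B`)
#'
#' Pairs are filtered to a strict 1:1 mapping: any gene id appearing more
#' than once (on either side) is dropped with a message.
#'
#' @param path File path.
#' @return data.frame with columns `GENE_A`, `GENE_B` (1:1).
#' @export
read_orthologs <- function(path) {
  df <- read_tabular(path, c("GENE_A", "GENE_B"))
  dup <- duplicated(df$GENE_A) | duplicated(df$GENE_A, fromLast = TRUE) |
    duplicated(df$GENE_B) | duplicated(df$GENE_B, fromLast = TRUE)
  if (any(dup)) {
    message(sprintf("%s: dropped %d non-1:1 ortholog pair(s)",
                    basename(path), sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  if (nrow(df) == 0L)
    stop(sprintf("%s: empty ortholog table after 1:1 filtering", path),
         call. = FALSE)
  rownames(df) <- NULL
  df
}

#' @rdname read_orthologs
#' @param orthologs Ortholog data.frame.
#' @export
write_orthologs <- function(orthologs, path) {
  utils::write.table(orthologs[, c("GENE_A", "GENE_B")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write an expression matrix (genes x samples TSV)
#'
#' First column `GENE`; remaining columns are sample ids.
#'
#' @param path File path.
#' @return Numeric matrix, genes in rows (rownames), samples in columns.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  storage.mode(mat) <- "double"
  mat
}

#' @rdname read_expression
#' @param expr Numeric gene x sample matrix with dimnames.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(GENE = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a clinical trait vector (`SAMPLE<TAB>VALUE`)
#'
#' @param path File path.
#' @return Named numeric vector (names are sample ids).
#' @export
read_trait <- function(path) {
  df <- read_tabular(path, c("SAMPLE", "VALUE"), "VALUE")
  stats::setNames(df$VALUE, df$SAMPLE)
}

#' @rdname read_trait
#' @param trait Named numeric vector.
#' @export
write_trait <- function(trait, path) {
  utils::write.table(data.frame(SAMPLE = names(trait), VALUE = unname(trait)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
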