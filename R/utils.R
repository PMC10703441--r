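# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible stage-specific seed from a master seed
#'
#' One master seed governs every stochastic stage; each stage re-keys it
#' deterministically by stage name so that stages are individually
#' reproducible without user-side seed bookkeeping.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label (e.g. `"gwas"`, `"null_120"`).
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # 32-bit mixing kept inside R's integer range via doubles
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807 + 12345) %% 2147483647)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

# Assert x is a single positive count
check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_field(field, "must be a single positive integer")
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_field(field, sprintf("must be a number in [%g, %g]", lo, hi))
  as.numeric(x)
}

# Stable file hash used in run manifests
file_md5 <- function(path) unname(tools::md5sum(path))
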