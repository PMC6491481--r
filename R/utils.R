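#' Derive a reproducible sub-seed from a master seed
#'
#' A single pipeline seed fans out to per-stage sub-seeds so that each stage is
#' reproducible in isolation. Sub-seeds stay below 2^31 - 1.
#'
#' @param seed master integer seed (or `NULL` for no seeding)
#' @param offset stage index (small integer)
#' @return integer sub-seed, or `NULL` when `seed` is `NULL`
#' @keywords internal
sub_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 1009L + as.integer(offset) * 9973L) %% 2147483587L
}

# Run `expr` under `seed` (restoring RNG state), or as-is when seed is NULL.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# scalar numeric check
chk_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (strict && x <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict && x < lower) stopf("'%s' must be >= %g", name, lower)
  invisible(x)
}
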