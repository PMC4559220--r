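# Internal helpers shared across modules.

#' @keywords internal
log_msg <- function(fmt, ...) {
  message(sprintf(fmt, ...))
  invisible(NULL)
}

# Derive a reproducible child seed from a master seed and a stage index.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage) {
  stage <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.numeric(stage)
  }
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483629)
}

# Stable composite key for a site: chrom, 0-based position, strand.
site_key <- function(chrom, pos, strand) {
  paste(chrom, pos, strand, sep = ":")
}

# log(exp(a) + exp(b)) without leaving log space.
logspace_add <- function(a, b) {
  if (is.infinite(a) && a < 0) return(b)
  if (is.infinite(b) && b < 0) return(a)
  m <- max(a, b)
  m + log1p(exp(min(a, b) - m))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
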