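#' Build a multi-individual consensus table
#'
#' Counts, for every site observed in any individual, the number of
#' individuals carrying it. Sites are matched across individuals by
#' (chrom, pos, strand); the table's entries are exactly the union of the
#' input site sets.
#'
#' @param sitesets List of `hmc_sites`, one per individual, with distinct
#'   `individual_id`s.
#' @return A data frame of class `hmc_consensus` with columns `chrom`, `pos`,
#'   `strand`, `count` and attributes `n_individuals`, `individual_ids`.
#' @export
build_consensus <- function(sitesets) {
  if (!length(sitesets)) stop("need at least one site set")
  ids <- vapply(sitesets, function(s) attr(s, "individual_id"), "")
  if (anyDuplicated(ids[!is.na(ids)])) stop("duplicate individual_id in inputs")
  all <- do.call(rbind, lapply(sitesets, function(s) {
    as.data.frame(s)[, c("chrom", "pos", "strand")]
  }))
  key <- site_key(all$chrom, all$pos, all$strand)
  counts <- table(key)
  first <- !duplicated(key)
  df <- all[first, , drop = FALSE]
  df$count <- as.integer(counts[site_key(df$chrom, df$pos, df$strand)])
  o <- order(df$chrom, df$pos, df$strand, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_individuals = length(sitesets), individual_ids = ids,
            class = c("hmc_consensus", "data.frame"))
}

#' @export
print.hmc_consensus <- function(x, ...) {
  n <- attr(x, "n_individuals")
  cat(sprintf("5hmC consensus: %d union sites over %d individuals\n",
              nrow(x), n))
  for (tier in c("low", "intermediate", "high")) {
    mc <- stringency_min_count(tier, n)
    cat(sprintf("  %-12s (>=%2d individuals): %d sites\n", tier, mc,
                sum(x$count >= mc)))
  }
  invisible(x)
}

STRINGENCY_FRACTIONS <- c(low = 0.25, intermediate = 0.50, high = 0.75)

#' Stringency threshold for a tier
#'
#' `min_count = ceiling(fraction * n_individuals)` with fractions 0.25 / 0.50
#' / 0.75 for the low / intermediate / high tiers; for a cohort of 19 this
#' gives thresholds 5, 10 and 15.
#'
#' @param tier `"low"`, `"intermediate"` or `"high"`.
#' @param n_individuals Cohort size.
#' @return Integer minimum individual count.
#' @export
stringency_min_count <- function(tier, n_individuals) {
  tier <- match.arg(tier, names(STRINGENCY_FRACTIONS))
  as.integer(ceiling(STRINGENCY_FRACTIONS[[tier]] * n_individuals))
}

#' Subset a consensus at a stringency tier
#'
#' @param consensus An `hmc_consensus`.
#' @param tier Tier name, ignored when `min_count` is given directly.
#' @param min_count Optional explicit threshold on the individual count.
#' @return An `hmc_sites` object whose `support` column carries the
#'   individual counts.
#' @export
stringency_subset <- function(consensus, tier = "intermediate",
                              min_count = NULL) {
  stopifnot(inherits(consensus, "hmc_consensus"))
  n <- attr(consensus, "n_individuals")
  if (is.null(min_count)) min_count <- stringency_min_count(tier, n)
  keep <- consensus$count >= min_count
  hmc_sites(chrom = consensus$chrom[keep], pos = consensus$pos[keep],
            strand = consensus$strand[keep],
            support = consensus$count[keep],
            individual_id = sprintf("consensus_ge%d", min_count))
}

#' Upper-tail hypergeometric overlap test
#'
#' Tests whether the observed number of sites shared between two samples is
#' larger than expected under random draws from a genome-wide site universe.
#' With X ~ Hypergeometric(N, K, n), computes P(X >= k) entirely in log
#' space: the point mass at the starting term is evaluated with log-gamma
#' factorials and successive terms are accumulated through the term ratio,
#' stopping once additional terms change the sum by less than a relative
#' 1e-12. The far tail of a 27-million-site universe underflows double
#' precision by hundreds of orders of magnitude, so the result is carried as
#' log10(P).
#'
#' @param K Sites in sample A.
#' @param n Sites in sample B.
#' @param k Observed shared sites.
#' @param N Size of the site universe (default 27,000,000, the estimated
#'   total number of 5hmC sites in the human brain genome).
#' @return An object of class `overlap_test`: list with `log10_p`, `p`
#'   (0 when underflowed), and the inputs.
#' @examples
#' overlap_hypergeometric(K = 5, n = 4, k = 4, N = 10)  # exact: 5/210
#' @export
overlap_hypergeometric <- function(K, n, k, N = 27000000) {
  K <- as.numeric(K); n <- as.numeric(n); k <- as.numeric(k); N <- as.numeric(N)
  if (K > N || n > N || k > min(K, n) || k < 0) {
    stop("infeasible counts: need k <= min(K, n) and K, n <= N")
  }
  log_p <- hyper_upper_log(k, K, n, N)
  structure(list(K = K, n = n, k = k, N = N,
                 log10_p = log_p / log(10),
                 p = exp(log_p)),
            class = "overlap_test")
}

# log P(X >= k) for X ~ Hypergeometric(N, K, n), log-space summation with
# early termination at relative tolerance 1e-12.
hyper_upper_log <- function(k, K, n, N, rel_tol = 1e-12) {
  lo <- max(0, n - (N - K))   # support minimum
  hi <- min(K, n)             # support maximum
  if (k <= lo) return(0)      # whole support: P = 1
  lpmf <- function(i) {
    lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  }
  lratio <- function(i) {     # log pmf(i + 1) - log pmf(i)
    log(K - i) + log(n - i) - log(i + 1) - log(N - K - n + i + 1)
  }
  mode <- floor((n + 1) * (K + 1) / (N + 2))
  if (k > mode) {
    # k sits above the mode: sum pmf(k..hi) upward; terms decay
    # geometrically, so the early stop engages after few terms
    lterm <- lpmf(k)
    lsum <- lterm
    i <- k
    while (i < hi) {
      lterm <- lterm + lratio(i)
      i <- i + 1
      new <- logspace_add(lsum, lterm)
      if (lterm - new < log(rel_tol)) {
        lsum <- new
        break
      }
      lsum <- new
    }
    lsum
  } else {
    # k at or below the mode: sum the complement pmf(lo..k-1) downward from
    # k - 1; terms decay going down, and P(X < k) <= ~1/2 so the
    # complement subtraction is well conditioned
    lterm <- lpmf(k - 1)
    lsum <- lterm
    i <- k - 1
    while (i > lo) {
      lterm <- lterm - lratio(i - 1)
      i <- i - 1
      new <- logspace_add(lsum, lterm)
      if (lterm - new < log(rel_tol)) {
        lsum <- new
        break
      }
      lsum <- new
    }
    log1p(-min(1, exp(lsum)))
  }
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Hypergeometric overlap test (upper tail)\n")
  fmt <- function(v) format(v, big.mark = ",", scientific = FALSE)
  cat(sprintf("  universe N = %s, K = %s, n = %s, shared k = %s\n",
              fmt(x$N), fmt(x$K), fmt(x$n), fmt(x$k)))
  cat(sprintf("  log10 P(X >= k) = %.4g  (P = %.4g)\n", x$log10_p, x$p))
  invisible(x)
}

#' Cohort quality-control summaries
#'
#' Tabulates per-individual read and site counts and tests, by Pearson
#' correlation, whether the number of detected sites tracks sequencing depth
#' or the age / post-mortem interval covariates. No correlation with depth
#' indicates saturated detection; no correlation with age or PMI indicates
#' the mark is stable over those covariates.
#'
#' @param sitesets List of `hmc_sites`.
#' @param metadata Data frame with `individual_id` plus any of `reads`,
#'   `age`, `pmi`.
#' @return A list of class `hmc_qc`: `table` (per-individual) and
#'   `correlations` (covariate, r, p, note).
#' @export
qc_summaries <- function(sitesets, metadata) {
  ids <- vapply(sitesets, function(s) attr(s, "individual_id"), "")
  tab <- data.frame(individual_id = ids,
                    n_sites = vapply(sitesets, nrow, 0L),
                    stringsAsFactors = FALSE)
  tab <- merge(tab, metadata, by = "individual_id", sort = TRUE)
  covars <- intersect(c("reads", "age", "pmi"), names(tab))
  cors <- lapply(covars, function(cv) {
    x <- tab[[cv]]; y <- tab$n_sites
    if (length(x) < 3) {
      return(data.frame(covariate = cv, r = NA_real_, p = NA_real_,
                        note = "fewer than 3 individuals"))
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(covariate = cv, r = NA_real_, p = NA_real_,
                        note = "zero variance"))
    }
    ct <- stats::cor.test(x, y)
    data.frame(covariate = cv, r = unname(ct$estimate), p = ct$p.value,
               note = "")
  })
  structure(list(table = tab,
                 correlations = do.call(rbind, cors)),
            class = "hmc_qc")
}

#' @export
print.hmc_qc <- function(x, ...) {
  cat("Cohort QC:", nrow(x$table), "individuals\n")
  print.data.frame(x$correlations, digits = 3)
  invisible(x)
}
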