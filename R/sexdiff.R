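#' Sex-comparison configuration
#'
#' @param n_male_sets Number of random male subsets (default 5).
#' @param male_set_size Males per subset (default 5).
#' @param seed Seed for subset sampling.
#' @param match `"overlap"` (default): clusters from different subsets are
#'   matched by >= 1 bp overlap; `"exact"`: identical coordinates required.
#' @return A list of class `sex_config`.
#' @export
sex_config <- function(n_male_sets = 5L, male_set_size = 5L, seed = 1L,
                       match = c("overlap", "exact")) {
  structure(list(n_male_sets = as.integer(n_male_sets),
                 male_set_size = as.integer(male_set_size),
                 seed = as.integer(seed), match = match.arg(match)),
            class = "sex_config")
}

site_union_keys <- function(sitesets) {
  unique(unlist(lapply(sitesets, function(s) {
    site_key(s$chrom, s$pos, s$strand)
  })))
}

union_sites <- function(sitesets, individual_id = "union") {
  all <- do.call(rbind, lapply(sitesets, function(s) {
    as.data.frame(s)[, c("chrom", "pos", "strand")]
  }))
  first <- !duplicated(site_key(all$chrom, all$pos, all$strand))
  hmc_sites(chrom = all$chrom[first], pos = all$pos[first],
            strand = all$strand[first], individual_id = individual_id)
}

#' Sites unique to females
#'
#' The union of all female site sets minus the union of all male site sets.
#'
#' @param female_sets,male_sets Lists of `hmc_sites`.
#' @return An `hmc_sites` object (id `"female_unique"`), disjoint from the
#'   male union by construction (asserted).
#' @export
female_unique_sites <- function(female_sets, male_sets) {
  if (!length(female_sets)) stop("no female site sets supplied")
  if (!length(male_sets)) stop("no male site sets supplied")
  f <- union_sites(female_sets, "female_union")
  male_keys <- site_union_keys(male_sets)
  keep <- !(site_key(f$chrom, f$pos, f$strand) %in% male_keys)
  out <- hmc_sites(chrom = f$chrom[keep], pos = f$pos[keep],
                   strand = f$strand[keep], individual_id = "female_unique",
                   sex = "F")
  stopifnot(!any(site_key(out$chrom, out$pos, out$strand) %in% male_keys))
  out
}

#' Male-specific 5hmC clusters by repeated subsampling
#'
#' Draws `n_male_sets` random subsets of `male_set_size` males (without
#' replacement within a subset; subsets may overlap across draws). For each
#' subset, the sites unique to that subset versus the union of all females
#' are clustered. A cluster is male-specific when every subset's cluster list
#' contains a cluster overlapping it (>= 1 bp, or exact coordinates under
#' `match = "exact"`); the returned regions are the merged extents of the
#' qualifying clusters. Deterministic given `cfg$seed`.
#'
#' @param male_sets List of `hmc_sites` from male individuals.
#' @param female_sets List of `hmc_sites` from female individuals.
#' @param cluster_cfg A [cluster_config()].
#' @param cfg A [sex_config()].
#' @return Data frame `chrom`, `start`, `end` of male-specific regions, with
#'   attribute `per_set_clusters` (list of per-subset `hmc_clusters`).
#' @export
male_specific_clusters <- function(male_sets, female_sets,
                                   cluster_cfg = cluster_config(),
                                   cfg = sex_config()) {
  if (length(male_sets) < cfg$male_set_size) {
    stop("fewer males (", length(male_sets), ") than male_set_size (",
         cfg$male_set_size, ")")
  }
  set.seed(cfg$seed)
  female_keys <- site_union_keys(female_sets)
  per_set <- vector("list", cfg$n_male_sets)
  for (s in seq_len(cfg$n_male_sets)) {
    pick <- sample(seq_along(male_sets), cfg$male_set_size)
    u <- union_sites(male_sets[pick], sprintf("male_set%d", s))
    keep <- !(site_key(u$chrom, u$pos, u$strand) %in% female_keys)
    uniq <- hmc_sites(chrom = u$chrom[keep], pos = u$pos[keep],
                      strand = u$strand[keep],
                      individual_id = sprintf("male_set%d", s))
    per_set[[s]] <- call_clusters(uniq, cluster_cfg)
  }
  grs <- lapply(per_set, function(cl) {
    GenomicRanges::GRanges(cl$chrom, IRanges::IRanges(cl$start + 1L, cl$end))
  })
  all_cl <- do.call(rbind, lapply(per_set, as.data.frame))
  if (!nrow(all_cl)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    attr(out, "per_set_clusters") <- per_set
    return(out)
  }
  cand <- GenomicRanges::GRanges(all_cl$chrom,
                                 IRanges::IRanges(all_cl$start + 1L, all_cl$end))
  ok <- rep(TRUE, length(cand))
  for (s in seq_len(cfg$n_male_sets)) {
    ok <- ok & if (cfg$match == "overlap") {
      IRanges::overlapsAny(cand, grs[[s]])
    } else {
      paste(all_cl$chrom, all_cl$start, all_cl$end) %in%
        paste(per_set[[s]]$chrom, per_set[[s]]$start, per_set[[s]]$end)
    }
  }
  merged <- GenomicRanges::reduce(cand[ok])
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                    start = GenomicRanges::start(merged) - 1L,
                    end = GenomicRanges::end(merged),
                    stringsAsFactors = FALSE)
  attr(out, "per_set_clusters") <- per_set
  out
}

#' Gene-body 5hmC density across X-inactivation escape scores
#'
#' For each scored X-chromosome gene, computes the female-union 5hmC rate of
#' the gene body per CpG (sites in body / CpGs in body; genes whose body has
#' no CpGs are skipped with a log message), groups genes as inactivated
#' (score 0), partial escape (1-8) and full escape (9), and compares escaping
#' (score >= 1) against inactivated genes with a two-sided Wilcoxon rank-sum
#' test.
#'
#' @param female_sets List of `hmc_sites` from female individuals.
#' @param genes A `gene_models` table restricted to (or containing) the X
#'   chromosome.
#' @param escape Data frame `gene_id`, `score` (integers 0-9).
#' @param cpg_index A `cpg_index`.
#' @param region `"body"` (default): the gene body; `"flank"`: the 2 kb
#'   flanks of the body, excluding any gene body (an intergenic reading).
#' @return A list of class `escape_density`: `per_gene`, `group_means`
#'   (inactivated / escape1_8 / escape9), `by_score` means, and `test`
#'   (the `htest`).
#' @export
escape_density <- function(female_sets, genes, escape, cpg_index,
                           region = c("body", "flank")) {
  region <- match.arg(region)
  if (any(escape$score < 0 | escape$score > 9)) {
    stop("escape scores must be integers 0-9")
  }
  g <- genes[genes$gene_id %in% escape$gene_id, , drop = FALSE]
  if (!nrow(g)) stop("no scored genes found in gene models")
  fem <- union_sites(female_sets, "female_union")
  if (region == "flank") {
    bodies <- GenomicRanges::reduce(GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$body_start + 1L, genes$body_end)))
  }
  per <- lapply(seq_len(nrow(g)), function(i) {
    if (region == "body") {
      ivs <- data.frame(start = g$body_start[i], end = g$body_end[i])
    } else {
      fl <- GenomicRanges::setdiff(
        GenomicRanges::GRanges(g$chrom[i], IRanges::IRanges(
          c(max(0L, g$body_start[i] - 2000L) + 1L, g$body_end[i] + 1L),
          c(g$body_start[i], g$body_end[i] + 2000L))),
        bodies)
      ivs <- data.frame(start = GenomicRanges::start(fl) - 1L,
                        end = GenomicRanges::end(fl))
    }
    n_cg <- sum(cpg_count(cpg_index, g$chrom[i], ivs$start, ivs$end))
    sp <- fem$pos[fem$chrom == g$chrom[i]]
    n_sites <- sum(vapply(seq_len(nrow(ivs)), function(r) {
      sum(sp >= ivs$start[r] & sp < ivs$end[r])
    }, 0L))
    data.frame(gene_id = g$gene_id[i],
               score = escape$score[match(g$gene_id[i], escape$gene_id)],
               n_sites = n_sites, n_cg = n_cg,
               density = if (n_cg > 0) n_sites / n_cg else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  skipped <- is.na(per$density)
  if (any(skipped)) {
    log_msg("escape_density: skipped %d gene(s) without CpGs in %s",
            sum(skipped), region)
  }
  per <- per[!skipped, , drop = FALSE]
  grp <- function(sel) if (any(sel)) mean(per$density[sel]) else NA_real_
  group_means <- c(inactivated = grp(per$score == 0),
                   escape1_8 = grp(per$score >= 1 & per$score <= 8),
                   escape9 = grp(per$score == 9))
  by_score <- tapply(per$density, per$score, mean)
  test <- if (any(per$score == 0) && any(per$score >= 1)) {
    x <- per$density[per$score >= 1]
    y <- per$density[per$score == 0]
    t <- stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)
    # fully tied samples have a degenerate rank variance: no evidence at all
    if (is.nan(t$p.value)) t$p.value <- 1
    t
  } else NULL
  structure(list(per_gene = per, group_means = group_means,
                 by_score = by_score, test = test, region = region),
            class = "escape_density")
}

#' @export
print.escape_density <- function(x, ...) {
  cat(sprintf("Gene-%s 5hmC per CpG by X-inactivation escape (%d genes)\n",
              x$region, nrow(x$per_gene)))
  print(round(x$group_means, 5))
  if (!is.null(x$test)) {
    cat(sprintf("  rank-sum escape (score >= 1) vs inactivated: p = %.3g\n",
                x$test$p.value))
  }
  invisible(x)
}
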