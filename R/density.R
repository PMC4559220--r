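#' Per-chromosome 5hmC density
#'
#' Density is the site count corrected for both chromosome length and CpG
#' content: `n_sites / (n_cg * length_bp)`. Chromosomes with no CpGs are
#' flagged undefined (`NA` density).
#'
#' @param sites An `hmc_sites` object (strands pooled).
#' @param genome A `DNAStringSet`.
#' @param cpg_index A `cpg_index` for `genome`; built on the fly if omitted.
#' @return Data frame: `unit`, `n_sites`, `n_cg`, `span_bp`, `density`,
#'   `undefined`.
#' @export
chromosome_density <- function(sites, genome, cpg_index = NULL) {
  if (is.null(cpg_index)) cpg_index <- build_cpg_index(genome)
  lens <- genome_lengths(genome)
  n_sites <- vapply(names(lens), function(ch) sum(sites$chrom == ch), 0L)
  n_cg <- vapply(names(lens), function(ch) length(cpg_positions(cpg_index, ch)), 0L)
  undef <- n_cg == 0L | lens == 0L
  density <- ifelse(undef, NA_real_, n_sites / (n_cg * as.numeric(lens)))
  data.frame(unit = names(lens), n_sites = n_sites, n_cg = n_cg,
             span_bp = unname(lens), density = unname(density),
             undefined = unname(undef), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-feature-kind 5hmC density
#'
#' For every feature kind, intervals of that kind are merged (overlaps within
#' a kind collapsed) before counting sites, CpGs and total span; density is
#' `n_sites / (n_cg * span_bp)`. Site-in-interval tests use the single-base
#' site position, half-open.
#'
#' @param sites An `hmc_sites` object.
#' @param feat An `hmc_features` table.
#' @param cpg_index A `cpg_index`.
#' @return Data frame as in [chromosome_density()], one row per kind.
#' @export
feature_density <- function(sites, feat, cpg_index) {
  kinds <- unique(feat$kind)
  sgr <- sites_granges(sites)
  rows <- lapply(kinds, function(kd) {
    f <- feat[feat$kind == kd, , drop = FALSE]
    gr <- GenomicRanges::reduce(features_granges(f), ignore.strand = TRUE)
    n_sites <- sum(IRanges::overlapsAny(sgr, gr, ignore.strand = TRUE))
    ch <- as.character(GenomicRanges::seqnames(gr))
    st <- GenomicRanges::start(gr) - 1L
    en <- GenomicRanges::end(gr)
    n_cg <- sum(cpg_count(cpg_index, ch, st, en))
    span <- sum(en - st)
    undef <- n_cg == 0L || span == 0L
    data.frame(unit = kd, n_sites = n_sites, n_cg = n_cg, span_bp = span,
               density = if (undef) NA_real_ else n_sites / (n_cg * as.numeric(span)),
               undefined = undef, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

profile_matrix <- function(scheme, rel_start, rel_end, value, n_regions,
                           total_count, extra = list()) {
  structure(c(list(scheme = scheme,
                   bins = data.frame(rel_start = rel_start, rel_end = rel_end,
                                     value = value),
                   n_regions = n_regions, total_count = total_count),
              extra),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("5hmC %s profile: %d bins over %d region(s), %d site hits\n",
              x$scheme, nrow(x$bins), x$n_regions, x$total_count))
  invisible(x)
}

#' @export
plot.profile_matrix <- function(x, ...) {
  mid <- (x$bins$rel_start + x$bins$rel_end) / 2
  graphics::plot(mid, x$bins$value, type = "l",
                 xlab = "relative position", ylab = "mean 5hmC signal",
                 main = paste0(x$scheme, " profile"), ...)
  invisible(x)
}

#' Write a profile as TSV
#'
#' @param x A `profile_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  utils::write.table(cbind(x$bins, n = x$n_regions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Peak-centered binned 5hmC profile
#'
#' Mean 5hmC site count per contiguous `bin`-bp bin from `half_window` bp
#' upstream to `half_window` bp downstream of each peak's central position
#' (midpoint of the interval; `start + floor(len/2)`). The mean is over
#' peaks, so duplicated peaks do not change the profile. Windows running past
#' a chromosome edge contribute their truncated counts (flagged in a log
#' message when lengths are supplied).
#'
#' @param sites An `hmc_sites` object.
#' @param peaks An `hmc_features` table (any kind; typically `chip_peak`).
#' @param half_window Half window in bp (default 3000).
#' @param bin Bin width in bp (default 100).
#' @param chrom_lengths Optional named lengths used to flag clipped windows.
#' @return A `profile_matrix` with `2 * half_window / bin` bins.
#' @export
peak_profile <- function(sites, peaks, half_window = 3000L, bin = 100L,
                         chrom_lengths = NULL) {
  if (!nrow(peaks)) stop("no peaks supplied")
  nbins <- as.integer(2 * half_window / bin)
  center <- peaks$start + (peaks$end - peaks$start) %/% 2L
  if (!is.null(chrom_lengths)) {
    lens <- chrom_lengths[peaks$chrom]
    clipped <- sum(center - half_window < 0 | center + half_window > lens)
    if (clipped) log_msg("peak_profile: %d window(s) clipped at chromosome edges", clipped)
  }
  counts <- matrix(0L, nrow = nrow(peaks), ncol = nbins)
  for (ch in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == ch)
    sp <- sites$pos[sites$chrom == ch]
    if (!length(sp)) next
    for (j in pk) {
      rel <- sp - (center[j] - half_window)
      b <- rel[rel >= 0 & rel < 2 * half_window] %/% bin + 1L
      if (length(b)) {
        t <- tabulate(b, nbins)
        counts[j, ] <- counts[j, ] + t
      }
    }
  }
  profile_matrix("peak",
                 rel_start = seq_len(nbins) * bin - bin - half_window,
                 rel_end = seq_len(nbins) * bin - half_window,
                 value = colMeans(counts),
                 n_regions = nrow(peaks),
                 total_count = sum(counts))
}

#' Expression quartiles
#'
#' Ranks genes by expression and assigns quartiles 1 (lowest) to 4 (highest)
#' with sizes equal up to one gene.
#'
#' @param expression Data frame with `gene_id` and `value`.
#' @return The data frame with a `quartile` column added (or replaced).
#' @export
expression_quartiles <- function(expression) {
  r <- rank(expression$value, ties.method = "first")
  expression$quartile <- as.integer(ceiling(4 * r / nrow(expression)))
  expression
}

#' Metagene 5hmC profile by expression quartile
#'
#' Gene bodies and fixed-width upstream/downstream flanks are each divided
#' into `nbins` intervals (orientation flipped for minus-strand genes so bin
#' 1 is always 5'-most; the TSS belongs to the first body bin). Per-bin
#' values are site counts normalized by bin width in bp, averaged across the
#' genes of each expression quartile with equal gene weights.
#'
#' @param sites An `hmc_sites` object (strands pooled).
#' @param genes A `gene_models` table.
#' @param expression Data frame with `gene_id` and `quartile` (see
#'   [expression_quartiles()]); genes without an expression entry are
#'   skipped.
#' @param flank Flank width in bp (default 20000).
#' @param nbins Bins per segment (default 50; total bins `3 * nbins`).
#' @param per_cpg Divide bin counts by bin CpG content instead of bp width
#'   (requires `cpg_index`).
#' @param cpg_index A `cpg_index`, needed when `per_cpg = TRUE`.
#' @return Named list of `profile_matrix`, one per quartile `"Q1"`..`"Q4"`.
#' @export
metagene_profile <- function(sites, genes, expression, flank = 20000L,
                             nbins = 50L, per_cpg = FALSE, cpg_index = NULL) {
  if (per_cpg && is.null(cpg_index)) stop("per_cpg = TRUE needs a cpg_index")
  if (flank < nbins) stop("flank must be at least nbins bp")
  genes <- genes[genes$gene_id %in% expression$gene_id, , drop = FALSE]
  short <- (genes$body_end - genes$body_start) < nbins
  if (any(short)) {
    log_msg("metagene_profile: skipped %d gene(s) with body < %d bp",
            sum(short), nbins)
    genes <- genes[!short, , drop = FALSE]
  }
  if (!nrow(genes)) stop("no usable genes")
  quart <- expression$quartile[match(genes$gene_id, expression$gene_id)]
  total <- 3L * nbins
  per_gene <- matrix(NA_real_, nrow = nrow(genes), ncol = total)
  total_count <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    edges_body <- round(seq(g$body_start, g$body_end, length.out = nbins + 1L))
    edges <- c(seq(g$body_start - flank, g$body_start, length.out = nbins + 1L)[-(nbins + 1L)],
               edges_body,
               seq(g$body_end, g$body_end + flank, length.out = nbins + 1L)[-1])
    sp <- sites$pos[sites$chrom == g$chrom]
    counts <- numeric(total)
    if (length(sp)) {
      idx <- cut(sp, breaks = edges, right = FALSE, labels = FALSE)
      t <- tabulate(idx[!is.na(idx)], total)
      counts <- as.numeric(t)
    }
    width <- diff(edges)
    denom <- if (per_cpg) {
      pmax(cpg_count(cpg_index, g$chrom, edges[-length(edges)], edges[-1]), 1L)
    } else {
      width
    }
    v <- counts / denom
    if (g$strand == "-") v <- rev(v)
    per_gene[i, ] <- v
    total_count <- total_count + sum(counts)
  }
  rel <- seq_len(total)
  out <- lapply(1:4, function(q) {
    rowsq <- which(quart == q)
    pm <- profile_matrix("metagene", rel_start = rel - 1L, rel_end = rel,
                         value = if (length(rowsq))
                           colMeans(per_gene[rowsq, , drop = FALSE])
                         else rep(NA_real_, total),
                         n_regions = length(rowsq),
                         total_count = total_count,
                         extra = list(segments = rep(c("upstream", "body",
                                                       "downstream"),
                                                     each = nbins)))
    pm
  })
  names(out) <- paste0("Q", 1:4)
  out
}

#' Exon-intron boundary 5hmC profiles
#'
#' Per-position 5hmC site counts in the `flank` bp on each side of the 5'
#' and 3' boundaries of internal exons (first and last exons and single-exon
#' genes excluded; genes with fewer than three exons contribute nothing).
#' Positions are transcript-oriented: at the 5' boundary, position 0 is the
#' first exonic base and negative positions are intronic; at the 3' boundary
#' position 0 is the last exonic base and positive positions are intronic.
#' The sense profile counts sites whose strand matches the gene; antisense
#' the opposite strand.
#'
#' @param sites An `hmc_sites` object.
#' @param genes A `gene_models` table.
#' @param flank Bases on each side of a boundary (default 20).
#' @return List with elements `five_prime` and `three_prime`, each a data
#'   frame `rel`, `sense`, `antisense`; plus `n_internal_exons`.
#' @export
exon_boundary_profile <- function(sites, genes, flank = 20L) {
  rel <- seq(-flank, flank - 1L)
  f5 <- matrix(0L, nrow = length(rel), ncol = 2,
               dimnames = list(NULL, c("sense", "antisense")))
  f3 <- f5
  n_internal <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$n_exons < 3L || g$single_exon) next
    es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
    internal <- 2:(length(es) - 1L)   # genomic order; ends trimmed
    n_internal <- n_internal + length(internal)
    sp <- sites[sites$chrom == g$chrom, , drop = FALSE]
    if (!nrow(sp)) next
    sense <- sp$strand == g$strand
    for (j in internal) {
      if (g$strand == "+") {
        b5 <- es[j]; b3 <- ee[j] - 1L
        r5 <- sp$pos - b5
        r3 <- sp$pos - b3
      } else {
        b5 <- ee[j] - 1L; b3 <- es[j]
        r5 <- b5 - sp$pos
        r3 <- b3 - sp$pos
      }
      in5 <- r5 >= -flank & r5 < flank
      in3 <- r3 >= -flank & r3 < flank
      if (any(in5)) {
        f5[, "sense"] <- f5[, "sense"] +
          tabulate(r5[in5 & sense] + flank + 1L, length(rel))
        f5[, "antisense"] <- f5[, "antisense"] +
          tabulate(r5[in5 & !sense] + flank + 1L, length(rel))
      }
      if (any(in3)) {
        f3[, "sense"] <- f3[, "sense"] +
          tabulate(r3[in3 & sense] + flank + 1L, length(rel))
        f3[, "antisense"] <- f3[, "antisense"] +
          tabulate(r3[in3 & !sense] + flank + 1L, length(rel))
      }
    }
  }
  list(five_prime = data.frame(rel = rel, sense = f5[, "sense"],
                               antisense = f5[, "antisense"]),
       three_prime = data.frame(rel = rel, sense = f3[, "sense"],
                                antisense = f3[, "antisense"]),
       n_internal_exons = n_internal)
}
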