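make_uniform_sites <- function(genome, idx, rate, seed, id = "u") {
  set.seed(seed)
  rows <- lapply(names(genome), function(ch) {
    p <- cpg_positions(idx, ch)
    take <- p[runif(length(p)) < rate]
    if (!length(take)) return(NULL)
    data.frame(chrom = ch, pos = take, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  hmc_sites(df$chrom, df$pos, rep("+", nrow(df)), individual_id = id)
}

test_that("chromosome density is sites over (CG count x length)", {
  s1 <- seq_with_cpgs(1000, seq(50, 950, by = 10))  # 91 CpGs
  g <- toy_genome(chr1 = s1, chr2 = "ATATATAT")
  idx <- build_cpg_index(g)
  sites <- hmc_sites(rep("chr1", 10), seq(50L, 140L, by = 10L), rep("+", 10))
  d <- chromosome_density(sites, g, idx)
  expect_equal(d$density[d$unit == "chr1"], 10 / (91 * 1000))
  # chromosome without CpGs: flagged undefined; no sites -> density 0
  expect_true(d$undefined[d$unit == "chr2"])
  d0 <- chromosome_density(hmc_sites(), g, idx)
  expect_equal(d0$density[d0$unit == "chr1"], 0)
})

test_that("feature density merges intervals per kind and is half-open", {
  s1 <- seq_with_cpgs(1000, seq(100, 190, by = 10))  # 10 CpGs in [100,200)
  g <- toy_genome(chr1 = s1)
  idx <- build_cpg_index(g)
  feat <- features(chrom = "chr1", start = 100L, end = 200L, kind = "exon")
  sites <- hmc_sites(rep("chr1", 2), c(100L, 150L), rep("+", 2))
  d <- feature_density(sites, feat, idx)
  expect_equal(d$density, 2 / (10 * 100))
  # site exactly at the interval end is excluded
  feat2 <- features(chrom = "chr1", start = 90L, end = 150L, kind = "exon")
  d2 <- feature_density(sites, feat2, idx)
  expect_identical(d2$n_sites, 1L)
  # overlapping intervals of one kind are merged before counting
  feat3 <- features(chrom = "chr1", start = c(100L, 150L), end = c(200L, 200L),
                    kind = "exon")
  d3 <- feature_density(sites, feat3, idx)
  expect_identical(d3$span_bp, 100L)
  expect_identical(d3$n_sites, 2L)
})

test_that("per-CpG planting rates agree across feature kinds under uniform planting", {
  cfg <- sim_config(n_chroms = 2, chrom_length = 100000, cpg_rate = 0.02,
                    seed = 41)
  g <- make_genome(cfg)
  idx <- build_cpg_index(g)
  ann <- make_annotations(g, cfg)
  rate <- 0.3
  sites <- make_uniform_sites(g, idx, rate, seed = 42)
  d <- feature_density(sites, ann$features, idx)
  d <- d[d$n_cg >= 50, ]
  for (i in seq_len(nrow(d))) {
    per_cpg <- d$n_sites[i] / d$n_cg[i]
    sd3 <- 3 * sqrt(rate * (1 - rate) / d$n_cg[i])
    expect_lt(abs(per_cpg - rate), sd3)
  }
})

test_that("peak profiles bin correctly and are means over peaks", {
  g <- toy_genome(chr1 = seq_with_cpgs(10000, c(5050)))
  peaks <- features(chrom = "chr1", start = 4900L, end = 5100L,
                    kind = "chip_peak")   # center 5000
  sites <- hmc_sites("chr1", 5050L, "+")
  pr <- peak_profile(sites, peaks)
  expect_identical(nrow(pr$bins), 60L)
  hot <- pr$bins$rel_start == 0
  expect_equal(pr$bins$value[hot], 1)
  expect_equal(sum(pr$bins$value), 1)
  # duplicating the peak leaves the mean profile unchanged
  pr2 <- peak_profile(sites, rbind(peaks, peaks, peaks))
  expect_equal(pr2$bins$value, pr$bins$value)
  expect_error(peak_profile(sites, peaks[0, ]), "no peaks")
})

test_that("uniform planting yields a flat peak profile within Poisson tolerance", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 200000, cpg_rate = 0.05,
                    seed = 43)
  g <- make_genome(cfg)
  idx <- build_cpg_index(g)
  sites <- make_uniform_sites(g, idx, 0.8, seed = 44)
  centers <- seq(10000L, 190000L, by = 4000L)
  peaks <- features(chrom = "chr1", start = centers - 100L,
                    end = centers + 100L, kind = "chip_peak")
  pr <- peak_profile(sites, peaks, chrom_lengths = genome_lengths(g))
  # mass conservation: mean x n_peaks sums to the site-peak incidence count
  expect_equal(sum(pr$bins$value) * pr$n_regions, pr$total_count)
  expect_lt(max(pr$bins$value) / min(pr$bins$value), 1.5)
})

test_that("metagene profiles are strand-flipped, TSS-in-body, and quartile-resolved", {
  tx <- data.frame(chrom = "chr1",
                   start = c(2000L, 6000L), end = c(4000L, 8000L),
                   gene_id = c("gp", "gm"), strand = c("+", "-"),
                   exon_starts = c("2000", "6000"), exon_ends = c("4000", "8000"),
                   stringsAsFactors = FALSE)
  genes <- build_gene_models(tx)
  g <- toy_genome(chr1 = seq_with_cpgs(10000, c(2000, 7990)))
  expr <- data.frame(gene_id = c("gp", "gm"), value = c(1, 100),
                     quartile = c(1L, 4L))
  # site at the plus gene's TSS -> first body bin of Q1
  sites <- hmc_sites(rep("chr1", 2), c(2000L, 7990L), c("+", "+"))
  mg <- metagene_profile(sites, genes, expr, flank = 1000L, nbins = 50L)
  q1 <- mg$Q1$bins$value
  expect_gt(q1[51], 0)            # first body bin
  expect_equal(sum(q1 > 0), 1L)
  # site near the minus gene's TES (pos 7990, body 6000-8000 minus strand):
  # transcript-oriented it sits at the start of the body -> early body bin
  q4 <- mg$Q4$bins$value
  expect_gt(sum(q4[51:60]), 0)
  expect_equal(sum(q4[c(1:50, 101:150)]), 0)
})

test_that("a planted gene-body enrichment in top-quartile genes is recovered", {
  cfg <- sim_config(n_chroms = 2, chrom_length = 200000, cpg_rate = 0.02,
                    seed = 45)
  g <- make_genome(cfg)
  idx <- build_cpg_index(g)
  ann <- make_annotations(g, cfg, genes_per_chrom = 20)
  base_rate <- 0.15
  set.seed(46)
  q4_genes <- ann$expression$gene_id[ann$expression$quartile == 4]
  rows <- lapply(names(g), function(ch) {
    p <- cpg_positions(idx, ch)
    in_q4 <- rep(FALSE, length(p))
    for (gi in which(ann$genes$chrom == ch & ann$genes$gene_id %in% q4_genes)) {
      in_q4 <- in_q4 | (p >= ann$genes$body_start[gi] & p < ann$genes$body_end[gi])
    }
    rate <- ifelse(in_q4, 5 * base_rate, base_rate)
    take <- p[runif(length(p)) < rate]
    if (!length(take)) return(NULL)
    data.frame(chrom = ch, pos = take, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  sites <- hmc_sites(df$chrom, df$pos, rep("+", nrow(df)))
  mg <- metagene_profile(sites, ann$genes, ann$expression, flank = 2000L)
  body <- 51:100
  ratio <- mean(mg$Q4$bins$value[body]) / mean(mg$Q1$bins$value[body])
  expect_gte(ratio, 4)
  expect_lte(ratio, 6)
})

test_that("exon boundary profiles use internal exons only, transcript-oriented", {
  tx <- data.frame(chrom = "chr1", start = 1000L, end = 4000L,
                   gene_id = "g3", strand = "+",
                   exon_starts = "1000,2000,3500", exon_ends = "1300,2400,4000",
                   stringsAsFactors = FALSE)
  genes <- build_gene_models(tx)
  # site at first base of the internal exon (2000) on the gene's strand
  sites <- hmc_sites(rep("chr1", 3), c(2000L, 2399L, 1000L), c("+", "-", "+"))
  eb <- exon_boundary_profile(sites, genes)
  expect_identical(eb$n_internal_exons, 1L)
  f5 <- eb$five_prime
  expect_identical(f5$sense[f5$rel == 0], 1L)       # exon start, sense
  expect_identical(sum(f5$sense), 1L)                # first-exon site ignored
  f3 <- eb$three_prime
  expect_identical(f3$antisense[f3$rel == 0], 1L)    # last exonic base, antisense
  # a 2-exon gene contributes nothing
  tx2 <- data.frame(chrom = "chr1", start = 1000L, end = 3000L,
                    gene_id = "g2", strand = "+",
                    exon_starts = "1000,2500", exon_ends = "1500,3000",
                    stringsAsFactors = FALSE)
  eb2 <- exon_boundary_profile(sites, build_gene_models(tx2))
  expect_identical(eb2$n_internal_exons, 0L)
  expect_identical(sum(eb2$five_prime$sense), 0L)
})

test_that("sense and antisense boundary profiles agree under strand-symmetric planting", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 100000, cpg_rate = 0.05,
                    seed = 47)
  g <- make_genome(cfg)
  idx <- build_cpg_index(g)
  ann <- make_annotations(g, cfg, genes_per_chrom = 10, exons_per_gene = 4)
  # plant each strand of each CpG independently: symmetric in distribution
  set.seed(48)
  p <- cpg_positions(idx, "chr1")
  tp <- p[runif(length(p)) < 0.5]
  tm <- p[runif(length(p)) < 0.5]
  sites <- hmc_sites(rep("chr1", length(tp) + length(tm)), c(tp, tm),
                     rep(c("+", "-"), c(length(tp), length(tm))))
  eb <- exon_boundary_profile(sites, ann$genes)
  for (side in c("five_prime", "three_prime")) {
    s <- eb[[side]]$sense; a <- eb[[side]]$antisense
    expect_true(all(abs(s - a) <= 3 * sqrt(pmax(s + a, 1))))
  }
})
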