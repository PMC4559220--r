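test_that("toy genomes hit the requested CpG rate and are seed-deterministic", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 100000, cpg_rate = 0.02,
                    seed = 9)
  g <- make_genome(cfg)
  n_cg <- length(cpg_positions(build_cpg_index(g), "chr1"))
  expect_true(n_cg >= 1600 && n_cg <= 2400)

  g2 <- make_genome(cfg)
  expect_identical(as.character(g), as.character(g2))

  cfg0 <- sim_config(n_chroms = 1, chrom_length = 100000, cpg_rate = 0,
                     seed = 9)
  g0 <- make_genome(cfg0)
  rate0 <- length(cpg_positions(build_cpg_index(g0), "chr1")) / 100000
  expect_lt(rate0, 0.01)

  expect_error(sim_config(cpg_rate = 0.6), "cpg_rate")
})

test_that("planted truth has the core-plus-private sharing structure", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 50000, n_individuals = 4,
                    core_fraction = 1, private_rate = 0, seed = 2)
  tt <- plant_truth(make_genome(cfg), cfg)
  keys <- lapply(tt$individuals, site_keys)
  expect_true(all(vapply(keys, identical, TRUE, keys[[1]])))

  # core subset invariant and per-individual uniqueness
  cfg2 <- sim_config(n_chroms = 1, chrom_length = 50000, n_individuals = 6,
                     core_fraction = 0.4, private_rate = 0.1, seed = 2)
  tt2 <- plant_truth(make_genome(cfg2), cfg2)
  core_keys <- site_keys(tt2$core)
  for (ind in tt2$individuals) {
    expect_true(all(core_keys %in% site_keys(ind)))
  }

  # sharing fraction is monotone non-increasing in k
  cons <- build_consensus(tt2$individuals)
  frac <- vapply(1:6, function(k) mean(cons$count >= k), 0)
  expect_true(all(diff(frac) <= 0))
})

test_that("private-site overlap between two individuals matches its binomial expectation", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 500000, cpg_rate = 0.02,
                    n_individuals = 2, core_fraction = 0, private_rate = 0.1,
                    seed = 13)
  g <- make_genome(cfg)
  tt <- plant_truth(g, cfg)
  k1 <- sub(" [+-]$", "", site_keys(tt$individuals[[1]]))
  k2 <- sub(" [+-]$", "", site_keys(tt$individuals[[2]]))
  obs <- length(intersect(k1, k2))
  # each eligible CpG is in both individuals w.p. private_rate^2
  idx <- build_cpg_index(g)
  pool <- sum(vapply(names(idx$pos), function(ch) {
    p <- cpg_positions(idx, ch)
    sum(p >= cfg$read_length & p <= genome_lengths(g)[[ch]] - cfg$read_length - 2)
  }, 0))
  expected <- pool * cfg$private_rate^2
  sd3 <- 3 * sqrt(pool * cfg$private_rate^2 * (1 - cfg$private_rate^2))
  expect_true(abs(obs - expected) <= sd3)
})

test_that("read placement puts the site's C at the drawn offset on the read's strand", {
  # one plus-strand site at pos 100, forced offset 11, read length 50
  s <- seq_with_cpgs(1000, c(100, 300))
  g <- toy_genome(chr1 = s)
  cfg <- sim_config(n_chroms = 1, chrom_length = 1000, noise_read_rate = 0,
                    reads_per_site = 1,
                    offset_weights = c(`11` = 1, `12` = 0, `13` = 0),
                    n_individuals = 1, seed = 1)
  plus <- hmc_sites("chr1", 100L, "+", individual_id = "p", genome = g)
  sam <- tempfile(fileext = ".sam")
  simulate_reads(g, plus, cfg, sam, seed = 4)
  r <- read_alignments(sam, g)
  expect_true(all(r$start == 90L))
  expect_true(all(r$strand == "+"))
  # reference dinucleotide at read offsets 11-12 is CG
  expect_identical(substr(s, r$start[1] + 11, r$start[1] + 12), "CG")

  # mirrored construction for a minus-strand site
  minus <- hmc_sites("chr1", 300L, "-", individual_id = "m", genome = g)
  simulate_reads(g, minus, cfg, sam, seed = 4)
  rm_ <- read_alignments(sam, g)
  expect_true(all(rm_$strand == "-"))
  # 5' end of a minus read is its rightmost base: offset 11 -> pos + 11
  expect_true(all(rm_$start + rm_$length - 1L == 300L + 11L))
})

test_that("read counts are centred on reads_per_site and SAM output is byte-deterministic", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 50000, noise_read_rate = 0,
                    reads_per_site = 5, n_individuals = 1, seed = 21)
  g <- make_genome(cfg)
  idx <- build_cpg_index(g)
  pos <- cpg_positions(idx, "chr1")
  pos <- pos[pos >= 50 & pos <= 49948][1:100]
  sites <- hmc_sites(rep("chr1", 100), pos, rep("+", 100),
                     individual_id = "x", genome = g)
  sam <- tempfile(fileext = ".sam")
  simulate_reads(g, sites, cfg, sam, seed = 5)
  n_reads <- sum(!startsWith(readLines(sam), "@"))
  # 100 sites x (1 + Poisson(4)): mean 500, sd 20
  expect_true(abs(n_reads - 500) <= 3 * sqrt(100 * 4))

  sam2 <- tempfile(fileext = ".sam")
  simulate_reads(g, sites, cfg, sam2, seed = 5)
  expect_identical(readLines(sam), readLines(sam2))
})

test_that("annotation fixtures satisfy their construction contracts", {
  cfg <- sim_config(n_chroms = 2, chrom_length = 100000, seed = 17)
  g <- make_genome(cfg)
  ann <- make_annotations(g, cfg, genes_per_chrom = 10, exons_per_gene = 3)
  expect_identical(nrow(ann$genes), 20L)
  expect_true(all(ann$genes$n_exons == 3L))
  # genes do not overlap
  for (ch in unique(ann$genes$chrom)) {
    gg <- ann$genes[ann$genes$chrom == ch, ]
    gg <- gg[order(gg$body_start), ]
    expect_true(all(utils::head(gg$body_end, -1) <= utils::tail(gg$body_start, -1)))
  }
  # expression quartiles near-equal; escape scores cover 0..9 given >= 30 genes
  expect_true(max(table(ann$expression$quartile)) -
                min(table(ann$expression$quartile)) <= 1)
  cfgX <- sim_config(n_chroms = 2, chrom_length = 400000, seed = 17)
  gX <- make_genome(cfgX)
  annX <- make_annotations(gX, cfgX, genes_per_chrom = 35)
  expect_setequal(unique(annX$escape$score), 0:9)
  # genome too small for the request errors out
  expect_error(make_annotations(g, cfg, genes_per_chrom = 60), "too small")
})
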