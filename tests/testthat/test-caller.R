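test_that("read filters use inclusive mapq and strict mean-baseq thresholds", {
  reads <- data.frame(
    read_id = c("a", "b", "c", "d"),
    chrom = "chr1", start = c(0L, 10L, 20L, 30L), strand = "+",
    length = 50L,
    mapq = c(10L, 9L, 42L, 42L),
    mean_baseq = c(31, 31, 30.0, 30.1),
    stringsAsFactors = FALSE)
  kept <- filter_reads(reads, caller_config())
  expect_identical(kept$read_id, c("a", "d"))   # mapq 10 kept; baseq 30.0 dropped
  expect_identical(unname(attr(kept, "dropped")), c(1L, 1L))
  empty <- filter_reads(reads[0, ], caller_config())
  expect_identical(nrow(empty), 0L)
  expect_identical(sum(attr(empty, "dropped")), 0L)
})

test_that("duplicate collapse keeps the best read per (chrom, start, strand)", {
  reads <- data.frame(
    read_id = c("r1", "r2", "r3", "r4", "r5"),
    chrom = "chr1", start = c(100L, 100L, 100L, 100L, 200L),
    strand = c("+", "+", "-", "+", "+"),
    length = 50L, mapq = c(40L, 20L, 30L, 40L, 10L), mean_baseq = 40,
    stringsAsFactors = FALSE)
  reads <- reads[order(reads$chrom, reads$start, reads$strand), ]
  out <- collapse_duplicates(reads)
  # highest mapq wins; mapq tie broken by lexicographic read id (r1 < r4);
  # opposite strands at one start both survive
  expect_setequal(out$read_id, c("r1", "r3", "r5"))
  nodup <- reads[reads$read_id %in% c("r3", "r5"), ]
  expect_identical(collapse_duplicates(nodup)$read_id, nodup$read_id)
  expect_error(collapse_duplicates(reads[c(5, 1, 2, 3, 4), ]), "sorted")
})

test_that("calling follows the offset geometry with first-matching-offset-wins", {
  # CpGs at 100 and 102: a '+' read starting at 90 tests offsets 11,12,13 ->
  # candidate positions 100,101,102; hit at 11 stops the scan
  s <- seq_with_cpgs(1000, c(100, 104, 500))
  g <- toy_genome(chr1 = s)
  reads <- data.frame(read_id = "r1", chrom = "chr1", start = 90L,
                      strand = "+", length = 50L, mapq = 42L,
                      mean_baseq = 40, stringsAsFactors = FALSE)
  got <- call_sites(reads, g, caller_config(), individual_id = "t")
  expect_identical(got$pos, 100L)
  expect_identical(got$strand, "+")

  # start 92: offset 11 -> 102 (no CG), offset 12 -> 103 (no), offset 13 -> 104 (CG)
  reads$start <- 92L
  got <- call_sites(reads, g, caller_config(), individual_id = "t")
  expect_identical(got$pos, 104L)

  # no CG at any offset -> no call
  reads$start <- 300L
  expect_identical(nrow(call_sites(reads, g, caller_config())), 0L)

  # restricting offsets is honoured
  reads$start <- 92L
  expect_identical(nrow(call_sites(reads, g, caller_config(offsets = c(11, 12)))), 0L)

  # minus-strand read: 5' end is the rightmost base; site at the plus-strand C
  mreads <- data.frame(read_id = "m1", chrom = "chr1", start = 462L,
                       strand = "-", length = 50L, mapq = 42L,
                       mean_baseq = 40, stringsAsFactors = FALSE)
  # rightmost base 511; offset 11 puts the minus-strand C at plus-coord 501,
  # i.e. the CpG whose plus-strand C sits at 500
  got <- call_sites(mreads, g, caller_config(offsets = 11), individual_id = "t")
  expect_identical(got$pos, 500L)
  expect_identical(got$strand, "-")
})

test_that("support aggregates reads, is conserved, and min_support nests outputs", {
  s <- seq_with_cpgs(2000, seq(100, 1900, by = 100))
  g <- toy_genome(chr1 = s)
  set.seed(31)
  n <- 60
  site_pos <- sample(seq(100L, 1900L, by = 100L), n, replace = TRUE)
  reads <- data.frame(read_id = sprintf("r%03d", 1:n), chrom = "chr1",
                      start = site_pos - 10L, strand = "+", length = 50L,
                      mapq = 42L, mean_baseq = 40, stringsAsFactors = FALSE)
  cfg <- caller_config(collapse_duplicates = FALSE)
  got <- call_sites(reads, g, cfg)
  expect_identical(sum(got$support), as.integer(n))  # every read produced exactly one call
  expect_identical(sort(unique(got$pos)), sort(unique(site_pos)))
  prev <- site_keys(got)
  for (ms in 2:4) {
    cur <- call_sites(reads, g, caller_config(collapse_duplicates = FALSE,
                                              min_support = ms))
    expect_true(all(site_keys(cur) %in% prev))
    prev <- site_keys(cur)
  }
})

test_that("noise-free simulation is recovered exactly; noisy calling stays precise", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 100000, cpg_rate = 0.02,
                    n_individuals = 1, noise_read_rate = 0,
                    reads_per_site = 3, seed = 23)
  g <- make_genome(cfg)
  tt <- plant_truth(g, cfg)
  sam <- tempfile(fileext = ".sam")
  simulate_reads(g, tt$individuals[[1]], cfg, sam)
  called <- call_sites(filter_reads(read_alignments(sam, g)), g,
                       individual_id = "ind01")
  expect_identical(site_keys(called), site_keys(tt$individuals[[1]]))

  cfgN <- sim_config(n_chroms = 1, chrom_length = 100000, cpg_rate = 0.02,
                     n_individuals = 1, noise_read_rate = 10,
                     reads_per_site = 3, seed = 23)
  samN <- tempfile(fileext = ".sam")
  simulate_reads(g, tt$individuals[[1]], cfgN, samN)
  calledN <- call_sites(filter_reads(read_alignments(samN, g)), g,
                        individual_id = "ind01")
  truth_k <- site_keys(tt$individuals[[1]])
  prec <- mean(site_keys(calledN) %in% truth_k)
  sens <- mean(truth_k %in% site_keys(calledN))
  expect_gte(prec, 0.9)
  expect_identical(sens, 1)
})

test_that("every emitted site passes the CpG re-check against the genome", {
  cfg <- sim_config(n_chroms = 2, chrom_length = 20000, n_individuals = 1,
                    noise_read_rate = 20, seed = 37)
  g <- make_genome(cfg)
  tt <- plant_truth(g, cfg)
  sam <- tempfile(fileext = ".sam")
  simulate_reads(g, tt$individuals[[1]], cfg, sam)
  called <- call_sites(filter_reads(read_alignments(sam, g)), g)
  for (ch in unique(called$chrom)) {
    seqs <- as.character(g[[ch]])
    p <- called$pos[called$chrom == ch]
    expect_true(all(substring(seqs, p + 1, p + 2) == "CG"))
  }
})
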