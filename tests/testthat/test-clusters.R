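cluster_sites <- function(pos, chrom = "chr1") {
  hmc_sites(rep(chrom, length(pos)), as.integer(pos),
            rep("+", length(pos)), individual_id = "c")
}

test_that("chaining joins runs of close sites and enforces min_sites", {
  cl <- call_clusters(cluster_sites(c(100, 250, 400, 700)))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$start, 100L)
  expect_identical(cl$end, 401L)     # last site + 1, half-open
  expect_identical(cl$n_sites, 3L)
  expect_identical(cl$midpoint, 250L)

  expect_identical(nrow(call_clusters(cluster_sites(c(100, 301)))), 0L)
  # exactly at the gap boundary joins; one past does not
  expect_identical(nrow(call_clusters(cluster_sites(c(0, 200, 400)))), 1L)
  expect_identical(nrow(call_clusters(cluster_sites(c(0, 201, 402)))), 0L)
})

test_that("cluster calling matches the brute-force chaining oracle on random instances", {
  set.seed(55)
  for (rep in 1:100) {
    n <- sample(c(10, 100, 1000, 10000), 1)
    chrom <- sample(paste0("chr", 1:3), n, replace = TRUE)
    pos <- sample.int(2e5, n)
    keep <- !duplicated(paste(chrom, pos))
    chrom <- chrom[keep]; pos <- pos[keep]
    cfg <- cluster_config(min_sites = sample(2:4, 1),
                          max_gap = sample(c(50, 200, 500), 1))
    s <- hmc_sites(chrom, pos, rep("+", length(pos)), individual_id = "r")
    got <- as.data.frame(call_clusters(s, cfg))[, c("chrom", "start", "end", "n_sites")]
    want <- oracle_chain_clusters(chrom, pos, cfg$max_gap, cfg$min_sites)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("clusters are disjoint, separated by more than the gap, and gap-monotone", {
  set.seed(56)
  pos <- sort(sample.int(50000, 2000))
  s <- cluster_sites(pos)
  cl <- call_clusters(s, cluster_config(max_gap = 100))
  if (nrow(cl) > 1) {
    expect_true(all(cl$start[-1] - cl$end[-nrow(cl)] > 100 - 1))
  }
  in_sites <- function(gap) {
    sum(call_clusters(s, cluster_config(max_gap = gap))$n_sites)
  }
  gaps <- c(20, 50, 100, 200)
  expect_true(all(diff(vapply(gaps, in_sites, 0)) >= 0))
})

test_that("cluster-gene assignment: body first, then nearest TSS within 250 kb", {
  tx <- data.frame(chrom = "chr1",
                   start = c(10000L, 400000L, 404000L),
                   end = c(12000L, 402000L, 406000L),
                   gene_id = c("near", "far", "farther"),
                   strand = "+",
                   exon_starts = c("10000", "400000", "404000"),
                   exon_ends = c("12000", "402000", "406000"),
                   stringsAsFactors = FALSE)
  genes <- build_gene_models(tx)
  cl <- data.frame(chrom = "chr1",
                   start = c(11000L, 20000L, 700000L, 399000L),
                   end = c(11101L, 20101L, 700101L, 399101L),
                   n_sites = 3L)
  cl$midpoint <- (cl$start + cl$end) %/% 2L
  class(cl) <- c("hmc_clusters", "data.frame")
  got <- assign_cluster_gene(cl, genes, cluster_config())
  expect_identical(got$assigned_gene[1], "near")
  expect_identical(got$assignment_mode[1], "within_body")
  expect_identical(got$assigned_gene[2], "near")   # 10 kb beats 380 kb
  expect_identical(got$assignment_mode[2], "nearest_tss")
  expect_identical(got$assignment_mode[3], "unassigned")  # > 250 kb from any TSS
  expect_identical(got$assigned_gene[4], "far")    # 1 kb vs 5 kb
})

test_that("nested gene bodies resolve to the smallest, ties to lexicographic id", {
  tx <- data.frame(chrom = "chr1", start = c(1000L, 1400L),
                   end = c(5000L, 1800L), gene_id = c("outer", "inner"),
                   strand = "+", exon_starts = c("1000", "1400"),
                   exon_ends = c("5000", "1800"), stringsAsFactors = FALSE)
  genes <- build_gene_models(tx)
  cl <- data.frame(chrom = "chr1", start = 1500L, end = 1601L, n_sites = 3L,
                   midpoint = 1550L)
  class(cl) <- c("hmc_clusters", "data.frame")
  expect_identical(assign_cluster_gene(cl, genes, cluster_config())$assigned_gene,
                   "inner")
})

test_that("enrichment p-values are exact and BH-corrected", {
  background <- sprintf("g%02d", 1:20)
  gene_list <- background[1:5]
  terms <- list(hit = background[c(1:4)],          # all 4 in the list
                whole = background)                 # term = background
  en <- enrich(gene_list, background, terms)
  expect_equal(en$p[en$term == "hit"], 16 / 15504, tolerance = 1e-12)
  expect_identical(en$direction[en$term == "hit"], "up")
  expect_equal(en$p[en$term == "whole"], 1)
  expect_equal(en$expected[en$term == "whole"], en$observed[en$term == "whole"])
  expect_error(enrich(c("g01", "zz"), background, terms), "zz")
})

test_that("BH step-up matches the direct formula on a five-term fixture", {
  background <- sprintf("g%03d", 1:100)
  set.seed(57)
  terms <- lapply(1:5, function(i) sample(background, 10 + 5 * i))
  names(terms) <- paste0("t", 1:5)
  gene_list <- sample(background, 20)
  en <- enrich(gene_list, background, terms)
  p <- en$p
  m <- length(p)
  direct <- vapply(seq_len(m), function(i) {
    min(p[i:m] * m / (i:m))   # en is sorted by p
  }, 0)
  expect_equal(en$fdr, pmin(1, direct))
  expect_true(all(en$fdr >= en$p - 1e-15))
})

test_that("enrichment p-values are uniform under a random-draw null", {
  background <- sprintf("g%03d", 1:200)
  set.seed(58)
  term <- sample(background, 80)
  pvals <- vapply(1:1000, function(i) {
    gl <- sample(background, 50)
    obs <- length(intersect(gl, term))
    # mid-p style smoothing is NOT applied; use the discrete tail as-is but
    # randomize within the atom to make the KS test applicable
    p_ge <- exp(hmcaller:::hyper_upper_log(obs, 80, 50, 200))
    p_gt <- if (obs < 50) exp(hmcaller:::hyper_upper_log(obs + 1, 80, 50, 200)) else 0
    runif(1, p_gt, p_ge)
  }, 0)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
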