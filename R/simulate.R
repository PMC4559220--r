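#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study conditions the package is designed around: a cohort of 19
#' individuals, 50 bp single-end reads, and the enzyme's 11-13 bp cut-to-5hmC
#' offset, on a CpG-poor toy genome.
#'
#' @param n_chroms Number of chromosomes (>= 2 adds a designated `"chrX"` as
#'   the last chromosome, used by the sex/X-inactivation analyses).
#' @param chrom_length Length of every chromosome in bp.
#' @param cpg_rate Target CG dinucleotide frequency (count per bp); must be
#'   <= 0.5. The generator injects exactly this many CGs into a CpG-free
#'   background, so the realized frequency is within sampling error of the
#'   target.
#' @param n_individuals Cohort size.
#' @param core_fraction Fraction of all CpGs planted as core 5hmC sites
#'   carried by every individual.
#' @param private_rate Per-individual probability that each non-core CpG
#'   carries a private 5hmC site.
#' @param reads_per_site Mean (Poisson) supporting reads per planted site.
#' @param offset_weights Named numeric over offsets 11, 12, 13: probability
#'   that a read's 5' end sits that many bases (1-based, along the read's own
#'   strand) from the hydroxymethylated C. Must sum to 1.
#' @param noise_read_rate Background (non-site) reads per kb of genome.
#' @param read_length Read length in bp.
#' @param sexes Optional character vector of length `n_individuals` with
#'   `"M"`/`"F"` labels; defaults to all-male as in the primary cohort.
#' @param seed Master seed; every downstream draw derives from it, so a fixed
#'   config reproduces byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 100000L, cpg_rate = 0.02,
                       n_individuals = 19L, core_fraction = 0.3,
                       private_rate = 0.05, reads_per_site = 5,
                       offset_weights = c(`11` = 0.25, `12` = 0.5, `13` = 0.25),
                       noise_read_rate = 5, read_length = 50L,
                       sexes = NULL, seed = 1L) {
  cfg <- list(n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              cpg_rate = cpg_rate, n_individuals = as.integer(n_individuals),
              core_fraction = core_fraction, private_rate = private_rate,
              reads_per_site = reads_per_site,
              offset_weights = offset_weights,
              noise_read_rate = noise_read_rate,
              read_length = as.integer(read_length),
              sexes = sexes, seed = as.integer(seed))
  if (cfg$cpg_rate < 0 || cfg$cpg_rate > 0.5) stop("cpg_rate must be in [0, 0.5]")
  if (!all(names(cfg$offset_weights) %in% c("11", "12", "13"))) {
    stop("offset_weights names must be among 11, 12, 13")
  }
  if (abs(sum(cfg$offset_weights) - 1) > 1e-9) stop("offset_weights must sum to 1")
  for (f in c("core_fraction", "private_rate")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (!is.null(sexes)) {
    if (length(sexes) != cfg$n_individuals || !all(sexes %in% c("M", "F"))) {
      stop("sexes must be length n_individuals with values 'M'/'F'")
    }
  }
  if (cfg$n_chroms < 1L || cfg$chrom_length < 100L) stop("genome too small")
  structure(cfg, class = "sim_config")
}

sim_chrom_names <- function(cfg) {
  if (cfg$n_chroms >= 2L) {
    c(paste0("chr", seq_len(cfg$n_chroms - 1L)), "chrX")
  } else {
    "chr1"
  }
}

#' Generate a toy genome with a controlled CpG rate
#'
#' Builds each chromosome from i.i.d. bases, removes every chance CG
#' dinucleotide, then injects `round(cpg_rate * chrom_length)` CG
#' dinucleotides at distinct even positions. The realized CG frequency is
#' therefore exact up to rounding, mimicking the CpG depletion of real
#' genomes while controlling the density.
#'
#' @param cfg A [sim_config()].
#' @return A `DNAStringSet`.
#' @export
make_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "genome"))
  L <- cfg$chrom_length
  seqs <- vapply(seq_len(cfg$n_chroms), function(i) {
    b <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # break background CGs: turn the G of each CG into A (cannot create a CG)
    g_at <- which(b[-L] == "C" & b[-1] == "G") + 1L
    if (length(g_at)) b[g_at] <- "A"
    n_inject <- round(cfg$cpg_rate * L)
    if (n_inject > 0) {
      # >= 4 bp between CG starts when the density permits: mirrors real CpG
      # depletion and keeps cut-site offset attribution unambiguous
      grid <- if (cfg$cpg_rate <= 0.25) seq(1L, L - 3L, by = 4L)
              else seq(1L, L - 1L, by = 2L)
      at <- sample(grid, n_inject)
      b[at] <- "C"; b[at + 1L] <- "G"
    }
    paste(b, collapse = "")
  }, character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- sim_chrom_names(cfg)
  g
}

#' Plant a multi-individual 5hmC truth table
#'
#' Samples a core site set (a `core_fraction` share of all CpGs, one strand
#' drawn per site) shared by every individual; each individual then adds
#' private sites independently at `private_rate` per remaining CpG, with
#' uniform strands. This reproduces the sharing structure the consensus
#' analyses operate on: a stable common backbone plus individual variability.
#'
#' @param genome A `DNAStringSet` (from [make_genome()] or elsewhere).
#' @param cfg A [sim_config()].
#' @return An object of class `truth_table`: list with `individuals` (named
#'   list of `hmc_sites`), `core` (`hmc_sites`), and `sexes`.
#' @export
plant_truth <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "truth"))
  idx <- build_cpg_index(genome)
  lens <- genome_lengths(genome)
  # plant only CpGs far enough from chromosome edges that every read offset
  # fits, so every planted site is recoverable
  margin <- cfg$read_length
  all_cpg <- do.call(rbind, lapply(names(idx$pos), function(ch) {
    p <- idx$pos[[ch]]
    p <- p[p >= margin & p <= lens[[ch]] - margin - 2L]
    if (!length(p)) return(NULL)
    data.frame(chrom = ch, pos = p, stringsAsFactors = FALSE)
  }))
  if (is.null(all_cpg) || !nrow(all_cpg)) stop("genome contains no CpGs")
  n_cpg <- nrow(all_cpg)
  n_core <- round(cfg$core_fraction * n_cpg)
  core_i <- sort(sample.int(n_cpg, n_core))
  core_strand <- sample(c("+", "-"), n_core, replace = TRUE)
  core <- hmc_sites(chrom = all_cpg$chrom[core_i], pos = all_cpg$pos[core_i],
                    strand = core_strand, individual_id = "core")
  rest_i <- setdiff(seq_len(n_cpg), core_i)
  sexes <- cfg$sexes %||% rep("M", cfg$n_individuals)
  ids <- sprintf("ind%02d", seq_len(cfg$n_individuals))
  individuals <- vector("list", cfg$n_individuals)
  for (j in seq_len(cfg$n_individuals)) {
    take <- rest_i[stats::runif(length(rest_i)) < cfg$private_rate]
    priv_strand <- sample(c("+", "-"), length(take), replace = TRUE)
    individuals[[j]] <- hmc_sites(
      chrom = c(all_cpg$chrom[core_i], all_cpg$chrom[take]),
      pos = c(all_cpg$pos[core_i], all_cpg$pos[take]),
      strand = c(core_strand, priv_strand),
      individual_id = ids[j], sex = sexes[j])
  }
  names(individuals) <- ids
  structure(list(individuals = individuals, core = core, sexes = sexes,
                 config = cfg),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("5hmC truth table: %d individuals, %d core sites\n",
              length(x$individuals), nrow(x$core)))
  n <- vapply(x$individuals, nrow, 0L)
  cat(sprintf("  sites per individual: %d-%d (median %g)\n",
              min(n), max(n), stats::median(n)))
  invisible(x)
}

#' Simulate AbaSI-style aligned reads for one site set
#'
#' Each site receives `Poisson(reads_per_site)` reads whose 5' aligned end is
#' placed so the site's C occupies read offset d (1-based along the read's
#' own strand), with d drawn from `offset_weights`. For a plus-strand site at
#' position p the read starts at `p - (d - 1)`; for a minus-strand site the
#' mirrored construction places the read's rightmost aligned base at
#' `p + d` (the minus-strand C sits at plus-coordinate p + 1). Background
#' noise reads are laid down uniformly at `noise_read_rate` per kb with mixed
#' mapping and base qualities; signal reads carry mapq 42 and uniformly high
#' base quality. Reads that would run past a chromosome edge are skipped with
#' a logged count. Output is coordinate-sorted, ungapped SAM.
#'
#' @param genome A `DNAStringSet`.
#' @param sites An `hmc_sites` object (the individual's truth).
#' @param cfg A [sim_config()].
#' @param path Output SAM path.
#' @param seed Seed for this individual's draws; defaults to a value derived
#'   from `cfg$seed` and the site set's individual id.
#' @return `path` invisibly, with attribute `n_skipped`.
#' @export
simulate_reads <- function(genome, sites, cfg, path,
                           seed = derive_seed(cfg$seed,
                                              attr(sites, "individual_id"))) {
  stopifnot(inherits(cfg, "sim_config"), inherits(sites, "hmc_sites"))
  set.seed(seed)
  lens <- genome_lengths(genome)
  L <- cfg$read_length
  offs <- as.integer(names(cfg$offset_weights))
  # zero-truncated Poisson: mean reads_per_site, but every site covered, so
  # noise-free recovery of the planted set is exact
  n_per_site <- 1L + stats::rpois(nrow(sites), max(cfg$reads_per_site - 1, 0))
  i_site <- rep(seq_len(nrow(sites)), n_per_site)
  n_sig <- length(i_site)
  d <- offs[sample.int(length(offs), n_sig, replace = TRUE,
                       prob = cfg$offset_weights)]
  chrom <- sites$chrom[i_site]
  pos <- sites$pos[i_site]
  strand <- sites$strand[i_site]
  start <- ifelse(strand == "+", pos - (d - 1L), pos + d - L + 1L)
  keep <- start >= 0L & start + L <= lens[chrom]
  n_skipped <- sum(!keep)
  if (n_skipped) log_msg("simulate_reads: %d read(s) skipped at chromosome edges", n_skipped)
  sig <- data.frame(chrom = chrom[keep], start = as.integer(start[keep]),
                    strand = strand[keep], mapq = 42L,
                    stringsAsFactors = FALSE)
  # background noise: uniform positions, mixed qualities
  n_noise <- stats::rpois(1L, cfg$noise_read_rate * sum(lens) / 1000)
  noise <- NULL
  if (n_noise > 0) {
    nch <- sample(names(lens), n_noise, replace = TRUE, prob = lens / sum(lens))
    nst <- vapply(nch, function(ch) sample.int(lens[[ch]] - L + 1L, 1L) - 1L, 0L)
    noise <- data.frame(chrom = nch, start = as.integer(nst),
                        strand = sample(c("+", "-"), n_noise, replace = TRUE),
                        mapq = sample(c(3L, 8L, 25L, 42L), n_noise,
                                      replace = TRUE,
                                      prob = c(0.1, 0.1, 0.3, 0.5)),
                        stringsAsFactors = FALSE)
  }
  reads <- rbind(sig, noise)
  if (is.null(reads) || !nrow(reads)) {
    reads <- data.frame(chrom = character(), start = integer(),
                        strand = character(), mapq = integer(),
                        stringsAsFactors = FALSE)
  }
  n_all <- nrow(reads)
  reads$read_id <- sprintf("%s_r%06d",
                           attr(sites, "individual_id") %||% "sim",
                           seq_len(n_all))
  # sequence from the reference; minus-strand reads are reverse-complemented
  reads$seq <- rep(NA_character_, n_all)
  for (ch in unique(reads$chrom)) {
    i <- which(reads$chrom == ch)
    v <- Biostrings::Views(genome[[ch]],
                           start = reads$start[i] + 1L,
                           width = L)
    s <- as.character(Biostrings::DNAStringSet(v))
    rev <- reads$strand[i] == "-"
    if (any(rev)) {
      s[rev] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(s[rev])))
    }
    reads$seq[i] <- s
  }
  # base qualities: signal reads Q40; a fraction of noise reads low quality
  qual_hi <- strrep("I", L)           # Q40
  qual_lo <- strrep("5", L)           # Q20, fails the mean-baseq filter
  is_noise <- seq_len(n_all) > nrow(sig)
  lowq <- is_noise & stats::runif(n_all) < 0.2
  reads$qual <- ifelse(lowq, qual_lo, qual_hi)
  write_sam(reads, genome, path)
  structure(invisible(path), n_skipped = n_skipped)
}

#' Emit simulated reads as FASTQ
#'
#' Companion to [simulate_reads()] for workflows that want to run their own
#' aligner; the package itself consumes the aligned SAM.
#'
#' @param sam_path A SAM file produced by [simulate_reads()].
#' @param fastq_path Output FASTQ path.
#' @return `fastq_path`, invisibly.
#' @export
sam_to_fastq <- function(sam_path, fastq_path) {
  lines <- readLines(sam_path)
  rec <- lines[!startsWith(lines, "@")]
  f <- strsplit(rec, "\t", fixed = TRUE)
  con <- file(fastq_path, "w")
  on.exit(close(con))
  for (x in f) {
    writeLines(c(paste0("@", x[1]), x[10], "+", x[11]), con)
  }
  invisible(fastq_path)
}
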