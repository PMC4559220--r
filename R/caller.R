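#' Site-caller configuration
#'
#' @param offsets Integer subset of `c(11, 12, 13)`: 1-based read offsets
#'   (from the 5' end, along the read's own strand) at which the
#'   hydroxymethylated C is expected, given the enzyme cuts 11-13 bp
#'   downstream of the modified base. Tested in ascending order,
#'   first match wins.
#' @param min_mean_baseq Reads with mean base quality **strictly greater**
#'   than this are kept (default 30).
#' @param min_mapq Reads with mapping quality **greater or equal** to this
#'   are kept (default 10).
#' @param collapse_duplicates Collapse reads sharing (chrom, start, strand)
#'   to one representative before calling.
#' @param min_support Minimum supporting reads for an emitted site.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(offsets = c(11L, 12L, 13L), min_mean_baseq = 30,
                          min_mapq = 10L, collapse_duplicates = TRUE,
                          min_support = 1L) {
  offsets <- sort(unique(as.integer(offsets)))
  if (!length(offsets) || !all(offsets %in% 11:13)) {
    stop("offsets must be a non-empty subset of 11:13")
  }
  if (min_mean_baseq < 0 || min_mapq < 0 || min_support < 1) {
    stop("thresholds must be non-negative and min_support >= 1")
  }
  structure(list(offsets = offsets, min_mean_baseq = min_mean_baseq,
                 min_mapq = as.integer(min_mapq),
                 collapse_duplicates = isTRUE(collapse_duplicates),
                 min_support = as.integer(min_support)),
            class = "caller_config")
}

#' Quality-filter aligned reads
#'
#' Keeps reads with mean base quality strictly above `min_mean_baseq` and
#' mapping quality at or above `min_mapq`; drop counts are logged by reason.
#'
#' @param reads Data frame from [read_alignments()].
#' @param cfg A [caller_config()].
#' @return The filtered data frame, with attribute `dropped` (named counts).
#' @export
filter_reads <- function(reads, cfg = caller_config()) {
  low_bq <- !(reads$mean_baseq > cfg$min_mean_baseq)
  low_mq <- !(reads$mapq >= cfg$min_mapq)
  dropped <- c(baseq = sum(low_bq), mapq = sum(low_mq & !low_bq))
  if (sum(dropped) > 0) {
    log_msg("filter_reads: dropped %d by base quality, %d by mapping quality",
            dropped[["baseq"]], dropped[["mapq"]])
  }
  out <- reads[!low_bq & !low_mq, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Collapse positional duplicate reads
#'
#' Retains at most one read per (chrom, start, strand): highest mapping
#' quality wins, ties broken by lexicographically smallest read id. This is
#' the package's stand-in for an upstream duplicate-marking step; input must
#' already be sorted by (chrom, start, strand).
#'
#' @param reads Data frame from [read_alignments()], coordinate-sorted.
#' @return The deduplicated data frame.
#' @export
collapse_duplicates <- function(reads) {
  if (!nrow(reads)) return(reads)
  o <- order(reads$chrom, reads$start, reads$strand, method = "radix")
  if (any(o != seq_along(o))) {
    stop("collapse_duplicates requires input sorted by (chrom, start, strand)")
  }
  key <- paste(reads$chrom, reads$start, reads$strand, sep = ":")
  pick <- order(key, -reads$mapq, reads$read_id, method = "radix")
  keep <- pick[!duplicated(key[pick])]
  out <- reads[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call 5hmC sites from filtered AbaSI reads
#'
#' For each read, candidate cytosine positions are tested at each configured
#' offset in ascending order: offset d puts the candidate d bases into the
#' read from its 5' aligned end on the read's own strand (for a minus-strand
#' read, counted leftward from its rightmost aligned base). If the reference
#' shows a CpG there — C at the candidate on the read strand with G adjacent
#' 3' on that strand — a site is emitted at the plus-strand C of that CpG
#' with the read's strand, and no further offsets are tested for that read.
#' Reads with no CpG at any tested offset yield no call. Identical sites are
#' aggregated; support is the number of contributing reads.
#'
#' @param reads Data frame of filtered alignments.
#' @param genome A `DNAStringSet`.
#' @param cfg A [caller_config()]; when `cfg$collapse_duplicates` is set the
#'   reads are deduplicated (after sorting) before calling.
#' @param individual_id Id recorded on the returned site set.
#' @param sex Optional sex label.
#' @return An `hmc_sites` object (validated against the genome).
#' @export
call_sites <- function(reads, genome, cfg = caller_config(),
                       individual_id = NA_character_, sex = NA_character_) {
  if (cfg$collapse_duplicates && nrow(reads)) {
    o <- order(reads$chrom, reads$start, reads$strand, method = "radix")
    reads <- collapse_duplicates(reads[o, , drop = FALSE])
  }
  n <- nrow(reads)
  if (!n) {
    return(hmc_sites(individual_id = individual_id, sex = sex))
  }
  lens <- genome_lengths(genome)
  missing <- setdiff(unique(reads$chrom), names(lens))
  if (length(missing)) {
    stop("read chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "))
  }
  site_pos <- rep(NA_integer_, n)
  chrom_seq <- new.env(parent = emptyenv())
  get_seq <- function(ch) {
    s <- get0(ch, envir = chrom_seq, inherits = FALSE)
    if (is.null(s)) {
      s <- as.character(genome[[ch]])
      assign(ch, s, envir = chrom_seq)
    }
    s
  }
  for (d in cfg$offsets) {
    todo <- which(is.na(site_pos))
    if (!length(todo)) break
    r <- reads[todo, , drop = FALSE]
    plus <- r$strand == "+"
    # candidate site position = plus-strand C of the CpG under test
    cand <- ifelse(plus,
                   r$start + d - 1L,                       # C at offset d
                   (r$start + r$length - 1L) - (d - 1L) - 1L) # G at offset d on '-'
    hit <- logical(length(todo))
    for (ch in unique(r$chrom)) {
      i <- which(r$chrom == ch)
      dn <- ref_dinuc(get_seq(ch), cand[i])
      hit[i] <- !is.na(dn) & dn == "CG"
    }
    site_pos[todo[hit]] <- as.integer(cand[hit])
  }
  called <- !is.na(site_pos)
  if (!any(called)) {
    return(hmc_sites(individual_id = individual_id, sex = sex))
  }
  key <- site_key(reads$chrom[called], site_pos[called], reads$strand[called])
  agg <- table(key)
  first <- !duplicated(key)
  chrom <- reads$chrom[called][first]
  pos <- site_pos[called][first]
  strand <- reads$strand[called][first]
  support <- as.integer(agg[site_key(chrom, pos, strand)])
  keep <- support >= cfg$min_support
  hmc_sites(chrom = chrom[keep], pos = pos[keep], strand = strand[keep],
            support = support[keep], individual_id = individual_id,
            sex = sex, genome = genome)
}
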