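#' Read aligned AbaSI reads from SAM or BAM
#'
#' Loads mapped single-end records into a plain data frame of alignment
#' summaries. Only the fields the downstream caller consumes are kept: flag
#' (strand, unmapped), position, mapping quality, and base qualities (reduced
#' to their mean). CIGAR strings are treated as fully aligned; records with
#' insertions, deletions or clipping are dropped with a logged count, since
#' the cut-site offset geometry is only defined for ungapped alignments.
#'
#' @param path A SAM (`.sam`) or BAM file. SAM input is converted in a
#'   temporary directory via [Rsamtools::asBam()].
#' @param genome Optional `DNAStringSet`; when given, every read chromosome
#'   must be present in it.
#' @return A data frame with columns `read_id`, `chrom`, `start` (0-based
#'   leftmost aligned position), `strand`, `length`, `mapq`, `mean_baseq`.
#'   Unmapped records are skipped.
#' @export
read_alignments <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    path
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  mapped <- bitwAnd(rec$flag, 4L) == 0L & !is.na(rec$pos)
  n_unmapped <- sum(!mapped)
  cig <- rec$cigar[mapped]
  simple <- is.na(cig) | grepl("^[0-9]+M$", cig)
  if (any(!simple)) {
    log_msg("read_alignments: dropped %d read(s) with non-trivial CIGAR",
            sum(!simple))
  }
  keep <- which(mapped)[simple]
  if (n_unmapped > 0) log_msg("read_alignments: skipped %d unmapped record(s)", n_unmapped)
  chrom <- as.character(rec$rname[keep])
  if (!is.null(genome)) {
    missing <- setdiff(unique(chrom), names(genome))
    if (length(missing)) {
      stop("read chromosome(s) absent from genome: ",
           paste(missing, collapse = ", "))
    }
  }
  qual <- as(rec$qual[keep], "IntegerList")
  data.frame(
    read_id = rec$qname[keep],
    chrom = chrom,
    start = rec$pos[keep] - 1L,
    strand = ifelse(bitwAnd(rec$flag[keep], 16L) != 0L, "-", "+"),
    length = Biostrings::width(rec$seq[keep]),
    mapq = rec$mapq[keep],
    mean_baseq = vapply(as.list(qual), mean, numeric(1)),
    stringsAsFactors = FALSE
  )
}

# Write aligned records as plain SAM. Used by the simulator; reads must carry
# chrom/start/strand/mapq plus seq and qual strings.
write_sam <- function(reads, genome, path) {
  lens <- genome_lengths(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens), con)
  if (nrow(reads)) {
    o <- order(match(reads$chrom, names(lens)), reads$start, reads$strand,
               reads$read_id, method = "radix")
    r <- reads[o, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                       r$read_id,
                       ifelse(r$strand == "-", 16L, 0L),
                       r$chrom, r$start + 1L, r$mapq,
                       nchar(r$seq), r$seq, r$qual), con)
  }
  invisible(path)
}
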