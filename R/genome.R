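#' Load a reference genome from FASTA
#'
#' Reads all records of a FASTA file into a [Biostrings::DNAStringSet],
#' uppercasing the sequence. Record names are truncated at the first
#' whitespace. Only the letters A, C, G, T and N are accepted; the coordinate
#' frame of every other object in the package (sites, features, reads) is
#' defined against these sequences, 0-based and half-open.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per chromosome, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- load_genome(fa)
#' genome_lengths(g)
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  g <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g))) stop("duplicate chromosome names in ", path)
  g <- Biostrings::DNAStringSet(toupper(as.character(g)))
  af <- Biostrings::alphabetFrequency(g)
  other <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(other > 0)) {
    stop("genome contains letters outside A/C/G/T/N on: ",
         paste(names(g)[other > 0], collapse = ", "))
  }
  g
}

#' Chromosome lengths of a genome
#'
#' @param genome A `DNAStringSet` as returned by [load_genome()].
#' @return Named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Index all CpG dinucleotides of a genome
#'
#' Scans the plus strand of every chromosome for CG dinucleotides and records
#' the 0-based position of the C. A CpG is one strand-symmetric unit: the
#' minus-strand cytosine of the same dinucleotide maps to the same indexed
#' position. Dinucleotides containing N are never indexed.
#'
#' @param genome A `DNAStringSet`.
#' @return An object of class `cpg_index` supporting [cpg_count()] and
#'   [cpg_positions()].
#' @export
build_cpg_index <- function(genome) {
  pos <- lapply(seq_along(genome), function(i) {
    as.integer(Biostrings::start(Biostrings::matchPattern("CG", genome[[i]]))) - 1L
  })
  names(pos) <- names(genome)
  structure(list(pos = pos, lengths = genome_lengths(genome)),
            class = "cpg_index")
}

#' CpG positions on one chromosome
#'
#' @param index A `cpg_index`.
#' @param chrom Chromosome name.
#' @return Sorted integer vector of 0-based positions of the plus-strand C.
#' @export
cpg_positions <- function(index, chrom) {
  stopifnot(inherits(index, "cpg_index"))
  p <- index$pos[[chrom]]
  if (is.null(p)) stop("chromosome not in CpG index: ", chrom)
  p
}

#' Count CpGs in half-open intervals
#'
#' Counts indexed CpG positions falling in `[start, end)`. Vectorized over
#' intervals; counts are additive over abutting intervals.
#'
#' @param index A `cpg_index`.
#' @param chrom Chromosome name(s), recycled against `start`/`end`.
#' @param start,end 0-based half-open interval bounds.
#' @return Integer vector of counts.
#' @export
cpg_count <- function(index, chrom, start, end) {
  stopifnot(inherits(index, "cpg_index"))
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  if (any(end < start)) stop("interval with end < start")
  out <- integer(n)
  for (ch in unique(chrom)) {
    p <- cpg_positions(index, ch)
    i <- which(chrom == ch)
    out[i] <- findInterval(end[i] - 0.5, p) - findInterval(start[i] - 0.5, p)
  }
  out
}

#' @export
print.cpg_index <- function(x, ...) {
  cat("CpG index over", length(x$pos), "chromosome(s)\n")
  for (ch in names(x$pos)) {
    cat(sprintf("  %s: %d CpGs / %d bp\n", ch, length(x$pos[[ch]]), x$lengths[[ch]]))
  }
  invisible(x)
}

# Reference dinucleotide at a 0-based position, vectorized. Used by the
# caller's CpG-context check; returns e.g. "CG", "AN", or NA out of range.
ref_dinuc <- function(chrom_seq, pos) {
  out <- rep(NA_character_, length(pos))
  ok <- pos >= 0 & pos + 1 < nchar(chrom_seq)
  out[ok] <- substring(chrom_seq, pos[ok] + 1L, pos[ok] + 2L)
  out
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
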