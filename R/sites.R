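#' Construct a per-individual 5hmC site set
#'
#' A site is a strand-aware single-base 5hmC call at a CpG. `pos` is always
#' the 0-based position of the plus-strand C of the CpG; hydroxymethylation of
#' the minus-strand cytosine of the same dinucleotide is recorded as the same
#' `pos` with strand `"-"`. Sites are unique by (chrom, pos, strand) and kept
#' sorted by chromosome then position.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector, 0-based positions of the plus-strand C.
#' @param strand Character vector, `"+"` or `"-"` (strand of the modified C).
#' @param support Integer vector of supporting read counts (>= 1).
#' @param individual_id Single string identifying the individual.
#' @param sex `"M"`, `"F"` or `NA` for unknown.
#' @param genome Optional `DNAStringSet`; when given, every site is checked to
#'   sit on a reference CG dinucleotide.
#' @return A data frame of class `hmc_sites` with columns
#'   `chrom`, `pos`, `strand`, `support` and attributes `individual_id`, `sex`.
#' @export
hmc_sites <- function(chrom = character(), pos = integer(),
                      strand = character(), support = 1L,
                      individual_id = NA_character_, sex = NA_character_,
                      genome = NULL) {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  support <- rep_len(as.integer(support), n)
  if (n > 0 && any(support < 1L)) stop("site support must be >= 1")
  if (n > 0 && !all(strand %in% c("+", "-"))) stop("site strand must be '+' or '-'")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), support = support,
                   stringsAsFactors = FALSE)
  o <- order(df$chrom, df$pos, df$strand, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(site_key(df$chrom, df$pos, df$strand))) {
    stop("duplicate (chrom, pos, strand) in site set")
  }
  if (!is.null(genome)) validate_sites_against_genome(df, genome)
  structure(df,
            individual_id = as.character(individual_id),
            sex = as.character(sex),
            class = c("hmc_sites", "data.frame"))
}

validate_sites_against_genome <- function(df, genome) {
  lens <- genome_lengths(genome)
  missing <- setdiff(unique(df$chrom), names(lens))
  if (length(missing)) stop("site chromosome(s) not in genome: ",
                            paste(missing, collapse = ", "))
  for (ch in unique(df$chrom)) {
    i <- df$chrom == ch
    if (any(df$pos[i] < 0L | df$pos[i] >= lens[[ch]] - 1L)) {
      stop("site position out of range on ", ch)
    }
    dn <- ref_dinuc(as.character(genome[[ch]]), df$pos[i])
    if (any(dn != "CG")) stop("site not at a reference CpG on ", ch)
  }
  invisible(TRUE)
}

#' @export
print.hmc_sites <- function(x, ...) {
  cat(sprintf("5hmC site set: %d sites", nrow(x)))
  id <- attr(x, "individual_id")
  if (!is.na(id)) cat(" [", id, "]", sep = "")
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
summary.hmc_sites <- function(object, ...) {
  c(n_sites = nrow(object),
    n_chroms = length(unique(object$chrom)),
    plus = sum(object$strand == "+"),
    minus = sum(object$strand == "-"),
    total_support = sum(object$support))
}

#' Write a site set as BED6
#'
#' One line per site: chrom, pos, pos+1, individual_id, support, strand.
#' The round trip through [read_sites()] is lossless.
#'
#' @param sites An `hmc_sites` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  stopifnot(inherits(sites, "hmc_sites"))
  id <- attr(sites, "individual_id")
  if (is.na(id)) id <- "."
  lines <- if (nrow(sites)) {
    sprintf("%s\t%d\t%d\t%s\t%d\t%s",
            sites$chrom, sites$pos, sites$pos + 1L, id, sites$support,
            sites$strand)
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read a site set from BED6
#'
#' @param path A BED6 file written by [write_sites()].
#' @param sex Optional sex label to attach.
#' @param genome Optional genome for CpG validation.
#' @return An `hmc_sites` object.
#' @export
read_sites <- function(path, sex = NA_character_, genome = NULL) {
  if (!file.exists(path)) stop("site file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(hmc_sites(individual_id = NA_character_, sex = sex, genome = genome))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 6L)
  if (length(bad)) stop("malformed BED6 line ", bad[1], " in ", path)
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  sup <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(pos) | is.na(end) | is.na(sup) | end != pos + 1L)
  if (length(bad)) stop("malformed BED6 line ", bad[1], " in ", path)
  id <- unique(m[, 4])
  if (length(id) != 1L) stop("multiple individual ids in ", path)
  hmc_sites(chrom = m[, 1], pos = pos, strand = m[, 6], support = sup,
            individual_id = if (id == ".") NA_character_ else id,
            sex = sex, genome = genome)
}

#' Merge the two strands of each CpG
#'
#' Collapses sites that share (chrom, pos) but differ in strand into one
#' plus-strand entry whose support is the sum. Off by default throughout the
#' package: strands are kept distinct because the data are strand-resolved.
#'
#' @param sites An `hmc_sites` object.
#' @return An `hmc_sites` object with at most one entry per CpG.
#' @export
merge_cpg_strands <- function(sites) {
  stopifnot(inherits(sites, "hmc_sites"))
  key <- paste(sites$chrom, sites$pos, sep = ":")
  agg <- rowsum(sites$support, key, reorder = FALSE)
  first <- !duplicated(key)
  hmc_sites(chrom = sites$chrom[first], pos = sites$pos[first],
            strand = rep("+", sum(first)),
            support = as.integer(agg[match(key[first], rownames(agg)), 1]),
            individual_id = attr(sites, "individual_id"),
            sex = attr(sites, "sex"))
}

# GRanges view of a site set (width-1 ranges at pos), for overlap machinery.
sites_granges <- function(sites, ignore_strand = TRUE) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L),
    strand = if (ignore_strand) "*" else sites$strand
  )
}
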