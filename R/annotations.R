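#' @name annotations
#' @title Annotation features and gene models
#' @description
#' Features are typed genomic intervals (0-based half-open) drawn from a
#' closed vocabulary; gene models carry a single canonical TSS/TES per gene
#' (5'-most transcript start on the plus strand, 3'-most coordinate on the
#' minus strand) plus merged, non-overlapping exons.
NULL

FEATURE_KINDS <- c("tss", "tes", "exon", "intron", "cpg_island", "cpg_shore",
                   "line", "sine", "enhancer_active", "enhancer_poised",
                   "promoter", "chip_peak")

#' Construct a feature table
#'
#' @param chrom,start,end,strand,kind,gene_id Parallel vectors; intervals are
#'   0-based half-open, `kind` must come from the closed vocabulary.
#' @return A data frame of class `hmc_features`.
#' @export
features <- function(chrom = character(), start = integer(), end = integer(),
                     strand = "*", kind = character(), gene_id = NA_character_) {
  n <- length(start)
  strand <- rep_len(strand, n); kind <- rep_len(kind, n)
  gene_id <- rep_len(as.character(gene_id), n)
  if (n > 0 && !all(kind %in% FEATURE_KINDS)) {
    stop("unknown feature kind(s): ",
         paste(setdiff(unique(kind), FEATURE_KINDS), collapse = ", "))
  }
  if (any(end <= start)) stop("feature with end <= start")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   kind = kind, gene_id = gene_id, stringsAsFactors = FALSE)
  o <- order(df$chrom, df$start, df$end, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hmc_features", "data.frame")
  df
}

features_granges <- function(feat) {
  GenomicRanges::GRanges(feat$chrom,
                         IRanges::IRanges(feat$start + 1L, feat$end),
                         strand = ifelse(feat$strand %in% c("+", "-"),
                                         feat$strand, "*"))
}

#' Build gene models from transcript rows
#'
#' Collapses one or more transcript rows per gene into a single model:
#' the canonical TSS is the 5'-most transcript start for plus-strand genes
#' and the 3'-most coordinate for minus-strand genes; exons are merged into
#' non-overlapping sorted intervals; the body spans the full extent.
#' Single-exon genes are flagged (`single_exon`) so boundary analyses can
#' exclude them.
#'
#' @param transcripts Data frame with columns `chrom`, `start`, `end`,
#'   `gene_id`, `strand`, `exon_starts`, `exon_ends` (comma-separated,
#'   0-based half-open).
#' @return A data frame of class `gene_models` with columns `gene_id`,
#'   `chrom`, `strand`, `tss`, `tes`, `body_start`, `body_end`, `n_exons`,
#'   `single_exon` and list columns `exon_starts`, `exon_ends`.
#' @export
build_gene_models <- function(transcripts) {
  req <- c("chrom", "start", "end", "gene_id", "strand", "exon_starts", "exon_ends")
  if (!all(req %in% names(transcripts))) {
    stop("transcript table must have columns: ", paste(req, collapse = ", "))
  }
  split_rows <- split(transcripts, transcripts$gene_id)
  out <- lapply(split_rows, function(tx) {
    strand <- unique(tx$strand)
    chrom <- unique(tx$chrom)
    if (length(strand) != 1L || length(chrom) != 1L) {
      stop("gene ", tx$gene_id[1], " spans multiple chromosomes or strands")
    }
    es <- unlist(lapply(strsplit(as.character(tx$exon_starts), ","), as.integer))
    ee <- unlist(lapply(strsplit(as.character(tx$exon_ends), ","), as.integer))
    if (length(es) != length(ee) || any(ee <= es)) {
      stop("malformed exon blocks for gene ", tx$gene_id[1])
    }
    merged <- IRanges::reduce(IRanges::IRanges(es + 1L, ee))
    body_start <- min(tx$start); body_end <- max(tx$end)
    tss <- if (strand == "+") min(tx$start) else max(tx$end) - 1L
    tes <- if (strand == "+") max(tx$end) - 1L else min(tx$start)
    list(gene_id = tx$gene_id[1], chrom = chrom, strand = strand,
         tss = as.integer(tss), tes = as.integer(tes),
         body_start = as.integer(body_start), body_end = as.integer(body_end),
         n_exons = length(merged),
         single_exon = length(merged) == 1L,
         exon_starts = list(IRanges::start(merged) - 1L),
         exon_ends = list(IRanges::end(merged)))
  })
  df <- data.frame(
    gene_id = vapply(out, `[[`, "", "gene_id"),
    chrom = vapply(out, `[[`, "", "chrom"),
    strand = vapply(out, `[[`, "", "strand"),
    tss = vapply(out, `[[`, 0L, "tss"),
    tes = vapply(out, `[[`, 0L, "tes"),
    body_start = vapply(out, `[[`, 0L, "body_start"),
    body_end = vapply(out, `[[`, 0L, "body_end"),
    n_exons = vapply(out, `[[`, 0L, "n_exons"),
    single_exon = vapply(out, `[[`, TRUE, "single_exon"),
    stringsAsFactors = FALSE
  )
  df$exon_starts <- lapply(out, function(x) x$exon_starts[[1]])
  df$exon_ends <- lapply(out, function(x) x$exon_ends[[1]])
  o <- order(df$chrom, df$body_start, df$gene_id, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Derive CpG shores from islands
#'
#' Shores are the 2 kb flanks on each side of every CpG island, clipped to
#' chromosome bounds and excluding any island interval itself.
#'
#' @param islands An `hmc_features` table of kind `cpg_island` (other kinds
#'   are ignored).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param flank Shore width in bp (default 2000).
#' @return An `hmc_features` table of kind `cpg_shore`.
#' @export
derive_shores <- function(islands, chrom_lengths, flank = 2000L) {
  isl <- islands[islands$kind == "cpg_island", , drop = FALSE]
  if (!nrow(isl)) {
    return(features(kind = character()))
  }
  out <- list()
  for (ch in unique(isl$chrom)) {
    len <- chrom_lengths[[ch]]
    if (is.null(len) || is.na(len)) stop("no chromosome length for ", ch)
    i <- isl$chrom == ch
    s <- isl$start[i]; e <- isl$end[i]
    cand <- IRanges::IRanges(
      start = c(pmax(0L, s - flank), e) + 1L,
      end = c(s, pmin(len, e + flank)))
    cand <- cand[IRanges::width(cand) > 0]
    shores <- IRanges::setdiff(IRanges::reduce(cand),
                               IRanges::reduce(IRanges::IRanges(s + 1L, e)))
    if (length(shores)) {
      out[[ch]] <- data.frame(chrom = ch,
                              start = IRanges::start(shores) - 1L,
                              end = IRanges::end(shores),
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(features(kind = character()))
  df <- do.call(rbind, out)
  features(chrom = df$chrom, start = df$start, end = df$end,
           kind = "cpg_shore")
}

#' Read a BED-like feature file
#'
#' Columns: chrom, start, end, and optionally name, score, strand.
#'
#' @param path File path.
#' @param kind Feature kind to assign to every interval.
#' @param chrom_lengths Optional named lengths; intervals extending past a
#'   chromosome end are clipped with a logged warning.
#' @return An `hmc_features` table.
#' @export
read_features <- function(path, kind, chrom_lengths = NULL) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand")[1:max(3, count_fields(path))],
                           fill = TRUE)
  strand <- if ("strand" %in% names(tab)) tab$strand else "*"
  strand[!(strand %in% c("+", "-"))] <- "*"
  start <- as.integer(tab$start); end <- as.integer(tab$end)
  if (!is.null(chrom_lengths)) {
    lens <- chrom_lengths[tab$chrom]
    over <- !is.na(lens) & end > lens
    if (any(over)) {
      warning(sum(over), " interval(s) in ", path,
              " clipped to chromosome end")
      end[over] <- lens[over]
    }
  }
  features(chrom = tab$chrom, start = start, end = end, strand = strand,
           kind = kind,
           gene_id = if ("name" %in% names(tab)) tab$name else NA_character_)
}

count_fields <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) return(3L)
  length(strsplit(first, "\t", fixed = TRUE)[[1]])
}

#' Read gene models from a transcript TSV
#'
#' @param path TSV with header `chrom start end gene_id strand exon_starts
#'   exon_ends` (exon columns comma-separated, 0-based half-open).
#' @return A `gene_models` table (see [build_gene_models()]).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  build_gene_models(tab)
}

#' Write feature and gene tables
#'
#' @param feat An `hmc_features` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(feat, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", feat$chrom, feat$start, feat$end,
                   ifelse(is.na(feat$gene_id), ".", feat$gene_id), feat$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Load a full annotation bundle
#'
#' Reads one BED-like file per feature kind plus a transcript table, derives
#' CpG shores from islands, and builds canonical gene models. TSS/TES point
#' features are added from the gene models.
#'
#' @param paths Named list/vector mapping feature kinds (from the closed
#'   vocabulary) to file paths; the special name `genes` maps to the
#'   transcript TSV.
#' @param chrom_lengths Named chromosome lengths used for clipping and shore
#'   derivation.
#' @return `list(features = <hmc_features>, genes = <gene_models>)`.
#' @export
load_annotations <- function(paths, chrom_lengths) {
  paths <- as.list(paths)
  genes <- NULL
  feat_list <- list()
  for (kind in names(paths)) {
    if (kind == "genes") {
      genes <- read_gene_models(paths[[kind]])
    } else {
      feat_list[[kind]] <- read_features(paths[[kind]], kind, chrom_lengths)
    }
  }
  if ("cpg_island" %in% names(feat_list)) {
    feat_list$cpg_shore <- derive_shores(feat_list$cpg_island, chrom_lengths)
  }
  if (!is.null(genes)) {
    feat_list$tss <- features(chrom = genes$chrom, start = genes$tss,
                              end = genes$tss + 1L, strand = genes$strand,
                              kind = "tss", gene_id = genes$gene_id)
    feat_list$tes <- features(chrom = genes$chrom, start = genes$tes,
                              end = genes$tes + 1L, strand = genes$strand,
                              kind = "tes", gene_id = genes$gene_id)
    ex <- gene_exon_features(genes)
    feat_list$exon <- ex$exons
    if (nrow(ex$introns)) feat_list$intron <- ex$introns
  }
  feat <- do.call(rbind, lapply(unname(feat_list), as.data.frame))
  feat <- features(chrom = feat$chrom, start = feat$start, end = feat$end,
                   strand = feat$strand, kind = feat$kind,
                   gene_id = feat$gene_id)
  list(features = feat, genes = genes)
}

# Exon and intron interval tables from gene models.
gene_exon_features <- function(genes) {
  ex <- list(); intr <- list()
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    ex[[i]] <- data.frame(chrom = genes$chrom[i], start = es, end = ee,
                          strand = genes$strand[i], kind = "exon",
                          gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
    if (length(es) > 1L) {
      intr[[i]] <- data.frame(chrom = genes$chrom[i],
                              start = ee[-length(ee)], end = es[-1],
                              strand = genes$strand[i], kind = "intron",
                              gene_id = genes$gene_id[i],
                              stringsAsFactors = FALSE)
    }
  }
  exdf <- do.call(rbind, ex)
  intdf <- if (length(intr)) do.call(rbind, intr) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), kind = character(),
               gene_id = character(), stringsAsFactors = FALSE)
  list(exons = features(chrom = exdf$chrom, start = exdf$start, end = exdf$end,
                        strand = exdf$strand, kind = "exon",
                        gene_id = exdf$gene_id),
       introns = if (nrow(intdf))
         features(chrom = intdf$chrom, start = intdf$start, end = intdf$end,
                  strand = intdf$strand, kind = "intron",
                  gene_id = intdf$gene_id)
       else features(kind = character()))
}

#' Write gene models back to the transcript TSV dialect
#'
#' @param genes A `gene_models` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- c("chrom\tstart\tend\tgene_id\tstrand\texon_starts\texon_ends",
             sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     genes$chrom, genes$body_start, genes$body_end,
                     genes$gene_id, genes$strand,
                     vapply(genes$exon_starts, paste, "", collapse = ","),
                     vapply(genes$exon_ends, paste, "", collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
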