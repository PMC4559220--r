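#' Generate annotation fixtures for a toy genome
#'
#' Tiles every chromosome with non-overlapping multi-exon genes separated by
#' intergenic gaps, places CpG islands over the most CG-rich windows,
#' scatters enhancer and ChIP-peak intervals through intergenic space, draws
#' log-normal expression values quartiled per the expression-profile
#' analyses, and assigns X-inactivation escape scores (0-9, stratified so
#' every score occurs) to genes on the designated X chromosome.
#'
#' @param genome A `DNAStringSet`; its last chromosome named `"chrX"` (as
#'   produced by [make_genome()]) hosts the escape-score genes.
#' @param cfg A [sim_config()]; only `seed` is consumed here.
#' @param genes_per_chrom Genes tiled on each chromosome.
#' @param exons_per_gene Exons per gene.
#' @param exon_length,intron_length Exon/intron sizes in bp.
#' @param n_islands CpG islands per chromosome (top CG-rich 1 kb windows).
#' @param intergenic_feature_length Width of enhancer/peak intervals.
#' @return A list with `features` (`hmc_features`), `genes` (`gene_models`),
#'   `expression` (data frame `gene_id`, `value`, `quartile`), `escape`
#'   (data frame `gene_id`, `score`) and `terms` (a toy term-to-gene map for
#'   enrichment testing).
#' @export
make_annotations <- function(genome, cfg, genes_per_chrom = 10L,
                             exons_per_gene = 3L, exon_length = 300L,
                             intron_length = 500L, n_islands = 3L,
                             intergenic_feature_length = 400L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "annotations"))
  lens <- genome_lengths(genome)
  gene_len <- exons_per_gene * exon_length +
    (exons_per_gene - 1L) * intron_length
  tx <- list(); enh <- list()
  for (ch in names(lens)) {
    L <- lens[[ch]]
    gap <- floor((L - 2000L - genes_per_chrom * gene_len) / (genes_per_chrom + 1L))
    if (gap < intergenic_feature_length + 200L) {
      stop("chromosome ", ch, " too small for ", genes_per_chrom, " genes")
    }
    start <- 1000L
    for (k in seq_len(genes_per_chrom)) {
      start <- start + gap
      es <- start + (seq_len(exons_per_gene) - 1L) * (exon_length + intron_length)
      ee <- es + exon_length
      tx[[length(tx) + 1L]] <- data.frame(
        chrom = ch, start = start, end = start + gene_len,
        gene_id = sprintf("%s_g%02d", ch, k),
        strand = if (k %% 2L == 0L) "-" else "+",
        exon_starts = paste(es, collapse = ","),
        exon_ends = paste(ee, collapse = ","),
        stringsAsFactors = FALSE)
      # one intergenic regulatory interval in the gap upstream of this gene
      fk <- c("enhancer_active", "enhancer_poised", "chip_peak")[(k - 1L) %% 3L + 1L]
      fs <- start - gap + 100L
      enh[[length(enh) + 1L]] <- data.frame(
        chrom = ch, start = fs, end = fs + intergenic_feature_length,
        strand = "*", kind = fk, gene_id = NA_character_,
        stringsAsFactors = FALSE)
      start <- start + gene_len
    }
  }
  txdf <- do.call(rbind, tx)
  genes <- build_gene_models(txdf)
  enhdf <- do.call(rbind, enh)

  # CpG islands: the most CG-dense non-overlapping 1 kb windows per chromosome
  idx <- build_cpg_index(genome)
  isl <- list()
  for (ch in names(lens)) {
    win_start <- seq(0L, lens[[ch]] - 1000L, by = 1000L)
    cg <- cpg_count(idx, ch, win_start, win_start + 1000L)
    top <- win_start[order(-cg, win_start)][seq_len(min(n_islands, length(win_start)))]
    isl[[ch]] <- data.frame(chrom = ch, start = top, end = top + 1000L,
                            stringsAsFactors = FALSE)
  }
  isldf <- do.call(rbind, isl)
  islands <- features(chrom = isldf$chrom, start = isldf$start,
                      end = isldf$end, kind = "cpg_island")
  shores <- derive_shores(islands, lens)
  regulatory <- features(chrom = enhdf$chrom, start = enhdf$start,
                         end = enhdf$end, strand = enhdf$strand,
                         kind = enhdf$kind)
  ex <- gene_exon_features(genes)
  tssf <- features(chrom = genes$chrom, start = genes$tss,
                   end = genes$tss + 1L, strand = genes$strand, kind = "tss",
                   gene_id = genes$gene_id)
  tesf <- features(chrom = genes$chrom, start = genes$tes,
                   end = genes$tes + 1L, strand = genes$strand, kind = "tes",
                   gene_id = genes$gene_id)
  allf <- rbind(as.data.frame(islands), as.data.frame(shores),
                as.data.frame(regulatory), as.data.frame(ex$exons),
                as.data.frame(ex$introns), as.data.frame(tssf),
                as.data.frame(tesf))
  feat <- features(chrom = allf$chrom, start = allf$start, end = allf$end,
                   strand = allf$strand, kind = allf$kind,
                   gene_id = allf$gene_id)

  # expression: log-normal, quartiled with equal sizes +/- 1 (1 = lowest)
  value <- stats::rlnorm(nrow(genes), meanlog = 2, sdlog = 1.5)
  r <- rank(value, ties.method = "first")
  quartile <- ceiling(4 * r / nrow(genes))
  expression <- data.frame(gene_id = genes$gene_id, value = value,
                           quartile = as.integer(quartile),
                           stringsAsFactors = FALSE)

  # X-inactivation escape scores on chrX genes, stratified over 0..9
  xgenes <- genes$gene_id[genes$chrom == "chrX"]
  escape <- if (length(xgenes)) {
    data.frame(gene_id = xgenes,
               score = (sample(seq_along(xgenes)) - 1L) %% 10L,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), score = integer(),
               stringsAsFactors = FALSE)
  }

  # toy functional term map over the simulated genes
  terms <- list()
  ids <- genes$gene_id
  n_terms <- 8L
  for (t in seq_len(n_terms)) {
    terms[[sprintf("term%02d", t)]] <-
      sort(sample(ids, max(3L, rbinom_size(length(ids)))))
  }
  list(features = feat, genes = genes, expression = expression,
       escape = escape, terms = terms)
}

rbinom_size <- function(n) stats::rbinom(1L, n, 0.3)

#' Write expression / escape / term tables
#'
#' @param x The data frame or term list to write.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
write_escape <- write_expression

#' @rdname write_expression
#' @export
write_terms <- function(x, path) {
  df <- data.frame(term = rep(names(x), lengths(x)),
                   gene_id = unlist(x, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read expression / escape / term tables
#'
#' @param path TSV path.
#' @return For expression and escape, the data frame; for terms, a named list
#'   of gene-id vectors.
#' @export
read_expression <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_expression
#' @export
read_escape <- read_expression

#' @rdname read_expression
#' @export
read_terms <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  split(df$gene_id, df$term)
}
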