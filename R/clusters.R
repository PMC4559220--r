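#' Cluster-calling configuration
#'
#' @param min_sites Minimum sites per cluster (default 3).
#' @param max_gap Maximum distance in bp between consecutive member sites
#'   (default 200).
#' @param max_tss_distance Clusters whose midpoint is farther than this from
#'   the nearest TSS stay unassigned (default 250,000).
#' @param method `"chain"` (default): single-linkage chaining of consecutive
#'   gaps; `"diameter"`: maximal windows whose total span is at most
#'   `max_gap`.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(min_sites = 3L, max_gap = 200L,
                           max_tss_distance = 250000L,
                           method = c("chain", "diameter")) {
  method <- match.arg(method)
  if (min_sites < 2L) stop("min_sites must be >= 2")
  if (max_gap <= 0L) stop("max_gap must be positive")
  structure(list(min_sites = as.integer(min_sites),
                 max_gap = as.integer(max_gap),
                 max_tss_distance = as.integer(max_tss_distance),
                 method = method),
            class = "cluster_config")
}

#' Call 5hmC clusters
#'
#' A cluster is a maximal run of at least `min_sites` sites in which each
#' consecutive pair lies within `max_gap` bp (strands pooled). Cluster
#' coordinates are half-open: `start` is the first member site, `end` the
#' last member site + 1; the midpoint is `floor((start + end) / 2)`.
#'
#' @param sites An `hmc_sites` object (sorted; unsorted input is sorted
#'   internally with a logged notice).
#' @param cfg A [cluster_config()].
#' @return A data frame of class `hmc_clusters`: `chrom`, `start`, `end`,
#'   `n_sites`, `midpoint`.
#' @export
call_clusters <- function(sites, cfg = cluster_config()) {
  df <- as.data.frame(sites)[, c("chrom", "pos")]
  o <- order(df$chrom, df$pos, method = "radix")
  if (any(o != seq_along(o))) {
    log_msg("call_clusters: input not sorted; sorting internally")
    df <- df[o, , drop = FALSE]
  }
  out <- list()
  for (ch in unique(df$chrom)) {
    p <- df$pos[df$chrom == ch]
    if (cfg$method == "chain") {
      runs <- cumsum(c(1L, as.integer(diff(p) > cfg$max_gap)))
      for (r in unique(runs)) {
        m <- p[runs == r]
        if (length(m) >= cfg$min_sites) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, start = m[1], end = m[length(m)] + 1L,
            n_sites = length(m), stringsAsFactors = FALSE)
        }
      }
    } else {
      # diameter reading: maximal windows with span <= max_gap
      j <- 1L
      last_j <- 0L
      for (i in seq_along(p)) {
        while (j < length(p) && p[j + 1L] - p[i] <= cfg$max_gap) j <- j + 1L
        if (j - i + 1L >= cfg$min_sites && j > last_j) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, start = p[i], end = p[j] + 1L,
            n_sites = j - i + 1L, stringsAsFactors = FALSE)
          last_j <- j
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_sites = integer(), stringsAsFactors = FALSE)
  }
  res$midpoint <- (res$start + res$end) %/% 2L
  rownames(res) <- NULL
  structure(res, config = cfg, class = c("hmc_clusters", "data.frame"))
}

#' @export
print.hmc_clusters <- function(x, ...) {
  cat(sprintf("5hmC clusters: %d cluster(s), %d member site(s)\n",
              nrow(x), sum(x$n_sites)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Assign clusters to genes
#'
#' A cluster whose midpoint falls inside a gene body is assigned to that gene
#' (smallest body wins when genes nest); otherwise to the gene with the
#' nearest TSS by absolute distance (ties broken by lexicographic gene id);
#' clusters farther than `max_tss_distance` from any TSS stay unassigned and
#' are excluded from downstream enrichment.
#'
#' @param clusters An `hmc_clusters` table.
#' @param genes A `gene_models` table.
#' @param cfg A [cluster_config()].
#' @return `clusters` with columns `assigned_gene`, `assignment_mode`
#'   (`within_body` / `nearest_tss` / `unassigned`) and `tss_distance` added.
#' @export
assign_cluster_gene <- function(clusters, genes, cfg = cluster_config()) {
  n <- nrow(clusters)
  gene <- rep(NA_character_, n)
  mode <- rep("unassigned", n)
  dist <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    m <- clusters$midpoint[i]
    g <- genes[genes$chrom == clusters$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    inside <- which(g$body_start <= m & m < g$body_end)
    if (length(inside)) {
      sz <- g$body_end[inside] - g$body_start[inside]
      pick <- inside[order(sz, g$gene_id[inside])][1]
      gene[i] <- g$gene_id[pick]
      mode[i] <- "within_body"
      dist[i] <- abs(m - g$tss[pick])
    } else {
      dd <- abs(m - g$tss)
      pick <- order(dd, g$gene_id)[1]
      if (dd[pick] <= cfg$max_tss_distance) {
        gene[i] <- g$gene_id[pick]
        mode[i] <- "nearest_tss"
        dist[i] <- dd[pick]
      }
    }
  }
  clusters$assigned_gene <- gene
  clusters$assignment_mode <- mode
  clusters$tss_distance <- dist
  clusters
}

#' Gene-set enrichment by hypergeometric test
#'
#' For each term, compares the observed overlap between `gene_list` and the
#' term's genes against the expectation under uniform draws from
#' `background`: `expected = |list| * |term| / |background|`. When observed
#' is at or above expectation the upper tail P(X >= obs) is reported
#' (direction `"up"`), otherwise the lower tail P(X <= obs) (`"down"`).
#' P-values are corrected across terms by Benjamini-Hochberg; terms with
#' FDR <= 0.05 are flagged significant.
#'
#' @param gene_list Character vector of foreground genes (must all be in
#'   `background`).
#' @param background Character vector of universe genes.
#' @param term_map Named list: term -> character vector of member genes
#'   (members outside `background` are ignored).
#' @return Data frame: `term`, `observed`, `expected`, `p`, `fdr`,
#'   `direction`, `significant`, sorted by `p`.
#' @export
enrich <- function(gene_list, background, term_map) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  missing <- setdiff(gene_list, background)
  if (length(missing)) {
    stop("gene(s) absent from background: ", paste(missing, collapse = ", "))
  }
  B <- length(background)
  L <- length(gene_list)
  rows <- lapply(names(term_map), function(tm) {
    tg <- intersect(term_map[[tm]], background)
    t_sz <- length(tg)
    obs <- length(intersect(gene_list, tg))
    expd <- L * t_sz / B
    if (obs >= expd) {
      p <- exp(hyper_upper_log(obs, t_sz, L, B))
      dir <- "up"
    } else {
      # lower tail P(X <= obs) = 1 - P(X >= obs + 1)
      p <- 1 - exp(hyper_upper_log(obs + 1, t_sz, L, B))
      dir <- "down"
    }
    data.frame(term = tm, observed = obs, expected = expd,
               p = min(1, max(0, p)), direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr <= 0.05
  out <- out[order(out$p, out$term), c("term", "observed", "expected", "p",
                                       "fdr", "direction", "significant")]
  rownames(out) <- NULL
  out
}
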