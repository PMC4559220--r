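# Shared fixtures: tiny genomes from literal strings, hand-built reads and
# sites, and independent oracles used against the package implementations.

# Genome from named literal sequences, via a temporary FASTA.
toy_genome <- function(...) {
  seqs <- c(...)
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(nm) c(paste0(">", nm), seqs[[nm]]))),
             fa)
  load_genome(fa)
}

# A sequence with CpGs at known, well-spaced positions (0-based starts).
seq_with_cpgs <- function(length, cpg_at) {
  b <- rep("A", length)
  b[seq(1, length, by = 2)] <- "T"
  for (p in cpg_at) {
    b[p + 1] <- "C"; b[p + 2] <- "G"
  }
  paste(b, collapse = "")
}

# Independent CpG-count oracle: plain regex rescan.
naive_cg_count <- function(seq, start = 0, end = nchar(seq)) {
  hits <- gregexpr("(?=CG)", seq, perl = TRUE)[[1]]
  if (hits[1] == -1) return(0L)
  pos0 <- hits - 1
  as.integer(sum(pos0 >= start & pos0 < end))
}

# Independent brute-force chaining oracle for cluster calling: O(n^2)-style
# repeated merging, no reliance on sortedness tricks.
oracle_chain_clusters <- function(chrom, pos, max_gap, min_sites) {
  out <- list()
  for (ch in unique(chrom)) {
    p <- sort(pos[chrom == ch])
    if (!length(p)) next
    members <- list(p[1])
    for (x in p[-1]) {
      cur <- members[[length(members)]]
      if (x - cur[length(cur)] <= max_gap) {
        members[[length(members)]] <- c(cur, x)
      } else {
        members[[length(members) + 1]] <- x
      }
    }
    for (m in members) {
      if (length(m) >= min_sites) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = as.integer(m[1]),
          end = as.integer(m[length(m)] + 1L),
          n_sites = length(m), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer()))
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

# Exhaustive hypergeometric upper tail by direct combinatorial enumeration.
oracle_hyper_upper <- function(k, K, n, N) {
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  i <- max(k, lo):hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Minimal hand-rolled SAM writer for caller tests (independent of write_sam).
hand_sam <- function(path, chroms, reads) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), unname(chroms)), con)
  for (r in reads) {
    writeLines(paste(r$id, r$flag, r$chrom, r$pos1, r$mapq,
                     paste0(nchar(r$seq), "M"), "*", "0", "0", r$seq, r$qual,
                     sep = "\t"), con)
  }
  invisible(path)
}

site_keys <- function(s) paste(s$chrom, s$pos, s$strand)

small_cohort <- function(specs, sexes = NULL) {
  lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    hmc_sites(chrom = sp$chrom, pos = sp$pos, strand = sp$strand,
              individual_id = names(specs)[i] %||% paste0("i", i),
              sex = if (is.null(sexes)) NA_character_ else sexes[i])
  })
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1 && is.na(x)) || identical(x, "")) y else x
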