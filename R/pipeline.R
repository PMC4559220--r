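#' Default pipeline configuration
#'
#' A full synthetic run: simulate a cohort (19 males + 5 females by default,
#' mirroring the study design the package emulates), call sites per
#' individual, build the consensus, compute densities and profiles on the
#' intermediate-stringency sites, call and assign clusters, test enrichment
#' on the simulated term map, and run the sex comparisons.
#'
#' @param outdir Output directory.
#' @param seed Global seed; every stage derives its own child seed from it.
#' @param n_males,n_females Cohort composition for the simulated data.
#' @param sim Optional [sim_config()] overriding the default simulation
#'   block.
#' @param caller A [caller_config()].
#' @param clusters A [cluster_config()].
#' @param sex A [sex_config()] (its seed is re-derived from the global seed).
#' @param stages Character vector of stages to run, in dependency order, a
#'   subset of `c("simulate", "call", "consensus", "density", "clusters",
#'   "sexdiff")`.
#' @param profile_flank,profile_nbins Metagene profile parameters used by the
#'   density stage (defaults sized for toy genomes).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("hmc_run_"), seed = 1L,
                            n_males = 19L, n_females = 5L, sim = NULL,
                            caller = caller_config(),
                            clusters = cluster_config(),
                            sex = sex_config(),
                            stages = c("simulate", "call", "consensus",
                                       "density", "clusters", "sexdiff"),
                            profile_flank = 2000L, profile_nbins = 50L) {
  n <- n_males + n_females
  if (is.null(sim)) {
    sim <- sim_config(n_individuals = n,
                      sexes = c(rep("M", n_males), rep("F", n_females)),
                      seed = derive_seed(seed, "sim"))
  }
  sex$seed <- derive_seed(seed, "sexdiff")
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 caller = caller, clusters = clusters, sex = sex,
                 stages = stages, profile_flank = as.integer(profile_flank),
                 profile_nbins = as.integer(profile_nbins)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] field-for-field; nested `sim`,
#' `caller`, `clusters` and `sex` blocks mirror the respective config
#' constructors. Missing fields take the constructor defaults, so the config
#' round-trips through serialization unchanged.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, block) {
    if (is.null(block)) return(NULL)
    if (ctor == "sim_config" && !is.null(block$offset_weights)) {
      block$offset_weights <- unlist(block$offset_weights)
    }
    do.call(ctor, block)
  }
  top <- y[intersect(names(y), c("outdir", "seed", "n_males", "n_females",
                                 "stages", "profile_flank", "profile_nbins"))]
  extra <- list(sim = build("sim_config", y$sim),
                caller = build("caller_config", y$caller),
                clusters = build("cluster_config", y$clusters),
                sex = build("sex_config", y$sex))
  do.call(pipeline_config, c(top, extra[!vapply(extra, is.null, TRUE)]))
}

#' Write a simulated dataset to disk
#'
#' Produces `genome.fa`, `truth/<id>.bed`, `reads/<id>.sam`,
#' `annotations/*.bed`, `annotations/genes.tsv`, `expression.tsv`,
#' `escape.tsv`, `terms.tsv` and `metadata.tsv` under `outdir`.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisible list with the in-memory objects (`genome`, `truth`,
#'   `annotations`) and `paths`.
#' @export
simulate_dataset <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("truth", "reads", "annotations")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }
  genome <- make_genome(cfg)
  write_genome(genome, file.path(outdir, "genome.fa"))
  truth <- plant_truth(genome, cfg)
  for (id in names(truth$individuals)) {
    write_sites(truth$individuals[[id]],
                file.path(outdir, "truth", paste0(id, ".bed")))
    simulate_reads(genome, truth$individuals[[id]], cfg,
                   file.path(outdir, "reads", paste0(id, ".sam")))
  }
  ann <- make_annotations(genome, cfg)
  for (kd in unique(ann$features$kind)) {
    write_features(ann$features[ann$features$kind == kd, ],
                   file.path(outdir, "annotations", paste0(kd, ".bed")))
  }
  write_gene_models(ann$genes, file.path(outdir, "annotations", "genes.tsv"))
  write_expression(ann$expression, file.path(outdir, "expression.tsv"))
  write_escape(ann$escape, file.path(outdir, "escape.tsv"))
  write_terms(ann$terms, file.path(outdir, "terms.tsv"))
  set.seed(derive_seed(cfg$seed, "metadata"))
  meta <- data.frame(individual_id = names(truth$individuals),
                     sex = truth$sexes,
                     age = round(stats::rnorm(cfg$n_individuals, 43, 12)),
                     pmi = round(stats::runif(cfg$n_individuals, 10, 70), 1),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, file.path(outdir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(genome = genome, truth = truth, annotations = ann,
                 metadata = meta, outdir = outdir))
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order, writing each stage's
#' outputs under `outdir/<stage>/` and recording every file with its MD5
#' checksum in a manifest (`manifest.tsv`). Rerunning with an identical
#' configuration reproduces byte-identical site and cluster files.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list with `manifest` (data frame `stage`, `path`, `md5`)
#'   and the principal in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, paths) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, path = basename(paths),
      md5 = unname(tools::md5sum(paths)), stringsAsFactors = FALSE)
  }
  results <- list()
  run_stage <- function(stage, fn) {
    if (!(stage %in% config$stages)) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- NULL
  run_stage("simulate", function() {
    sim <<- simulate_dataset(config$sim, file.path(outdir, "sim"))
    note("simulate", c(file.path(outdir, "sim", "genome.fa"),
                       list.files(file.path(outdir, "sim", "truth"),
                                  full.names = TRUE),
                       list.files(file.path(outdir, "sim", "reads"),
                                  full.names = TRUE)))
  })
  if (!("call" %in% config$stages) || is.null(sim)) {
    mdf <- if (length(manifest)) do.call(rbind, manifest) else
      data.frame(stage = character(), path = character(), md5 = character())
    utils::write.table(mdf, file.path(outdir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(list(manifest = mdf, sim = sim)))
  }
  genome <- sim$genome
  meta <- sim$metadata
  ann <- sim$annotations
  idx <- build_cpg_index(genome)

  sitesets <- NULL
  run_stage("call", function() {
    dir.create(file.path(outdir, "sites"), showWarnings = FALSE)
    ids <- names(sim$truth$individuals)
    sitesets <<- lapply(ids, function(id) {
      reads <- read_alignments(file.path(outdir, "sim", "reads",
                                         paste0(id, ".sam")), genome)
      reads <- filter_reads(reads, config$caller)
      s <- call_sites(reads, genome, config$caller, individual_id = id,
                      sex = meta$sex[match(id, meta$individual_id)])
      write_sites(s, file.path(outdir, "sites", paste0(id, ".bed")))
      s
    })
    names(sitesets) <<- ids
    note("call", list.files(file.path(outdir, "sites"), full.names = TRUE))
  })

  consensus <- NULL; inter <- NULL
  run_stage("consensus", function() {
    dir.create(file.path(outdir, "consensus"), showWarnings = FALSE)
    males <- sitesets[meta$sex == "M"]
    consensus <<- build_consensus(males)
    for (tier in c("low", "intermediate", "high")) {
      write_sites(stringency_subset(consensus, tier),
                  file.path(outdir, "consensus", paste0(tier, ".bed")))
    }
    inter <<- stringency_subset(consensus, "intermediate")
    reads_per_ind <- vapply(names(sitesets), function(id) {
      length(readLines(file.path(outdir, "sim", "reads", paste0(id, ".sam"))))
    }, 0L)
    qc <- qc_summaries(sitesets, cbind(meta, reads = reads_per_ind))
    utils::write.table(qc$correlations,
                       file.path(outdir, "consensus", "qc_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("consensus", list.files(file.path(outdir, "consensus"),
                                 full.names = TRUE))
  })

  run_stage("density", function() {
    dir.create(file.path(outdir, "density"), showWarnings = FALSE)
    chrd <- chromosome_density(inter, genome, idx)
    utils::write.table(chrd, file.path(outdir, "density", "chromosomes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fd <- feature_density(inter, ann$features, idx)
    utils::write.table(fd, file.path(outdir, "density", "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    peaks <- ann$features[ann$features$kind == "chip_peak", ]
    if (nrow(peaks)) {
      write_profile(peak_profile(inter, peaks,
                                 chrom_lengths = genome_lengths(genome)),
                    file.path(outdir, "density", "peak_profile.tsv"))
    }
    mg <- metagene_profile(inter, ann$genes, ann$expression,
                           flank = config$profile_flank,
                           nbins = config$profile_nbins)
    for (q in names(mg)) {
      write_profile(mg[[q]],
                    file.path(outdir, "density",
                              paste0("metagene_", q, ".tsv")))
    }
    eb <- exon_boundary_profile(inter, ann$genes)
    utils::write.table(eb$five_prime,
                       file.path(outdir, "density", "boundary_5prime.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(eb$three_prime,
                       file.path(outdir, "density", "boundary_3prime.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("density", list.files(file.path(outdir, "density"),
                               full.names = TRUE))
  })

  cl <- NULL
  run_stage("clusters", function() {
    dir.create(file.path(outdir, "clusters"), showWarnings = FALSE)
    cl <<- assign_cluster_gene(call_clusters(inter, config$clusters),
                               ann$genes, config$clusters)
    utils::write.table(as.data.frame(cl),
                       file.path(outdir, "clusters", "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gl <- unique(stats::na.omit(cl$assigned_gene))
    if (length(gl) >= 2) {
      en <- enrich(gl, ann$genes$gene_id, ann$terms)
      utils::write.table(en, file.path(outdir, "clusters", "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    note("clusters", list.files(file.path(outdir, "clusters"),
                                full.names = TRUE))
  })

  run_stage("sexdiff", function() {
    if (!any(meta$sex == "F") || !any(meta$sex == "M")) {
      log_msg("sexdiff: skipped (need both sexes in the cohort)")
      return(invisible(NULL))
    }
    dir.create(file.path(outdir, "sexdiff"), showWarnings = FALSE)
    females <- sitesets[meta$sex == "F"]
    males <- sitesets[meta$sex == "M"]
    fu <- female_unique_sites(females, males)
    write_sites(fu, file.path(outdir, "sexdiff", "female_unique.bed"))
    fu_cl <- call_clusters(fu, config$clusters)
    utils::write.table(as.data.frame(fu_cl),
                       file.path(outdir, "sexdiff", "female_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(males) >= config$sex$male_set_size) {
      msc <- male_specific_clusters(males, females, config$clusters,
                                    config$sex)
      utils::write.table(msc,
                         file.path(outdir, "sexdiff",
                                   "male_specific_clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    xgenes <- ann$genes[ann$genes$chrom == "chrX", ]
    if (nrow(ann$escape) && nrow(xgenes)) {
      ed <- escape_density(females, xgenes, ann$escape, idx)
      utils::write.table(ed$per_gene,
                         file.path(outdir, "sexdiff", "escape_density.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$escape <<- ed
    }
    note("sexdiff", list.files(file.path(outdir, "sexdiff"),
                               full.names = TRUE))
  })

  mdf <- do.call(rbind, manifest)
  utils::write.table(mdf, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(list(manifest = mdf, sim = sim, sitesets = sitesets,
                   consensus = consensus, clusters = cl),
              results))
}
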