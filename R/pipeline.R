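#' Default pipeline configuration
#'
#' Collects every stage threshold in one list, mirroring the parameters
#' printed in the run summary for auditability. Values are the
#' conventional ones: 10-kb windows, 5th-quantile Tajima's D cut-off,
#' 5-kb merging, r-squared 0.4 blocks, 85% identity, 4-generation cHTB
#' rule, missingness < 0.8 and MAF > 0.05 filters.
#'
#' @param outdir output directory.
#' @param seed global seed; every stage derives its seed from it.
#' @param ... overrides for any default element.
#' @return a named list (class `RunConfig`).
#' @export
pipelineConfig <- function(outdir = tempfile("breedtrace_"), seed = 1L,
                           ...) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    window_bp = 10000L, step_bp = 10000L,
    sweep_quantile = 0.05, merge_gap_bp = 5000L, n_temporal_clusters = 4L,
    r2_min = 0.4, identity_threshold = 0.85, min_generations = 4L,
    max_missing = 0.80, min_maf = 0.05,
    n_pcs = 3L, p_threshold = 1e-4, n_permutations = 200L,
    gff = NULL)
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "RunConfig"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pedigree-analysis pipeline
#'
#' Executes the analysis stages in order on one data set: marker
#' filtering, the sweep scan (windowed diversity statistics, sweep-block
#' calling, temporal-pattern clustering), haplotype-block tracing (LD
#' blocks, origin tracing along the pedigree flow, conserved-block
#' calling, derivative conservation), and per-trait association plus PVE
#' estimation and architecture classification. Every stage writes its
#' table under `outdir` and the run ends with a JSON summary of counts,
#' thresholds and seeds. The selection simulator is a standalone tool
#' ([runSimulation()]) and is not part of this pipeline.
#'
#' @param genotypes a [GenotypeMatrix-class] or a genotype file path.
#' @param pedigree a [PedigreeGraph-class] or a pedigree TSV path.
#' @param phenotypes optional long phenotype `data.frame` or TSV path;
#'   when omitted the QTL stage is skipped.
#' @param config a [pipelineConfig()] list.
#' @return the summary list (also written as `summary.json`),
#'   invisibly; stage outputs are files under `config$outdir`.
#' @export
runPipeline <- function(genotypes, pedigree, phenotypes = NULL,
                        config = pipelineConfig()) {
  if (is.character(pedigree))
    pedigree <- .stage("read_pedigree", readPedigreeTSV(pedigree))
  if (is.character(genotypes))
    genotypes <- .stage("read_genotypes",
                        readGenotypes(genotypes, lineData = pedigree))
  if (is.character(phenotypes))
    phenotypes <- .stage("read_phenotypes", readPhenotypes(phenotypes))
  if (!is(pedigree, "PedigreeGraph"))
    stop("pipeline stage 'block_trace' needs a pedigree (missing or invalid)")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  focal <- focalLine(pedigree)

  filtered <- .stage("marker_filter",
                     markerFilter(genotypes, config$max_missing,
                                  config$min_maf))

  # the sweep scan runs on the unfiltered panel: a MAF filter would
  # delete the near-fixed markers that carry the sweep signal
  ws <- .stage("sweep_scan", windowStats(genotypes, config$window_bp,
                                         config$step_bp))
  utils::write.table(as.data.frame(ws), out("window_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sweeps <- .stage("sweep_scan",
                   callSweeps(ws, config$sweep_quantile,
                              config$merge_gap_bp))
  sweeps$score <- -sweeps$min_tajima_d * 100
  writeIntervalsBED(sweeps, out("sweep_blocks.bed"), score_col = "score")
  clus <- if (length(sweeps) >= config$n_temporal_clusters &&
              !anyNA(lineInfo(genotypes)$year))
    .stage("sweep_scan",
           clusterTemporalPatterns(sweeps, genotypes, focal,
                                   k = config$n_temporal_clusters,
                                   identity_min =
                                     config$identity_threshold))
  else NULL

  gene_annot <- if (!is.null(config$gff))
    .stage("annotate", annotateBlocks(sweeps, config$gff)) else NULL

  hb <- .stage("block_trace",
               findHaplotypeBlocks(filtered, config$r2_min))
  writeIntervalsBED(hb, out("haplotype_blocks.bed"))
  htb <- .stage("block_trace",
                traceOrigin(hb, filtered, pedigree, focal,
                            config$identity_threshold))
  htb <- callCHTB(htb, config$min_generations)
  utils::write.table(htb, out("htb_records.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  deriv <- NULL
  if (length(derivativeGroups(pedigree)) && any(htb$is_chtb)) {
    deriv <- .stage("block_trace",
                    derivativeConservation(hb[htb$is_chtb], filtered,
                                           derivativeGroups(pedigree),
                                           focal,
                                           config$identity_threshold))
    jsonlite::write_json(
      list(proportions = as.list(deriv$proportions),
           overlap_fraction = as.list(deriv$overlap_fraction)),
      out("derivative_conservation.json"), auto_unbox = TRUE,
      digits = NA)
  }

  qtl_tabs <- list()
  classes <- list()
  if (!is.null(phenotypes)) {
    for (tr in unique(phenotypes$trait)) {
      qt <- .stage("qtl_pve",
                   associateQTL(filtered, phenotypes, trait = tr,
                                n_pcs = config$n_pcs,
                                p_threshold = config$p_threshold,
                                n_permutations = config$n_permutations,
                                seed = config$seed))
      qtl_tabs[[tr]] <- qt
      classes[[tr]] <- classifyTrait(qt)
      if (nrow(qt)) {
        traj <- .stage("qtl_pve",
                       accumulatedPVETrajectory(qt, filtered, pedigree))
        utils::write.table(traj,
                           out(sprintf("trajectory_%s.tsv", tr)),
                           sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
    }
    all_qtl <- do.call(rbind, qtl_tabs)
    utils::write.table(all_qtl, out("qtl_records.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    seed = config$seed,
    thresholds = config[c("window_bp", "sweep_quantile", "merge_gap_bp",
                          "r2_min", "identity_threshold",
                          "min_generations", "max_missing", "min_maf",
                          "p_threshold")],
    n_markers_input = nrow(genotypes),
    n_markers_filtered = nrow(filtered),
    n_lines = ncol(filtered),
    focal = focal,
    n_windows = length(ws),
    sweep_threshold = metadata(sweeps)$threshold,
    n_sweep_blocks = length(sweeps),
    temporal_changepoints = if (!is.null(clus))
      as.list(clus$changepoint_year) else NULL,
    n_genes_in_sweeps = if (!is.null(gene_annot))
      gene_annot$total_genes else NULL,
    n_haplotype_blocks = length(hb),
    n_htb = sum(htb$traceable),
    n_chtb = sum(htb$is_chtb),
    derivative_proportions = if (!is.null(deriv))
      as.list(deriv$proportions) else NULL,
    n_qtls = if (length(qtl_tabs))
      vapply(qtl_tabs, nrow, integer(1)) else NULL,
    trait_groups = if (length(classes)) classes else NULL)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(summary)
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration round-trips: `readRunConfig(writeRunConfig(cfg))`
#' is identical to `cfg`.
#'
#' @param config a [pipelineConfig()] list.
#' @param path YAML file path.
#' @return `writeRunConfig` returns `path` invisibly; `readRunConfig`
#'   returns the configuration list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  full <- unclass(pipelineConfig())
  # assign via [ so that NULL-valued fields (e.g. gff) survive
  for (nm in names(cfg)) full[nm] <- list(cfg[[nm]])
  # integer-typed fields survive YAML round-trip as integers
  for (f in c("seed", "window_bp", "step_bp", "merge_gap_bp",
              "n_temporal_clusters", "min_generations", "n_pcs",
              "n_permutations"))
    full[[f]] <- as.integer(full[[f]])
  class(full) <- "RunConfig"
  full
}
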