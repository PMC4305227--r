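#' Pipeline configuration
#'
#' Collects the inputs and thresholds of a full run. Either a
#' [simulation_config()] (synthetic study) or the three input paths
#' (probe matrix, sample sheet, annotation) must be supplied.
#'
#' @param simulate optional [simulation_config()]; when given, the study
#'   is generated rather than read.
#' @param matrix_path,sample_sheet_path,annotation_path input TSV paths
#'   (ignored when \code{simulate} is given).
#' @param gene_sets_path optional GMT file for over-representation.
#' @param dess_path optional DESS component record TSV; when absent and
#'   \code{simulate} is given, records are simulated with the default
#'   severity targets.
#' @param up_thresholds,down_thresholds census fold thresholds (the
#'   conventional screen grids).
#' @param panel_up_threshold,panel_down_threshold fold thresholds for both
#'   co-differential panels.
#' @param trajectory_threshold qualifying-fold threshold of the pattern
#'   census.
#' @param dess_targets named per-group DESS mean targets used when DESS
#'   records are simulated; defaults follow the published severity course.
#' @param output_dir directory for all stage outputs and the manifest.
#' @param seed integer seed covering every stochastic step.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulate = NULL, matrix_path = NULL,
                            sample_sheet_path = NULL, annotation_path = NULL,
                            gene_sets_path = NULL, dess_path = NULL,
                            up_thresholds = c(2, 5, 8, 10, 15, 20, 30, 50, 100),
                            down_thresholds = c(2, 5, 6, 8, 10, 15, 20, 30, 50, 100),
                            panel_up_threshold = 5, panel_down_threshold = 2,
                            trajectory_threshold = 2,
                            dess_targets = c(CON = 3.2, STABLE = 38.7,
                                             AE1 = 85.7, AE3 = 70.5,
                                             AE10 = 36.7),
                            output_dir, seed = 1L) {
  if (is.null(simulate) &&
      (is.null(matrix_path) || is.null(sample_sheet_path) ||
       is.null(annotation_path))) {
    stop("either 'simulate' or matrix/sample sheet/annotation paths required")
  }
  for (p in c(matrix_path, sample_sheet_path, annotation_path,
              gene_sets_path, dess_path)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(simulate = simulate, matrix_path = matrix_path,
                 sample_sheet_path = sample_sheet_path,
                 annotation_path = annotation_path,
                 gene_sets_path = gene_sets_path, dess_path = dess_path,
                 up_thresholds = up_thresholds,
                 down_thresholds = down_thresholds,
                 panel_up_threshold = panel_up_threshold,
                 panel_down_threshold = panel_down_threshold,
                 trajectory_threshold = trajectory_threshold,
                 dess_targets = dess_targets,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes simulate (optional) -> quantile normalization -> log2 ->
#' probe summarization -> fold changes over the ten comparisons ->
#' threshold census -> co-differential panels -> trajectory
#' classification -> DESS scoring and severity concordance ->
#' over-representation (if gene sets given), writing every stage output
#' as TSV plus a JSON run manifest into the output directory. Given the
#' same configuration and seed the outputs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulate)) {
    stage_log("simulate", "generating synthetic study (seed ",
              config$simulate$seed, ")")
    study <- generate_study(config$simulate)
    write_study(study, out)
    probes <- study$probes
    design <- study$design
    annotation <- study$annotation
  } else {
    stage_log("input", "reading ", config$matrix_path)
    probes <- read_expression_tsv(config$matrix_path)
    design <- read_sample_sheet(config$sample_sheet_path)
    annotation <- utils::read.delim(config$annotation_path,
                                    stringsAsFactors = FALSE)
    study <- NULL
  }

  stage_log("normalize", "quantile normalization + log2 (RMA-style, ",
            nrow(probes), " probes x ", ncol(probes), " samples)")
  norm <- quantile_normalize(probes)
  log2m <- log2_transform(norm)
  genes <- summarize_probes(log2m, annotation)
  write_expression_tsv(genes, file.path(out, "gene_matrix.tsv"))

  stage_log("diffexp", "fold changes for ", nrow(comparison_pairs()),
            " comparison pairs")
  records <- fold_change_all(genes, design)
  write_tsv(records, file.path(out, "fold_changes.tsv"))
  census_up <- threshold_census(records, "up", config$up_thresholds)
  census_down <- threshold_census(records, "down", config$down_thresholds)
  write_tsv(data.frame(pair = rownames(census_up), census_up,
                       check.names = FALSE),
            file.path(out, "census_up.tsv"))
  write_tsv(data.frame(pair = rownames(census_down), census_down,
                       check.names = FALSE),
            file.path(out, "census_down.tsv"))

  stage_log("panels", "co-differential selection")
  panels <- list(
    copd = select_panel(records, panel_spec("copd_specific",
                                            config$panel_up_threshold,
                                            config$panel_down_threshold)),
    aecopd = select_panel(records, panel_spec("aecopd_specific",
                                              config$panel_up_threshold,
                                              config$panel_down_threshold)))
  for (nm in names(panels)) {
    write_tsv(rbind(panels[[nm]]$up, panels[[nm]]$down),
              file.path(out, paste0("panel_", nm, ".tsv")))
  }

  stage_log("trajectory", "two-step pattern classification")
  calls <- classify_trajectory(records[records$pair == "AE3_vs_AE1", ],
                               records[records$pair == "AE10_vs_AE3", ])
  write_tsv(calls, file.path(out, "trajectory_calls.tsv"))
  traj_census <- pattern_census(calls, config$trajectory_threshold)

  stage_log("dess", "severity scoring")
  if (!is.null(config$dess_path)) {
    dess <- read_dess_records(config$dess_path)
  } else {
    dess <- generate_dess_records(design, config$dess_targets,
                                  seed = config$seed)
  }
  write_dess_records(dess, file.path(out, "dess_records.tsv"))
  scores <- score_dess(dess)
  groups <- design$group[match(scores$sample_id, design$sample_id)]
  dess_summary <- summarize_dess(scores, groups)
  write_tsv(dess_summary, file.path(out, "dess_summary.tsv"))
  ae_means <- dess_summary$mean[match(c("AE1", "AE3", "AE10"),
                                      dess_summary$group)]
  dess_pattern <- if (anyNA(ae_means)) NA_character_ else
    severity_trajectory(ae_means)

  enrichment <- NULL
  if (!is.null(config$gene_sets_path)) {
    stage_log("enrich", "over-representation against ",
              config$gene_sets_path)
    sets <- read_gmt(config$gene_sets_path)
    query <- unique(c(panels$aecopd$up$gene_id, panels$aecopd$down$gene_id))
    enrichment <- enrich_all(query, sets, rownames(genes))
    write_tsv(enrichment, file.path(out, "enrichment.tsv"))
  }

  manifest <- list(
    seed = config$seed,
    simulated = !is.null(config$simulate),
    n_probes = nrow(probes), n_genes = nrow(genes),
    n_samples = ncol(probes),
    comparisons = comparison_pairs()$pair,
    up_thresholds = config$up_thresholds,
    down_thresholds = config$down_thresholds,
    panel_thresholds = c(up = config$panel_up_threshold,
                         down = config$panel_down_threshold),
    panel_counts = list(copd = panels$copd$counts,
                        aecopd = panels$aecopd$counts),
    trajectory_census = as.list(traj_census),
    dess_pattern = dess_pattern,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("pbmcopd")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("done", "outputs in ", out)
  invisible(list(study = study, genes = genes, records = records,
                 census_up = census_up, census_down = census_down,
                 panels = panels, trajectory = calls,
                 trajectory_census = traj_census,
                 dess_summary = dess_summary, dess_pattern = dess_pattern,
                 enrichment = enrichment, manifest = manifest))
}
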