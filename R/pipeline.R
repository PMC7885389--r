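# Configuration-driven orchestration: simulate (or load) -> stratify ->
# differential expression -> six-list prioritization -> report, with a
# run manifest of content hashes for reproducibility.

.config_defaults <- function() {
  list(marker = "PTGS2",
       z_high = 1, z_low = -0.25, fraction = 0.15,
       fc = 1.5, p = 0.05, t_abs = 2, fdr = 0.35,
       gl1_threshold = 10, gl2_threshold = 1, p_max = 0.05, r_min = 0.2,
       n_perm = 1000, seed = 7L,
       cohort = NULL, metastatic = NULL, panel = NULL,
       gene_lists = NULL)
}

#' Build a pipeline configuration
#'
#' All thresholds default to the pipeline's reference values: z gates +1 and
#' -0.25 with a 15% quantile cap, fold change 1.5, p 0.05, |t| 2, FDR 0.35,
#' GL1 alteration rate 10%, GL2 amplification 1%, co-expression r 0.2.
#' `cohort`, `metastatic` and `panel` may each be a list of generator
#' arguments (simulation mode) or a list of file paths; `gene_lists` (a
#' character vector of list files) switches to lists-only mode, where only
#' the intersection is computed.
#'
#' @param ... Overrides of the default fields. Unknown keys are errors.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  base <- .config_defaults()
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("pipeline_config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, over, keep.null = TRUE)
  for (f in c("z_high", "z_low", "fraction", "fc", "p", "t_abs", "fdr",
              "gl1_threshold", "gl2_threshold", "p_max", "r_min", "n_perm"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1)
      stop("pipeline_config: field '", f, "' must be a single number")
  if (cfg$fraction <= 0 || cfg$fraction > 1)
    stop("pipeline_config: field 'fraction' must lie in (0, 1]")
  if (cfg$p <= 0 || cfg$p > 1 || cfg$fdr <= 0 || cfg$fdr > 1)
    stop("pipeline_config: p and fdr thresholds must lie in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' YAML mapping with the fields of [pipeline_config]; unknown keys are
#' errors, not warnings. The configuration round-trips losslessly.
#'
#' @param path File path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @param config A `pipeline_config`.
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.load_or_simulate_cohort <- function(node, seed) {
  if (!is.null(node$expression)) {
    for (p in unlist(node)) if (!file.exists(p))
      stop("run_pipeline: input path does not exist: ", p)
    list(expression = read_expression(node$expression),
         clinical = read_clinical(node$clinical),
         cna = read_cna(node$cna), truth = NULL)
  } else {
    args <- if (is.null(node)) list() else node
    args$seed <- args$seed %||% seed
    simulate_cohort(do.call(cohort_spec, args))
  }
}

#' Run the full prioritization pipeline
#'
#' Executes simulate/load -> TNBC selection -> z-scoring -> stratification ->
#' permutation differential expression -> compound filter -> signature
#' clustering validation -> six criterion lists -> intersection ->
#' co-expression confirmation. Every intermediate table is written to
#' `outdir` together with a human-readable report and a manifest holding the
#' configuration, the seed, and an MD5 content hash of every output, so a
#' re-run with the same configuration and seed is byte-reproducible.
#'
#' In lists-only mode (`config$gene_lists` set) only the list intersection
#' is computed and reported.
#'
#' @param config A [pipeline_config] (or a list of its fields).
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a list with the stage results (`cohort`, `strat`,
#'   `deg`, `filtered`, `validation`, `result`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(writer, object, file) {
    path <- file.path(outdir, file)
    writer(object, path)
    outputs <<- c(outputs, path)
    path
  }

  if (!is.null(config$gene_lists)) {
    lists <- lapply(config$gene_lists, read_gene_list)
    inter <- intersect_gene_lists(lists)
    emit(write_gene_list, inter, "intersection.txt")
    emit(write_gene_lists_json, c(lists, list(intersection = inter)),
         "gene_lists.json")
    report <- c("prioritization report (lists-only mode)",
                sprintf("  %s: %d genes", vapply(lists, `[[`, "", "name"),
                        vapply(lists, length, 0L)),
                sprintf("  intersection: %d genes: %s", length(inter),
                        paste(inter$symbols, collapse = " ")))
    writeLines(report, file.path(outdir, "report.txt"))
    outputs <- c(outputs, file.path(outdir, "report.txt"))
    .write_manifest(config, outputs, outdir)
    return(invisible(list(lists = lists, result = inter)))
  }

  seed <- as.integer(config$seed)
  cohort <- .load_or_simulate_cohort(config$cohort, seed)
  met <- if (!is.null(config$metastatic$cna) &&
             is.character(config$metastatic$cna)) {
    read_cna(config$metastatic$cna)
  } else {
    args <- config$metastatic %||% list(n_patients = 180)
    args$n_patients <- args$n_patients %||% 180
    args$seed <- args$seed %||% (seed + 1000L)
    # metastatic cohort shares the gene universe of the primary cohort
    spec <- cohort_spec(n_genes = nrow(cohort$expression),
                        marker_gene = rownames(cohort$expression)[1],
                        planted_genes = if (is.null(cohort$truth))
                          character() else cohort$truth$planted_genes,
                        n_patients = args$n_patients, seed = args$seed)
    simulate_cohort(spec)$cna
  }
  panel <- if (!is.null(config$panel$path)) read_panel(config$panel$path)
  else {
    args <- config$panel %||% list()
    args$seed <- args$seed %||% (seed + 2000L)
    simulate_panel(panel_spec(
      genes = rownames(cohort$expression),
      resistance_genes = args$resistance_genes %||%
        (if (is.null(cohort$truth)) character()
         else cohort$truth$planted_genes),
      n_lines = args$n_lines %||% 37, seed = args$seed))
  }

  emit(write_expression, cohort$expression, "expression.tsv")
  emit(write_clinical, cohort$clinical, "clinical.tsv")
  emit(write_cna, cohort$cna, "cna.tsv")
  emit(write_cna, met, "cna_metastatic.tsv")
  emit(write_panel, panel, "panel.tsv")

  tnbc <- select_tnbc(cohort$clinical)
  if (length(tnbc) < 4)
    stop("run_pipeline: stage tnbc-selection: fewer than 4 TNBC samples")
  expr_tnbc <- cohort$expression[, tnbc, drop = FALSE]
  z_tnbc <- zscore_matrix(expr_tnbc)
  strat <- stratify(z_tnbc, config$marker, z_high = config$z_high,
                    z_low = config$z_low, fraction = config$fraction)
  deg <- run_deg(expr_tnbc, strat, n_perm = config$n_perm, seed = seed)
  emit(function(d, p) .write_tsv(d, p), deg, "deg_table.tsv")
  volcano <- data.frame(gene = deg$gene, log2_fc = log2(deg$fold_change),
                        neg_log10_p = -log10(deg$p))
  emit(function(d, p) .write_tsv(d, p), volcano, "volcano.tsv")
  filtered <- filter_deg(deg, fc = config$fc, p = config$p,
                         t_abs = config$t_abs, fdr = config$fdr)
  emit(write_gene_list, filtered$up, "deg_up.txt")
  emit(write_gene_list, filtered$down, "deg_down.txt")

  signature <- gene_list("signature",
                         c(filtered$up$symbols, filtered$down$symbols))
  validation <- if (length(signature) >= 2)
    validate_signature(expr_tnbc, strat, signature) else NULL

  result <- prioritize(filtered$up, cna = cohort$cna[, tnbc, drop = FALSE],
                       z = z_tnbc, expr = cohort$expression,
                       clinical = cohort$clinical, tnbc_ids = tnbc,
                       cna_metastatic = met, panel = panel,
                       marker = config$marker,
                       thresholds = list(gl1_threshold = config$gl1_threshold,
                                         gl2_threshold = config$gl2_threshold,
                                         p_max = config$p_max,
                                         r_min = config$r_min))
  for (nm in names(result$gene_lists))
    emit(write_gene_list, result$gene_lists[[nm]],
         paste0(tolower(nm), ".txt"))
  emit(write_gene_list, result$intersection, "intersection.txt")
  emit(write_gene_list, result$coexpressed, "coexpressed.txt")
  emit(write_gene_lists_json,
       c(result$gene_lists, list(intersection = result$intersection,
                                 coexpressed = result$coexpressed)),
       "gene_lists.json")

  report <- c("prioritization report",
              sprintf("  marker: %s, seed: %d", config$marker, seed),
              sprintf("  TNBC samples: %d of %d", length(tnbc),
                      ncol(cohort$expression)),
              sprintf("  stratification: %d high / %d low",
                      length(strat$high_ids), length(strat$low_ids)),
              sprintf("  DEGs: %d up, %d down (of %d tested)",
                      length(filtered$up), length(filtered$down), nrow(deg)),
              if (!is.null(validation))
                sprintf("  signature clustering ARI: %.3f",
                        validation$ari),
              sprintf("  %s: %d genes", names(result$gene_lists),
                      vapply(result$gene_lists, length, 0L)),
              sprintf("  intersection: %d genes: %s",
                      length(result$intersection),
                      paste(result$intersection$symbols, collapse = " ")),
              sprintf("  co-expressed with %s: %d genes: %s", config$marker,
                      length(result$coexpressed),
                      paste(result$coexpressed$symbols, collapse = " ")))
  writeLines(report, file.path(outdir, "report.txt"))
  outputs <- c(outputs, file.path(outdir, "report.txt"))
  .write_manifest(config, outputs, outdir)
  invisible(list(cohort = cohort, metastatic_cna = met, panel = panel,
                 strat = strat, deg = deg, filtered = filtered,
                 validation = validation, result = result))
}

.write_manifest <- function(config, outputs, outdir) {
  hashes <- tools::md5sum(outputs)
  names(hashes) <- basename(names(hashes))
  jsonlite::write_json(list(config = unclass(config),
                            hashes = as.list(hashes)),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
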