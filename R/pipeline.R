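#' Pipeline configuration with the workflow's default thresholds
#'
#' Bundles every stage threshold: minimum shared miRNAs (3), correlation
#' cutoff for network edges (0.25, strict), FDR threshold (0.05),
#' dysregulation alpha (0.05), permutations (1000), minimum supporting
#' probes for re-annotation (11), lncRNA-pathway correlation threshold
#' (0.5), cross-validation folds (10), plus the global seed and the two
#' condition names.
#'
#' @param min_shared,r_threshold,fdr_threshold,alpha,n_perm,min_probes,pathway_threshold,k_folds
#'   Stage thresholds (defaults above).
#' @param seed Global integer seed; every stochastic stage derives its own
#'   substream from it.
#' @param conditions Length-2 character: normal then disease condition.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_shared = 3, r_threshold = 0.25,
                            fdr_threshold = 0.05, alpha = 0.05,
                            n_perm = 1000, min_probes = 11,
                            pathway_threshold = 0.5, k_folds = 10,
                            seed = 1L, conditions = c("normal", "disease")) {
  cfg <- list(min_shared = min_shared, r_threshold = r_threshold,
              fdr_threshold = fdr_threshold, alpha = alpha,
              n_perm = as.integer(n_perm), min_probes = min_probes,
              pathway_threshold = pathway_threshold,
              k_folds = as.integer(k_folds), seed = as.integer(seed),
              conditions = conditions)
  stopifnot(cfg$min_shared >= 0, cfg$r_threshold >= -1, cfg$r_threshold <= 1,
            cfg$fdr_threshold > 0, cfg$fdr_threshold <= 1,
            cfg$alpha >= 0, cfg$alpha <= 1, cfg$n_perm >= 1,
            cfg$min_probes >= 1, cfg$k_folds >= 2,
            length(cfg$conditions) == 2)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full ceRNA discovery workflow
#'
#' Executes the pipeline stages in order -- hypergeometric candidate pairs,
#' per-condition co-expression networks, network intersection,
#' permutation-based dysregulation -- and, when the corresponding inputs
#' are supplied, the trio, pathway and diagnostics stages. All stage
#' outputs are written as TSV into `out_dir` together with a
#' machine-readable JSON manifest (parameters, seed, per-stage record
#' counts; no timestamps, so identical runs are bit-identical).
#'
#' @param expr Features x samples expression matrix, or a TSV path.
#' @param labels Named condition vector, or a labels TSV path.
#' @param catalog An `interaction_catalog`, or `c(mrna_path, lncrna_path)`.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param feature_type Optional named vector tagging features as
#'   `"mirna"`, `"mrna"` or `"lncrna"`; required for the trio stage.
#' @param gene_sets Optional named list of gene sets (or a GMT path);
#'   enables the ssGSEA pathway stage.
#' @param markers Optional character vector of marker feature ids; enables
#'   the diagnostics stage (exhaustive panel cross-validation).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(expr, labels, catalog, out_dir,
                         config = pipeline_config(), feature_type = NULL,
                         gene_sets = NULL, markers = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(expr)) expr <- read_expression(expr)
  if (is.character(labels) && length(labels) == 1L && file.exists(labels))
    labels <- read_labels(labels)
  if (is.character(catalog)) catalog <- read_catalog(catalog[1], catalog[2])
  check_expression(expr)
  labels <- check_labels(labels, expr)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  log_stage <- function(stage, n) {
    counts[[stage]] <<- n
    message("[", stage, "] ", n, " records")
  }

  candidates <- candidate_pairs(catalog, min_shared = config$min_shared,
                                fdr_threshold = config$fdr_threshold)
  write_tsv(candidates, file.path(out_dir, "candidates.tsv"))
  log_stage("candidates", nrow(candidates))

  nets <- lapply(config$conditions, function(cond)
    build_condition_network(candidates, expr, labels, cond,
                            r_threshold = config$r_threshold,
                            fdr_threshold = config$fdr_threshold))
  names(nets) <- config$conditions
  for (cond in config$conditions) {
    write_tsv(nets[[cond]], file.path(out_dir,
                                      paste0("network_", cond, ".tsv")))
    log_stage(paste0("network_", cond), nrow(nets[[cond]]))
  }

  inter <- network_intersection(nets[[1]], nets[[2]])
  write_tsv(inter, file.path(out_dir, "intersection.tsv"))
  log_stage("intersection", nrow(inter))

  dys <- dysregulated_pairs(inter, expr, labels, alpha = config$alpha,
                            n_perm = config$n_perm, seed = config$seed,
                            conditions = config$conditions)
  write_tsv(dys, file.path(out_dir, "dysregulated.tsv"))
  log_stage("dysregulated", nrow(dys))

  results <- list(candidates = candidates, networks = nets,
                  intersection = inter, dysregulated = dys)

  if (!is.null(feature_type)) {
    mir_ids <- names(feature_type)[feature_type == "mirna"]
    mir_ids <- intersect(mir_ids, rownames(expr))
    if (length(mir_ids)) {
      mirna_expr <- expr[mir_ids, , drop = FALSE]
      dys_mm <- mirna_target_dysregulation(
        mirna_expr, expr[setdiff(rownames(expr), mir_ids), , drop = FALSE],
        catalog$mrna, labels, alpha = config$alpha, n_perm = config$n_perm,
        seed = config$seed, conditions = config$conditions)
      dys_ml <- mirna_target_dysregulation(
        mirna_expr, expr[setdiff(rownames(expr), mir_ids), , drop = FALSE],
        catalog$lncrna, labels, alpha = config$alpha, n_perm = config$n_perm,
        seed = config$seed, conditions = config$conditions)
      trios <- build_ternary_network(dys_mm, dys_ml, inter)
      write_tsv(dys_mm, file.path(out_dir, "dys_mirna_mrna.tsv"))
      write_tsv(dys_ml, file.path(out_dir, "dys_mirna_lncrna.tsv"))
      write_tsv(trios, file.path(out_dir, "trios.tsv"))
      log_stage("trios", nrow(trios))
      results$trios <- trios
      results$dys_mirna_mrna <- dys_mm
      results$dys_mirna_lncrna <- dys_ml
    }
  }

  if (!is.null(gene_sets)) {
    if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
    lnc_ids <- if (!is.null(feature_type))
      intersect(names(feature_type)[feature_type == "lncrna"],
                rownames(expr)) else rownames(expr)
    scores <- ssgsea_scores(expr, gene_sets)
    assoc <- lncrna_pathway_association(scores,
                                        expr[lnc_ids, , drop = FALSE],
                                        threshold = config$pathway_threshold)
    write_expression(scores, file.path(out_dir, "ssgsea_scores.tsv"),
                     id_column = "gene_set")
    write_tsv(assoc$associations,
              file.path(out_dir, "pathway_associations.tsv"))
    log_stage("pathway_associations", nrow(assoc$associations))
    results$ssgsea <- scores
    results$pathway_associations <- assoc
  }

  if (!is.null(markers)) {
    panels <- enumerate_panels(markers, min_size = 2)
    evals <- lapply(panels, function(p)
      crossval_panel(expr, labels, p, k = config$k_folds,
                     seed = config$seed, conditions = config$conditions))
    ranked <- rank_panels(evals)
    panel_df <- do.call(rbind, lapply(ranked, function(e)
      data.frame(panel = paste(e$panel, collapse = ";"),
                 size = length(e$panel), accuracy = e$accuracy,
                 sensitivity = e$sensitivity, specificity = e$specificity,
                 n_correct = e$n_correct, stringsAsFactors = FALSE)))
    write_tsv(panel_df, file.path(out_dir, "panel_evaluations.tsv"))
    log_stage("panel_evaluations", nrow(panel_df))
    results$panel_evaluations <- ranked
  }

  manifest <- list(
    package = "cernet",
    parameters = unclass(config)[setdiff(names(unclass(config)), NULL)],
    stages = counts,
    files = sort(setdiff(list.files(out_dir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
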