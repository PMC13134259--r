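#' Assemble and validate a pipeline run configuration
#'
#' Collects everything one end-to-end run needs: input paths, the disease
#' gene set, optional gene lengths, QC/normalization parameters, the
#' Monte-Carlo control configuration, and a master seed echoed into every
#' output header. All referenced paths must exist at validation time.
#'
#' @param mtx_dir directory holding `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, `cell_meta.tsv` (as written by [write_mtx_dataset()]).
#' @param gene_set_path disease gene-set TSV (see [read_gene_set()]).
#' @param gene_length_path optional gene-length TSV; required when
#'   `match_length = TRUE`.
#' @param out_dir output directory for result TSVs.
#' @param min_genes_per_cell,min_cells_per_gene QC thresholds.
#' @param target_sum normalization target (default 1e4).
#' @param n_control_sets,n_expr_bins,n_len_bins,match_length,exclude_seed_genes
#'   control-set parameters; see [control_config()].
#' @param min_cells_per_type smallest cell type admitted to type-level tests.
#' @param seed master seed; stage-specific streams are derived from it.
#' @param dataset_label label for the run.
#' @return a validated `RunConfig` list.
#' @export
run_config <- function(mtx_dir, gene_set_path, gene_length_path = NULL,
                       out_dir = "screlev_results",
                       min_genes_per_cell = 200, min_cells_per_gene = 3,
                       target_sum = 1e4, n_control_sets = 1000,
                       n_expr_bins = 20, n_len_bins = 5, match_length = FALSE,
                       exclude_seed_genes = TRUE, min_cells_per_type = 10,
                       seed = 1L, dataset_label = basename(mtx_dir)) {
  needed <- file.path(mtx_dir, c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                                 "cell_meta.tsv"))
  missing <- c(needed[!file.exists(needed)],
               if (!file.exists(gene_set_path)) gene_set_path,
               if (!is.null(gene_length_path) && !file.exists(gene_length_path))
                 gene_length_path)
  if (length(missing))
    abort_validation(paste0("missing input files: ", paste(missing, collapse = ", ")))
  if (match_length && is.null(gene_length_path))
    abort_validation("match_length = TRUE requires gene_length_path")
  structure(list(
    mtx_dir = mtx_dir, gene_set_path = gene_set_path,
    gene_length_path = gene_length_path, out_dir = out_dir,
    min_genes_per_cell = min_genes_per_cell,
    min_cells_per_gene = min_cells_per_gene, target_sum = target_sum,
    n_control_sets = n_control_sets, n_expr_bins = n_expr_bins,
    n_len_bins = n_len_bins, match_length = match_length,
    exclude_seed_genes = exclude_seed_genes,
    min_cells_per_type = min_cells_per_type, seed = as.integer(seed),
    dataset_label = dataset_label
  ), class = "RunConfig")
}

# derive a per-stage stream seed from the master seed by a fixed counter
# scheme (kept below 2^31)
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 1103L + counter * 12721L) %% 2147483647)
}

write_result_tsv <- function(df, path, params) {
  hdr <- vapply(names(params), function(k)
    sprintf("# %s=%s", k, paste(params[[k]], collapse = ",")), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Simulate a dataset bundle to disk
#'
#' Thin wrapper around [generate_dataset()] that writes the MTX bundle the
#' readers consume, plus the ground truth (program membership and gene
#' lengths) as TSVs.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
cmd_simulate <- function(cfg, out_dir) {
  res <- generate_dataset(cfg)
  write_mtx_dataset(res$dataset, out_dir)
  truth <- data.frame(
    gene_id = names(res$truth$lengths),
    length_bp = round(unname(res$truth$lengths)),
    baseline_mean = unname(res$truth$baseline),
    is_program_gene = names(res$truth$lengths) %in% res$truth$program_genes,
    stringsAsFactors = FALSE
  )
  write_result_tsv(truth, file.path(out_dir, "ground_truth.tsv"),
                   list(seed = cfg$seed, program_fold = cfg$program_fold,
                        program_types = cfg$program_types))
  invisible(out_dir)
}

#' Run the full pipeline on one dataset
#'
#' QC -> normalization -> gene-set mapping -> per-gene specificity screen
#' (on the disease set) with top-type enrichment -> matched-control scoring
#' -> cell-type association and heterogeneity -> driver ranking. All result
#' tables are written as TSVs whose header comments echo the seed and
#' parameters; the return value carries the same objects in memory.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `dataset`, `gene_set`, `specificity`,
#'   `enrichment`, `scores`, `association`, `heterogeneity`, `drivers`.
#' @export
cmd_run <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  ds <- read_mtx_dataset(file.path(config$mtx_dir, "matrix.mtx"),
                         file.path(config$mtx_dir, "genes.tsv"),
                         file.path(config$mtx_dir, "barcodes.tsv"),
                         file.path(config$mtx_dir, "cell_meta.tsv"),
                         dataset_label = config$dataset_label)
  ds <- qc_filter(ds, config$min_genes_per_cell, config$min_cells_per_gene)
  ds <- normalize_log1p(ds, config$target_sum)

  gs <- read_gene_set(config$gene_set_path)
  mapping <- match_gene_set(gs, gene_ids(ds))
  if (!length(mapping$mapped))
    abort_degenerate("no gene-set member maps into the dataset")

  spec <- kruskal_wallis_specificity(ds, mapping$mapped,
                                     min_cells_per_type = config$min_cells_per_type)
  enr <- top_type_enrichment(spec, ds)

  lengths <- if (!is.null(config$gene_length_path))
    read_gene_lengths(config$gene_length_path) else NULL
  ccfg <- control_config(
    n_control_sets = config$n_control_sets, n_expr_bins = config$n_expr_bins,
    n_len_bins = config$n_len_bins, match_length = config$match_length,
    exclude_seed_genes = config$exclude_seed_genes,
    seed = derive_seed(config$seed, 1L)
  )
  mean_expr <- Matrix::colMeans(ds$normalized)
  bins <- bin_genes(mean_expr, lengths, ccfg)
  controls <- sample_control_sets(mapping$mapped, bins, ccfg)
  scores <- score_cells(ds, mapping$mapped, controls)
  assoc <- celltype_association(scores, cell_types_of(ds),
                                config$min_cells_per_type)
  het <- celltype_heterogeneity(scores, cell_types_of(ds),
                                config$min_cells_per_type)
  drv <- gene_score_correlation(ds, scores, seed_set = mapping$mapped)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- list(seed = config$seed, K = config$n_control_sets,
                 n_expr_bins = config$n_expr_bins,
                 n_len_bins = config$n_len_bins,
                 match_length = config$match_length,
                 min_genes_per_cell = config$min_genes_per_cell,
                 min_cells_per_gene = config$min_cells_per_gene,
                 dataset = config$dataset_label)
  w <- function(df, name) write_result_tsv(df, file.path(config$out_dir, name), params)
  w(as.data.frame(spec), "specificity.tsv")
  w(enr$table, "top_type_enrichment.tsv")
  w(scores$scores, "cell_scores.tsv")
  w(merge(as.data.frame(assoc), het, by = c("cell_type", "n_cells")),
    "celltype_association.tsv")
  w(as.data.frame(drv), "driver_table.tsv")

  invisible(list(dataset = ds, gene_set = gs, mapping = mapping,
                 specificity = spec, enrichment = enr, scores = scores,
                 association = assoc, heterogeneity = het, drivers = drv))
}
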