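#' Configuration for the synthetic single-cell generator
#'
#' Defines a negative-binomial count model with per-gene baselines, per-cell
#' library-size factors, a planted "disease program" (a set of genes
#' overexpressed by a common fold in designated cell types), and an optional
#' gene-length model that couples length to baseline expression through a
#' Gaussian copula (the one-knob confounder used to exercise the dual
#' expression+length matched null).
#'
#' @param n_genes number of genes.
#' @param cell_type_sizes named integer vector, cells per cell type.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters for the
#'   per-gene baseline mean expression.
#' @param dispersion negative-binomial size parameter (shared across genes);
#'   larger values approach Poisson.
#' @param program_genes character vector of planted program genes (subset of
#'   the gene universe `g1..gN`); may be empty.
#' @param program_types character vector of cell types carrying the program.
#' @param program_fold fold-change (> 0) applied to program genes in program
#'   types; 1 plants nothing (a null dataset).
#' @param length_model `"independent"` or `"expression_correlated"`.
#' @param rho copula correlation between gene length and baseline expression
#'   when `length_model = "expression_correlated"`.
#' @param lib_size_log_sd log-normal sd of per-cell size factors (default
#'   0.3), so library-size normalization is non-trivial.
#' @param length_log_mean,length_log_sd log-normal parameters of gene length.
#' @param seed integer RNG seed; the generator is fully reproducible from it.
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_genes = 2000,
                             cell_type_sizes = c(A = 400, B = 400, C = 400,
                                                 D = 400, E = 400),
                             baseline_log_mean = log(0.3),
                             baseline_log_sd = 1,
                             dispersion = 2,
                             program_genes = character(),
                             program_types = character(),
                             program_fold = 1,
                             length_model = c("independent", "expression_correlated"),
                             rho = 0,
                             lib_size_log_sd = 0.3,
                             length_log_mean = log(2500),
                             length_log_sd = 0.8,
                             seed = 1L) {
  length_model <- match.arg(length_model)
  if (n_genes < 1 || any(cell_type_sizes < 1))
    abort_validation("n_genes and all cell_type_sizes must be positive")
  if (is.null(names(cell_type_sizes)))
    abort_validation("cell_type_sizes must be named by cell type")
  if (program_fold <= 0)
    abort_validation("program_fold must be > 0")
  if (rho < 0 || rho > 1)
    abort_validation("rho must lie in [0, 1]")
  universe <- paste0("g", seq_len(n_genes))
  if (!all(program_genes %in% universe))
    abort_validation("program_genes must be a subset of the gene universe g1..gN")
  if (!all(program_types %in% names(cell_type_sizes)))
    abort_validation("program_types must be a subset of the configured cell types")
  structure(list(
    n_genes = as.integer(n_genes), cell_type_sizes = cell_type_sizes,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    dispersion = dispersion, program_genes = program_genes,
    program_types = program_types, program_fold = program_fold,
    length_model = length_model, rho = rho,
    lib_size_log_sd = lib_size_log_sd,
    length_log_mean = length_log_mean, length_log_sd = length_log_sd,
    seed = as.integer(seed)
  ), class = "SyntheticConfig")
}

#' Generate a synthetic single-cell dataset with known ground truth
#'
#' Counts are drawn as `NegBin(mean = size_factor_cell * baseline_gene *
#' fold, size = dispersion)` where `fold = program_fold` iff the gene is a
#' program gene and the cell belongs to a program type, and 1 otherwise.
#' Gene lengths are log-normal; under `length_model =
#' "expression_correlated"` their ranks are coupled to the baseline means by
#' a Gaussian copula with correlation `rho`.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `dataset` (a [CellExpressionDataset()], counts only)
#'   and `truth` (program genes/types, per-gene lengths and baselines, and
#'   per-cell size factors).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  withr::with_seed(cfg$seed, generate_dataset_impl(cfg))
}

generate_dataset_impl <- function(cfg) {
  genes <- paste0("g", seq_len(cfg$n_genes))
  types <- rep(names(cfg$cell_type_sizes), times = cfg$cell_type_sizes)
  n_cells <- length(types)
  cells <- sprintf("cell%05d", seq_len(n_cells))

  baseline <- stats::rlnorm(cfg$n_genes, cfg$baseline_log_mean, cfg$baseline_log_sd)
  names(baseline) <- genes

  # copula-coupled lengths: same marginal either way, rho controls coupling
  z_expr <- stats::qnorm(rank(baseline, ties.method = "first") / (cfg$n_genes + 1))
  eps <- stats::rnorm(cfg$n_genes)
  z_len <- if (cfg$length_model == "expression_correlated")
    cfg$rho * z_expr + sqrt(1 - cfg$rho^2) * eps else eps
  lengths <- stats::qlnorm(stats::pnorm(z_len), cfg$length_log_mean, cfg$length_log_sd)
  lengths <- pmax(lengths, 1)
  names(lengths) <- genes

  size_factor <- stats::rlnorm(n_cells, 0, cfg$lib_size_log_sd)

  fold <- rep(1, cfg$n_genes)
  fold[genes %in% cfg$program_genes] <- cfg$program_fold
  in_prog_type <- types %in% cfg$program_types

  counts <- matrix(0L, n_cells, cfg$n_genes, dimnames = list(cells, genes))
  for (g in seq_len(cfg$n_genes)) {
    mu <- size_factor * baseline[g]
    if (fold[g] != 1) mu[in_prog_type] <- mu[in_prog_type] * fold[g]
    counts[, g] <- stats::rnbinom(n_cells, mu = mu, size = cfg$dispersion)
  }

  meta <- data.frame(cell_id = cells, cell_type = types, stringsAsFactors = FALSE)
  ds <- CellExpressionDataset(counts, meta, dataset_label = "synthetic")
  truth <- list(
    program_genes = cfg$program_genes, program_types = cfg$program_types,
    lengths = lengths, baseline = baseline, size_factor = size_factor,
    program_fold = cfg$program_fold, seed = cfg$seed
  )
  list(dataset = ds, truth = truth)
}

#' Generate a series of stage-labelled datasets on a shared gene universe
#'
#' One configuration per developmental stage; configs may differ in
#' `program_fold` (to plant early-peak or late-rise genes) but must agree on
#' the gene universe. Gene lengths and baselines are drawn from the first
#' stage's seed so the universe is biologically consistent across stages.
#'
#' @param cfg_list list of [synthetic_config()] objects, one per stage, in
#'   developmental order.
#' @param stage_labels character vector of stage names, same length.
#' @return named list of `generate_dataset`-style results; each dataset's
#'   `cell_meta` carries the stage label.
#' @export
generate_stage_series <- function(cfg_list, stage_labels) {
  if (length(cfg_list) != length(stage_labels))
    abort_validation("one config per stage label required")
  n_genes <- unique(vapply(cfg_list, function(c) c$n_genes, integer(1)))
  if (length(n_genes) != 1)
    abort_validation("all stage configs must share the same gene universe")
  out <- vector("list", length(cfg_list))
  names(out) <- stage_labels
  for (i in seq_along(cfg_list)) {
    res <- generate_dataset(cfg_list[[i]])
    res$dataset$cell_meta$stage <- stage_labels[i]
    res$dataset$dataset_label <- paste0("synthetic_", stage_labels[i])
    out[[i]] <- res
  }
  out
}
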