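#' Configuration for matched control-set sampling
#'
#' @param n_control_sets number of Monte-Carlo control gene sets K
#'   (default 1000). Empirical p-values are multiples of 1/(K+1).
#' @param n_expr_bins quantile bins of mean expression (default 20).
#' @param n_len_bins quantile bins of gene length, used only with
#'   `match_length = TRUE` (default 5).
#' @param match_length match controls on gene length as well as expression
#'   (the dual-matched null; default FALSE).
#' @param exclude_seed_genes keep disease genes out of control pools
#'   (default TRUE).
#' @param min_bin_occupancy bins with fewer genes are merged into a
#'   neighboring bin (default 10).
#' @param seed RNG seed for control sampling.
#' @return a `ControlConfig` list.
#' @export
control_config <- function(n_control_sets = 1000, n_expr_bins = 20,
                           n_len_bins = 5, match_length = FALSE,
                           exclude_seed_genes = TRUE, min_bin_occupancy = 10,
                           seed = 1L) {
  if (n_control_sets < 1 || n_expr_bins < 1 || n_len_bins < 1)
    abort_validation("n_control_sets and bin counts must be >= 1")
  structure(list(
    n_control_sets = as.integer(n_control_sets),
    n_expr_bins = as.integer(n_expr_bins), n_len_bins = as.integer(n_len_bins),
    match_length = isTRUE(match_length),
    exclude_seed_genes = isTRUE(exclude_seed_genes),
    min_bin_occupancy = as.integer(min_bin_occupancy), seed = as.integer(seed)
  ), class = "ControlConfig")
}

# equal-occupancy quantile bins via ranks (ties broken by order, so 100 genes
# into 4 bins always gives 25/25/25/25)
ntile_bins <- function(x, n_bins) {
  n_bins <- min(n_bins, length(x))
  as.integer(ceiling(rank(x, ties.method = "first") * n_bins / length(x)))
}

#' Assign genes to expression (and optionally length) bins
#'
#' Expression bins are equal-occupancy quantile bins of the gene's mean
#' normalized expression over all cells; with `match_length = TRUE` the bin
#' is the (expression bin, length bin) pair. Bins holding fewer than
#' `min_bin_occupancy` genes are merged into the nearest neighboring
#' expression bin (falling back to the neighboring length bin) until all
#' bins are adequately occupied.
#'
#' @param mean_expr named numeric vector: per-gene mean of the normalized
#'   layer over all cells.
#' @param lengths named numeric vector of gene lengths (bp); required when
#'   `cfg$match_length`.
#' @param cfg a [control_config()].
#' @return named character vector of bin labels per gene; attribute
#'   `bin_table` tabulates occupancy.
#' @export
bin_genes <- function(mean_expr, lengths = NULL, cfg = control_config()) {
  genes <- names(mean_expr)
  if (is.null(genes)) abort_contract("mean_expr must be named by gene ID")
  eb <- ntile_bins(mean_expr, cfg$n_expr_bins)
  if (cfg$match_length) {
    if (is.null(lengths))
      abort_contract("match_length = TRUE requires gene lengths")
    miss <- setdiff(genes, names(lengths))
    if (length(miss))
      abort_contract(sprintf("missing lengths for %d genes (e.g. %s)",
                             length(miss), paste(utils::head(miss, 5), collapse = ", ")))
    lb <- ntile_bins(lengths[genes], cfg$n_len_bins)
  } else {
    lb <- rep(1L, length(genes))
  }

  repeat {
    lab <- paste0("e", eb, if (cfg$match_length) paste0(".l", lb) else "")
    tab <- table(lab)
    small <- names(tab)[tab < cfg$min_bin_occupancy]
    if (!length(small) || length(tab) == 1) break
    # merge the smallest bin into its nearest existing neighbor, preferring
    # the expression axis
    b <- small[which.min(tab[small])]
    members <- lab == b
    e0 <- eb[members][1]; l0 <- lb[members][1]
    other_e <- sort(unique(eb[lab != b & lb == l0]))
    if (length(other_e)) {
      eb[members] <- other_e[which.min(abs(other_e - e0))]
    } else {
      other_l <- sort(unique(lb[lab != b & eb == e0]))
      if (length(other_l)) {
        lb[members] <- other_l[which.min(abs(other_l - l0))]
      } else {
        # isolated bin: collapse onto the globally nearest expression bin
        all_e <- sort(unique(eb[lab != b]))
        eb[members] <- all_e[which.min(abs(all_e - e0))]
        lb[members] <- lb[lab != b][1]
      }
    }
  }
  bins <- stats::setNames(lab, genes)
  attr(bins, "bin_table") <- table(bins)
  bins
}

#' Sample matched control gene sets
#'
#' For each control set and each seed (disease) gene, draws one gene
#' uniformly from the seed gene's bin. Within one control set, draws inside
#' a bin are without replacement where the pool allows; exhausted bins fall
#' back to with-replacement sampling and are logged in the
#' `with_replacement_bins` field.
#'
#' @param seed_genes character vector of mapped disease-gene IDs.
#' @param bins bin assignment from [bin_genes()] covering all genes.
#' @param cfg a [control_config()]; its `seed` makes sampling reproducible.
#' @return a `ControlSetCollection`: list with `sets` (|seed_genes| x K
#'   character matrix, rows aligned to `seed_genes`), `seed_genes`,
#'   `seed_bins`, `with_replacement_bins`, `seed`.
#' @export
sample_control_sets <- function(seed_genes, bins, cfg = control_config()) {
  miss <- setdiff(seed_genes, names(bins))
  if (length(miss))
    abort_contract(sprintf("seed genes missing from the bin assignment: %s",
                           paste(utils::head(miss, 5), collapse = ", ")))
  seed_bins <- bins[seed_genes]
  pools <- split(names(bins), bins)
  if (cfg$exclude_seed_genes)
    pools <- lapply(pools, setdiff, y = seed_genes)
  for (b in unique(seed_bins)) {
    if (length(pools[[b]]) < 1)
      abort_contract(sprintf("bin %s has no eligible control genes", b))
  }

  K <- cfg$n_control_sets
  by_bin <- split(seq_along(seed_genes), seed_bins)
  sets <- matrix(NA_character_, length(seed_genes), K)
  wr_bins <- character()
  withr::with_seed(cfg$seed, {
    for (b in names(by_bin)) {
      idx <- by_bin[[b]]
      pool <- pools[[b]]
      replace <- length(pool) < length(idx)
      if (replace) wr_bins <- c(wr_bins, b)
      for (k in seq_len(K))
        sets[idx, k] <- sample(pool, length(idx), replace = replace)
    }
  })
  structure(list(sets = sets, seed_genes = seed_genes, seed_bins = seed_bins,
                 with_replacement_bins = unique(wr_bins), seed = cfg$seed),
            class = "ControlSetCollection")
}

#' @export
print.ControlSetCollection <- function(x, ...) {
  cat(sprintf("ControlSetCollection: %d sets of %d genes (seed %d)\n",
              ncol(x$sets), nrow(x$sets), x$seed))
  invisible(x)
}

# mean over a gene list per cell, as one sparse matrix product; duplicated
# genes (with-replacement bins) contribute proportionally to their weight
set_mean_matrix <- function(normalized, gene_sets_matrix) {
  m <- nrow(gene_sets_matrix); K <- ncol(gene_sets_matrix)
  gi <- match(as.vector(gene_sets_matrix), colnames(normalized))
  W <- Matrix::sparseMatrix(i = gi, j = rep(seq_len(K), each = m),
                            x = 1 / m, dims = c(ncol(normalized), K))
  as.matrix(normalized %*% W)
}

#' Score cells for disease-gene-set overexpression
#'
#' The raw score of a cell is the mean of its normalized expression over the
#' disease genes. Each control set yields an analogous score; per cell, the
#' K control scores form the null used to standardize:
#' `norm_score = (raw - mean_K) / sd_K`, and the Monte-Carlo p-value is
#' `(1 + #(control >= raw)) / (K + 1)`. Cells whose control scores have zero
#' spread get `norm_score = 0` and are flagged.
#'
#' @param ds a normalized [CellExpressionDataset()].
#' @param seed_genes mapped disease-gene IDs (must match the collection's).
#' @param controls a `ControlSetCollection` from [sample_control_sets()].
#' @return a `CellScoreTable`: list with `scores` (data.frame: `cell_id`,
#'   `raw_score`, `norm_score`, `mc_p`, `sd_zero`), `control_norm`
#'   (cells x K matrix of identically standardized control scores, the
#'   material for the cell-type null), and `K`.
#' @export
score_cells <- function(ds, seed_genes, controls) {
  require_normalized(ds)
  if (!identical(sort(seed_genes), sort(controls$seed_genes)))
    abort_contract("seed_genes must match the control collection's seed genes")
  miss <- setdiff(seed_genes, gene_ids(ds))
  if (length(miss)) abort_contract("seed genes missing from the dataset")

  # the observed score goes through the same accumulation path as the
  # control scores, so exact ties (e.g. a control set equal to the disease
  # set) survive floating-point summation
  raw <- as.numeric(set_mean_matrix(ds$normalized,
                                    matrix(controls$seed_genes, ncol = 1)))
  ctrl <- set_mean_matrix(ds$normalized, controls$sets)
  K <- ncol(ctrl)
  mu <- rowMeans(ctrl)
  sdv <- sqrt(pmax(rowSums(ctrl^2) - K * mu^2, 0) / (K - 1))
  sd_zero <- sdv == 0
  denom <- ifelse(sd_zero, 1, sdv)
  norm <- ifelse(sd_zero, 0, (raw - mu) / denom)
  control_norm <- (ctrl - mu) / denom
  mc_p <- (1 + rowSums(ctrl >= raw)) / (K + 1)

  structure(list(
    scores = data.frame(cell_id = cell_ids(ds), raw_score = raw,
                        norm_score = norm, mc_p = mc_p, sd_zero = sd_zero,
                        stringsAsFactors = FALSE),
    control_norm = control_norm, K = K
  ), class = "CellScoreTable")
}

#' Empirical p-value and z-score against a Monte-Carlo null
#'
#' `p = (1 + #(null >= observed)) / (n + 1)` (one-sided, enrichment
#' direction) and `z = (observed - mean(null)) / sd(null)` with the sample
#' standard deviation. With a single null value or zero spread, `z` is `NA`
#' and flagged; `p` is still returned.
#'
#' @param observed observed statistic.
#' @param null_values non-empty numeric vector of null statistics.
#' @return list with `p`, `z`, `z_defined`.
#' @export
empirical_p_and_z <- function(observed, null_values) {
  if (!length(null_values)) abort_contract("null_values must be non-empty")
  p <- (1 + sum(null_values >= observed)) / (length(null_values) + 1)
  s <- stats::sd(null_values)
  ok <- length(null_values) > 1 && is.finite(s) && s > 0
  z <- if (ok) (observed - mean(null_values)) / s else NA_real_
  list(p = p, z = z, z_defined = ok)
}

type_aggregate <- function(values_matrix, cell_types, sizes_min) {
  ind <- type_indicator(cell_types)
  n <- Matrix::rowSums(ind)
  keep <- n >= sizes_min
  list(ind = ind[keep, , drop = FALSE], n = n[keep],
       types = rownames(ind)[keep], excluded = rownames(ind)[!keep])
}

#' Cell-type association with the disease gene set
#'
#' Aggregates the standardized per-cell scores to the cell-type level
#' (type mean) and compares the observed statistic to the identical
#' aggregation of each control set's standardized scores:
#' `empirical_p = (1 + #(null_k >= observed)) / (K + 1)` (one-sided,
#' enrichment) and `z = (observed - mean_k) / sd_k`. Cell types smaller than
#' `min_cells_per_type` are excluded and listed in the `excluded_types`
#' attribute.
#'
#' @param cell_scores a `CellScoreTable` from [score_cells()].
#' @param cell_types character vector of per-cell type labels, aligned with
#'   the score table's cells.
#' @param min_cells_per_type smallest admissible type (default 10).
#' @return an `AssociationResult` data.frame: `cell_type`, `n_cells`,
#'   `observed_statistic`, `null_mean`, `null_sd`, `z`, `empirical_p`.
#' @export
celltype_association <- function(cell_scores, cell_types, min_cells_per_type = 10) {
  stopifnot(inherits(cell_scores, "CellScoreTable"))
  agg <- type_aggregate(cell_scores$control_norm, cell_types, min_cells_per_type)
  obs <- as.numeric(agg$ind %*% cell_scores$scores$norm_score) / agg$n
  nulls <- as.matrix(agg$ind %*% cell_scores$control_norm) / agg$n  # types x K
  K <- cell_scores$K
  null_mean <- rowMeans(nulls)
  null_sd <- apply(nulls, 1, stats::sd)
  out <- data.frame(
    cell_type = agg$types, n_cells = agg$n,
    observed_statistic = obs, null_mean = null_mean, null_sd = null_sd,
    z = (obs - null_mean) / null_sd,
    empirical_p = (1 + rowSums(nulls >= obs)) / (K + 1),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "excluded_types") <- agg$excluded
  class(out) <- c("AssociationResult", "data.frame")
  out
}

#' Within-type heterogeneity of disease scores
#'
#' Monte-Carlo test of whether the disease scores of a cell type are more
#' dispersed than matched-control scores: the statistic is the sample
#' variance of the standardized score within the type, the null the same
#' computation on each control set. Detects types that mix strongly scoring
#' subpopulations with unremarkable cells.
#'
#' @inheritParams celltype_association
#' @return a data.frame: `cell_type`, `n_cells`, `heterogeneity_statistic`,
#'   `het_null_mean`, `heterogeneity_p`.
#' @export
celltype_heterogeneity <- function(cell_scores, cell_types, min_cells_per_type = 10) {
  stopifnot(inherits(cell_scores, "CellScoreTable"))
  agg <- type_aggregate(cell_scores$control_norm, cell_types, min_cells_per_type)
  n <- agg$n
  var_by_type <- function(v) {
    s1 <- as.numeric(agg$ind %*% v)
    s2 <- as.numeric(agg$ind %*% (v^2))
    (s2 - s1^2 / n) / (n - 1)
  }
  obs <- var_by_type(cell_scores$scores$norm_score)
  K <- cell_scores$K
  nulls <- vapply(seq_len(K), function(k) var_by_type(cell_scores$control_norm[, k]),
                  numeric(length(n)))
  nulls <- matrix(nulls, nrow = length(n))
  out <- data.frame(
    cell_type = agg$types, n_cells = n,
    heterogeneity_statistic = obs,
    het_null_mean = rowMeans(nulls),
    heterogeneity_p = (1 + rowSums(nulls >= obs)) / (K + 1),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "excluded_types") <- agg$excluded
  out
}
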