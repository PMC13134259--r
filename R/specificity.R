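type_indicator <- function(cell_types) {
  types <- sort(unique(cell_types))
  Matrix::sparseMatrix(
    i = match(cell_types, types), j = seq_along(cell_types), x = 1,
    dims = c(length(types), length(cell_types)),
    dimnames = list(types, NULL)
  )
}

resolve_genes <- function(ds, genes) {
  if (is.null(genes) || identical(genes, "all")) return(gene_ids(ds))
  miss <- setdiff(genes, gene_ids(ds))
  if (length(miss))
    warning(sprintf("%d requested genes not in the dataset were excluded", length(miss)))
  genes[genes %in% gene_ids(ds)]
}

#' Mean log-normalized expression per cell type
#'
#' @param ds a normalized [CellExpressionDataset()].
#' @param genes gene IDs to include, or `"all"` (default). Unmapped genes
#'   are dropped with a warning.
#' @return gene x cell-type matrix of arithmetic means of the normalized
#'   layer.
#' @export
mean_expression_by_type <- function(ds, genes = "all") {
  require_normalized(ds)
  genes <- resolve_genes(ds, genes)
  ind <- type_indicator(cell_types_of(ds))
  sums <- ind %*% ds$normalized[, genes, drop = FALSE]
  means <- as.matrix(sums / Matrix::rowSums(ind))
  t(means)
}

#' Detection rate per cell type
#'
#' Fraction of cells of each type in which the gene has a nonzero count.
#'
#' @inheritParams mean_expression_by_type
#' @return gene x cell-type matrix with entries in \code{[0, 1]}.
#' @export
detection_rate_by_type <- function(ds, genes = "all") {
  genes <- resolve_genes(ds, genes)
  ind <- type_indicator(cell_types_of(ds))
  det <- ds$counts[, genes, drop = FALSE] > 0
  rates <- as.matrix(ind %*% det / Matrix::rowSums(ind))
  t(rates)
}

#' Per-gene cell-type specificity (Kruskal-Wallis screen)
#'
#' Tests, for each gene, whether its log-normalized expression distribution
#' differs between cell types (tie-corrected Kruskal-Wallis with the
#' chi-squared approximation), then adjusts the p-values across the tested
#' gene list with Benjamini-Hochberg. Genes constant across all cells get
#' the degenerate convention H = 0, p = 1. Cell types with fewer than
#' `min_cells_per_type` cells are excluded from the test and listed in the
#' `excluded_types` attribute.
#'
#' @param ds a normalized [CellExpressionDataset()].
#' @param genes gene IDs to test, or `"all"`.
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @param min_cells_per_type smallest cell-type size admitted to the test
#'   (default 10).
#' @return a `SpecificityResult` data.frame with columns `gene_id`,
#'   `kw_statistic`, `p_value`, `fdr`, `significant`, `top_cell_type`;
#'   attributes `mean_expr` and `detection_rate` hold the gene x type
#'   matrices used for top-type calls.
#' @export
kruskal_wallis_specificity <- function(ds, genes = "all", alpha = 0.05,
                                       min_cells_per_type = 10) {
  require_normalized(ds)
  genes <- resolve_genes(ds, genes)
  ct <- cell_types_of(ds)
  sizes <- table(ct)
  keep_types <- names(sizes)[sizes >= min_cells_per_type]
  excluded <- setdiff(names(sizes), keep_types)
  if (length(keep_types) < 2)
    abort_contract("Kruskal-Wallis needs at least two cell types of admissible size")
  in_keep <- ct %in% keep_types
  grp <- factor(ct[in_keep])
  X <- ds$normalized[in_keep, genes, drop = FALSE]

  stat <- p <- numeric(length(genes))
  for (j in seq_along(genes)) {
    x <- X[, j]
    if (max(x) == min(x)) {          # all values identical: no variation
      stat[j] <- 0; p[j] <- 1
    } else {
      kt <- stats::kruskal.test(x, grp)
      stat[j] <- unname(kt$statistic); p[j] <- kt$p.value
    }
  }
  fdr <- stats::p.adjust(p, method = "BH")

  me <- mean_expression_by_type(ds, genes)[, keep_types, drop = FALSE]
  dr <- detection_rate_by_type(ds, genes)[, keep_types, drop = FALSE]
  top <- vapply(seq_along(genes), function(j) {
    m <- me[j, ]
    cand <- keep_types[m == max(m)]
    if (length(cand) > 1) {          # break ties by detection rate, then name
      d <- dr[j, cand]
      cand <- sort(cand[d == max(d)])
    }
    cand[1]
  }, character(1))

  out <- data.frame(
    gene_id = genes, kw_statistic = stat, p_value = p, fdr = fdr,
    significant = fdr < alpha, top_cell_type = top,
    stringsAsFactors = FALSE
  )
  attr(out, "mean_expr") <- me
  attr(out, "detection_rate") <- dr
  attr(out, "excluded_types") <- excluded
  attr(out, "alpha") <- alpha
  class(out) <- c("SpecificityResult", "data.frame")
  out
}

#' Enrichment of top-expressing cell types over the background composition
#'
#' Counts how often each cell type is the top-expressing type across the
#' tested genes, compares the counts to the expectation under the dataset's
#' cell-type abundances with a chi-squared goodness-of-fit test, and reports
#' per-type observed/expected ratios. Types with expected count below
#' `min_expected` are pooled into an `"other"` category before the test
#' (classical validity rule); O/E ratios are still reported unpooled.
#'
#' @param spec a `SpecificityResult` from [kruskal_wallis_specificity()].
#' @param ds the dataset the screen was run on (supplies type abundances).
#' @param gene_ids optional subset of `spec$gene_id` to restrict to; default
#'   all tested genes.
#' @param min_expected pooling threshold (default 1).
#' @return a `TopTypeEnrichment` list: `table` (data.frame with `cell_type`,
#'   `observed`, `expected`, `oe_ratio`), `chi2_statistic`, `df`, `p_value`,
#'   and `pooled_types`.
#' @export
top_type_enrichment <- function(spec, ds, gene_ids = NULL, min_expected = 1) {
  stopifnot(inherits(spec, "SpecificityResult"))
  if (is.null(gene_ids)) gene_ids <- spec$gene_id
  rows <- spec[spec$gene_id %in% gene_ids, , drop = FALSE]
  if (nrow(rows) == 0) abort_contract("no tested genes in the requested set")
  types <- colnames(attr(spec, "mean_expr"))
  observed <- table(factor(rows$top_cell_type, levels = types))
  abund <- table(factor(cell_types_of(ds), levels = types))
  expected <- nrow(rows) * as.numeric(abund) / sum(abund)
  oe <- as.numeric(observed) / expected

  pool <- expected < min_expected & length(types) > 1
  if (any(pool) && sum(!pool) >= 1) {
    obs_t <- c(as.numeric(observed)[!pool], sum(as.numeric(observed)[pool]))
    exp_t <- c(expected[!pool], sum(expected[pool]))
    pooled <- types[pool]
  } else {
    obs_t <- as.numeric(observed); exp_t <- expected; pooled <- character()
  }
  ct <- suppressWarnings(stats::chisq.test(obs_t, p = exp_t / sum(exp_t)))

  structure(list(
    table = data.frame(cell_type = types, observed = as.numeric(observed),
                       expected = expected, oe_ratio = oe,
                       stringsAsFactors = FALSE),
    chi2_statistic = unname(ct$statistic), df = unname(ct$parameter),
    p_value = ct$p.value, pooled_types = pooled
  ), class = "TopTypeEnrichment")
}
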