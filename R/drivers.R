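#' Rank genes by correlation with per-cell disease scores
#'
#' Correlates each gene's normalized expression with the standardized
#' per-cell disease score and ranks genes by descending correlation. Genes
#' whose correlation tracks the disease signal most closely are candidate
#' drivers of the cell-type association. Constant genes are excluded and
#' listed in the `excluded_genes` attribute; rank ties are broken by gene ID.
#'
#' @param ds a normalized [CellExpressionDataset()].
#' @param cell_scores a `CellScoreTable` from [score_cells()] on the same
#'   cells.
#' @param genes gene IDs to rank, or `"all"` (default).
#' @param method `"pearson"` (default) or `"spearman"` for heavy-tailed
#'   expression.
#' @param seed_set optional character vector of disease-gene IDs used to
#'   flag membership.
#' @return a `DriverTable` data.frame: `gene_id`, `r`, `rank`,
#'   `in_seed_set`.
#' @export
gene_score_correlation <- function(ds, cell_scores, genes = "all",
                                   method = c("pearson", "spearman"),
                                   seed_set = NULL) {
  require_normalized(ds)
  method <- match.arg(method)
  stopifnot(inherits(cell_scores, "CellScoreTable"))
  if (!identical(cell_scores$scores$cell_id, cell_ids(ds)))
    abort_contract("score table and dataset must cover the same cells, in order")
  genes <- resolve_genes(ds, genes)
  X <- as.matrix(ds$normalized[, genes, drop = FALSE])
  y <- cell_scores$scores$norm_score
  r <- suppressWarnings(as.numeric(stats::cor(X, y, method = method)))
  names(r) <- genes
  excluded <- genes[is.na(r)]
  r <- r[!is.na(r)]
  ord <- order(-r, names(r))
  out <- data.frame(
    gene_id = names(r), r = unname(r),
    rank = match(names(r), names(r)[ord]),
    in_seed_set = if (is.null(seed_set)) FALSE else names(r) %in% seed_set,
    stringsAsFactors = FALSE
  )
  attr(out, "excluded_genes") <- excluded
  attr(out, "method") <- method
  class(out) <- c("DriverTable", "data.frame")
  out
}

#' Compare driver rankings between two datasets
#'
#' Joins two driver tables on their shared gene universe and labels each
#' gene by where it sits relative to the diagonal of the r-vs-r plane:
#' genes more than `delta` above the diagonal are `b_specific`, more than
#' `delta` below are `a_specific`; genes within the margin are labeled by
#' their common sign (`both_positive`, `both_negative`) or `neither` when
#' the signs disagree or either correlation is zero.
#'
#' @param table_a,table_b `DriverTable`s from [gene_score_correlation()].
#' @param delta off-diagonal margin in correlation units (default 0.05).
#' @return data.frame with `gene_id`, `r_a`, `r_b`, `quadrant`; attribute
#'   `n_shared` records the intersection size.
#' @export
compare_rankings <- function(table_a, table_b, delta = 0.05) {
  shared <- intersect(table_a$gene_id, table_b$gene_id)
  if (!length(shared)) abort_contract("the two tables share no genes")
  ra <- table_a$r[match(shared, table_a$gene_id)]
  rb <- table_b$r[match(shared, table_b$gene_id)]
  quadrant <- ifelse(rb - ra > delta, "b_specific",
              ifelse(ra - rb > delta, "a_specific",
              ifelse(ra > 0 & rb > 0, "both_positive",
              ifelse(ra < 0 & rb < 0, "both_negative", "neither"))))
  out <- data.frame(gene_id = shared, r_a = ra, r_b = rb,
                    quadrant = quadrant, stringsAsFactors = FALSE)
  attr(out, "n_shared") <- length(shared)
  out
}
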