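#' Top-K genes of a ranked table
#'
#' @param ranked_table a `DriverTable` (or any data.frame with `gene_id` and
#'   `rank`).
#' @param k number of genes to take (default 100). If fewer genes are
#'   available, all are returned with a warning.
#' @return character vector of gene IDs, best rank first; rank ties broken
#'   by gene ID.
#' @export
top_k_genes <- function(ranked_table, k = 100) {
  ord <- order(ranked_table$rank, ranked_table$gene_id)
  if (nrow(ranked_table) < k) {
    warning(sprintf("table has only %d genes; returning all", nrow(ranked_table)))
    k <- nrow(ranked_table)
  }
  ranked_table$gene_id[ord][seq_len(k)]
}

#' Cross-organ overlap of top gene lists with a disease set
#'
#' Intersects each organ's top-K list with the disease gene set, and
#' partitions the hits into organ-specific candidates (in exactly one
#' organ's intersection) and genes shared across every organ.
#'
#' @param set_genes character vector of disease-gene IDs (dataset IDs).
#' @param organ_top_lists named list of character vectors, one top-K list
#'   per organ.
#' @return an `OverlapResult` list: `per_organ` (list with `top_k`,
#'   `overlap`, `n_overlap` per organ), `organ_specific` (named list),
#'   `shared_all_organs`.
#' @export
overlap_analysis <- function(set_genes, organ_top_lists) {
  if (!length(organ_top_lists)) abort_contract("need at least one organ list")
  if (is.null(names(organ_top_lists)))
    names(organ_top_lists) <- paste0("organ", seq_along(organ_top_lists))
  overlaps <- lapply(organ_top_lists, intersect, y = set_genes)
  counts <- table(unlist(overlaps))
  specific <- lapply(overlaps, function(o) o[counts[o] == 1])
  shared <- Reduce(intersect, overlaps)
  structure(list(
    per_organ = Map(function(top, ov) list(top_k = top, overlap = ov,
                                           n_overlap = length(ov)),
                    organ_top_lists, overlaps),
    organ_specific = specific,
    shared_all_organs = shared
  ), class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  for (o in names(x$per_organ))
    cat(sprintf("%s: %d of top %d genes in the disease set\n", o,
                x$per_organ[[o]]$n_overlap, length(x$per_organ[[o]]$top_k)))
  cat(sprintf("shared across all organs: %s\n",
              if (length(x$shared_all_organs))
                paste(x$shared_all_organs, collapse = ", ") else "none"))
  invisible(x)
}
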