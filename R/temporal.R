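#' Classify genes as early-peak, late-rise, or stable across stages
#'
#' Takes driver tables for two or more ordered developmental stages,
#' restricts to the shared gene universe (re-ranking within it), and labels
#' each gene:
#' * `early_peak` - ranked within the top `r_early` at the first stage and
#'   worsening by at least `drop_frac` of the tested universe by the last;
#' * `late_rise` - the mirrored criterion (top-ranked late, much worse
#'   early);
#' * `stable` - everything else.
#'
#' Labels depend only on ranks, so any monotone transform of the underlying
#' correlations leaves them unchanged, and reversing the stage order swaps
#' `early_peak` and `late_rise` exactly.
#'
#' @param stage_tables ordered list (earliest first) of `DriverTable`s from
#'   [gene_score_correlation()], or any data.frames with `gene_id` and `r`.
#' @param r_early rank threshold defining "top-ranked" (default 5).
#' @param drop_frac minimum rank change, as a fraction of the shared
#'   universe, to call a gene dynamic (default 0.10).
#' @return a `TemporalClassification` data.frame: `gene_id`, one
#'   `rank_<stage>` column per stage, `rank_drop` (last minus first rank),
#'   `label`.
#' @export
classify_temporal <- function(stage_tables, r_early = 5, drop_frac = 0.10) {
  if (length(stage_tables) < 2)
    abort_contract("temporal classification needs at least two stages")
  shared <- Reduce(intersect, lapply(stage_tables, function(t) t$gene_id))
  if (!length(shared)) abort_contract("stages share no genes")
  G <- length(shared)
  stage_names <- names(stage_tables)
  if (is.null(stage_names)) stage_names <- paste0("stage", seq_along(stage_tables))

  ranks <- vapply(stage_tables, function(t) {
    r <- t$r[match(shared, t$gene_id)]
    as.numeric(rank(-r, ties.method = "first"))
  }, numeric(G))
  colnames(ranks) <- stage_names

  first <- ranks[, 1]; last <- ranks[, ncol(ranks)]
  min_drop <- drop_frac * G
  label <- ifelse(first <= r_early & (last - first) >= min_drop, "early_peak",
           ifelse(last <= r_early & (first - last) >= min_drop, "late_rise",
                  "stable"))
  out <- data.frame(gene_id = shared, ranks,
                    rank_drop = last - first, label = label,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[seq_along(stage_names) + 1] <- paste0("rank_", stage_names)
  class(out) <- c("TemporalClassification", "data.frame")
  out
}
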