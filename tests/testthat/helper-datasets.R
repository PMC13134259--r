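# Small in-memory datasets used across the suite.

# dataset from explicit matrices; `normalized` defaults to the counts so
# rank-based and correlation checks can use hand-written values directly
toy_dataset <- function(counts, cell_types, normalized = counts) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("c", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  if (!is.null(normalized)) dimnames(normalized) <- dimnames(counts)
  CellExpressionDataset(
    counts,
    data.frame(cell_id = rownames(counts), cell_type = cell_types,
               stringsAsFactors = FALSE),
    normalized = normalized
  )
}

# a modest planted-program dataset, normalized and ready to score
planted_dataset <- function(seed = 11, n_genes = 400, fold = 4,
                            program_genes = paste0("g", 1:12),
                            sizes = c(A = 100, B = 100, C = 100)) {
  cfg <- synthetic_config(
    n_genes = n_genes, cell_type_sizes = sizes,
    program_genes = program_genes, program_types = "A",
    program_fold = fold, seed = seed
  )
  res <- generate_dataset(cfg)
  res$dataset <- normalize_log1p(qc_filter(res$dataset, 1, 1))
  res
}

score_pipeline <- function(ds, seed_genes, K = 100, match_length = FALSE,
                           lengths = NULL, seed = 5, n_expr_bins = 10,
                           n_len_bins = 4) {
  ccfg <- control_config(n_control_sets = K, n_expr_bins = n_expr_bins,
                         n_len_bins = n_len_bins, match_length = match_length,
                         seed = seed)
  bins <- bin_genes(Matrix::colMeans(ds$normalized), lengths, ccfg)
  controls <- sample_control_sets(seed_genes, bins, ccfg)
  score_cells(ds, seed_genes, controls)
}

# independent brute-force oracles -------------------------------------------

# tie-corrected Kruskal-Wallis from the rank formula
kw_brute <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / C
  list(statistic = H, p = stats::pchisq(H, length(unique(g)) - 1, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up by direct enumeration
bh_brute <- function(p) {
  G <- length(p)
  ord <- order(p)
  adj <- p[ord] * G / seq_len(G)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

pearson_brute <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * stats::sd(x) * stats::sd(y))
}
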