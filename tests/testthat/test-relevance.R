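test_that("quantile binning gives equal occupancy and sane joint bins", {
  x <- stats::setNames(seq_len(100) / 10, paste0("g", 1:100))

  one <- bin_genes(x, cfg = control_config(n_expr_bins = 1, min_bin_occupancy = 1))
  expect_equal(length(unique(one)), 1)

  four <- bin_genes(x, cfg = control_config(n_expr_bins = 4, min_bin_occupancy = 1))
  expect_equal(unname(sort(table(four), decreasing = TRUE)), rep(25L, 4),
               ignore_attr = TRUE)
  # bins respect the ordering of the underlying values
  expect_equal(length(unique(four[paste0("g", 1:25)])), 1)

  lens <- stats::setNames(withr::with_seed(1, stats::runif(100, 100, 5000)),
                          names(x))
  joint <- bin_genes(x, lens,
                     control_config(n_expr_bins = 4, n_len_bins = 2,
                                    match_length = TRUE, min_bin_occupancy = 5))
  occ <- table(joint)
  expect_true(all(occ >= 5))
  expect_gte(length(occ), 4)

  expect_error(bin_genes(x, lengths = NULL,
                         control_config(match_length = TRUE)),
               class = "screlev_contract_error")
  expect_error(bin_genes(x, lens[1:50],
                         control_config(match_length = TRUE)),
               "missing lengths")
})

test_that("control sets are bin-matched, seed-free, and reproducible", {
  x <- stats::setNames(seq_len(200), paste0("g", 1:200))
  cfg <- control_config(n_control_sets = 50, n_expr_bins = 5,
                        min_bin_occupancy = 5, seed = 77)
  bins <- bin_genes(x, cfg = cfg)
  seeds <- c("g3", "g50", "g120", "g199")
  ctr <- sample_control_sets(seeds, bins, cfg)

  expect_equal(dim(ctr$sets), c(4, 50))
  # every control shares its seed gene's bin
  for (i in 1:4)
    expect_true(all(bins[ctr$sets[i, ]] == bins[seeds[i]]))
  # seed genes never appear in any control set
  expect_equal(length(intersect(as.vector(ctr$sets), seeds)), 0)
  # same seed, same collection
  ctr2 <- sample_control_sets(seeds, bins, cfg)
  expect_identical(ctr$sets, ctr2$sets)
  # within a set, same-bin draws are distinct while the pool allows
  two_in_bin <- c("g1", "g2")
  ctr3 <- sample_control_sets(two_in_bin, bins, cfg)
  same_bin_rows <- ctr3$sets[, 1]
  expect_false(same_bin_rows[1] == same_bin_rows[2])
})

test_that("scoring a set against itself is the degenerate identity", {
  res <- planted_dataset(seed = 5, n_genes = 50, sizes = c(A = 20, B = 20))
  ds <- res$dataset
  genes <- gene_ids(ds)
  controls <- structure(list(
    sets = matrix(rep(genes, 4), ncol = 4), seed_genes = genes,
    seed_bins = stats::setNames(rep("e1", length(genes)), genes),
    with_replacement_bins = character(), seed = 1L
  ), class = "ControlSetCollection")
  sc <- score_cells(ds, genes, controls)
  expect_equal(sc$scores$norm_score, rep(0, nrow(ds$counts)))
  expect_equal(sc$scores$mc_p, rep(1, nrow(ds$counts)))
  expect_true(all(sc$scores$sd_zero))
})

test_that("Monte-Carlo p-values have the (r+1)/(K+1) granularity", {
  res <- planted_dataset(seed = 6, n_genes = 300, fold = 8)
  sc <- score_pipeline(res$dataset, res$truth$program_genes, K = 100, seed = 2)
  expect_true(all(abs(sc$scores$mc_p * 101 - round(sc$scores$mc_p * 101)) < 1e-9))
  expect_gte(min(sc$scores$mc_p), 1 / 101)
  # strongly scoring program-type cells reach the floor
  expect_equal(min(sc$scores$mc_p), 1 / 101)
})

test_that("the planted type outscores the rest and tops the association table", {
  res <- planted_dataset(seed = 19, n_genes = 400, fold = 4)
  sc <- score_pipeline(res$dataset, res$truth$program_genes, K = 200, seed = 3)
  ct <- cell_types_of(res$dataset)
  tt <- stats::t.test(sc$scores$norm_score[ct == "A"],
                      sc$scores$norm_score[ct != "A"], alternative = "greater")
  expect_lt(tt$p.value, 1e-6)

  assoc <- celltype_association(sc, ct)
  expect_equal(assoc$cell_type[which.min(assoc$empirical_p)], "A")
  expect_equal(min(assoc$empirical_p), 1 / 201)
  expect_equal(assoc$z, (assoc$observed_statistic - assoc$null_mean) / assoc$null_sd)
  # p-granularity at the type level too
  expect_true(all(abs(assoc$empirical_p * 201 - round(assoc$empirical_p * 201)) < 1e-9))
})

test_that("association and heterogeneity agree with direct counting on toys", {
  ez <- empirical_p_and_z(2.5, c(1, 2, 3, 4))
  expect_equal(ez$p, (1 + 2) / 5)
  expect_equal(ez$z, (2.5 - 2.5) / stats::sd(1:4))

  expect_equal(empirical_p_and_z(5, c(1, 2, 3, 4))$p, 1 / 5)
  # observed below every null is maximally non-significant
  expect_equal(empirical_p_and_z(0, c(1, 2, 3, 4))$p, 1)
  deg <- empirical_p_and_z(0, c(0, 0, 0, 0))
  expect_equal(deg$p, 1)
  expect_false(deg$z_defined)
  one <- empirical_p_and_z(3, 1)
  expect_equal(one$p, 1 / 2)
  expect_false(one$z_defined)
})

test_that("heterogeneity flags mixed types, not homogeneous enrichment", {
  # type "Mix" is half strong-program cells, half null cells; type "Homo" is
  # uniformly enriched; "Null" is background
  n_genes <- 300
  prog <- paste0("g", 1:15)
  cfg <- synthetic_config(n_genes = n_genes,
                          cell_type_sizes = c(Homo = 120, Mix = 60, Null = 120),
                          program_genes = prog, program_types = "Homo",
                          program_fold = 4, seed = 23)
  res <- generate_dataset(cfg)
  cfg2 <- synthetic_config(n_genes = n_genes, cell_type_sizes = c(Mix = 60),
                           program_genes = prog, program_types = "Mix",
                           program_fold = 6, seed = 24)
  extra <- generate_dataset(cfg2)
  counts <- rbind(as.matrix(res$dataset$counts), as.matrix(extra$dataset$counts))
  rownames(counts) <- sprintf("cell%04d", seq_len(nrow(counts)))
  types <- c(cell_types_of(res$dataset), cell_types_of(extra$dataset))
  ds <- normalize_log1p(toy_dataset(counts, types, normalized = NULL))

  sc <- score_pipeline(ds, prog, K = 200, seed = 7)
  het <- celltype_heterogeneity(sc, types)
  expect_lt(het$heterogeneity_p[het$cell_type == "Mix"], 0.05)
  expect_gt(het$heterogeneity_p[het$cell_type == "Homo"],
            het$heterogeneity_p[het$cell_type == "Mix"])

  # constant scores within a type give variance 0 and p = 1
  v <- rep(1, 10)
  cs <- structure(list(
    scores = data.frame(cell_id = paste0("c", 1:10), raw_score = v,
                        norm_score = 0 * v, mc_p = 1, sd_zero = FALSE),
    control_norm = matrix(stats::rnorm(40), 10, 4), K = 4
  ), class = "CellScoreTable")
  het0 <- celltype_heterogeneity(cs, rep("T", 10), min_cells_per_type = 1)
  expect_equal(het0$heterogeneity_statistic, 0)
  expect_equal(het0$heterogeneity_p, 1)
})

test_that("relabeling cell types permutes association rows without changing values", {
  res <- planted_dataset(seed = 29, n_genes = 200)
  sc <- score_pipeline(res$dataset, res$truth$program_genes, K = 50, seed = 9)
  ct <- cell_types_of(res$dataset)
  a <- celltype_association(sc, ct)
  relab <- c(A = "Z_type", B = "M_type", C = "A_type")
  b <- celltype_association(sc, unname(relab[ct]))
  b_reord <- b[match(unname(relab[a$cell_type]), b$cell_type), ]
  expect_equal(b_reord$observed_statistic, a$observed_statistic)
  expect_equal(b_reord$empirical_p, a$empirical_p)
  expect_equal(b_reord$z, a$z)
})

test_that("dual expression+length matching neutralizes a length confounder", {
  # long-gene, non-programmatic "disease" set on a length-confounded null:
  # dual matching should not inflate |z| relative to expression-only matching
  zs <- sapply(1:6, function(rep) {
    cfg <- synthetic_config(n_genes = 800, cell_type_sizes = c(A = 80, B = 80),
                            length_model = "expression_correlated", rho = 0.8,
                            seed = 100 + rep)
    res <- generate_dataset(cfg)
    ds <- normalize_log1p(qc_filter(res$dataset, 1, 1))
    lens <- res$truth$lengths[gene_ids(ds)]
    long_genes <- names(sort(lens, decreasing = TRUE))[1:30]
    ct <- cell_types_of(ds)
    z_of <- function(match_length) {
      sc <- score_pipeline(ds, long_genes, K = 100, match_length = match_length,
                           lengths = lens, seed = 300 + rep, n_expr_bins = 10,
                           n_len_bins = 4)
      mean(abs(celltype_association(sc, ct)$z))
    }
    c(expr_only = z_of(FALSE), dual = z_of(TRUE))
  })
  expect_lte(mean(zs["dual", ]), mean(zs["expr_only", ]) + 0.05)
})
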