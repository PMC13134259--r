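#' Construct a single-cell expression dataset
#'
#' The container used throughout the package: a cells x genes count matrix,
#' an optional log-normalized layer of identical shape, and per-cell
#' annotations. All downstream operations address cells and genes by ID,
#' never by position.
#'
#' @param counts cells x genes matrix of non-negative integer counts
#'   (base matrix or a [Matrix::Matrix]); row names are cell IDs, column
#'   names are gene IDs, both mandatory and unique.
#' @param cell_meta data.frame with one row per cell: column `cell_id`
#'   matching the count-matrix row names, a mandatory `cell_type` column,
#'   and optional `stage` and `organ` columns.
#' @param dataset_label short label recorded in outputs.
#' @param normalized optional normalized layer with the same dimnames as
#'   `counts`; usually left `NULL` and filled by [normalize_log1p()].
#'
#' @return An object of class `CellExpressionDataset`: a list with elements
#'   `counts`, `normalized`, `cell_meta`, `dataset_label`.
#' @export
CellExpressionDataset <- function(counts, cell_meta, dataset_label = "dataset",
                                  normalized = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_validation("counts must carry cell IDs as rownames and gene IDs as colnames")
  if (anyDuplicated(rownames(counts)))
    abort_validation("duplicate cell IDs in counts")
  if (anyDuplicated(colnames(counts)))
    abort_validation("duplicate gene IDs in counts")
  if (any(counts@x < 0))
    abort_validation("counts must be non-negative")
  if (!is.data.frame(cell_meta) || !all(c("cell_id", "cell_type") %in% names(cell_meta)))
    abort_schema("cell_meta must be a data.frame with columns cell_id and cell_type")
  cell_meta <- cell_meta[match(rownames(counts), cell_meta$cell_id), , drop = FALSE]
  if (anyNA(cell_meta$cell_id))
    abort_validation("every cell in counts needs a cell_meta row")
  if (anyNA(cell_meta$cell_type))
    abort_validation("every cell needs a cell_type annotation")
  rownames(cell_meta) <- NULL
  if (!is.null(normalized)) {
    normalized <- methods::as(methods::as(methods::as(Matrix::Matrix(normalized, sparse = TRUE),
      "dMatrix"), "generalMatrix"), "CsparseMatrix")
    if (!identical(dimnames(normalized), dimnames(counts)))
      abort_validation("normalized layer must share dimnames with counts")
  }
  structure(
    list(counts = counts, normalized = normalized, cell_meta = cell_meta,
         dataset_label = dataset_label),
    class = "CellExpressionDataset"
  )
}

#' @export
print.CellExpressionDataset <- function(x, ...) {
  cat(sprintf(
    "CellExpressionDataset '%s': %d cells x %d genes; %d cell types; normalized layer: %s\n",
    x$dataset_label, nrow(x$counts), ncol(x$counts),
    length(unique(x$cell_meta$cell_type)),
    if (is.null(x$normalized)) "absent" else "present"
  ))
  invisible(x)
}

#' @export
dim.CellExpressionDataset <- function(x) dim(x$counts)

#' Dataset accessors
#'
#' @param ds a [CellExpressionDataset()].
#' @return `cell_ids`/`gene_ids` return the ID character vectors;
#'   `cell_types_of` the per-cell type labels, aligned with `cell_ids`.
#' @export
cell_ids <- function(ds) rownames(ds$counts)

#' @rdname cell_ids
#' @export
gene_ids <- function(ds) colnames(ds$counts)

#' @rdname cell_ids
#' @export
cell_types_of <- function(ds) as.character(ds$cell_meta$cell_type)

#' Read a Matrix Market expression bundle
#'
#' Reads the conventional sparse triplet bundle: `matrix.mtx` with genes in
#' rows and cells in columns, a genes TSV (first column gene ID, optional
#' second column symbol, no header), a barcodes TSV (one barcode per line,
#' no header), and a cell-metadata TSV keyed by barcode with a mandatory
#' `cell_type` column. Cells present in the matrix but absent from the
#' metadata are dropped with a message.
#'
#' @param matrix_path path to the MTX file.
#' @param genes_path path to the genes TSV.
#' @param barcodes_path path to the barcodes file.
#' @param cell_meta_path path to the cell-metadata TSV. Its key column may be
#'   named `cell_id` or `barcode`.
#' @param dataset_label label stored on the dataset.
#' @return A [CellExpressionDataset()] with counts populated and no
#'   normalized layer.
#' @export
read_mtx_dataset <- function(matrix_path, genes_path, barcodes_path,
                             cell_meta_path, dataset_label = "dataset") {
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) abort_format(paste0("invalid MTX file: ", conditionMessage(e))))
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "")
  barcodes <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE, quote = "")[[1]]
  if (nrow(genes) != nrow(m))
    abort_format(sprintf("genes file has %d rows but matrix has %d gene rows",
                         nrow(genes), nrow(m)))
  if (length(barcodes) != ncol(m))
    abort_format(sprintf("barcodes file has %d rows but matrix has %d cell columns",
                         length(barcodes), ncol(m)))
  meta <- utils::read.delim(cell_meta_path, stringsAsFactors = FALSE)
  key <- intersect(c("cell_id", "barcode"), names(meta))
  if (!length(key))
    abort_schema("cell metadata needs a cell_id or barcode column")
  names(meta)[names(meta) == key[1]] <- "cell_id"
  if (!"cell_type" %in% names(meta))
    abort_schema("cell metadata is missing the required cell_type column")

  counts <- Matrix::t(m)
  dimnames(counts) <- list(barcodes, genes[[1]])
  keep <- barcodes %in% meta$cell_id
  if (!all(keep)) {
    message(sprintf("dropping %d cells without metadata rows", sum(!keep)))
    counts <- counts[keep, , drop = FALSE]
  }
  CellExpressionDataset(counts, meta[meta$cell_id %in% rownames(counts), , drop = FALSE],
                        dataset_label = dataset_label)
}

#' Write a dataset as a Matrix Market bundle
#'
#' Inverse of [read_mtx_dataset()]: writes `matrix.mtx` (genes x cells),
#' `genes.tsv`, `barcodes.tsv` and `cell_meta.tsv` into `dir`.
#'
#' @param ds a [CellExpressionDataset()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_mtx_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(ds$counts), file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene_id = gene_ids(ds)),
                     file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(cell_ids(ds), file.path(dir, "barcodes.tsv"))
  utils::write.table(ds$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a disease gene set
#'
#' Expects a TSV with a header; a column whose name contains "symbol" or
#' "hgnc" and/or a column containing "ensembl" must be present. Optional
#' `evidence` and `inheritance` columns are carried along. Rows are
#' deduplicated on Ensembl ID where available, otherwise on symbol;
#' duplicates raise a warning.
#'
#' @param path path to the TSV.
#' @param name name recorded on the set; defaults to the file name.
#' @return A `GeneSet`: list with `entries` (data.frame with columns
#'   `symbol`, `ensembl_id`, `evidence`, `inheritance`) and `name`.
#' @export
read_gene_set <- function(path, name = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) abort_schema("gene-set file has no data rows")
  lc <- tolower(names(tab))
  sym_col <- which(grepl("symbol|hgnc", lc))[1]
  ens_col <- which(grepl("ensembl", lc))[1]
  if (is.na(sym_col) && is.na(ens_col))
    abort_schema("gene-set file needs a symbol/HGNC and/or an Ensembl column")
  pick <- function(col, pattern) {
    hit <- which(grepl(pattern, lc))[1]
    if (is.na(hit)) rep(NA_character_, nrow(tab)) else as.character(tab[[hit]])
  }
  entries <- data.frame(
    symbol      = if (is.na(sym_col)) NA_character_ else as.character(tab[[sym_col]]),
    ensembl_id  = if (is.na(ens_col)) NA_character_ else as.character(tab[[ens_col]]),
    evidence    = pick(NA, "evidence"),
    inheritance = pick(NA, "inheritance"),
    stringsAsFactors = FALSE
  )
  entries$ensembl_id[!is.na(entries$ensembl_id) & entries$ensembl_id == ""] <- NA_character_
  key <- ifelse(is.na(entries$ensembl_id), paste0("sym:", entries$symbol),
                paste0("ens:", entries$ensembl_id))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("%d duplicate gene-set rows removed", sum(dup)))
    entries <- entries[!dup, , drop = FALSE]
  }
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 name = if (is.null(name)) basename(path) else name),
            class = "GeneSet")
}

#' @export
length.GeneSet <- function(x) nrow(x$entries)

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x)))
  invisible(x)
}

#' Map a gene set onto a dataset's gene universe
#'
#' Resolves each entry to a dataset gene ID, trying the Ensembl ID first and
#' falling back to the HGNC symbol. Unmapped members are reported via a
#' warning and returned, not fatal: downstream analysis proceeds on the
#' mapped subset.
#'
#' @param gene_set a `GeneSet` from [read_gene_set()].
#' @param universe character vector of dataset gene IDs.
#' @return list with `mapped` (character vector of dataset gene IDs, in set
#'   order) and `unmapped` (data.frame of unresolved entries).
#' @export
match_gene_set <- function(gene_set, universe) {
  e <- gene_set$entries
  id <- ifelse(!is.na(e$ensembl_id) & e$ensembl_id %in% universe, e$ensembl_id,
        ifelse(!is.na(e$symbol) & e$symbol %in% universe, e$symbol, NA_character_))
  unmapped <- e[is.na(id), , drop = FALSE]
  if (nrow(unmapped) > 0)
    warning(sprintf("%d of %d gene-set members not found in the dataset",
                    nrow(unmapped), nrow(e)))
  list(mapped = unique(id[!is.na(id)]), unmapped = unmapped)
}

#' Read a gene-length table
#'
#' @param path TSV with header columns `gene_id` and `length_bp` (any column
#'   whose name contains "length" is accepted for the latter).
#' @return named numeric vector of lengths in bp.
#' @export
read_gene_lengths <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab))
    abort_schema("gene-length table needs a gene_id column")
  len_col <- which(grepl("length", tolower(names(tab))))[1]
  if (is.na(len_col)) abort_schema("gene-length table needs a length column")
  lens <- as.numeric(tab[[len_col]])
  if (any(!is.finite(lens) | lens <= 0))
    abort_validation("gene lengths must be strictly positive")
  stats::setNames(lens, tab$gene_id)
}

#' Union-exon gene lengths from a GFF/GTF file
#'
#' Computes, per gene, the total non-redundant exonic length (exons reduced
#' to disjoint intervals before summing widths). Union-exon length tracks
#' transcript detectability better than genomic span, which is why it is
#' the default length covariate for the matched null.
#'
#' @param path GFF3/GTF file readable by `rtracklayer::import`.
#' @return named numeric vector of union-exon lengths (bp) keyed by gene ID.
#' @export
gene_lengths_from_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
      !requireNamespace("GenomicRanges", quietly = TRUE))
    abort_validation("gene_lengths_from_gff requires rtracklayer and GenomicRanges")
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!length(gr)) abort_format("no exon features found in annotation")
  gid <- gr$gene_id
  if (is.null(gid)) abort_schema("exon features carry no gene_id attribute")
  by_gene <- GenomicRanges::reduce(GenomicRanges::split(gr, as.character(gid)))
  vapply(by_gene, function(g) sum(GenomicRanges::width(g)), numeric(1))
}

#' Quality-control filtering
#'
#' Removes low-quality cells (too few detected genes), then rarely detected
#' genes (detected in too few cells), iterating until the dataset is stable
#' so that re-applying the same thresholds is a no-op. Defaults follow
#' common single-cell practice; both thresholds are recorded on the result.
#'
#' @param ds a [CellExpressionDataset()].
#' @param min_genes_per_cell minimum number of genes with count > 0 a cell
#'   must have (default 200).
#' @param min_cells_per_gene minimum number of cells a gene must be detected
#'   in (default 3).
#' @return the filtered dataset; attribute `qc_report` records removals and
#'   thresholds.
#' @export
qc_filter <- function(ds, min_genes_per_cell = 200, min_cells_per_gene = 3) {
  if (min_genes_per_cell < 0 || min_cells_per_gene < 0)
    abort_validation("QC thresholds must be >= 0")
  counts <- ds$counts
  removed_cells <- 0L; removed_genes <- 0L
  repeat {
    det <- counts > 0
    keep_cells <- Matrix::rowSums(det) >= min_genes_per_cell
    if (!any(keep_cells))
      abort_degenerate("QC removed every cell; lower min_genes_per_cell")
    counts <- counts[keep_cells, , drop = FALSE]
    keep_genes <- Matrix::colSums(counts > 0) >= min_cells_per_gene
    counts <- counts[, keep_genes, drop = FALSE]
    removed_cells <- removed_cells + sum(!keep_cells)
    removed_genes <- removed_genes + sum(!keep_genes)
    if (all(keep_cells) && all(keep_genes)) break
  }
  if (ncol(counts) == 0)
    abort_degenerate("QC removed every gene; lower min_cells_per_gene")
  out <- CellExpressionDataset(
    counts,
    ds$cell_meta[ds$cell_meta$cell_id %in% rownames(counts), , drop = FALSE],
    dataset_label = ds$dataset_label
  )
  attr(out, "qc_report") <- list(
    cells_removed = removed_cells, genes_removed = removed_genes,
    min_genes_per_cell = min_genes_per_cell,
    min_cells_per_gene = min_cells_per_gene
  )
  out
}

#' Library-size normalization and log transform
#'
#' Scales each cell's counts to a common total (default 10,000) and applies
#' `log1p` with the natural logarithm:
#' `normalized[i, g] = log(1 + counts[i, g] * target_sum / total_i)`.
#' The counts layer is left untouched.
#'
#' @param ds a [CellExpressionDataset()] whose cells all have total
#'   count > 0 (run [qc_filter()] first otherwise).
#' @param target_sum per-cell total after scaling (default 1e4).
#' @return the dataset with the `normalized` layer populated.
#' @export
normalize_log1p <- function(ds, target_sum = 1e4) {
  totals <- Matrix::rowSums(ds$counts)
  if (any(totals == 0))
    abort_degenerate("cells with zero total count present; run qc_filter first")
  scaled <- Matrix::Diagonal(x = target_sum / totals) %*% ds$counts
  norm <- scaled
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(ds$counts)
  out <- ds
  out$normalized <- methods::as(norm, "CsparseMatrix")
  out
}

require_normalized <- function(ds) {
  if (is.null(ds$normalized))
    abort_contract("normalized layer missing; call normalize_log1p first")
  invisible(ds)
}
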