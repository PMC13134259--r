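#' Path to the bundled CAKUT gene-set fixture
#'
#' A curated set of 91 genes implicated in congenital anomalies of the
#' kidney and urinary tract (CAKUT), assembled from the published CAKUT
#' genetics literature (monogenic disease genes and strongly supported
#' candidates). The file is a reconstruction built for this package --
#' hence the `_synthetic` suffix -- not an authoritative clinical resource;
#' Ensembl IDs are filled in only where unambiguous. It exists so the
#' readers, the mapping logic, and the worked examples have a realistic
#' disease gene set to operate on.
#'
#' @return path to the TSV, readable with [read_gene_set()].
#' @export
cakut_gene_set_path <- function() {
  system.file("extdata", "cakut_gene_set_synthetic.tsv", package = "screlev",
              mustWork = TRUE)
}
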