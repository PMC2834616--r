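#' Load the bundled study fixtures
#'
#' Returns the three reference tables shipped with the package: the 29
#' schizophrenia-associated miRNA precursors with location and conservation
#' class, the 32 published TF-miRNA-gene feed-forward loops (with merged
#' matrix labels, consensus strings and TF symbols), and the FFL counts per
#' miRNA set (schizophrenia / brain-expressed / non-brain) across the four
#' candidate-gene lists, plus the matrix-to-TF sidecar catalog.
#'
#' @return A list with elements `mirnas` (tibble, 29 precursors),
#'   `ffl_table` (tibble, 32 loops), `counts_table` (tibble, 12 rows of
#'   set-by-gene-list FFL counts) and `matrix_tf` (tibble, matrix to symbol).
#' @export
#' @examples
#' fx <- load_reference_fixtures()
#' nrow(fx$ffl_table)
load_reference_fixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "fflnet")
  mirnas <- read_mirna_annotation(ext("sz_mirna_annotation.gff3"))
  ffl_table <- readr::read_tsv(
    ext("sz_ffl_table.tsv"),
    col_types = readr::cols(no = "i", .default = "c"), progress = FALSE
  )
  counts_table <- readr::read_tsv(
    ext("ffl_count_table.tsv"),
    col_types = readr::cols(n_mirnas = "i", ffls = "i", .default = "c"),
    progress = FALSE
  )
  matrix_tf <- read_matrix_map(ext("matrix_tf_map.tsv"))
  list(mirnas = mirnas, ffl_table = as_tibble(ffl_table),
       counts_table = as_tibble(counts_table), matrix_tf = matrix_tf)
}
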