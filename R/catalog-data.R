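#' Published catalog of conserved ascidian miRNA precursor loci
#'
#' A transcription of the printed survey table of conserved miRNA
#' precursors identified in the Halocynthia roretzi draft genome: locus
#' string (1-based inclusive, minus-strand loci printed high-to-low),
#' miRNA family, reported mature sequence(s), precursor length (nt) and
#' reported MFE (kcal/mol, as computed by the original thermodynamic
#' folder on the real genome).  Bundled as a fixture for coordinate and
#' threshold arithmetic; the sequences of the precursors themselves are
#' not part of the table.
#'
#' @return data frame with columns `locus`, `family`, `matures`
#'   (comma-separated where both arms were reported), `length_nt`,
#'   `mfe_kcal`.
#' @examples
#' tab <- conserved_mirna_table()
#' all(interval_length(parse_locus(tab$locus)) == tab$length_nt)
#' @export
conserved_mirna_table <- function() {
  path <- system.file("extdata", "conserved_mirnas_printed.tsv",
                      package = "mirforge", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
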