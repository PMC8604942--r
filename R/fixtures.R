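#' Catalogue of known spacer-inversion events in yeast coding genes
#'
#' Returns the curated set of ten template-switch events observed in
#' *Saccharomyces cerevisiae* coding genes, shipped with the package: for
#' each gene the parental and derived sequences over the IR footprint
#' (spacers in lowercase in the source file, upper-cased on load), the IR
#' arm and spacer lengths, the strains carrying the derived form, the
#' reading-frame offset of the footprint within the CDS, and the
#' amino-acid changes caused by the inversion (parental to derived,
#' including synonymous ones). Nine events are pure spacer inversions on
#' previously perfect arms; the *REG2* event combines arm homogenization
#' with a spacer inversion.
#'
#' @param raw Keep the original lowercase-spacer formatting (default
#'   `FALSE`).
#' @return Data.frame with columns `gene`, `arm_len`, `spacer_len`,
#'   `strains`, `kind`, `frame_offset`, `aa_changes`, `parental_seq`,
#'   `derived_seq`.
#' @export
yeast_inversion_catalogue <- function(raw = FALSE) {
  path <- system.file("extdata", "yeast_spacer_inversions.tsv",
                      package = "irswitch")
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!raw) {
    df$parental_seq <- toupper(df$parental_seq)
    df$derived_seq <- toupper(df$derived_seq)
  }
  df
}
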