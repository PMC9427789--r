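#' Synthetic Burosumab-like Fv sequence
#'
#' A Chothia-numbered heavy/light variable-domain sequence shipped with the
#' package (`inst/extdata/synthetic_burosumab_like_fv.csv`). It is a
#' synthetic reconstruction on a generic human germline-like scaffold,
#' constrained to carry every residue identity reported for the antibody at
#' the positions that matter to the analyses here (heavy chain Y33, H35,
#' I50, T58, S59, R94, D95, V97, D98, D101; light chain A32, Y49, D50, S52,
#' S67, T69, F96); it is not the deposited antibody sequence. In particular
#' Chothia H3 (95-102) carries three aspartates and no basic residue, so its
#' net formal charge is a property of the sequence, not an input.
#'
#' @return list with `table` (data.frame `chain`, `resno`, `icode`, `aa`),
#'   `sequence` (named vector residue key -> letter) and `annotation`
#'   (an [annotate_fv()] result for chains `"H"`/`"L"`).
#' @export
synthetic_fv_sequence <- function() {
  path <- system.file("extdata", "synthetic_burosumab_like_fv.csv",
                      package = "abscan", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$icode <- ifelse(is.na(tab$icode), "", tab$icode)
  key <- residue_key(tab$chain, tab$resno, tab$icode)
  ann <- annotate_fv(data.frame(chain = tab$chain, resno = tab$resno,
                                icode = tab$icode, stringsAsFactors = FALSE),
                     heavy = "H", light = "L")
  list(table = tab, sequence = stats::setNames(tab$aa, key), annotation = ann)
}
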