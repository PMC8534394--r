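#' Bundled PTM peptide annotations
#'
#' The fifteen PTM-annotated peptides identified by mass spectrometry in
#' a kidney-cancer plasma proteome survey, in the hyphen-token notation
#' understood by [parse_ptm_peptide()], together with their gene labels.
#' The eight peptides that also have a structural (solvent-accessibility)
#' survey row carry the expected position label in `loc`.
#'
#' @return data.frame with columns gene, annotated, loc (NA where no
#'   survey row exists)
#' @export
ptm_peptide_set <- function() {
  data.frame(
    gene = c("TCOF", "AKAP9", "ITAX", "ABCA1", "JKIP1", "ACAP1", "ASPM",
             "DYH7", "SCLT1", "TENA", "APOB", "RPB1B", "APOA1", "CERU",
             "ORC3"),
    annotated = c(
      "SPAGPAATPAQAQAAS-P(T)-PRK",
      "QE-AC(K)-EQVSLR",
      "ILIVI-P(T)-DGK",
      "LEPIA-P(T)-EVWLINK",
      "LSAQA-P(S)-LKR",
      "Y-AC(K)-DPVTVVVDDLR",
      "LYLAVKNAN-AC(K)",
      "IEDFWGPA-AC(K)-R",
      "LILEHQE-AC(K)",
      "IK-P(Y)-APISGGDHAEVDVPK",
      "P(Y)-HWEHTGLTLR",
      "VPHPLEH-AC(K)-IIIR",
      "AC(K)-WQEEMELYR",
      "VTFHN-AC(K)-GAYPLSIEPIGVR",
      "LLLT-P(T)-QFPFKINEK"),
    loc = c(NA, NA, "T6", "T6", NA, "K2", NA, "K9", NA, NA, NA, "K8",
            "K1", "K6", "T5"),
    stringsAsFactors = FALSE
  )
}
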