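#' Reported specificity constants for characterized aminotransferases
#'
#' The kcat/Km specificity constants (M^-1 s^-1) for the aspartate and
#' aromatic (phenylalanine) reactions of the characterized subfamily Ia
#' aminotransferases, as reported to 2 significant figures, together
#' with the reported specificity ratio and whether the enzyme was part
#' of the previously characterized panel or newly characterized.
#'
#' @return data.frame with columns `enzyme`, `kcat_km_asp`,
#'   `kcat_km_aromatic`, `reported_ratio`, `cohort`.
#' @export
published_kinetic_constants <- function() {
  path <- system.file("extdata", "aminotransferase_kinetic_constants.csv",
                      package = "specswap", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Classify enzymes from their specificity constants
#'
#' Applies [specificity_call()] row-wise to a constants table such as
#' [published_kinetic_constants()]: the ratio of the aspartate to the
#' aromatic specificity constant, rounded to 2 significant figures, with
#' the AATase (>1) / TATase (<1) label.
#'
#' @param constants data.frame with columns `enzyme`, `kcat_km_asp`,
#'   `kcat_km_aromatic`.
#' @return the input with added `ratio`, `rounded_ratio`, `label`
#'   columns.
#' @export
classify_specificity_table <- function(constants = published_kinetic_constants()) {
  calls <- Map(specificity_call, constants$kcat_km_asp,
               constants$kcat_km_aromatic)
  constants$ratio <- vapply(calls, `[[`, numeric(1), "ratio")
  constants$rounded_ratio <- vapply(calls, `[[`, numeric(1), "rounded_ratio")
  constants$label <- vapply(calls, `[[`, character(1), "label")
  constants
}
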