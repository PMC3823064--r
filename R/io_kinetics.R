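KINETIC_COLUMNS <- c("enzyme", "substrate", "conc_aa_mM", "conc_cosub_mM",
                     "conc_e", "rate")

#' Construct a kinetic dataset
#'
#' Initial-rate measurements for enzyme/substrate pairs. Concentrations of
#' the varied amino acid and the co-substrate (2-oxoglutarate) are in mM;
#' `conc_e` is the enzyme concentration in units consistent across rows
#' (typically M); `rate` is the observed initial rate in
#' s^-1 x the units of `conc_e`.
#'
#' @param rows data.frame with columns
#'   `enzyme, substrate, conc_aa_mM, conc_cosub_mM, conc_e, rate`.
#' @return an object of class `kinetic_dataset` (a validated data.frame).
#' @export
new_kinetic_dataset <- function(rows) {
  missing <- setdiff(KINETIC_COLUMNS, names(rows))
  if (length(missing) > 0L) {
    abort_input("kinetic table lacks column(s): %s",
                paste(missing, collapse = ", "))
  }
  rows <- rows[, KINETIC_COLUMNS]
  for (col in c("conc_aa_mM", "conc_cosub_mM", "conc_e", "rate")) {
    rows[[col]] <- as.numeric(rows[[col]])
  }
  if (any(rows$conc_aa_mM < 0 | rows$conc_cosub_mM < 0 | rows$conc_e < 0,
          na.rm = TRUE)) {
    abort_input("negative concentration in kinetic table")
  }
  if (any(!is.finite(rows$rate))) abort_input("non-finite rate in kinetic table")
  structure(rows, class = c("kinetic_dataset", "data.frame"))
}

#' Read a kinetic rate table
#'
#' Comma- or tab-delimited text with a header row naming the columns
#' `enzyme,substrate,conc_aa_mM,conc_cosub_mM,conc_e,rate`. Rows whose
#' numeric fields do not parse (e.g. `NA` rates) are dropped with a warning
#' rather than aborting; structurally bad input (missing columns, negative
#' concentrations) is an error.
#'
#' @param path path to the delimited file.
#' @return a [new_kinetic_dataset()].
#' @export
read_kinetic_table <- function(path) {
  if (!file.exists(path)) abort_input("kinetic table not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, fill = TRUE)
  missing <- setdiff(KINETIC_COLUMNS, names(tab))
  if (length(missing) > 0L) {
    abort_input("kinetic table %s lacks column(s): %s", path,
                paste(missing, collapse = ", "))
  }
  num <- tab[, c("conc_aa_mM", "conc_cosub_mM", "conc_e", "rate")]
  num[] <- lapply(num, function(x) suppressWarnings(as.numeric(x)))
  bad <- !stats::complete.cases(num) | !is.finite(num$rate)
  if (any(bad)) {
    warning(sprintf("dropping %d unparseable row(s) from %s (rows: %s)",
                    sum(bad), path,
                    paste(utils::head(which(bad), 10), collapse = ", ")),
            call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
  }
  if (nrow(tab) == 0L) abort_input("no usable rows in kinetic table %s", path)
  new_kinetic_dataset(tab)
}

#' Write a kinetic dataset as CSV
#' @param data a `kinetic_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kinetic_table <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
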