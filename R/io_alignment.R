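#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
NULL

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
MSA_ALPHABET <- c(AA_ALPHABET20, "-")

#' Construct a protein multiple sequence alignment object
#'
#' An `msa` stores named, gapped, equal-length protein sequences over the
#' 20 standard amino acids plus the gap character `-`. Columns are 1-based.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param sequences character vector of aligned sequences (same order as
#'   `ids`), all of equal length.
#' @return An object of class `msa` with elements `ids`, `sequences`
#'   (named character vector), `mat` (sequence-by-column character matrix)
#'   and `n_col`.
#' @export
new_msa <- function(ids, sequences) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences)) {
    abort_input("ids (%d) and sequences (%d) differ in length",
                length(ids), length(sequences))
  }
  if (length(ids) == 0L) abort_input("alignment must contain >= 1 sequence")
  if (anyDuplicated(ids)) {
    abort_input("duplicate sequence ids: %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    abort_input("sequences are not aligned: lengths %s",
                paste(unique(lens), collapse = ", "))
  }
  if (lens[1] < 1L) abort_input("alignment must have >= 1 column")
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  rownames(mat) <- ids
  bad <- setdiff(unique(as.vector(mat)), MSA_ALPHABET)
  if (length(bad) > 0L) {
    abort_input("illegal characters in alignment: %s",
                paste(bad, collapse = ", "))
  }
  structure(
    list(ids = ids, sequences = stats::setNames(sequences, ids),
         mat = mat, n_col = unname(lens[1])),
    class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("Protein alignment: %d sequences x %d columns\n",
              length(x$ids), x$n_col))
  show <- utils::head(x$ids, 5)
  for (id in show) {
    s <- x$sequences[[id]]
    cat(sprintf("  %-20s %s%s\n", id, substr(s, 1, 50),
                if (nchar(s) > 50) "..." else ""))
  }
  if (length(x$ids) > 5) cat(sprintf("  ... and %d more\n", length(x$ids) - 5))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Only the aligned-FASTA dialect is supported: every record must have the
#' same length and use the 20 amino-acid letters plus `-`.
#'
#' @param path path to an aligned FASTA file.
#' @return an [new_msa()] object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) abort_input("alignment file not found: %s", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) abort_input(
                    "could not parse FASTA %s: %s", path, conditionMessage(e)))
  if (length(set) == 0L) abort_input("no sequences in %s", path)
  # FASTA headers may carry descriptions; the id is the first token
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  new_msa(ids, as.character(set))
}

#' Write an alignment to aligned FASTA
#'
#' @param msa an [new_msa()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  set <- Biostrings::AAStringSet(msa$sequences)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Subset an alignment by sequence id
#' @param msa an `msa` object.
#' @param ids ids to keep, in the given order.
#' @return an `msa` with the selected records.
#' @export
msa_subset <- function(msa, ids) {
  stopifnot(inherits(msa, "msa"))
  missing <- setdiff(ids, msa$ids)
  if (length(missing) > 0L) {
    abort_input("ids not in alignment: %s", paste(missing, collapse = ", "))
  }
  new_msa(ids, unname(msa$sequences[ids]))
}
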