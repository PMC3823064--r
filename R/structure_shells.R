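# Default shell radii (Angstrom). The first shell is residues with any
# heavy atom <= 3.40 A of a cofactor/ligand atom; outer shells follow the
# ~5 A-per-shell spacing of the eAAT active site (third shell within
# 16.3 A, fourth within 22 A). The second-shell boundary is not observed
# directly and is taken as the midpoint-interpolated 11.3 A.
DEFAULT_SHELL_RADII <- c(3.4, 11.3, 16.3, 22.0)

#' Minimum heavy-atom distance of every residue to a target group
#'
#' For each polymer residue, the minimum Euclidean distance between any of
#' its heavy atoms and any heavy atom of the selected hetero group(s)
#' (e.g. the PLP cofactor, or PLP plus a bound ligand). Hydrogens are
#' excluded on both sides.
#'
#' @param structure a [new_structure_model()] object.
#' @param target_resnames character vector of hetero residue names whose
#'   atoms form the target (their union when several are given).
#' @return a data.frame of class `distance_table` with columns
#'   `residue_number`, `residue_name`, `min_distance` (A), and attribute
#'   `target_description`.
#' @export
residue_min_distances <- function(structure, target_resnames) {
  stopifnot(inherits(structure, "structure_model"))
  if (length(target_resnames) == 0L) {
    abort_config("empty target selection")
  }
  a <- structure$atoms
  heavy <- a$element != "H"
  pol <- a[a$record_kind == "polymer" & heavy, , drop = FALSE]
  if (nrow(pol) == 0L) abort_input("structure has no polymer atoms")
  tgt <- a[a$record_kind == "hetero" & a$residue_name %in% target_resnames &
             heavy, , drop = FALSE]
  if (nrow(tgt) == 0L) {
    abort_config("no hetero atoms match target(s): %s",
                 paste(target_resnames, collapse = ", "))
  }
  px <- as.matrix(pol[, c("x", "y", "z")])
  tx <- as.matrix(tgt[, c("x", "y", "z")])
  # squared cross-distance matrix, residue-wise minimum
  cross <- outer(rowSums(px^2), rowSums(tx^2), "+") - 2 * px %*% t(tx)
  dmin_atom <- sqrt(pmax(apply(cross, 1, min), 0))
  key <- paste(pol$chain, pol$residue_number, sep = "|")
  split_min <- tapply(dmin_atom, key, min)
  first <- !duplicated(key)
  tab <- data.frame(
    residue_number = pol$residue_number[first],
    residue_name = pol$residue_name[first],
    chain = pol$chain[first],
    min_distance = as.numeric(split_min[key[first]]),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$chain, tab$residue_number), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "target_description") <- paste(target_resnames, collapse = "+")
  class(tab) <- c("distance_table", "data.frame")
  tab
}

#' Assign active-site shells from residue distances
#'
#' Shell `i` is the smallest index with `min_distance <= radii[i]`
#' (closed boundaries); residues beyond the last radius get `NA`.
#'
#' @param distances a `distance_table` from [residue_min_distances()].
#' @param radii strictly ascending vector of shell cutoffs in Angstrom.
#' @return the distance table with an added integer `shell` column;
#'   attribute `radii` records the cutoffs.
#' @export
assign_shells <- function(distances, radii = DEFAULT_SHELL_RADII) {
  stopifnot(inherits(distances, "distance_table"))
  if (length(radii) == 0L || any(diff(radii) <= 0)) {
    abort_config("shell radii must be nonempty and strictly ascending")
  }
  shell <- vapply(distances$min_distance, function(d) {
    i <- which(d <= radii)
    if (length(i) == 0L) NA_integer_ else i[1]
  }, integer(1))
  out <- distances
  out$shell <- shell
  attr(out, "radii") <- radii
  class(out) <- c("shell_assignment", class(distances))
  out
}

#' Residues within a distance cutoff
#'
#' Convenience filter used for both the first-shell set (cutoff 3.40 A,
#' closed) and the active-site selection (15 A, open).
#'
#' @param distances a `distance_table`.
#' @param cutoff distance cutoff in Angstrom.
#' @param closed if `TRUE` use `<=` (shell convention); if `FALSE` use `<`
#'   (the active-site "<15 A" selection).
#' @return integer vector of residue numbers.
#' @export
residues_within <- function(distances, cutoff, closed = TRUE) {
  stopifnot(inherits(distances, "distance_table"))
  keep <- if (closed) distances$min_distance <= cutoff
          else distances$min_distance < cutoff
  distances$residue_number[keep]
}
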