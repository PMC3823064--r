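# Distance-and-variability (D&V) selection of candidate enzymes:
# alignment columns near the cofactor and moderately variable define the
# scoring positions; candidates are scored against a characterized
# reference panel, compared pairwise, and grouped.

#' Map alignment columns to structure residue numbers via a reference
#'
#' The reference sequence's non-gap columns are put in bijection with the
#' polymer residues of the structure (in residue-number order). The
#' reference's ungapped length must equal the number of polymer residues
#' unless an explicit numbering `offset` is supplied.
#'
#' @param msa an [new_msa()] object.
#' @param ref_id id of the structure's sequence in the alignment.
#' @param distances optional `distance_table` whose residue count is
#'   checked against the reference's ungapped length.
#' @param offset added to the ungapped position to obtain the residue
#'   number; `NULL` (default) requires exact length agreement and uses
#'   offset 0.
#' @return data.frame of class `column_map` with columns `column`
#'   (1-based alignment column) and `residue_number`.
#' @export
map_columns_to_reference <- function(msa, ref_id, distances = NULL,
                                     offset = NULL) {
  stopifnot(inherits(msa, "msa"))
  if (!ref_id %in% msa$ids) abort_input("reference id '%s' not in alignment", ref_id)
  ref <- msa$mat[ref_id, ]
  cols <- which(ref != "-")
  if (!is.null(distances)) {
    n_res <- nrow(distances)
    if (is.null(offset) && length(cols) != n_res) {
      abort_input(
        "reference ungapped length (%d) != structure residue count (%d); supply offset",
        length(cols), n_res)
    }
  }
  off <- offset %||% 0L
  out <- data.frame(column = cols,
                    residue_number = seq_along(cols) + as.integer(off))
  class(out) <- c("column_map", "data.frame")
  out
}

#' Select positions meeting the distance-and-variability criteria
#'
#' A column qualifies when its mapped residue lies strictly within `d_max`
#' of the cofactor (minimum heavy-atom distance) and its modal residue
#' fraction is moderately variable: at least `f_low` but below `f_high`
#' of the aligned (non-gap) residues.
#'
#' @param profiles a [column_profiles()] result.
#' @param map a [map_columns_to_reference()] result.
#' @param distances a `distance_table` from [residue_min_distances()].
#' @param d_max distance cutoff in Angstrom (strict `<`, default 15).
#' @param f_low,f_high variability window on the modal fraction
#'   (`f_low <= f < f_high`, defaults 0.25 and 0.75).
#' @return data.frame of class `dv_positions` with columns `column`,
#'   `residue_number`, `distance`, `modal_fraction`, ordered by column.
#' @export
select_dv_positions <- function(profiles, map, distances,
                                d_max = 15, f_low = 0.25, f_high = 0.75) {
  stopifnot(inherits(profiles, "conservation_profile"),
            inherits(map, "column_map"),
            inherits(distances, "distance_table"))
  dist_by_res <- stats::setNames(distances$min_distance,
                                 distances$residue_number)
  d <- dist_by_res[as.character(map$residue_number)]
  if (anyNA(d)) {
    abort_input("mapped residue(s) missing from distance table: %s",
                paste(map$residue_number[is.na(d)], collapse = ", "))
  }
  f <- profiles$modal_fraction[map$column]
  keep <- d < d_max & f >= f_low & f < f_high
  out <- data.frame(column = map$column[keep],
                    residue_number = map$residue_number[keep],
                    distance = unname(d[keep]),
                    modal_fraction = f[keep])
  out <- out[order(out$column), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dv_positions", "data.frame")
  out
}

#' D&V score of one candidate against a reference panel
#'
#' The score increases by one for every selected position at which the
#' candidate's symbol differs from the symbols of all reference sequences
#' at that column. A gap is treated as a 21st symbol: gap vs residue is a
#' difference, gap vs gap is identity.
#'
#' @param candidate_id candidate sequence id.
#' @param msa an [new_msa()] object containing candidate and references.
#' @param reference_ids ids of the characterized reference panel.
#' @param positions a `dv_positions` table (or integer column vector).
#' @return list with `id`, `score` (integer) and `contributing_columns`.
#' @export
dv_score <- function(candidate_id, msa, reference_ids, positions) {
  stopifnot(inherits(msa, "msa"))
  if (length(reference_ids) == 0L) abort_config("empty reference panel")
  missing <- setdiff(c(candidate_id, reference_ids), msa$ids)
  if (length(missing) > 0L) {
    abort_input("ids not in alignment: %s", paste(missing, collapse = ", "))
  }
  cols <- if (is.data.frame(positions)) positions$column else as.integer(positions)
  cand <- msa$mat[candidate_id, cols, drop = TRUE]
  refs <- msa$mat[reference_ids, cols, drop = FALSE]
  differs_all <- colSums(refs == rep(cand, each = length(reference_ids))) == 0L
  list(id = candidate_id,
       score = as.integer(sum(differs_all)),
       contributing_columns = cols[differs_all])
}

#' D&V scorecards for many candidates
#'
#' @inheritParams dv_score
#' @param candidate_ids candidate sequence ids.
#' @return list of class `dv_scorecards`, one [dv_score()] entry per
#'   candidate, named by id.
#' @export
dv_scorecards <- function(candidate_ids, msa, reference_ids, positions) {
  cards <- lapply(candidate_ids, dv_score, msa = msa,
                  reference_ids = reference_ids, positions = positions)
  names(cards) <- candidate_ids
  class(cards) <- "dv_scorecards"
  cards
}

#' @export
print.dv_scorecards <- function(x, ...) {
  s <- vapply(x, `[[`, integer(1), "score")
  cat(sprintf("D&V scorecards for %d candidates (scores %d..%d)\n",
              length(x), min(s), max(s)))
  invisible(x)
}

#' Shortlist candidates by D&V score
#'
#' Keeps candidates whose score is strictly greater than `min_score`
#' (default 10), the rule used to carry diverse sequences forward.
#'
#' @param scorecards a [dv_scorecards()] list.
#' @param min_score strict lower bound on the score.
#' @return character vector of shortlisted candidate ids.
#' @export
dv_shortlist <- function(scorecards, min_score = 10L) {
  s <- vapply(scorecards, `[[`, integer(1), "score")
  names(s)[s > min_score]
}

#' Asymmetric pairwise D&V score matrix
#'
#' `s(i -> j)` counts the positions contributing to candidate `i`'s D&V
#' score at which `i` and `j` hold different symbols. Because the
#' contributing positions differ between candidates, the matrix is not
#' generally symmetric.
#'
#' @param candidate_ids candidates to compare (rows and columns).
#' @param scorecards a [dv_scorecards()] list covering the candidates.
#' @param msa an [new_msa()] object.
#' @return integer matrix of class `pairwise_dv_matrix` with
#'   `s[i, j] = s(i -> j)` and zero diagonal.
#' @export
pairwise_dv_matrix <- function(candidate_ids, scorecards, msa) {
  stopifnot(inherits(msa, "msa"))
  missing <- setdiff(candidate_ids, names(scorecards))
  if (length(missing) > 0L) {
    abort_input("scorecards missing for: %s", paste(missing, collapse = ", "))
  }
  n <- length(candidate_ids)
  out <- matrix(0L, n, n, dimnames = list(candidate_ids, candidate_ids))
  for (i in candidate_ids) {
    cols <- scorecards[[i]]$contributing_columns
    if (length(cols) == 0L) next
    ci <- msa$mat[i, cols, drop = TRUE]
    for (j in candidate_ids) {
      if (identical(i, j)) next
      out[i, j] <- sum(msa$mat[j, cols, drop = TRUE] != ci)
    }
  }
  class(out) <- c("pairwise_dv_matrix", class(out))
  out
}

#' Group candidates by mutual pairwise similarity
#'
#' Two candidates are linked when both directed pairwise scores are below
#' `cutoff` (`s(i->j) < cutoff` and `s(j->i) < cutoff`); groups are the
#' connected components of the resulting undirected graph, ordered by the
#' first appearance of a member in the input order.
#'
#' @param matrix a [pairwise_dv_matrix()].
#' @param cutoff strict upper bound on both directed scores (default 9).
#' @return list of class `group_partition`: `groups` (list of id vectors)
#'   and `membership` (named integer vector).
#' @export
group_candidates <- function(matrix, cutoff = 9L) {
  ids <- rownames(matrix)
  adj <- (matrix < cutoff) & (t(matrix) < cutoff)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
  comp <- igraph::components(g)$membership
  # stable ordering: renumber components by first occurrence in input order
  first <- match(unique(comp[ids]), comp[ids])
  relabel <- stats::setNames(seq_along(first), comp[ids][first])
  membership <- stats::setNames(relabel[as.character(comp[ids])], ids)
  groups <- split(ids, membership)
  names(groups) <- NULL
  structure(list(groups = groups, membership = membership,
                 cutoff = as.integer(cutoff)),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf("%d group(s) at mutual cutoff <%d:\n",
              length(x$groups), x$cutoff))
  for (i in seq_along(x$groups)) {
    cat(sprintf("  group %d: %s\n", i, paste(x$groups[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Pick one representative per group
#'
#' Gene availability, the criterion used in practice, is not computable;
#' representative choice is therefore a pluggable policy: `"lex"`
#' (lexicographically smallest id, the deterministic default),
#' `"max-score"` (largest D&V score, ties broken lexicographically), or
#' `"manual"` (caller-supplied choices).
#'
#' @param partition a [group_candidates()] result.
#' @param policy one of `"lex"`, `"max-score"`, `"manual"`.
#' @param scorecards required for `"max-score"`.
#' @param manual named or unnamed character vector, one id per group, for
#'   `"manual"`.
#' @return character vector, one representative id per group.
#' @export
pick_representatives <- function(partition, policy = c("lex", "max-score", "manual"),
                                 scorecards = NULL, manual = NULL) {
  if (!is.character(policy) || !policy[1] %in% c("lex", "max-score", "manual")) {
    abort_config("unknown representative policy '%s'", policy[1])
  }
  policy <- policy[1]
  vapply(seq_along(partition$groups), function(i) {
    members <- partition$groups[[i]]
    switch(policy,
      "lex" = sort(members)[1],
      "max-score" = {
        if (is.null(scorecards)) abort_config("max-score policy needs scorecards")
        s <- vapply(scorecards[members], `[[`, integer(1), "score")
        sort(members[s == max(s)])[1]
      },
      "manual" = {
        if (is.null(manual)) abort_config("manual policy needs choices")
        pick <- intersect(manual, members)
        if (length(pick) != 1L) {
          abort_config("manual choice for group %d must name exactly one member", i)
        }
        pick
      })
  }, character(1))
}
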