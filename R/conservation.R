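#' Per-column residue profiles of an alignment
#'
#' Counts each of the 21 symbols (20 amino acids + gap) per column. The
#' modal fraction is taken over non-gap residues only; the gap fraction is
#' reported separately. An all-gap column has modal fraction 0 and modal
#' residue `NA`.
#'
#' @param msa an [new_msa()] object.
#' @return a data.frame of class `conservation_profile` with one row per
#'   column: `column`, `modal_residue`, `modal_fraction`, `gap_fraction`;
#'   the full 21 x n_col count matrix is attached as attribute `counts`.
#' @export
column_profiles <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  n_seq <- length(msa$ids)
  counts <- apply(msa$mat, 2, function(col) {
    tabulate(factor(col, levels = MSA_ALPHABET), nbins = length(MSA_ALPHABET))
  })
  rownames(counts) <- MSA_ALPHABET
  aa_counts <- counts[AA_ALPHABET20, , drop = FALSE]
  gap_counts <- counts["-", ]
  non_gap <- n_seq - gap_counts
  top <- apply(aa_counts, 2, max)
  modal_idx <- apply(aa_counts, 2, which.max)
  modal_residue <- AA_ALPHABET20[modal_idx]
  modal_residue[non_gap == 0L] <- NA_character_
  modal_fraction <- ifelse(non_gap > 0L, top / non_gap, 0)
  out <- data.frame(
    column = seq_len(msa$n_col),
    modal_residue = modal_residue,
    modal_fraction = modal_fraction,
    gap_fraction = gap_counts / n_seq,
    stringsAsFactors = FALSE
  )
  attr(out, "counts") <- counts
  attr(out, "n_seq") <- n_seq
  class(out) <- c("conservation_profile", "data.frame")
  out
}

# Substitution matrices shipped with Biostrings, restricted to the 20
# standard amino acids.
substitution_matrix <- function(name = "BLOSUM62") {
  available <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
                 "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!name %in% available) {
    abort_config("unknown substitution matrix '%s' (available: %s)",
                 name, paste(available, collapse = ", "))
  }
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  m[AA_ALPHABET20, AA_ALPHABET20]
}

#' Per-column alignment quality scores (q-scores)
#'
#' A 0-100 score of column conservation in the style of the ClustalX
#' column quality score. With `scorer = "clustalx"`, each residue is
#' mapped to its profile vector in substitution-matrix space (its row of
#' the matrix); a column's consensus is the mean profile of its non-gap
#' residues; each residue's similarity is `1 - d/dmax` where `d` is its
#' Euclidean distance to the consensus and `dmax` the largest distance any
#' of the 20 amino acids could have to that consensus. Gap rows contribute
#' 0 and the column score is 100 times the mean over all rows. A column is
#' scored 100 exactly when it holds a single residue type and no gaps; an
#' all-gap column scores 0. `scorer = "modal"` is the simpler
#' `100 * modal_fraction * (1 - gap_fraction)`.
#'
#' @param msa an [new_msa()] object.
#' @param scorer `"clustalx"` (default) or `"modal"`.
#' @param matrix substitution-matrix name for the clustalx scorer.
#' @return numeric vector of length `msa$n_col` in \[0, 100\].
#' @export
qscores <- function(msa, scorer = c("clustalx", "modal"),
                    matrix = "BLOSUM62") {
  stopifnot(inherits(msa, "msa"))
  scorer <- match.arg(scorer)
  if (scorer == "modal") {
    prof <- column_profiles(msa)
    return(100 * prof$modal_fraction * (1 - prof$gap_fraction))
  }
  M <- substitution_matrix(matrix)
  n_seq <- length(msa$ids)
  apply(msa$mat, 2, function(col) {
    ng <- col != "-"
    if (!any(ng)) return(0)
    X <- M[col[ng], , drop = FALSE]
    cons <- colMeans(X)
    d <- sqrt(rowSums((X - rep(cons, each = nrow(X)))^2))
    dmax <- max(sqrt(rowSums((M - rep(cons, each = nrow(M)))^2)))
    s <- if (dmax > 0) 1 - d / dmax else rep(1, length(d))
    100 * sum(s) / n_seq
  })
}

#' Sum of q-scores over a set of columns
#'
#' @param q numeric q-score vector (one entry per alignment column).
#' @param positions integer column indices.
#' @return the arithmetic sum.
#' @export
conservation_sum <- function(q, positions) {
  if (length(positions) == 0L) abort_config("empty position set")
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > length(q))) {
    abort_input("positions outside 1..%d", length(q))
  }
  sum(q[positions])
}

#' Permutation test of active-site conservation
#'
#' Tests whether the summed q-score of the observed column set is larger
#' than expected for an equally sized set drawn at random. The null
#' distribution is formed by repeatedly sampling `length(observed_positions)`
#' columns without replacement from `eligible_columns` (typically, all
#' columns without a gap in the reference sequence) and summing their
#' q-scores. The p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_perm)`, so it is never zero; a run
#' in which no resample reaches the observed sum reports `1/(n_perm + 1)`.
#'
#' @param q numeric q-score vector.
#' @param observed_positions integer column indices of the observed set.
#' @param eligible_columns integer column indices the null draws from.
#' @param n_perm number of random draws (>= 1).
#' @param seed integer seed; the test is bit-reproducible given the seed.
#' @param allow_outside permit observed positions outside the eligible set
#'   (logged with a warning) instead of erroring.
#' @return list of class `permutation_result`: `observed_sum`,
#'   `null_samples`, `null_max`, `p_value`, `seed`.
#' @export
permutation_test <- function(q, observed_positions, eligible_columns,
                             n_perm = 100000L, seed = 1L,
                             allow_outside = FALSE) {
  observed_positions <- unique(as.integer(observed_positions))
  eligible_columns <- unique(as.integer(eligible_columns))
  if (n_perm < 1L) abort_config("n_perm must be >= 1")
  k <- length(observed_positions)
  if (length(eligible_columns) < k) {
    abort_config("fewer eligible columns (%d) than observed positions (%d)",
                 length(eligible_columns), k)
  }
  outside <- setdiff(observed_positions, eligible_columns)
  if (length(outside) > 0L) {
    if (!allow_outside) {
      abort_config("observed positions outside eligible set: %s",
                   paste(outside, collapse = ", "))
    }
    warning(sprintf("%d observed position(s) outside eligible set",
                    length(outside)), call. = FALSE)
  }
  observed_sum <- conservation_sum(q, observed_positions)
  qe <- q[eligible_columns]
  m <- length(qe)
  null_sums <- with_seed(seed, vapply(
    seq_len(n_perm),
    function(i) sum(qe[sample.int(m, k)]),
    numeric(1)))
  structure(
    list(observed_sum = observed_sum,
         null_samples = as.integer(n_perm),
         null_max = max(null_sums),
         null_sums = null_sums,
         p_value = (1 + sum(null_sums >= observed_sum)) / (1 + n_perm),
         seed = as.integer(seed)),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed sum %.1f, null max %.1f over %d draws, p = %.3g\n",
    x$observed_sum, x$null_max, x$null_samples, x$p_value))
  invisible(x)
}

#' Columns conserved within a sequence subset
#'
#' A column is conserved if some single amino acid (gaps excluded) occurs
#' in at least `ceiling(level * n)` of the `n` subset sequences. With the
#' default level 0.75, subsets of 19, 12 and 7 sequences use count
#' thresholds 15, 9 and 6.
#'
#' @param msa an [new_msa()] object.
#' @param subset_ids ids of the subset (nonempty, all present in `msa`).
#' @param level conservation level in (0, 1\].
#' @return integer vector of conserved column indices; the per-column
#'   conserved residue is attached as attribute `residue`.
#' @export
conserved_set <- function(msa, subset_ids, level = 0.75) {
  stopifnot(inherits(msa, "msa"))
  if (length(subset_ids) == 0L) abort_config("empty sequence subset")
  sub <- msa_subset(msa, subset_ids)
  need <- ceiling(level * length(subset_ids))
  counts <- attr(column_profiles(sub), "counts")[AA_ALPHABET20, , drop = FALSE]
  top <- apply(counts, 2, max)
  keep <- which(top >= need)
  res <- AA_ALPHABET20[apply(counts[, keep, drop = FALSE], 2, which.max)]
  structure(keep, residue = stats::setNames(res, keep), threshold = need)
}

#' Venn partition of conserved columns between two specificity classes
#'
#' Classifies alignment columns by conservation in two disjoint sequence
#' groups (e.g. AATases and TATases): the intersection set is conserved at
#' `level` across the union of both groups; the A-only and B-only sets are
#' conserved in one group but not the other. Membership ignores which
#' residue is conserved: a column conserved as different residues in the
#' two groups belongs to both group-conserved sets and therefore to
#' neither "only" set; such columns are flagged.
#'
#' @param msa an [new_msa()] object.
#' @param group_A_ids,group_B_ids disjoint, nonempty id sets.
#' @param level conservation level (default 0.75).
#' @return list of class `venn_sets`: `set_intersection`, `set_A_only`,
#'   `set_B_only` (integer column sets), `thresholds` (named counts used),
#'   and `discordant` (columns conserved in both groups as different
#'   residues).
#' @export
venn_partition <- function(msa, group_A_ids, group_B_ids, level = 0.75) {
  if (length(intersect(group_A_ids, group_B_ids)) > 0L) {
    abort_input("groups overlap: %s",
                paste(intersect(group_A_ids, group_B_ids), collapse = ", "))
  }
  if (length(group_A_ids) == 0L || length(group_B_ids) == 0L) {
    abort_config("both groups must be nonempty")
  }
  consA <- conserved_set(msa, group_A_ids, level)
  consB <- conserved_set(msa, group_B_ids, level)
  consU <- conserved_set(msa, c(group_A_ids, group_B_ids), level)
  both <- intersect(as.integer(consA), as.integer(consB))
  resA <- attr(consA, "residue")
  resB <- attr(consB, "residue")
  discordant <- both[resA[as.character(both)] != resB[as.character(both)]]
  structure(
    list(set_intersection = as.integer(consU),
         set_A_only = setdiff(as.integer(consA), as.integer(consB)),
         set_B_only = setdiff(as.integer(consB), as.integer(consA)),
         thresholds = c(union = attr(consU, "threshold"),
                        A = attr(consA, "threshold"),
                        B = attr(consB, "threshold")),
         discordant = discordant,
         level = level),
    class = "venn_sets"
  )
}

#' @export
print.venn_sets <- function(x, ...) {
  cat(sprintf(
    "Conserved-column Venn sets (level %.2f): |A n B| = %d, |A only| = %d, |B only| = %d\n",
    x$level, length(x$set_intersection), length(x$set_A_only),
    length(x$set_B_only)))
  invisible(x)
}

#' Pairwise percent identity between two aligned sequences
#'
#' 100 times the fraction of identical residues over columns where both
#' sequences are ungapped.
#'
#' @param msa an [new_msa()] object.
#' @param id1,id2 sequence ids.
#' @return percent identity in \[0, 100\]; `NaN` if the sequences share no
#'   ungapped column.
#' @export
percent_identity <- function(msa, id1, id2) {
  stopifnot(inherits(msa, "msa"))
  missing <- setdiff(c(id1, id2), msa$ids)
  if (length(missing) > 0L) {
    abort_input("ids not in alignment: %s", paste(missing, collapse = ", "))
  }
  a <- msa$mat[id1, ]
  b <- msa$mat[id2, ]
  both <- a != "-" & b != "-"
  100 * sum(a[both] == b[both]) / sum(both)
}

#' All-pairs percent identity matrix
#' @param msa an [new_msa()] object.
#' @param ids ids to include (default all).
#' @return symmetric numeric matrix of percent identities.
#' @export
percent_identity_matrix <- function(msa, ids = msa$ids) {
  n <- length(ids)
  out <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        out[i, j] <- out[j, i] <- percent_identity(msa, ids[i], ids[j])
      }
    }
  }
  out
}
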