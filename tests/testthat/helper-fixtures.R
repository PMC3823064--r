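# Fixtures built in code: tiny alignments, PDB texts and cluster plants
# shared across test files.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

fasta_tmp <- function(ids, seqs) {
  write_lines_tmp(as.vector(rbind(paste0(">", ids), seqs)), ".fasta")
}

# Hand-positioned PDB ATOM/HETATM lines (fixed-width v3.3 layout).
pdb_atom_line <- function(record, serial, name, resname, chain, resno,
                          x, y, z, altloc = " ", element = "C") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resname, chain, resno,
          x, y, z, 1, 0, element)
}

# An alignment whose candidates form `n_groups` planted clusters over the
# scored positions: references are all-modal, each group's prototype
# carries a group-specific residue at every position, and members deviate
# from their prototype at `noise` positions. Within-group pairwise
# mismatches are <= 2*noise and between-group mismatches >= n_pos - 2*noise.
make_cluster_msa <- function(n_groups = 3, per_group = 4, n_pos = 15,
                             noise = 2, seed = 1) {
  stopifnot(n_groups <= 18)
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    base <- "A"
    group_res <- setdiff(c("R","N","D","C","Q","E","G","H","I","L","K","M",
                           "F","P","S","T","W","Y","V"), base)[seq_len(n_groups)]
    spare <- "V" # deviation residue, distinct from base and usually from groups
    refs <- replicate(3, paste(rep(base, n_pos), collapse = ""))
    ids <- c("REF_A", "REF_B", "REF_C")
    seqs <- refs
    truth <- integer(0)
    for (g in seq_len(n_groups)) {
      proto <- rep(group_res[g], n_pos)
      for (m in seq_len(per_group)) {
        s <- proto
        if (noise > 0) {
          flip <- sample.int(n_pos, noise)
          dev <- setdiff(c(spare, "W", "Y"), group_res[g])[1]
          s[flip] <- dev
        }
        ids <- c(ids, sprintf("G%d_M%d", g, m))
        seqs <- c(seqs, paste(s, collapse = ""))
        truth <- c(truth, g)
      }
    }
    msa <- new_msa(ids, seqs)
    attr(msa, "truth") <- stats::setNames(truth, ids[-(1:3)])
    msa
  })
}

# Canonical form for comparing collections of edge sets.
canon_sets <- function(sets) {
  sort(vapply(sets, function(x) paste(x, collapse = ","), character(1)))
}

# Exhaustive small-parsimony oracle: minimum changes over every labeling
# of internal nodes and unannotated leaves (trees small enough for 2^n).
brute_force_parsimony <- function(tree, leaf_states, root_constraint = NULL) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  free <- c(which(!(tree$tip.label %in% names(leaf_states))),
            (n_tip + 1L):n_node)
  fixed <- rep(NA_integer_, n_node)
  for (i in seq_len(n_tip)) {
    lbl <- tree$tip.label[i]
    if (lbl %in% names(leaf_states)) {
      fixed[i] <- match(leaf_states[[lbl]], c("AAT", "TAT"))
    }
  }
  root <- n_tip + 1L
  best <- Inf
  best_sets <- list()
  n_free <- length(free)
  for (mask in 0:(2^n_free - 1)) {
    a <- fixed
    bits <- bitwAnd(bitwShiftR(mask, seq_len(n_free) - 1L), 1L)
    a[free] <- bits + 1L
    if (!is.null(root_constraint) &&
        a[root] != match(root_constraint, c("AAT", "TAT"))) next
    changes <- which(a[tree$edge[, 1]] != a[tree$edge[, 2]])
    if (length(changes) < best) {
      best <- length(changes)
      best_sets <- list(sort(changes))
    } else if (length(changes) == best) {
      best_sets <- unique(c(best_sets, list(sort(changes))))
    }
  }
  list(min_changes = best, edge_sets = best_sets)
}
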