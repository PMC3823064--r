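# Seeded generators emulating every input the analysis assumes: protein
# alignments with planted per-column modal fractions, structures with
# planted residue-to-cofactor distances, kinetic rates drawn from the
# ping-pong law, and annotated trees with planted specificity switches.
# All generators are deterministic given their seed and leave the global
# RNG state untouched.

#' Simulate a protein alignment with planted column conservation
#'
#' Each column gets a modal residue; exactly `round(target * n_nongap)`
#' of its non-gap cells carry that residue and the rest are drawn
#' uniformly from the other 19 amino acids, so the realised modal
#' fraction matches the target up to rounding. Gaps are dropped in
#' independently at `gap_prob`, except in the reference sequence, which
#' is kept ungapped so it can anchor a column-to-structure map.
#'
#' @param n_sequences number of sequences (>= 2).
#' @param n_columns number of alignment columns.
#' @param modal_fraction scalar or per-column vector of target modal
#'   fractions in `[1/20, 1]`.
#' @param gap_prob per-cell gap probability in `[0, 1)`.
#' @param ref_id id of the ungapped reference sequence (default
#'   `"REF_1"`, the first record).
#' @param seed integer seed.
#' @return an [new_msa()] object; the planted modal residues and target
#'   fractions are attached as attributes `modal_residue` and
#'   `modal_target`.
#' @export
simulate_msa <- function(n_sequences, n_columns, modal_fraction = 0.5,
                         gap_prob = 0.05, ref_id = "REF_1", seed = 1L) {
  if (n_sequences < 2L) abort_config("need >= 2 sequences")
  targets <- rep_len(modal_fraction, n_columns)
  if (any(targets < 1 / 20 | targets > 1)) {
    abort_config("modal fractions must lie in [1/20, 1]")
  }
  if (gap_prob < 0 || gap_prob >= 1) abort_config("gap_prob must be in [0,1)")
  with_seed(seed, {
    modal <- sample(AA_ALPHABET20, n_columns, replace = TRUE)
    mat <- matrix("-", n_sequences, n_columns)
    for (j in seq_len(n_columns)) {
      gap <- stats::runif(n_sequences) < gap_prob
      gap[1] <- FALSE  # reference row stays ungapped
      ng <- which(!gap)
      k <- round(targets[j] * length(ng))
      k <- max(1L, min(k, length(ng)))
      pick <- ng[sample.int(length(ng), k)]
      mat[pick, j] <- modal[j]
      rest <- setdiff(ng, pick)
      if (length(rest) > 0L) {
        others <- setdiff(AA_ALPHABET20, modal[j])
        mat[rest, j] <- sample(others, length(rest), replace = TRUE)
      }
    }
    ids <- c(ref_id, sprintf("SEQ_%03d", seq_len(n_sequences - 1L) + 1L))
    msa <- new_msa(ids, apply(mat, 1, paste, collapse = ""))
    attr(msa, "modal_residue") <- modal
    attr(msa, "modal_target") <- targets
    msa
  })
}

#' Simulate a structure with planted residue-to-cofactor distances
#'
#' A single-atom pseudo-cofactor sits at the origin; each residue is one
#' heavy atom placed on the sphere of its planted radius, so the minimum
#' heavy-atom distance equals the plant exactly. Exact distance control
#' matters more than stereochemical realism here.
#'
#' @param distances positive vector: planted distance (Angstrom) of each
#'   residue to the cofactor; residue numbers are `1..length(distances)`.
#' @param cofactor_name 3-letter hetero name (default `"PLP"`).
#' @param chain chain identifier.
#' @param seed integer seed (controls the direction of each residue on
#'   its sphere).
#' @return a [new_structure_model()]; the planted distance table is
#'   attached as attribute `planted_distances`.
#' @export
simulate_structure <- function(distances, cofactor_name = "PLP",
                               chain = "A", seed = 1L) {
  if (length(distances) == 0L || any(!is.finite(distances) | distances <= 0)) {
    abort_config("planted distances must be finite and > 0")
  }
  n <- length(distances)
  with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    xyz <- u * distances
    atoms <- data.frame(
      residue_number = c(seq_len(n), n + 1L),
      residue_name = c(rep("ALA", n), cofactor_name),
      chain = chain,
      atom_name = c(rep("CA", n), "P"),
      x = c(xyz[, 1], 0), y = c(xyz[, 2], 0), z = c(xyz[, 3], 0),
      record_kind = c(rep("polymer", n), "hetero"),
      stringsAsFactors = FALSE
    )
    s <- new_structure_model(atoms)
    planted <- data.frame(residue_number = seq_len(n),
                          residue_name = "ALA",
                          min_distance = distances)
    attr(s, "planted_distances") <- planted
    s
  })
}

#' Simulate kinetic initial-rate data from the ping-pong law
#'
#' Rates are `pingpong_rate(truth, A, B, E) * (1 + eps)` with
#' multiplicative Gaussian noise `eps ~ N(0, noise^2)` (assay error
#' scales with signal in initial-rate measurements). Draws producing a
#' negative rate are resampled (with a message).
#'
#' @param truth a [rate_law_params()] object.
#' @param design data.frame with columns `conc_aa_mM`, `conc_cosub_mM`.
#' @param conc_e enzyme concentration.
#' @param noise multiplicative standard deviation (>= 0).
#' @param enzyme,substrate labels for the emitted rows.
#' @param seed integer seed.
#' @return a [new_kinetic_dataset()].
#' @export
simulate_kinetics <- function(truth, design, conc_e = 1e-8, noise = 0.01,
                              enzyme = "ENZ1", substrate = "Asp",
                              seed = 1L) {
  stopifnot(inherits(truth, "rate_law_params"))
  if (nrow(design) == 0L) abort_config("empty design")
  if (noise < 0) abort_config("noise must be >= 0")
  mu <- pingpong_rate(truth, design$conc_aa_mM, design$conc_cosub_mM, conc_e)
  rates <- with_seed(seed, {
    r <- mu * (1 + stats::rnorm(length(mu), 0, noise))
    n_bad <- 0L
    while (any(r < 0)) {
      bad <- which(r < 0)
      n_bad <- n_bad + length(bad)
      r[bad] <- mu[bad] * (1 + stats::rnorm(length(bad), 0, noise))
    }
    if (n_bad > 0L) message(sprintf("resampled %d negative rate draw(s)", n_bad))
    r
  })
  new_kinetic_dataset(data.frame(
    enzyme = enzyme, substrate = substrate,
    conc_aa_mM = design$conc_aa_mM, conc_cosub_mM = design$conc_cosub_mM,
    conc_e = conc_e, rate = rates, stringsAsFactors = FALSE))
}

#' Standard two-substrate assay design
#'
#' A crossed grid of amino-acid and co-substrate concentrations spanning
#' sub- to supra-Km levels, mirroring how ping-pong assays vary both
#' substrates.
#'
#' @param conc_aa,conc_cosub concentration levels in mM.
#' @return data.frame with `conc_aa_mM`, `conc_cosub_mM`.
#' @export
kinetic_design <- function(conc_aa = c(0.25, 0.5, 1, 2, 5, 10),
                           conc_cosub = c(0.2, 0.5, 1, 2, 5)) {
  expand.grid(conc_aa_mM = conc_aa, conc_cosub_mM = conc_cosub,
              KEEP.OUT.ATTRS = FALSE)
}

# Closure testing whether edge j's subtree is nested in edge i's.
edge_nested <- function(tree) {
  n_tip <- length(tree$tip.label)
  parent_of <- integer(n_tip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  function(i, j) {
    v <- tree$edge[j, 2]
    top <- tree$edge[i, 2]
    while (v != 0L) {
      if (v == top) return(TRUE)
      v <- if (v == n_tip + 1L) 0L else parent_of[v]
    }
    FALSE
  }
}

#' Simulate a rooted tree with planted specificity switches
#'
#' A random rooted bifurcating topology with `k` switch edges chosen so
#' that no chosen edge is nested in or sibling to another; the root state
#' propagates down and flips below each switch edge, producing `k`
#' clade-coherent discordant clades whose parsimony minimum is exactly
#' `k`.
#'
#' @param n_leaves number of leaves.
#' @param k number of planted switches (`0 <= k <= n_leaves - 1`).
#' @param root_state `"AAT"` (default) or `"TAT"`.
#' @param prop_annotated fraction of leaves that keep their annotation
#'   (1 = fully annotated; sampling preserves at least one leaf per
#'   discordant clade so the plant stays recoverable).
#' @param seed integer seed.
#' @return an [annotated_phylogeny()]; planted switch edge indices (rows
#'   of `tree$edge`) are attached as attribute `planted_switch_edges` and
#'   the full leaf truth as `true_leaf_states`.
#' @export
simulate_annotated_tree <- function(n_leaves, k = 0L, root_state = "AAT",
                                    prop_annotated = 1, seed = 1L) {
  if (!root_state %in% PHYLO_STATES) abort_config("bad root state")
  if (k < 0L || k > n_leaves - 1L) {
    abort_config("k must lie in [0, n_leaves - 1]")
  }
  with_seed(seed, {
    tree <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
    tree <- validate_phylogeny(tree)
    # cladewise edge order lists every parent before its children
    tree <- ape::reorder.phylo(tree, "cladewise")
    n_tip <- length(tree$tip.label)
    nested <- edge_nested(tree)
    siblings <- function(i, j) {
      tree$edge[i, 1] == tree$edge[j, 1]
    }
    # subtree sizes: smaller subtrees block fewer later choices, so a
    # size-ascending greedy (with random tie-breaks, retried a few times)
    # finds a non-nested, non-sibling edge set whenever one plausibly fits
    n_desc <- vapply(seq_len(nrow(tree$edge)), function(e) {
      v <- tree$edge[e, 2]
      if (v <= n_tip) 1L else length(ape::extract.clade(tree, v)$tip.label)
    }, integer(1))
    chosen <- integer(0)
    for (attempt in seq_len(50L)) {
      chosen <- integer(0)
      # early attempts try arbitrary clades; later ones fall back to
      # small subtrees, which interfere least
      ord <- if (attempt <= 10L) sample(seq_along(n_desc))
             else order(n_desc + stats::runif(length(n_desc)))
      for (e in ord) {
        if (length(chosen) >= k) break
        ok <- all(vapply(chosen, function(c0) {
          !nested(c0, e) && !nested(e, c0) && !siblings(c0, e)
        }, logical(1)))
        if (ok) chosen <- c(chosen, e)
      }
      if (length(chosen) >= k) break
    }
    if (length(chosen) < k) {
      abort_config("could not place %d non-interfering switches on %d leaves",
                   k, n_leaves)
    }
    # propagate states from the root, flipping below each chosen edge
    states_idx <- integer(n_tip + tree$Nnode)
    states_idx[n_tip + 1L] <- match(root_state, PHYLO_STATES)
    for (i in seq_len(nrow(tree$edge))) {
      p <- tree$edge[i, 1]
      c <- tree$edge[i, 2]
      s <- states_idx[p]
      if (i %in% chosen) s <- 3L - s
      states_idx[c] <- s
    }
    truth <- stats::setNames(PHYLO_STATES[states_idx[seq_len(n_tip)]],
                             tree$tip.label)
    keep <- names(truth)
    if (prop_annotated < 1) {
      n_keep <- max(2L, round(prop_annotated * n_tip))
      # always retain one leaf inside each flipped clade
      must <- vapply(chosen, function(e) {
        v <- tree$edge[e, 2]
        if (v <= n_tip) tree$tip.label[v]
        else ape::extract.clade(tree, v)$tip.label[1]
      }, character(1))
      pool <- setdiff(names(truth), must)
      keep <- c(must, sample(pool, max(0L, n_keep - length(must))))
    }
    ann <- annotated_phylogeny(tree, truth[keep])
    attr(ann, "planted_switch_edges") <- sort(chosen)
    attr(ann, "true_leaf_states") <- truth
    ann
  })
}

#' Deterministic 92-leaf consistency preset for root-state parsimony
#'
#' A rooted tree with 19 annotated leaves (12 AAT, 7 TAT) in which the
#' TAT annotations fall in three separate clades hanging off an
#' AAT-dominated backbone, alternating with AAT clades so the two root
#' hypotheses separate: constrained parsimony needs 3 switches with an
#' AAT root and 5 with a TAT root. The remaining 73 leaves are
#' unannotated free variables, mimicking a sparsely characterized
#' subfamily. The topology is fixed (no randomness).
#'
#' @return an [annotated_phylogeny()] with 92 leaves.
#' @export
fig_tree_preset <- function() {
  # nested binary (caterpillar) clade; `extra` is a subtree string grafted
  # at the deepest position
  clade <- function(prefix, n, extra = NULL) {
    tips <- sprintf("%s_%02d", prefix, seq_len(n))
    inner <- if (is.null(extra)) tips[n] else sprintf("(%s,%s)", tips[n], extra)
    for (t in rev(tips[-n])) inner <- sprintf("(%s,%s)", t, inner)
    inner
  }
  # backbone: (L, R) with L = (A1,(T1,(A2,(T2,A3)))) and R = (A4,(T3,A5));
  # AAT clades A1..A5 (3+2+3+2+2 = 12 annotated leaves), TAT clades
  # T1..T3 (3+2+2 = 7) in three separate clades. Unannotated filler
  # clades U1-U3 (73 leaves) are grafted deep inside A1, A3 and A4 where,
  # as free variables, they leave all parsimony costs unchanged.
  newick <- sprintf(
    "((%s,(%s,(%s,(%s,%s)))),(%s,(%s,%s)));",
    clade("A1", 3, clade("U1", 25)), clade("T1", 3), clade("A2", 2),
    clade("T2", 2), clade("A3", 3, clade("U2", 25)),
    clade("A4", 2, clade("U3", 23)), clade("T3", 2), clade("A5", 2))
  tree <- validate_phylogeny(ape::read.tree(text = newick))
  stopifnot(length(tree$tip.label) == 92L)
  aat <- grep("^A[1-5]_", tree$tip.label, value = TRUE)
  tat <- grep("^T[1-3]_", tree$tip.label, value = TRUE)
  states <- stats::setNames(c(rep("AAT", length(aat)), rep("TAT", length(tat))),
                            c(aat, tat))
  annotated_phylogeny(tree, states)
}
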