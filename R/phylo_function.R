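# Binary-trait (AATase/TATase) parsimony on a rooted phylogeny: Sankoff
# dynamic programming with a unit cost matrix (equivalent to Fitch for two
# states), supporting root constraints, partially annotated leaves
# (unannotated leaves are free variables optimised over), counting and
# enumeration of co-optimal labelings, and a parsimony-based
# leave-one-out predictor.

PHYLO_STATES <- c("AAT", "TAT")

#' Attach partial leaf states to a rooted phylogeny
#'
#' @param tree a rooted [ape::phylo] (validated with
#'   [validate_phylogeny()]).
#' @param leaf_states named character vector over `{"AAT","TAT"}` for a
#'   subset of the leaves; unannotated leaves are allowed and treated as
#'   free during parsimony.
#' @return list of class `annotated_phylogeny`.
#' @export
annotated_phylogeny <- function(tree, leaf_states) {
  tree <- validate_phylogeny(tree)
  if (length(leaf_states) == 0L) abort_input("no annotated leaves")
  bad_state <- setdiff(unique(leaf_states), PHYLO_STATES)
  if (length(bad_state) > 0L) {
    abort_input("states outside {AAT, TAT}: %s",
                paste(bad_state, collapse = ", "))
  }
  missing <- setdiff(names(leaf_states), tree$tip.label)
  if (length(missing) > 0L) {
    abort_input("annotated leaves not in tree: %s",
                paste(missing, collapse = ", "))
  }
  structure(list(tree = tree, leaf_states = leaf_states),
            class = "annotated_phylogeny")
}

#' @export
print.annotated_phylogeny <- function(x, ...) {
  tab <- table(factor(x$leaf_states, PHYLO_STATES))
  cat(sprintf(
    "Annotated phylogeny: %d leaves, %d annotated (%d AAT, %d TAT)\n",
    length(x$tree$tip.label), length(x$leaf_states), tab["AAT"], tab["TAT"]))
  invisible(x)
}

# Children lists and a postorder node sequence for a rooted phylo.
tree_topology <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  children <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    children[[p]] <- c(children[[p]], tree$edge[i, 2])
  }
  root <- n_tip + 1L
  # iterative postorder
  post <- integer(0)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    post <- c(v, post)
    stack <- c(stack, children[[v]])
  }
  list(n_tip = n_tip, n_node = n_node, root = root,
       children = children, postorder = post)
}

# Sankoff up-pass. Returns cost and count matrices (n_node x 2); column
# j is state PHYLO_STATES[j]. Counts are numbers of co-optimal labelings
# of the subtree conditional on the subtree root's state (free leaves
# count as labeled).
sankoff_costs <- function(annotated, extra_fixed = NULL) {
  tree <- annotated$tree
  topo <- tree_topology(tree)
  states <- annotated$leaf_states
  if (!is.null(extra_fixed)) states[names(extra_fixed)] <- extra_fixed
  cost <- matrix(0, topo$n_node, 2)
  count <- matrix(1, topo$n_node, 2)
  for (i in seq_len(topo$n_tip)) {
    lbl <- tree$tip.label[i]
    if (lbl %in% names(states)) {
      s <- match(states[[lbl]], PHYLO_STATES)
      cost[i, -s] <- Inf
      count[i, -s] <- 0
    }
  }
  for (v in topo$postorder) {
    kids <- topo$children[[v]]
    if (length(kids) == 0L) next
    for (s in 1:2) {
      tot <- 0
      cnt <- 1
      for (c in kids) {
        opts <- cost[c, ] + (1:2 != s)
        m <- min(opts)
        tot <- tot + m
        cnt <- cnt * sum(count[c, opts == m & is.finite(opts)])
      }
      cost[v, s] <- tot
      count[v, s] <- if (is.finite(tot)) cnt else 0
    }
  }
  list(cost = cost, count = count, topo = topo, states = states)
}

#' Minimum number of specificity switches under parsimony
#'
#' Small-parsimony minimum over all labelings of internal nodes and
#' unannotated leaves, with unit change cost per branch; optionally with
#' the root state fixed. The constrained minimum is never below the
#' unconstrained one.
#'
#' @param annotated an [annotated_phylogeny()].
#' @param root_constraint `"AAT"`, `"TAT"`, or `NULL`/`"none"` for
#'   unconstrained.
#' @return list of class `parsimony_result`: `min_changes`,
#'   `root_constraint`, `optimal_root_states`, `n_optimal_labelings`,
#'   plus the internal DP tables reused by
#'   [enumerate_switch_edges()].
#' @export
min_changes <- function(annotated, root_constraint = NULL) {
  stopifnot(inherits(annotated, "annotated_phylogeny"))
  if (!is.null(root_constraint) && identical(root_constraint, "none")) {
    root_constraint <- NULL
  }
  if (!is.null(root_constraint) && !root_constraint %in% PHYLO_STATES) {
    abort_input("root constraint must be AAT, TAT or none")
  }
  dp <- sankoff_costs(annotated)
  root_costs <- dp$cost[dp$topo$root, ]
  if (is.null(root_constraint)) {
    m <- min(root_costs)
    opt_states <- PHYLO_STATES[root_costs == m]
  } else {
    s <- match(root_constraint, PHYLO_STATES)
    m <- root_costs[s]
    opt_states <- root_constraint
  }
  if (!is.finite(m)) abort_input("no labeling consistent with annotations")
  n_opt <- sum(dp$count[dp$topo$root, match(opt_states, PHYLO_STATES)])
  structure(
    list(min_changes = as.integer(m),
         root_constraint = root_constraint %||% "none",
         optimal_root_states = opt_states,
         n_optimal_labelings = n_opt,
         dp = dp),
    class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf(
    "Parsimony: %d change(s) (root %s), optimal root state(s): %s, %g co-optimal labeling(s)\n",
    x$min_changes, x$root_constraint,
    paste(x$optimal_root_states, collapse = "/"), x$n_optimal_labelings))
  invisible(x)
}

#' Enumerate the switch branches of all most-parsimonious labelings
#'
#' Backtracks through the Sankoff tables to list every co-optimal
#' labeling's set of switch edges (edges whose endpoint states differ);
#' each set has exactly `min_changes` edges. The union over labelings is
#' the set of candidate switch branches.
#'
#' @param annotated the [annotated_phylogeny()] used for `result`.
#' @param result a [min_changes()] result on the same inputs.
#' @param max_labelings guard against combinatorial blow-up.
#' @return list of class `switch_edge_sets`: `edge_sets` (list of sorted
#'   integer vectors indexing rows of `tree$edge`), `union`, and
#'   `edge_labels` (readable `parent->child` descriptions of the union).
#' @export
enumerate_switch_edges <- function(annotated, result, max_labelings = 10000) {
  stopifnot(inherits(annotated, "annotated_phylogeny"),
            inherits(result, "parsimony_result"))
  if (result$n_optimal_labelings > max_labelings) {
    abort_config("%g co-optimal labelings exceed max_labelings = %g",
                 result$n_optimal_labelings, max_labelings)
  }
  dp <- result$dp
  topo <- dp$topo
  tree <- annotated$tree
  root_idx <- match(result$optimal_root_states, PHYLO_STATES)

  # depth-first expansion of co-optimal assignments; an assignment is an
  # integer state vector over all nodes
  assignments <- list()
  expand <- function(assign, frontier) {
    if (length(frontier) == 0L) {
      assignments[[length(assignments) + 1L]] <<- assign
      return(invisible())
    }
    v <- frontier[1]
    rest <- frontier[-1]
    s <- assign[v]
    kids <- topo$children[[v]]
    if (length(kids) == 0L) {
      expand(assign, rest)
      return(invisible())
    }
    choice_sets <- lapply(kids, function(c) {
      opts <- dp$cost[c, ] + (1:2 != s)
      which(opts == min(opts) & is.finite(opts) & dp$count[c, ] > 0)
    })
    grid <- expand.grid(choice_sets, KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(max(nrow(grid), 0L))) {
      a2 <- assign
      a2[kids] <- as.integer(grid[r, ])
      expand(a2, c(rest, kids))
    }
  }
  for (s in root_idx) {
    if (dp$count[topo$root, s] == 0) next
    assign <- rep(NA_integer_, topo$n_node)
    assign[topo$root] <- s
    expand(assign, topo$root)
  }
  edge_sets <- unique(lapply(assignments, function(a) {
    sort(which(a[tree$edge[, 1]] != a[tree$edge[, 2]]))
  }))
  union_edges <- sort(unique(unlist(edge_sets)))
  node_name <- function(v) {
    if (v <= topo$n_tip) tree$tip.label[v] else sprintf("node%d", v)
  }
  labels <- vapply(union_edges, function(e) {
    sprintf("%s->%s", node_name(tree$edge[e, 1]), node_name(tree$edge[e, 2]))
  }, character(1))
  structure(list(edge_sets = edge_sets, union = union_edges,
                 edge_labels = labels),
            class = "switch_edge_sets")
}

#' Parsimony prediction of a leaf's specificity state
#'
#' The set of states the query leaf takes across all minimum-change
#' labelings (any existing annotation of the query is masked first). A
#' singleton is a confident call; both states means the parsimony
#' criterion cannot decide.
#'
#' @param annotated an [annotated_phylogeny()].
#' @param query_leaf leaf label to predict.
#' @return character vector of states (`"AAT"`, `"TAT"`, or both).
#' @export
parsimony_predict <- function(annotated, query_leaf) {
  stopifnot(inherits(annotated, "annotated_phylogeny"))
  if (!query_leaf %in% annotated$tree$tip.label) {
    abort_input("query leaf '%s' not in tree", query_leaf)
  }
  masked <- annotated
  masked$leaf_states <- masked$leaf_states[
    setdiff(names(masked$leaf_states), query_leaf)]
  if (length(masked$leaf_states) == 0L) {
    abort_input("no annotations remain after masking '%s'", query_leaf)
  }
  per_state <- vapply(PHYLO_STATES, function(s) {
    dp <- sankoff_costs(masked, extra_fixed = stats::setNames(s, query_leaf))
    min(dp$cost[dp$topo$root, ])
  }, numeric(1))
  PHYLO_STATES[per_state == min(per_state)]
}

#' Leave-one-out accuracy of the parsimony predictor
#'
#' Each annotated leaf in turn is masked and re-predicted with
#' [parsimony_predict()]. A prediction is correct when it is the
#' singleton of the true state; an undecided prediction (both states
#' tied) scores 0 by default or 0.5 with `half_credit`.
#'
#' @param annotated an [annotated_phylogeny()] with >= 2 annotated
#'   leaves.
#' @param half_credit score undecided predictions 0.5 instead of 0.
#' @return list: `accuracy`, and `calls` (per-leaf predicted state sets).
#' @export
loo_accuracy <- function(annotated, half_credit = FALSE) {
  stopifnot(inherits(annotated, "annotated_phylogeny"))
  leaves <- names(annotated$leaf_states)
  if (length(leaves) < 2L) abort_input("need >= 2 annotated leaves")
  calls <- lapply(leaves, function(lv) parsimony_predict(annotated, lv))
  names(calls) <- leaves
  score <- vapply(leaves, function(lv) {
    pred <- calls[[lv]]
    if (length(pred) == 1L) {
      as.numeric(pred == annotated$leaf_states[[lv]])
    } else if (half_credit) 0.5 else 0
  }, numeric(1))
  list(accuracy = mean(score), calls = calls)
}
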