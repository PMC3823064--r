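#' Read a rooted phylogeny from Newick
#'
#' Wraps [ape::read.tree()] and enforces the invariants the downstream
#' parsimony machinery relies on: a single root, unique leaf labels, and no
#' singleton internal nodes (singles are collapsed).
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object (rooted).
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) abort_input("tree file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!grepl(";", txt, fixed = TRUE)) abort_input("no Newick ';' terminator in %s", path)
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) {
    abort_input("unbalanced parentheses in %s (%d '(' vs %d ')')",
                path, n_open, n_close)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) abort_input(
                     "could not parse Newick %s: %s", path,
                     conditionMessage(e)))
  if (is.null(tree)) abort_input("could not parse Newick %s", path)
  validate_phylogeny(tree)
}

#' Validate a phylogeny for use in this package
#' @param tree an [ape::phylo] object.
#' @return the (possibly single-collapsed) tree, invisibly usable.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) abort_input("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    abort_input("duplicate leaf names: %s",
                paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                      collapse = ", "))
  }
  tree <- ape::collapse.singles(tree)
  if (!ape::is.rooted(tree)) abort_input("tree is not rooted")
  tree
}

#' Write a phylogeny as Newick
#' @param tree an [ape::phylo] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read partial leaf-state annotations
#'
#' Two-column tab-separated table (`leaf_id`, `state`) assigning
#' AATase/TATase states to a subset of leaves.
#'
#' @param path path to the TSV file (no header required; a
#'   `leaf_id<TAB>state` header line is tolerated).
#' @param tree optional [ape::phylo]; if given, ids are checked against its
#'   leaves.
#' @return named character vector of states (`"AAT"`/`"TAT"`).
#' @export
read_leaf_states <- function(path, tree = NULL) {
  if (!file.exists(path)) abort_input("annotation file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, col.names = c("leaf_id", "state"))
  if (nrow(tab) > 0 && tab$leaf_id[1] == "leaf_id") tab <- tab[-1, , drop = FALSE]
  states <- stats::setNames(toupper(tab$state), tab$leaf_id)
  bad <- setdiff(unique(states), c("AAT", "TAT"))
  if (length(bad) > 0L) {
    abort_input("states outside {AAT, TAT}: %s", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(names(states))) abort_input("duplicate leaf annotations")
  if (!is.null(tree)) {
    missing <- setdiff(names(states), tree$tip.label)
    if (length(missing) > 0L) {
      abort_input("annotated leaves not in tree: %s",
                  paste(missing, collapse = ", "))
    }
  }
  states
}

#' Write leaf-state annotations as TSV
#' @param states named character vector of `"AAT"`/`"TAT"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_leaf_states <- function(states, path) {
  utils::write.table(
    data.frame(leaf_id = names(states), state = unname(states)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
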