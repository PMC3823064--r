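test_that("uniform annotations need no changes and force the root", {
  tree <- read_tree(write_lines_tmp("((A,B),(C,D));", ".nwk"))
  ann <- annotated_phylogeny(tree, c(A = "AAT", B = "AAT", C = "AAT", D = "AAT"))
  res <- min_changes(ann)
  expect_equal(res$min_changes, 0L)
  expect_equal(res$optimal_root_states, "AAT")
  expect_equal(res$n_optimal_labelings, 1)
  sw <- enumerate_switch_edges(ann, res)
  expect_equal(sw$edge_sets, list(integer(0)))
  expect_length(sw$union, 0)
})

test_that("a 4-leaf discordant tree matches the brute-force oracle", {
  tree <- read_tree(write_lines_tmp("((A,B),(C,D));", ".nwk"))
  states <- c(A = "AAT", B = "TAT", C = "AAT", D = "TAT")
  ann <- annotated_phylogeny(tree, states)
  oracle <- brute_force_parsimony(tree, states)
  res <- min_changes(ann)
  expect_equal(res$min_changes, oracle$min_changes)
  sw <- enumerate_switch_edges(ann, res)
  expect_equal(canon_sets(sw$edge_sets), canon_sets(oracle$edge_sets))
  expect_true(all(lengths(sw$edge_sets) == res$min_changes))
  for (rc in c("AAT", "TAT")) {
    expect_equal(min_changes(ann, rc)$min_changes,
                 brute_force_parsimony(tree, states, rc)$min_changes)
  }
})

test_that("random trees up to 8 leaves agree with exhaustive enumeration", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(3:8, 1)
    tree <- validate_phylogeny(ape::rtree(n, br = NULL))
    labels <- tree$tip.label
    n_ann <- sample(seq(1, n), 1)
    states <- setNames(sample(c("AAT", "TAT"), n_ann, replace = TRUE),
                       sample(labels, n_ann))
    ann <- annotated_phylogeny(tree, states)
    res <- min_changes(ann)
    oracle <- brute_force_parsimony(tree, states)
    expect_equal(res$min_changes, oracle$min_changes)
    sw <- enumerate_switch_edges(ann, res)
    expect_equal(canon_sets(sw$edge_sets), canon_sets(oracle$edge_sets))
    for (rc in c("AAT", "TAT")) {
      expect_equal(min_changes(ann, rc)$min_changes,
                   brute_force_parsimony(tree, states, rc)$min_changes)
    }
  }
})

test_that("the constrained minimum over both roots equals the unconstrained one", {
  for (seed in 41:60) {
    ann <- simulate_annotated_tree(10, k = sample(0:4, 1), seed = seed)
    free <- min_changes(ann)$min_changes
    roots <- c(min_changes(ann, "AAT")$min_changes,
               min_changes(ann, "TAT")$min_changes)
    expect_equal(min(roots), free)
    expect_true(all(roots >= free))
  }
})

test_that("parsimony is invariant under child-order permutation", {
  t1 <- read_tree(write_lines_tmp("((A,(B,C)),(D,E));", ".nwk"))
  t2 <- read_tree(write_lines_tmp("((E,D),((C,B),A));", ".nwk"))
  states <- c(A = "AAT", B = "TAT", C = "TAT", D = "AAT", E = "TAT")
  r1 <- min_changes(annotated_phylogeny(t1, states))
  r2 <- min_changes(annotated_phylogeny(t2, states))
  expect_equal(r1$min_changes, r2$min_changes)
  expect_equal(r1$n_optimal_labelings, r2$n_optimal_labelings)
  expect_setequal(r1$optimal_root_states, r2$optimal_root_states)
})

test_that("a single discordant leaf with an annotated sister pins the switch to its pendant edge", {
  tree <- read_tree(write_lines_tmp("(((A,B),C),(D,E));", ".nwk"))
  states <- c(A = "AAT", B = "AAT", C = "AAT", D = "AAT", E = "TAT")
  ann <- annotated_phylogeny(tree, states)
  res <- min_changes(ann)
  expect_equal(res$min_changes, 1L)
  sw <- enumerate_switch_edges(ann, res)
  expect_length(sw$edge_sets, 1L)
  e <- sw$edge_sets[[1]]
  expect_length(e, 1L)
  expect_equal(tree$tip.label[tree$edge[e, 2]], "E")
})

test_that("predictions follow clade membership", {
  # query nested inside a uniformly AAT clade; every annotated leaf
  # keeps an annotated sister when masked
  tree <- read_tree(write_lines_tmp("(((A,B),(Q,G)),((C,D),E));", ".nwk"))
  states <- c(A = "AAT", B = "AAT", G = "AAT",
              C = "TAT", D = "TAT", E = "TAT")
  ann <- annotated_phylogeny(tree, states)
  expect_equal(parsimony_predict(ann, "Q"), "AAT")
  # a query at the boundary between two uniform clades stays undecided
  tree2 <- read_tree(write_lines_tmp("(((A,B),(C,D)),Q);", ".nwk"))
  states2 <- c(A = "AAT", B = "AAT", C = "TAT", D = "TAT")
  ann2 <- annotated_phylogeny(tree2, states2)
  expect_setequal(parsimony_predict(ann2, "Q"), c("AAT", "TAT"))
  # masking an annotated leaf defines leave-one-out
  expect_equal(parsimony_predict(ann, "A"), "AAT")
  expect_error(parsimony_predict(ann, "ZZ"), class = "specswap_input_error")
})

test_that("leave-one-out accuracy is perfect on clade-segregated states", {
  # every leaf has an annotated sister, so each masked call is decided
  tree <- read_tree(write_lines_tmp("(((A,B),(C,G)),((D,E),(F,H)));", ".nwk"))
  states <- c(A = "AAT", B = "AAT", C = "AAT", G = "AAT",
              D = "TAT", E = "TAT", F = "TAT", H = "TAT")
  ann <- annotated_phylogeny(tree, states)
  loo <- loo_accuracy(ann)
  expect_equal(loo$accuracy, 1)
  sisters <- annotated_phylogeny(
    read_tree(write_lines_tmp("((A,B),C);", ".nwk")),
    c(A = "AAT", B = "AAT"))
  expect_equal(loo_accuracy(sisters)$accuracy, 1)
  expect_error(
    loo_accuracy(annotated_phylogeny(tree, states[1])),
    class = "specswap_input_error")
})

test_that("accuracy degrades as planted switch counts rise", {
  acc_for_k <- function(k) {
    mean(vapply(1:6, function(seed) {
      ann <- simulate_annotated_tree(24, k = k, seed = 100 + seed)
      loo_accuracy(ann)$accuracy
    }, numeric(1)))
  }
  accs <- vapply(c(0, 3, 8), acc_for_k, numeric(1))
  expect_true(accs[1] >= accs[2])
  expect_gt(accs[1], accs[3])
})

test_that("planted switches are counted exactly by parsimony", {
  for (seed in 1:20) {
    k <- seed %% 5
    ann <- simulate_annotated_tree(16, k = k, seed = 200 + seed)
    expect_equal(min_changes(ann)$min_changes, k)
  }
})

test_that("the 92-leaf preset separates the two root hypotheses", {
  ann <- fig_tree_preset()
  expect_length(ann$tree$tip.label, 92L)
  expect_equal(sum(ann$leaf_states == "AAT"), 12L)
  expect_equal(sum(ann$leaf_states == "TAT"), 7L)
  expect_equal(min_changes(ann)$min_changes, 3L)
  expect_equal(min_changes(ann, "AAT")$min_changes, 3L)
  expect_equal(min_changes(ann, "TAT")$min_changes, 5L)
  expect_equal(min_changes(ann)$optimal_root_states, "AAT")
})
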