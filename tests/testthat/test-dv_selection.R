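toy_distance_table <- function(d) {
  tab <- data.frame(residue_number = seq_along(d), residue_name = "ALA",
                    chain = "A", min_distance = d)
  class(tab) <- c("distance_table", "data.frame")
  tab
}

test_that("column map pairs non-gap reference columns with residues", {
  msa <- new_msa(c("ref", "o"), c("A-CD", "AACD"))
  map <- map_columns_to_reference(msa, "ref")
  expect_equal(map$column, c(1L, 3L, 4L))
  expect_equal(map$residue_number, 1:3)
  d <- toy_distance_table(c(1, 2, 3, 4))
  expect_error(map_columns_to_reference(msa, "ref", d),
               class = "specswap_input_error")
  map2 <- map_columns_to_reference(msa, "ref", d, offset = 1L)
  expect_equal(map2$residue_number, 2:4)
  # generator round-trip: the ungapped reference row maps 1:1
  sim <- simulate_msa(10, 20, gap_prob = 0.15, seed = 5)
  m <- map_columns_to_reference(sim, "REF_1")
  expect_equal(m$column, 1:20)
  expect_equal(m$residue_number, 1:20)
})

test_that("D&V position selection applies strict/closed-open boundaries", {
  profiles <- structure(data.frame(
    column = 1:4,
    modal_residue = "A",
    modal_fraction = c(0.25, 0.5, 0.75, 0.25),
    gap_fraction = 0), class = c("conservation_profile", "data.frame"))
  map <- structure(data.frame(column = 1:4, residue_number = 1:4),
                   class = c("column_map", "data.frame"))
  d <- toy_distance_table(c(14.9, 14.9, 14.9, 15.0))
  pos <- select_dv_positions(profiles, map, d)
  # 14.9 A at 0.25 is in; 0.75 is out (f < 0.75); 15.0 A is out (< 15)
  expect_equal(pos$column, c(1L, 2L))
})

test_that("D&V position selection equals the brute-force filter", {
  set.seed(77)
  n <- 20
  profiles <- structure(data.frame(
    column = 1:n, modal_residue = "A",
    modal_fraction = round(runif(n), 2), gap_fraction = 0),
    class = c("conservation_profile", "data.frame"))
  map <- structure(data.frame(column = 1:n, residue_number = 1:n),
                   class = c("column_map", "data.frame"))
  dvals <- round(runif(n, 5, 25), 1)
  d <- toy_distance_table(dvals)
  pos <- select_dv_positions(profiles, map, d)
  oracle <- integer(0)
  for (j in 1:n) {
    if (dvals[j] < 15 && profiles$modal_fraction[j] >= 0.25 &&
        profiles$modal_fraction[j] < 0.75) {
      oracle <- c(oracle, j)
    }
  }
  expect_equal(pos$column, oracle)
})

test_that("D&V scores count residues unlike every reference", {
  msa <- new_msa(c("r1", "r2", "c_same", "c_two", "c_gap"),
                 c("ACDE", "ACDF", "ACDE", "AWWE", "A-DE"))
  pos <- 1:4
  expect_equal(dv_score("c_same", msa, c("r1", "r2"), pos)$score, 0L)
  sc <- dv_score("c_two", msa, c("r1", "r2"), pos)
  expect_equal(sc$score, 2L)
  expect_equal(sc$contributing_columns, c(2L, 3L))
  # gap differs from residues but matches gap
  expect_equal(dv_score("c_gap", msa, c("r1", "r2"), pos)$score, 1L)
  msa_gapref <- new_msa(c("r1", "cand"), c("A-", "A-"))
  expect_equal(dv_score("cand", msa_gapref, "r1", 1:2)$score, 0L)
  expect_error(dv_score("c_two", msa, character(0), pos),
               class = "specswap_config_error")
})

test_that("adding references never increases a D&V score", {
  msa <- simulate_msa(15, 30, modal_fraction = 0.4, seed = 10)
  pos <- 1:30
  cand <- msa$ids[15]
  refs <- msa$ids[1:6]
  scores <- vapply(seq_along(refs), function(k) {
    dv_score(cand, msa, refs[1:k], pos)$score
  }, integer(1))
  expect_true(all(diff(scores) <= 0))
  # equal to a reference on the positions -> score 0
  expect_equal(dv_score(refs[1], msa, refs, pos)$score, 0L)
})

test_that("pairwise scores restrict to contributing columns and can be asymmetric", {
  msa <- new_msa(c("r", "i", "j", "k"),
                 c("AAAA", "WWAA", "WYYA", "AAAA"))
  cards <- dv_scorecards(c("i", "j", "k"), msa, "r", 1:4)
  expect_equal(cards$i$score, 2L)
  expect_equal(cards$j$score, 3L)
  expect_equal(cards$k$score, 0L)
  m <- pairwise_dv_matrix(c("i", "j", "k"), cards, msa)
  # i's columns {1,2}: j matches at 1, differs at 2 -> s(i->j) = 1
  # j's columns {1,2,3}: i differs at 2? no: i=W,j=Y at col2; col3 A vs Y
  expect_equal(m["i", "j"], 1L)
  expect_equal(m["j", "i"], 2L)
  expect_false(isSymmetric(unclass(m)))
  expect_equal(unname(diag(m)), c(0L, 0L, 0L))
  # empty contributing set scores 0 against everyone
  expect_equal(unname(m["k", ]), c(0L, 0L, 0L))
  # exhaustive oracle over all pairs and columns
  for (a in c("i", "j", "k")) {
    for (b in c("i", "j", "k")) {
      if (a == b) next
      cols <- cards[[a]]$contributing_columns
      mm <- 0L
      for (cc in cols) {
        if (msa$mat[a, cc] != msa$mat[b, cc]) mm <- mm + 1L
      }
      expect_equal(unname(m[a, b]), mm)
    }
  }
})

test_that("grouping takes connected components of the mutual <cutoff graph", {
  ids <- c("x", "y", "z")
  m <- matrix(20L, 3, 3, dimnames = list(ids, ids))
  diag(m) <- 0L
  class(m) <- c("pairwise_dv_matrix", class(m))
  part_all_far <- group_candidates(m, cutoff = 9)
  expect_length(part_all_far$groups, 3L)
  # chain x-y and y-z below cutoff, x-z above: one component by closure
  m2 <- m
  m2["x", "y"] <- m2["y", "x"] <- 3L
  m2["y", "z"] <- m2["z", "y"] <- 5L
  part <- group_candidates(m2, cutoff = 9)
  expect_length(part$groups, 1L)
  expect_setequal(part$groups[[1]], ids)
  # one-sided closeness is not an edge (both directions must be < cutoff)
  m3 <- m
  m3["x", "y"] <- 2L # but y->x stays 20
  expect_length(group_candidates(m3, cutoff = 9)$groups, 3L)
  # singleton input
  m1 <- matrix(0L, 1, 1, dimnames = list("solo", "solo"))
  class(m1) <- c("pairwise_dv_matrix", class(m1))
  expect_length(group_candidates(m1)$groups, 1L)
})

test_that("grouping is invariant under candidate reordering", {
  msa <- make_cluster_msa(n_groups = 3, per_group = 4, n_pos = 15,
                          noise = 2, seed = 42)
  cands <- setdiff(msa$ids, c("REF_A", "REF_B", "REF_C"))
  cards <- dv_scorecards(cands, msa, c("REF_A", "REF_B", "REF_C"), 1:15)
  m_fwd <- pairwise_dv_matrix(cands, cards, msa)
  m_rev <- pairwise_dv_matrix(rev(cands), cards, msa)
  g_fwd <- group_candidates(m_fwd)
  g_rev <- group_candidates(m_rev)
  canon <- function(p) {
    s <- lapply(p$groups, sort)
    s[order(vapply(s, `[`, character(1), 1))]
  }
  expect_equal(canon(g_fwd), canon(g_rev))
})

test_that("planted clusters are recovered exactly", {
  for (seed in c(1, 7, 23)) {
    msa <- make_cluster_msa(n_groups = 3, per_group = 4, n_pos = 15,
                            noise = 2, seed = seed)
    truth <- attr(msa, "truth")
    cands <- names(truth)
    cards <- dv_scorecards(cands, msa, c("REF_A", "REF_B", "REF_C"), 1:15)
    m <- pairwise_dv_matrix(cands, cards, msa)
    part <- group_candidates(m, cutoff = 9)
    expect_length(part$groups, 3L)
    for (g in part$groups) expect_length(unique(truth[g]), 1L)
  }
})

test_that("shortlisting is strict and representatives follow policy", {
  msa <- new_msa(c("r", "lo", "hi1", "hi2"),
                 c(strrep("A", 12), paste0(strrep("W", 10), "AA"),
                   strrep("W", 12), paste0(strrep("Y", 11), "A")))
  cards <- dv_scorecards(c("lo", "hi1", "hi2"), msa, "r", 1:12)
  expect_equal(cards$lo$score, 10L)
  expect_setequal(dv_shortlist(cards, 10), c("hi1", "hi2"))
  part <- structure(list(groups = list(c("hi2", "hi1")),
                         membership = c(hi2 = 1L, hi1 = 1L), cutoff = 9L),
                    class = "group_partition")
  expect_equal(pick_representatives(part, "lex"), "hi1")
  expect_equal(pick_representatives(part, "max-score", scorecards = cards),
               "hi1") # 12 > 11
  expect_equal(pick_representatives(part, "manual", manual = "hi2"), "hi2")
  expect_error(pick_representatives(part, "nonsense"),
               class = "specswap_config_error")
})
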