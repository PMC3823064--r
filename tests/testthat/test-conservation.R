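test_that("column profiles count residues with gap-free modal fractions", {
  msa <- new_msa(c("a", "b", "c", "d"), c("AA-C", "AA-C", "AC-G", "A--T"))
  prof <- column_profiles(msa)
  expect_equal(prof$modal_fraction[1], 1)
  expect_equal(prof$gap_fraction[1], 0)
  # column 2: A,A,C,- -> modal A 2/3 over non-gaps, gap 1/4
  expect_equal(prof$modal_residue[2], "A")
  expect_equal(prof$modal_fraction[2], 2 / 3)
  expect_equal(prof$gap_fraction[2], 1 / 4)
  # all-gap column degenerates to modal 0
  expect_equal(prof$modal_fraction[3], 0)
  expect_equal(prof$gap_fraction[3], 1)
  expect_true(is.na(prof$modal_residue[3]))
  counts <- attr(prof, "counts")
  expect_true(all(colSums(counts) == 4))
})

test_that("q-scores hit the documented endpoints and frozen values", {
  msa <- new_msa(c("a", "b", "c"), c("AAV", "AAV", "AVV"))
  # fully conserved column (col 3) scores exactly 100; hand-evaluated
  # profile-space value for an A/A/V column is frozen below
  q <- qscores(msa)
  expect_equal(q[3], 100)
  expect_equal(q[2], 76.6606984685, tolerance = 1e-9)
  all_gap <- new_msa(c("a", "b"), c("A-", "C-"))
  expect_equal(qscores(all_gap)[2], 0)
  # gapped column A/A/C/- frozen from the same independent evaluation
  msa2 <- new_msa(c("a", "b", "c", "d"), c("AA", "AA", "AC", "A-"))
  expect_equal(qscores(msa2)[2], 52.5796120285, tolerance = 1e-9)
  expect_true(all(q >= 0 & q <= 100))
  expect_error(qscores(msa, matrix = "NOSUCH"),
               class = "specswap_config_error")
})

test_that("q-scores are invariant under row reordering and the modal scorer matches its formula", {
  msa <- simulate_msa(15, 25, modal_fraction = 0.6, gap_prob = 0.1, seed = 21)
  q1 <- qscores(msa)
  perm <- rev(msa$ids)
  q2 <- qscores(msa_subset(msa, perm))
  expect_equal(q1, q2)
  prof <- column_profiles(msa)
  expect_equal(qscores(msa, scorer = "modal"),
               100 * prof$modal_fraction * (1 - prof$gap_fraction))
})

test_that("conservation sums reduce to the naive loop", {
  q <- c(10, 40, 100, 100, 55.5)
  expect_equal(conservation_sum(q, 3), 100)
  expect_equal(conservation_sum(q, c(2, 5)), 40 + 55.5)
  set.seed(8)
  qq <- runif(50, 0, 100)
  pos <- sample(50, 16)
  naive <- 0
  for (p in pos) naive <- naive + qq[p]
  expect_equal(conservation_sum(qq, pos), naive)
  expect_equal(conservation_sum(rep(100, 20), 1:16), 1600)
  expect_error(conservation_sum(q, integer(0)), class = "specswap_config_error")
})

test_that("permutation test matches its degenerate closed forms", {
  q <- rep(5, 30)
  res <- permutation_test(q, 1:4, 1:30, n_perm = 50, seed = 1)
  expect_equal(res$p_value, 1)
  # observed strictly above every achievable null sum
  q2 <- c(rep(100, 3), rep(0, 27))
  res2 <- permutation_test(q2, 1:3, 1:30, n_perm = 200, seed = 2)
  expect_equal(res2$p_value, 1 / 201)
  expect_true(res2$null_max < res2$observed_sum)
})

test_that("permutation p approximates the exhaustive tail on a 5-column toy", {
  q <- c(9, 3, 7, 1, 5)
  obs <- c(1, 3) # sum 16
  subsets <- combn(5, 2)
  tail_exact <- mean(apply(subsets, 2, function(s) sum(q[s])) >= 16)
  n_perm <- 4000
  res <- permutation_test(q, obs, 1:5, n_perm = n_perm, seed = 31)
  p_expected <- (1 + n_perm * tail_exact) / (1 + n_perm)
  tol <- 3 * sqrt(tail_exact * (1 - tail_exact) / n_perm)
  expect_lt(abs(res$p_value - p_expected), tol + 1e-9)
})

test_that("permutation test is bit-reproducible and validates inputs", {
  q <- runif(40, 0, 100)
  a <- permutation_test(q, 1:5, 1:40, n_perm = 500, seed = 99)
  b <- permutation_test(q, 1:5, 1:40, n_perm = 500, seed = 99)
  expect_identical(a$null_sums, b$null_sums)
  expect_identical(a$p_value, b$p_value)
  expect_error(permutation_test(q, 1:5, 3:40, n_perm = 10, seed = 1),
               class = "specswap_config_error")
  expect_warning(
    permutation_test(q, 1:5, 3:40, n_perm = 10, seed = 1,
                     allow_outside = TRUE), "outside")
  expect_error(permutation_test(q, 1:30, 1:20, n_perm = 10, seed = 1),
               class = "specswap_config_error")
})

test_that("conserved sets use ceiling count thresholds", {
  # 12 sequences at level 0.75 -> a residue must appear in >= 9
  seqs <- c(rep("AC", 9), rep("CC", 3))
  msa <- new_msa(sprintf("s%02d", 1:12), seqs)
  cons <- conserved_set(msa, msa$ids, 0.75)
  expect_equal(attr(cons, "threshold"), 9)
  # column 1 sits exactly at the threshold (9 of 12 A), column 2 is uniform
  expect_setequal(as.integer(cons), c(1L, 2L))
  # one sequence fewer drops column 1 below ceiling(0.75 * 11) = 9? no:
  # with 11 sequences the threshold is still 9 but only 8 A remain
  cons11 <- conserved_set(msa, msa$ids[c(1:8, 10:12)], 0.75)
  expect_equal(attr(cons11, "threshold"), 9)
  expect_setequal(as.integer(cons11), 2L)
})

test_that("a 7-sequence subset needs 6 and single sequences conserve all non-gaps", {
  msa <- new_msa(sprintf("s%d", 1:7),
                 c(rep("AD-", 6), "CD-"))
  cons <- conserved_set(msa, msa$ids, 0.75)
  expect_equal(attr(cons, "threshold"), 6)
  expect_setequal(as.integer(cons), c(1L, 2L))
  one <- conserved_set(msa, "s7", 0.75)
  expect_setequal(as.integer(one), c(1L, 2L))
  expect_error(conserved_set(msa, character(0)), class = "specswap_config_error")
})

test_that("raising the conservation level never adds columns", {
  msa <- simulate_msa(20, 40, modal_fraction = runif(40, 0.3, 1),
                      gap_prob = 0.1, seed = 17)
  lv <- c(0.5, 0.65, 0.8, 0.95)
  sets <- lapply(lv, function(l) as.integer(conserved_set(msa, msa$ids, l)))
  for (i in seq_along(lv)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("venn partition separates group-specific conservation", {
  # identical groups: everything in the intersection
  msa <- new_msa(sprintf("s%d", 1:8), rep("ACDE", 8))
  v <- venn_partition(msa, msa$ids[1:4], msa$ids[5:8])
  expect_setequal(v$set_intersection, 1:4)
  expect_length(v$set_A_only, 0)
  expect_length(v$set_B_only, 0)
  # planted A-specific column: conserved W in group A, variable in B
  a_seqs <- c("AW", "AW", "AW", "AW")
  b_seqs <- c("AC", "AD", "AE", "AF")
  msa2 <- new_msa(c(sprintf("a%d", 1:4), sprintf("b%d", 1:4)),
                  c(a_seqs, b_seqs))
  v2 <- venn_partition(msa2, sprintf("a%d", 1:4), sprintf("b%d", 1:4))
  expect_true(2L %in% v2$set_A_only)
  expect_false(2L %in% v2$set_B_only)
  expect_true(1L %in% v2$set_intersection)
  # the three sets are pairwise disjoint
  expect_length(intersect(v2$set_A_only, v2$set_B_only), 0)
  expect_error(venn_partition(msa2, c("a1", "a2"), c("a2", "b1")),
               class = "specswap_input_error")
})

test_that("venn thresholds for 12+7 groups are 15/9/6", {
  msa <- simulate_msa(19, 10, modal_fraction = 0.8, gap_prob = 0, seed = 2)
  v <- venn_partition(msa, msa$ids[1:12], msa$ids[13:19])
  expect_equal(unname(v$thresholds), c(15, 9, 6))
})

test_that("percent identity counts shared ungapped columns", {
  msa <- new_msa(c("x", "y", "z"), c("ACD-", "ACE-", "ACD-"))
  expect_equal(percent_identity(msa, "x", "x"), 100)
  expect_equal(percent_identity(msa, "x", "y"), 100 * 2 / 3)
  expect_equal(percent_identity(msa, "x", "z"), 100)
  expect_error(percent_identity(msa, "x", "nope"),
               class = "specswap_input_error")
  m <- percent_identity_matrix(msa)
  expect_equal(m["x", "y"], m["y", "x"])
  expect_equal(diag(m), c(x = 100, y = 100, z = 100))
})
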