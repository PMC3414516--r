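# Identity statistics, group comparisons, catalytic-site conservation.

test_that("pairwise identity respects the denominator policy", {
  pa <- protein_alignment(c(x = "ACDE", y = "ACDF", z = "AC-E"))
  expect_equal(pairwise_identity(pa, "x", "x"), 100)
  expect_equal(pairwise_identity(pa, "x", "y"), 75)
  expect_equal(pairwise_identity(pa, "z", "x", "both_ungapped"), 100)
  expect_equal(pairwise_identity(pa, "z", "x", "alignment_length"), 75)
  gappy <- protein_alignment(c(a = "A---", b = "-CDE"))
  expect_error(pairwise_identity(gappy, "a", "b"), "undefined identity")
})

test_that("identity matrices are symmetric with a 100 diagonal", {
  pa <- toy_protein_alignment()
  m <- identity_matrix(pa)
  expect_equal(diag(unclass(m)), rep(100, 3), ignore_attr = TRUE)
  expect_equal(unclass(m), t(unclass(m)))
  # hand-computed entries (both-ungapped): s1/s2 share 5/5 compared,
  # s1/s3 share 3/5, s2/s3 share 4/6
  expect_equal(m["s1", "s2"], 100)
  expect_equal(m["s1", "s3"], 60)
  expect_equal(m["s2", "s3"], 100 * 4 / 6)
})

test_that("group distributions partition all unordered pairs", {
  pa <- protein_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  m <- identity_matrix(pa)
  cm <- c(a = "I", b = "I", c = "II", d = "II")
  st <- group_identity_stats(m, cm)
  sizes <- vapply(st$distributions, length, integer(1))
  expect_equal(unname(sizes), c(1L, 1L, 4L))
  expect_equal(sum(sizes), 4 * 3 / 2)
  expect_true(all(unlist(st$distributions) == 100))
  expect_error(group_identity_stats(m, cm[-1]), "missing class")
})

test_that("the independent t-test matches the pooled closed form", {
  r <- independent_t_test(c(1, 2, 3), c(4, 5, 6), variant = "pooled")
  expect_equal(abs(r$t), 3 * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(r$df, 4)
  # identical samples: defined degenerate result
  same <- independent_t_test(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # equal variance and size: Welch reduces to pooled
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  w <- independent_t_test(a, b, "welch")
  p <- independent_t_test(a, b, "pooled")
  expect_equal(w$t, p$t, tolerance = 1e-12)
  expect_equal(w$df, p$df, tolerance = 1e-9)
})

test_that("the column-permutation null separates real class structure", {
  # two sharply distinct classes: observed t should beat the shuffles
  ca <- sim_small_codon_alignment(60, seed = 29, omega = 0.4)
  pa <- translate_rows(ca)
  cm <- stats::setNames(rep(c("I", "II"), each = 4), pa$ids)
  r <- group_identity_permutation_test(pa, cm, n_perm = 30, seed = 2)
  expect_lt(r$p, 0.2)
  expect_length(r$permuted_t, 30)
  # determinism under the seed
  r2 <- group_identity_permutation_test(pa, cm, n_perm = 30, seed = 2)
  expect_identical(r$permuted_t, r2$permuted_t)
})

test_that("catalytic-site conservation counts absolutely conserved columns", {
  ref <- "MKVLEQ"
  pa <- protein_alignment(c(ref = "MKVLEQ", a1 = "MKVLEQ", a2 = "MKVLEQ",
                            b1 = "MKALEQ", b2 = "MKVLEQ"))
  cm <- c(a1 = "I", a2 = "I", b1 = "II", b2 = "II")
  res <- catalytic_site_conservation(pa, "ref", c(1, 3, 5), cm)
  expect_equal(res$counts[["I"]], 3L)
  expect_equal(res$counts[["II"]], 2L)  # column 3 broken by b1
  # reference with gaps: positions map through the gap
  pa2 <- protein_alignment(c(ref = "M-KV", a1 = "MAKV", b1 = "MAKQ"))
  res2 <- catalytic_site_conservation(pa2, "ref", c(2, 3),
                                      c(a1 = "I", b1 = "II"))
  expect_equal(res2$counts[["I"]], 2L)
  expect_equal(res2$counts[["II"]], 1L)
  expect_error(
    catalytic_site_conservation(pa2, "ref", 9, c(a1 = "I", b1 = "II")),
    "out of range")
})
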