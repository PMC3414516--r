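# GY94 building blocks: codon frequencies, rate matrix, transition
# probabilities.

test_that("codon frequency models behave at their boundary cases", {
  eq <- build_codon_freqs(model = "equal")
  expect_equal(unname(eq$pi), rep(1 / 61, 61))
  atg <- codon_alignment(matrix("ATG", 2, 3,
                                dimnames = list(c("a", "b"), NULL)))
  f <- build_codon_freqs(atg, "F3x4")
  expect_gt(f$pi[["ATG"]], 0.99)
  expect_equal(sum(f$pi), 1, tolerance = 1e-12)
})

test_that("F3x4 frequencies are positional products", {
  m <- rbind(a = c("ATG", "CTT"), b = c("ATG", "CTA"))
  f <- build_codon_freqs(codon_alignment(m), "F3x4")
  # position 1: A/C half each; position 3: G 1/2, T 1/4, A 1/4
  expect_equal(f$pi[["ATG"]] / f$pi[["CTG"]], 1, tolerance = 1e-4)
  expect_equal(f$pi[["ATG"]] / f$pi[["ATA"]], 2, tolerance = 1e-4)
  expect_equal(f$pi[["ATG"]] / f$pi[["ATT"]], 2, tolerance = 1e-4)
})

test_that("the rate matrix is reversible and correctly normalised", {
  ca <- sim_small_codon_alignment(50, seed = 23)
  freqs <- build_codon_freqs(ca, "F3x4")
  Q <- gy94_rate_matrix(kappa = 3, omega = 0.25, freqs)
  pi <- attr(Q, "pi")
  expect_equal(max(abs(rowSums(unclass(Q)))), 0, tolerance = 1e-12)
  expect_equal(-sum(pi * diag(unclass(Q))), 1, tolerance = 1e-12)
  # detailed balance pi_i q_ij = pi_j q_ji over all entries
  flux <- pi * unclass(Q)
  expect_equal(flux, t(flux), tolerance = 1e-14)
  # kappa = omega = 1 with equal frequencies: one shared off-diagonal rate
  Q1 <- gy94_rate_matrix(1, 1, build_codon_freqs(model = "equal"))
  offd <- unclass(Q1)[tpsevol:::codon_masks()$single]
  expect_equal(diff(range(offd)), 0, tolerance = 1e-14)
})

test_that("transition matrices satisfy CTMC identities", {
  freqs <- build_codon_freqs(model = "equal")
  Q <- gy94_rate_matrix(2, 0.3, freqs)
  P0 <- transition_matrix(Q, 0)
  expect_equal(unclass(P0), diag(61), tolerance = 1e-10, ignore_attr = TRUE)
  # long branches forget the starting state
  Pinf <- transition_matrix(Q, 100)
  for (i in c(1, 30, 61)) {
    expect_equal(unname(Pinf[i, ]), unname(attr(Q, "pi")), tolerance = 1e-6)
  }
  # semigroup property P(s+t) = P(s) P(t)
  lhs <- transition_matrix(Q, 0.3)
  rhs <- transition_matrix(Q, 0.1) %*% transition_matrix(Q, 0.2)
  expect_equal(lhs, rhs, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(transition_matrix(Q, -0.1), "non-negative")
})
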