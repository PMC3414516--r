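# Counting estimators: NG86 site/difference counting, the weighted
# YN00-style variant, domain scatter, paired domain test.

test_that("NG86 site fractions match hand enumeration", {
  s <- ng86_sites("TTT")
  expect_equal(s[["s"]], 1 / 3, tolerance = 1e-12)
  expect_equal(ng86_sites("ATG")[["s"]], 0)
  expect_equal(ng86_sites("ATG")[["n"]], 3)
  # partition of sites holds for every sense codon
  for (cd in sense_codons()) {
    x <- ng86_sites(cd)
    expect_equal(x[["s"]] + x[["n"]], 3, tolerance = 1e-12)
  }
  expect_error(ng86_sites("TAA"), "sense")
})

test_that("NG86 difference counting follows minimal pathways", {
  e0 <- ng86_pair("TTTAAA", "TTTAAA")
  expect_equal(e0$Sd + e0$Nd, 0)
  expect_equal(e0$dS, 0)
  expect_equal(e0$dN, 0)
  expect_true("undefined_dS0" %in% e0$flags)
  e1 <- ng86_pair("TTT", "TTC")
  expect_equal(e1$Sd, 1)
  expect_equal(e1$Nd, 0)
  expect_equal(e1$dN, 0)
  e2 <- ng86_pair("ATGAAA", "ATGAAG")
  expect_equal(e2$Sd, 1)
  expect_equal(e2$Nd, 0)
  # site partition S + N = 3L and symmetry under swapping
  p <- two_taxon_pair(100, seed = 13)
  a <- ng86_pair(p$s1, p$s2)
  b <- ng86_pair(p$s2, p$s1)
  expect_equal(a$S + a$N, 3 * 100, tolerance = 1e-9)
  expect_equal(a$dN, b$dN)
  expect_equal(a$dS, b$dS)
})

test_that("two-difference codons average over stop-avoiding pathways", {
  # TTT (Phe) vs GTA (Val): pathways TTT->GTT(V)->GTA(V) [1 syn step]
  # and TTT->TTA(L)->GTA(V) [0 syn steps]; equal weights -> Sd = 0.5
  e <- ng86_pair("TTT", "GTA")
  expect_equal(e$Sd, 0.5, tolerance = 1e-12)
  expect_equal(e$Nd, 1.5, tolerance = 1e-12)
})

test_that("the weighted estimator reduces to NG86 in the neutral limit", {
  p <- two_taxon_pair(400, seed = 5, kappa = 3)
  g <- ng86_pair(p$s1, p$s2)
  y <- yn00_pair(p$s1, p$s2, freqs = "equal", kappa = 1)
  expect_equal(y$dN, g$dN, tolerance = 1e-6)
  expect_equal(y$dS, g$dS, tolerance = 1e-6)
})

test_that("YN00-style omega estimates recover the simulated truth", {
  oms <- vapply(1:20, function(i) {
    p <- two_taxon_pair(500, t = 0.3, omega = 0.2, kappa = 2,
                        seed = 200 + i)
    yn00_pair(p$s1, p$s2)$omega
  }, numeric(1))
  expect_gt(stats::median(oms), 0.15)
  expect_lt(stats::median(oms), 0.25)
})

test_that("omega estimation error shrinks with sequence length", {
  err_at <- function(L) {
    oms <- vapply(1:30, function(i) {
      p <- two_taxon_pair(L, t = 0.3, omega = 0.2, kappa = 2,
                          seed = 300 + i)
      yn00_pair(p$s1, p$s2)$omega
    }, numeric(1))
    mean(abs(oms - 0.2))
  }
  e <- c(err_at(100), err_at(500), err_at(2000))
  expect_lt(e[2], e[1])
  expect_lt(e[3], e[2])
})

test_that("degenerate domain partitions give identical omegas per pair", {
  ca <- sim_small_codon_alignment(40, seed = 17)
  part <- structure(list(TPS = 1:20, TPP = 1:20, n_columns = 40L,
                         note = "degenerate"),
                    class = "domain_partition")
  tab <- domain_rate_scatter(ca, part, "NG86")
  defined <- !is.na(tab$omega_TPS) & !is.na(tab$omega_TPP)
  expect_true(any(defined))
  expect_equal(tab$omega_TPS[defined], tab$omega_TPP[defined])
})

test_that("the paired domain test matches the closed-form paired t", {
  tab0 <- data.frame(omega_TPS = c(0.1, 0.2, 0.15),
                     omega_TPP = c(0.1, 0.2, 0.15), valid = TRUE)
  expect_equal(paired_domain_test(tab0)$p, 1)
  tab1 <- data.frame(omega_TPS = c(0, 0, 0),
                     omega_TPP = c(0.1, 0.2, 0.15), valid = TRUE)
  r <- paired_domain_test(tab1)
  expect_equal(r$t, 0.15 / (0.05 / sqrt(3)), tolerance = 1e-9)
  expect_equal(r$df, 2)
})

test_that("relaxed TPP blocks push the scatter above the diagonal", {
  tr <- sim_default_tree(8, 0.8)
  spec <- simulation_spec(tr, kappa = 2, omega = 0.1, n_codons = 300,
                          seed = 31,
                          domains = list(TPS = c(200, 0.08),
                                         TPP = c(100, 0.14)))
  ca <- simulate_codon_alignment(spec)
  part <- domain_partition(c(1, 201), c(201, 301), 300)
  tab <- domain_rate_scatter(ca, part, "YN00")
  expect_gt(mean(tab$omega_TPP[tab$valid]), mean(tab$omega_TPS[tab$valid]))
})
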