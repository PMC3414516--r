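# Branch-model fitting and likelihood-ratio tests.

test_that("a one-ratio fit recovers the generating parameters", {
  tr <- ape::unroot(sim_default_tree(8, 1.0))
  ca <- simulate_codon_alignment(
    simulation_spec(tr, kappa = 2, omega = 0.1, n_codons = 400, seed = 77))
  fit <- fit_branch_model(tr, ca, "one_ratio", n_starts = 1)
  expect_true(fit$converged)
  expect_gt(fit$omega_by_class[["all"]], 0.07)
  expect_lt(fit$omega_by_class[["all"]], 0.13)
  expect_gt(fit$kappa, 1.4)
  expect_lt(fit$kappa, 2.8)
  expect_equal(fit$n_free_params, nrow(tr$edge) + 2)
  # S3 surface
  expect_output(print(fit), "one_ratio")
  expect_named(coef(fit), c("kappa", "omega_all"))
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), fit$loglik)
  expect_equal(attr(ll, "df"), fit$n_free_params)
})

test_that("the two-ratio model nests the one-ratio model", {
  tr <- ape::unroot(sim_default_tree(8, 1.0))
  fg <- paste0("t", 5:8)
  ca <- simulate_codon_alignment(
    simulation_spec(tr, kappa = 2, omega = 0.1, n_codons = 200, seed = 78))
  f0 <- fit_branch_model(tr, ca, "one_ratio", n_starts = 1)
  f1 <- fit_branch_model(tr, ca, "two_ratio", foreground = fg, n_starts = 1)
  expect_gte(f1$loglik, f0$loglik - 1e-6)
  lrt <- likelihood_ratio_test(f0, f1)
  expect_equal(lrt$df, 1)
  expect_gte(lrt$statistic, 0)
  expect_lte(lrt$p, 1)
})

test_that("LRT arithmetic matches the chi-squared oracle", {
  fake <- function(l, k) list(loglik = l, n_free_params = k,
                              data_digest = "d")
  r <- likelihood_ratio_test(fake(0, 10), fake(3.841 / 2, 11))
  expect_equal(r$statistic, 3.841)
  expect_equal(r$p, 0.05, tolerance = 1e-3)
  same <- likelihood_ratio_test(fake(-5, 10), fake(-5, 11))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  # negative excursions from optimiser noise are clipped
  clip <- likelihood_ratio_test(fake(-5, 10), fake(-5 - 1e-9, 11))
  expect_equal(clip$statistic, 0)
  expect_error(likelihood_ratio_test(fake(0, 11), fake(0, 10)),
               "more free parameters")
  mismatch <- fake(0, 11); mismatch$data_digest <- "other"
  expect_error(likelihood_ratio_test(fake(0, 10), mismatch), "checksum")
})

test_that("simulate() on a fit round-trips through the estimator", {
  tr <- ape::unroot(sim_default_tree(8, 1.0))
  ca <- simulate_codon_alignment(
    simulation_spec(tr, kappa = 2, omega = 0.15, n_codons = 150, seed = 80))
  fit <- fit_branch_model(tr, ca, "one_ratio", n_starts = 1)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "codon_alignment")
  expect_equal(ncol(sims[[1]]$mat), fit$nsites)
  expect_false(identical(sims[[1]]$mat, sims[[2]]$mat))
})

test_that("the suite flags a relaxed foreground clade", {
  tr <- ape::unroot(sim_default_tree(8, 1.0))
  fg <- paste0("t", 5:8)
  ca <- simulate_codon_alignment(
    simulation_spec(tr, kappa = 2, omega = c(0.08, 0.45), foreground = fg,
                    n_codons = 300, seed = 90,
                    domains = list(TPS = c(200, c(0.08, 0.45)),
                                   TPP = c(100, c(0.08, 0.45)))))
  part <- domain_partition(c(1, 201), c(201, 301), 300)
  suite <- run_table1_suite(
    ca, trees = list(list(label = "t", tree = tr, foreground = fg)),
    part = part, n_starts = 1, seed = 1)
  expect_equal(nrow(suite), 6)
  full <- suite[suite$region == "full_length" & suite$model == "two_ratio", ]
  expect_lt(full$p, 0.05)
  fit <- attr(suite, "fits")[["t.full_length"]]$two_ratio
  expect_gt(fit$omega_by_class[["foreground"]],
            fit$omega_by_class[["background"]])
})
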