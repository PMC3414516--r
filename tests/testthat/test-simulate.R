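# Generators: determinism, process correctness, closed loops.

test_that("the codon simulator is a pure function of spec and seed", {
  tr <- sim_default_tree(8, 1.0)
  s <- function() simulate_codon_alignment(
    simulation_spec(tr, kappa = 2, omega = 0.2, n_codons = 50, seed = 123))
  expect_identical(s()$mat, s()$mat)
  other <- simulate_codon_alignment(
    simulation_spec(tr, kappa = 2, omega = 0.2, n_codons = 50, seed = 124))
  expect_false(identical(s()$mat, other$mat))
  expect_error(simulation_spec(tr, omega = 0.2, n_codons = 10),
               "seed is mandatory")
})

test_that("simulated alignments hold only sense codons, no gaps", {
  ca <- sim_small_codon_alignment(200, seed = 66)
  expect_true(all(ca$mat %in% sense_codons()))
})

test_that("zero-length branches copy the root draw to every tip", {
  tr <- sim_default_tree(4, 1.0)
  tr$edge.length[] <- 0
  ca <- simulate_codon_alignment(
    simulation_spec(tr, kappa = 2, omega = 0.2, n_codons = 30, seed = 3))
  for (i in 2:4) expect_identical(ca$mat[i, ], ca$mat[1, ])
})

test_that("single-edge divergence matches the analytic expectation", {
  tr <- ape::read.tree(text = "(a:0.5,b:0);")
  spec <- simulation_spec(tr, kappa = 2, omega = 0.2, n_codons = 2000,
                          seed = 9)
  ca <- simulate_codon_alignment(spec)
  Q <- gy94_rate_matrix(2, 0.2, spec$freqs)
  P <- transition_matrix(Q, 0.5)
  pi <- attr(Q, "pi")
  p_expect <- 1 - sum(pi * diag(P))
  p_obs <- mean(ca$mat["a", ] != ca$mat["b", ])
  se <- sqrt(p_expect * (1 - p_expect) / 2000)
  expect_lt(abs(p_obs - p_expect), 3 * se)
})

test_that("gene-model generation is byte-deterministic", {
  path1 <- withr::local_tempfile(fileext = ".gff3")
  path2 <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(simulate_gene_models(c(I = 1, II = 1), seed = 21)$records,
                    path1)
  write_gene_models(simulate_gene_models(c(I = 1, II = 1), seed = 21)$records,
                    path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("noise-free expression fixtures close the fate loop", {
  fates <- c("shared_expression", "nonfunctionalization_candidate",
             "subfunctionalization_candidate", "divergent")
  pairs <- data.frame(gene1 = paste0("gA", 1:4), gene2 = paste0("gB", 1:4),
                      fate = fates, stringsAsFactors = FALSE)
  em <- simulate_expression_matrix(pairs, noise = 0, seed = 12)
  got <- vapply(seq_len(nrow(pairs)), function(k) {
    classify_duplicate_fate(pairs$gene1[k], pairs$gene2[k], em)
  }, character(1))
  expect_identical(got, fates)
})

test_that("mild call noise still recovers most fates", {
  # four conditions: with miscall rate 0.05 the chance that a pair's
  # 2 x 4 calls survive untouched is 0.95^8 ~ 0.66, and the decision
  # rule absorbs most single flips, putting expected recovery near 0.82;
  # averaged over replicates to damp the per-draw binomial noise
  fates <- rep(c("shared_expression", "nonfunctionalization_candidate",
                 "subfunctionalization_candidate", "divergent"), 25)
  pairs <- data.frame(gene1 = paste0("gA", seq_along(fates)),
                      gene2 = paste0("gB", seq_along(fates)),
                      fate = fates, stringsAsFactors = FALSE)
  recovery <- vapply(1:20, function(s) {
    em <- simulate_expression_matrix(pairs, conditions = paste0("c", 1:4),
                                     noise = 0.05, seed = 500 + s)
    got <- vapply(seq_len(nrow(pairs)), function(k) {
      classify_duplicate_fate(pairs$gene1[k], pairs$gene2[k], em)
    }, character(1))
    mean(got == fates)
  }, numeric(1))
  expect_gte(mean(recovery), 0.8)
})
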