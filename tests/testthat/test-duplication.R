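# Duplication mechanism and duplicate-fate classification rules.

gene_tab <- data.frame(
  gene_id = c("g1", "g2", "g3", "g4", "g5"),
  species = "sp",
  chromosome = c("chr1", "chr1", "chr2", "chr3", NA),
  start = c(10000, 25000, 500000, 100000, NA),
  end = c(15000, 30000, 520000, 140000, NA),
  stringsAsFactors = FALSE)

test_that("tandem and block-based mechanisms follow the rules", {
  expect_identical(
    classify_duplication_mechanism("g1", "g2", gene_tab), "tandem")
  # beyond 100 kb on different chromosomes: unknown without blocks
  expect_identical(
    classify_duplication_mechanism("g1", "g3", gene_tab), "unknown")
  blocks <- data.frame(chromA = "chr1", startA = 1, endA = 50000,
                       chromB = "chr2", startB = 400000, endB = 600000,
                       stringsAsFactors = FALSE)
  expect_identical(
    classify_duplication_mechanism("g1", "g3", gene_tab, blocks),
    "whole_genome_block")
  # block order must not matter
  expect_identical(
    classify_duplication_mechanism("g3", "g1", gene_tab, blocks),
    "whole_genome_block")
  blocks$mechanism <- "segmental"
  expect_identical(
    classify_duplication_mechanism("g1", "g3", gene_tab, blocks),
    "segmental")
  # missing coordinates are not an error
  expect_identical(
    classify_duplication_mechanism("g1", "g5", gene_tab), "unknown")
})

test_that("expression fates follow the decision rule", {
  m <- rbind(
    broadA = rep(1, 6), broadB = rep(1, 6),      # shared
    keepA  = rep(1, 6), deadB  = rep(0, 6),      # nonfunctionalization
    fullA  = rep(1, 6), partB  = c(1, 1, 0, 0, 0, 0),  # subfunctionalization
    leftA  = c(1, 1, 1, 0, 0, 0), rightB = c(0, 0, 0, 1, 1, 1))  # divergent
  colnames(m) <- paste0("c", 1:6)
  em <- expression_matrix(m)
  expect_identical(classify_duplicate_fate("broadA", "broadB", em),
                   "shared_expression")
  expect_identical(classify_duplicate_fate("keepA", "deadB", em),
                   "nonfunctionalization_candidate")
  expect_identical(classify_duplicate_fate("fullA", "partB", em),
                   "subfunctionalization_candidate")
  expect_identical(classify_duplicate_fate("partB", "fullA", em),
                   "subfunctionalization_candidate")
  expect_identical(classify_duplicate_fate("leftA", "rightB", em),
                   "divergent")
  expect_identical(classify_duplicate_fate("broadA", "absent", em),
                   "unknown")
})

test_that("missing calls are excluded from the assayed conditions", {
  m <- matrix(c(1, 1, 1, NA,
                1, 1, 1, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("c", 1:4)))
  em <- expression_matrix(m)
  # condition 4 is missing for `a`, so both genes look broad
  expect_identical(classify_duplicate_fate("a", "b", em),
                   "shared_expression")
})

test_that("annotate_duplicate_pairs combines mechanism and fate", {
  pairs <- data.frame(gene1 = "g1", gene2 = "g2", species = "sp",
                      stringsAsFactors = FALSE)
  em <- expression_matrix(matrix(1, 2, 4,
                                 dimnames = list(c("g1", "g2"),
                                                 paste0("c", 1:4))))
  ann <- annotate_duplicate_pairs(pairs, gene_tab, em)
  expect_identical(ann$mechanism, "tandem")
  expect_identical(ann$fate, "shared_expression")
})
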