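# Sequence plumbing: translation, back-translation, gap masking.

test_that("translation follows the standard code and stop conventions", {
  expect_identical(translate_cds("ATG"), "M")
  expect_identical(translate_cds("ATGTTTTAA"), "MF")
  expect_error(translate_cds("ATGTAATTT"), "premature stop")
  expect_error(translate_cds("ATGXA T"), "invalid sequence")
  expect_error(translate_cds("ATGC"), "multiple of 3")
})

test_that("back-translation maps residues to source codons", {
  pa <- protein_alignment(c(a = "M-A", b = "MFA"))
  ca <- back_translate(pa, c(a = "ATGGCT", b = "ATGTTCGCA"))
  expect_identical(unname(ca$mat["a", ]), c("ATG", "---", "GCT"))
  expect_identical(unname(ca$mat["b", ]), c("ATG", "TTC", "GCA"))
  expect_error(
    back_translate(protein_alignment(c(a = "MA")), c(a = "ATGGC")),
    "backtranslation error")
  expect_error(
    back_translate(protein_alignment(c(a = "MV")), c(a = "ATGGCA")),
    "residue 2")
})

test_that("back-translation round-trips the stop-trimmed CDS", {
  ca0 <- sim_small_codon_alignment(40, seed = 7)
  # inject gaps: delete codon 5 from the first row, align with a gap
  cds <- apply(ca0$mat, 1, paste0, collapse = "")
  cds[1] <- paste0(ca0$mat[1, -5], collapse = "")
  prot <- vapply(cds, translate_cds, character(1))
  rows <- vapply(seq_along(prot), function(i) {
    if (i == 1) paste0(substr(prot[i], 1, 4), "-", substr(prot[i], 5, 39))
    else prot[i]
  }, character(1))
  pa <- protein_alignment(stats::setNames(rows, names(cds)))
  ca <- back_translate(pa, cds)
  for (id in ca$ids) {
    rebuilt <- paste0(ca$mat[id, ca$mat[id, ] != "---"], collapse = "")
    expect_identical(rebuilt, unname(cds[id]))
  }
})

test_that("complete deletion removes exactly the gapped columns", {
  m <- rbind(a = c("ATG", "---", "TTT"), b = c("ATG", "AAA", "TTT"))
  ca <- codon_alignment(m)
  cd <- mask_gapped_columns(ca, "complete_deletion")
  expect_equal(ncol(cd$mat), 2)
  expect_false(any(cd$mat == "---"))
  # gap-free alignment passes through unchanged
  free <- sim_small_codon_alignment(10, seed = 3)
  expect_identical(mask_gapped_columns(free, "complete_deletion")$mat,
                   free$mat)
  # every column gapped somewhere -> error (3 rows, one gap per column)
  m3 <- rbind(a = c("---", "AAA", "TTT"), b = c("ATG", "---", "TTT"),
              c = c("ATG", "AAA", "---"))
  expect_error(mask_gapped_columns(codon_alignment(m3)), "empty alignment")
})

test_that("pairwise deletion returns per-pair comparable columns", {
  m <- rbind(a = c("ATG", "---", "TTT"), b = c("ATG", "AAA", "TTT"),
             c = c("ATG", "AAA", "---"))
  sets <- mask_gapped_columns(codon_alignment(m), "pairwise_deletion")
  expect_equal(sets[["a|b"]], c(1L, 3L))
  expect_equal(sets[["a|c"]], 1L)
  expect_equal(sets[["b|c"]], c(1L, 2L))
})

test_that("ambiguous codons count as gaps for masking", {
  m <- rbind(a = c("ATG", "ANA", "TTT"), b = c("ATG", "AAA", "TTT"))
  cd <- mask_gapped_columns(codon_alignment(m), "complete_deletion")
  expect_equal(ncol(cd$mat), 2)
})

test_that("codon alignments survive a PHYLIP round trip", {
  ca <- sim_small_codon_alignment(15, seed = 9)
  path <- withr::local_tempfile(fileext = ".phy")
  write_phylip(ca, path)
  back <- read_codon_alignment(path)
  expect_identical(back$mat, ca$mat)
})

test_that("domain partitions enforce disjoint in-bounds ranges", {
  p <- domain_partition(c(1, 6), c(6, 11), 12)
  expect_equal(p$TPS, 1:5)
  expect_equal(p$TPP, 6:10)
  expect_error(domain_partition(c(1, 7), c(6, 11), 12), "overlap")
  expect_error(domain_partition(c(1, 6), c(6, 14), 12), "bounds")
})
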