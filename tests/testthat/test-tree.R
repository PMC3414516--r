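# JTT distances, neighbour joining, bootstrap support, duplicate pairs
# and ancestral-lineage counting.

test_that("JTT distances behave like an ML distance", {
  s <- paste0(rep("ARNDCQEGHILKMFPSTWYV", 10), collapse = "")
  expect_equal(jtt_distance(s, s), 0)
  p <- two_taxon_pair(150, t = 0.4, seed = 44)
  a <- translate_cds(paste0(p$s1, collapse = ""))
  b <- translate_cds(paste0(p$s2, collapse = ""))
  expect_equal(jtt_distance(a, b), jtt_distance(b, a), tolerance = 1e-6)
  # grid-search oracle over t on the same pairwise likelihood surface
  d <- jtt_distance(a, b)
  grid <- seq(max(d - 0.05, 1e-4), d + 0.05, by = 1e-4)
  ll <- vapply(grid, function(t) {
    P <- tpsevol:::jtt_pmat(t)
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    sum(log(P[cbind(match(ac, tpsevol:::JTT_AA),
                    match(bc, tpsevol:::JTT_AA))]))
  }, numeric(1))
  expect_equal(d, grid[which.max(ll)], tolerance = 2e-4)
  expect_error(jtt_distance("---", "AAA"), "no comparable")
})

test_that("JTT distances agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  p <- two_taxon_pair(200, t = 0.5, seed = 45)
  a <- strsplit(translate_cds(paste0(p$s1, collapse = "")), "")[[1]]
  b <- strsplit(translate_cds(paste0(p$s2, collapse = "")), "")[[1]]
  pd <- phangorn::phyDat(rbind(x = a, y = b), type = "AA")
  ref <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))["x", "y"]
  mine <- jtt_distance(paste0(a, collapse = ""), paste0(b, collapse = ""))
  expect_equal(mine, ref, tolerance = 5e-3)
})

test_that("NJ recovers additive trees and closed-form 3-taxon lengths", {
  # additive matrix on ((a,b),(c,d)) with internal branch 2
  dm <- matrix(c(0, 3, 8, 9,
                 3, 0, 9, 10,
                 8, 9, 0, 5,
                 9, 10, 5, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(dm)
  expect_true(ape::is.monophyletic(ape::root(tr, "d"), c("a", "b")))
  expect_equal(sum(tr$edge.length), 13)  # 1+2+2+3 tips + internal 5
  # 3 taxa: unique resolution with exact branch lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  len <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(len[["a"]], 1)
  expect_equal(len[["b"]], 1)
  expect_equal(len[["c"]], 2)
  # permuting taxa leaves the unrooted topology unchanged
  perm <- c(3, 1, 4, 2)
  tr2 <- nj_tree(dm[perm, perm])
  expect_equal(ape::dist.topo(tr, tr2), 0, ignore_attr = TRUE)
  expect_error(nj_tree(dm * NA), "finite")
})

test_that("bootstrap support is deterministic and saturates on clean data", {
  tr <- sim_default_tree(6, 1.2)
  ca <- simulate_codon_alignment(
    simulation_spec(tr, kappa = 2, omega = 0.3, n_codons = 250, seed = 50))
  pa <- translate_rows(ca)
  b1 <- bootstrap_support(pa, n_reps = 20, seed = 99)
  b2 <- bootstrap_support(pa, n_reps = 20, seed = 99)
  expect_identical(b1$node.label, b2$node.label)
  sup <- as.numeric(b1$node.label[-1])
  expect_true(all(sup == 100))
  # single replicate can only give 0 or 100
  b3 <- bootstrap_support(pa, n_reps = 1, seed = 7)
  expect_true(all(as.numeric(b3$node.label[-1]) %in% c(0, 100)))
})

test_that("same-species cherries are called as duplicate pairs", {
  t1 <- ape::read.tree(text = "((aTPS1:1,bTPS1:1):1,(cTPS1:1,dTPS1:1):1);")
  expect_equal(nrow(find_species_duplicate_pairs(t1)), 0)
  t2 <- ape::read.tree(text = "((aTPS1:1,aTPS2:1):1,cTPS1:1);")
  p2 <- find_species_duplicate_pairs(t2)
  expect_equal(p2$gene1, "aTPS1")
  expect_equal(p2$gene2, "aTPS2")
  # polytomy members are reported, not auto-paired
  t3 <- ape::read.tree(text = "(aTPS1:1,aTPS2:1,aTPS3:1,(bTPS1:1,bTPS2:1):1);")
  p3 <- find_species_duplicate_pairs(t3)
  expect_equal(nrow(p3), 1)
  expect_setequal(attr(p3, "polytomy_leaves"),
                  c("aTPS1", "aTPS2", "aTPS3"))
  # calls survive leaf rotation
  t2r <- ape::read.tree(text = "(cTPS1:1,(aTPS2:1,aTPS1:1):1);")
  expect_equal(find_species_duplicate_pairs(t2r)$gene1, "aTPS1")
})

test_that("ancestral lineage counting merges opposite-side sisters", {
  side <- c(r1 = "monocot", r2 = "monocot", d1 = "dicot", d2 = "dicot",
            d3 = "dicot", d4 = "dicot")
  t1 <- ape::read.tree(text = "((r1:1,d1:1):1,(r2:1,d2:1):1);")
  expect_equal(count_ancestral_lineages(t1, side)$count, 2)
  # one-sided tree of any shape collapses to one lineage
  t2 <- ape::read.tree(text = "((d1:1,d2:1):1,(d3:1,d4:1):1);")
  expect_equal(count_ancestral_lineages(t2, side)$count, 1)
  # a dicot-only subclade counts as its own (loss-implying) group
  t3 <- ape::read.tree(
    text = "(((r1:1,d1:1):1,(r2:1,d2:1):1):1,(d3:1,d4:1):1);")
  r3 <- count_ancestral_lineages(t3, side)
  expect_equal(r3$count, 3)
  # monotonicity: pruning a whole orthologous group drops the count by 1
  pruned <- ape::drop.tip(t3, c("d3", "d4"))
  expect_equal(count_ancestral_lineages(pruned, side)$count, 2)
  expect_error(count_ancestral_lineages(t3, side[-1]), "unmapped")
})
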