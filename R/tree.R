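# Tree construction and family-evolution analysis: JTT-distance
# neighbour joining with bootstrap support, species duplicate-pair
# discovery (same-species cherries), and the minimum count of ancestral
# lineages at the monocot-dicot split.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining (via [ape::nj()]) on a symmetric distance
#' matrix; the result is unrooted.
#'
#' @param d Symmetric numeric matrix or `dist` with >= 3 taxa.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("need at least 3 taxa")
  if (any(!is.finite(m))) stop("distances must be finite")
  if (any(m < 0)) stop("distances must be non-negative")
  ape::nj(stats::as.dist(m))
}

#' Protein tree with bootstrap support
#'
#' Builds the point-estimate tree with a distance builder (default: NJ
#' on pairwise JTT ML distances), then resamples alignment columns with
#' replacement `n_reps` times and scores each bipartition of the
#' point-estimate tree by the percentage of replicate trees containing
#' it. Supports are stored in `$node.label` (root position empty).
#'
#' @param pa A [protein_alignment()].
#' @param builder Function `protein_alignment -> phylo`.
#' @param n_reps Bootstrap replicates (the family analysis used 100).
#' @param seed Seed for the resampling; logged as an attribute.
#' @return `phylo` tree with percentage supports in `node.label`.
#' @export
bootstrap_support <- function(pa,
                              builder = function(x) nj_tree(jtt_distance_matrix(x)),
                              n_reps = 100, seed = 1) {
  main <- builder(pa)
  set.seed(seed)
  ncol_aln <- ncol(pa$mat)
  part_main <- ape::prop.part(main)
  boot_trees <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    bp <- protein_alignment(pa$mat[, cols, drop = FALSE])
    boot_trees[[b]] <- builder(bp)
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(main, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  main$node.label <- as.character(support)
  if (length(main$node.label) > 0) main$node.label[1] <- ""
  attr(main, "bootstrap_seed") <- seed
  attr(main, "n_reps") <- n_reps
  main
}

#' Same-species duplicate pairs (cherries)
#'
#' A recently duplicated pair is operationalised as a cherry (two-leaf
#' sister clade) whose leaves belong to one species. Leaves inside
#' polytomies are reported but not auto-paired.
#'
#' @param tree `phylo` tree.
#' @param species_map Named vector leaf id -> species; by default the
#'   species is parsed from the id prefix (letters before "TPS").
#' @return Data frame of class `duplicate_pairs`: gene1, gene2, species;
#'   attribute `polytomy_leaves` lists leaves skipped inside polytomies.
#' @export
find_species_duplicate_pairs <- function(tree, species_map = NULL) {
  if (is.null(species_map)) {
    species_map <- stats::setNames(sub("TPS.*$", "", tree$tip.label),
                                   tree$tip.label)
  }
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  ntip <- length(tree$tip.label)
  rows <- list()
  polytomy <- character(0)
  for (node in names(kids)) {
    ch <- kids[[node]]
    leaf_ch <- ch[ch <= ntip]
    if (length(ch) == 2 && length(leaf_ch) == 2) {
      g <- tree$tip.label[leaf_ch]
      if (species_map[[g[1]]] == species_map[[g[2]]]) {
        g <- sort(g)
        rows[[length(rows) + 1L]] <- data.frame(
          gene1 = g[1], gene2 = g[2], species = species_map[[g[1]]],
          stringsAsFactors = FALSE)
      }
    } else if (length(ch) > 2 && length(leaf_ch) >= 2) {
      polytomy <- c(polytomy, tree$tip.label[leaf_ch])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene1 = character(0), gene2 = character(0),
               species = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$gene1), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("duplicate_pairs", "data.frame")
  attr(out, "polytomy_leaves") <- unique(polytomy)
  out
}

#' Minimum number of ancestral lineages at the monocot-dicot split
#'
#' Finds all maximal clades whose leaves are drawn from one side
#' (monocot or dicot), merges any two maximal clades of opposite sides
#' that are sisters into one orthologous group, and counts the groups:
#' the minimum number of family members in the monocot-dicot common
#' ancestor under a duplication/loss parsimony argument.
#'
#' @param tree Rooted `phylo` tree (root with the outgroup, then drop
#'   it, before calling).
#' @param side_map Named vector leaf id -> `"monocot"` / `"dicot"`.
#' @return List: `count`, and `groups` (list of leaf-id vectors, one per
#'   inferred ancestral lineage).
#' @export
count_ancestral_lineages <- function(tree, side_map) {
  miss <- setdiff(tree$tip.label, names(side_map))
  if (length(miss)) stop("unmapped leaves: ", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  side <- character(nnode)    # "monocot", "dicot" or "mixed"
  post <- ape::reorder.phylo(tree, "postorder")$edge
  side[seq_len(ntip)] <- unname(unlist(side_map[tree$tip.label]))
  for (e in seq_len(nrow(post))) {
    p <- post[e, 1]; c <- post[e, 2]
    side[p] <- if (side[p] == "") side[c]
               else if (side[p] == side[c]) side[p] else "mixed"
  }
  root <- post[nrow(post), 1]
  parent <- integer(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # maximal single-side clades: pure node whose parent is mixed (or root)
  maximal <- which(vapply(seq_len(nnode), function(v) {
    side[v] != "mixed" && side[v] != "" &&
      (v == root || side[parent[v]] == "mixed")
  }, logical(1)))
  leaves_of <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    tree$tip.label[intersect(clade_nodes(tree, v), seq_len(ntip))]
  }
  groups <- lapply(maximal, leaves_of)
  sides <- side[maximal]
  parents <- ifelse(maximal == root, NA_integer_, parent[maximal])
  merged <- rep(FALSE, length(maximal))
  out_groups <- list()
  for (i in seq_along(maximal)) {
    if (merged[i]) next
    j <- which(!merged & seq_along(maximal) != i &
                 parents == parents[i] & !is.na(parents) &
                 !is.na(parents[i]) & sides != sides[i])
    # sisters of opposite side under a binary parent merge into one group
    if (length(j) >= 1 &&
        length(kids[[as.character(parents[i])]]) == 2) {
      j <- j[1]
      out_groups[[length(out_groups) + 1L]] <- c(groups[[i]], groups[[j]])
      merged[c(i, j)] <- TRUE
    } else {
      out_groups[[length(out_groups) + 1L]] <- groups[[i]]
      merged[i] <- TRUE
    }
  }
  list(count = length(out_groups), groups = out_groups)
}
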