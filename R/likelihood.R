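# Phylogenetic likelihood of a codon alignment under GY94: R-side
# preparation (pattern compression, edge classes, tip coding) around the
# C++ pruning engine.

# Compress alignment columns into site patterns. Cells that are not
# sense codons are coded -1 (ambiguous: unit partial likelihood).
codon_patterns <- function(ca, tip_order) {
  tb <- codon_tables()
  mat <- ca$mat[tip_order, , drop = FALSE]
  idx <- matrix(match(mat, tb$codons), nrow = nrow(mat)) - 1L  # 0-based
  idx[is.na(idx)] <- -1L
  key <- apply(idx, 2, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.numeric(table(key)[key[first]])
  list(tips = idx[, first, drop = FALSE], weights = weights,
       nsites = ncol(idx))
}

# Per-edge class vector (1-based) for a two-class branch model: all
# edges inside the clade spanned by the foreground leaves, plus its stem
# edge, are class 2; everything else class 1.
edge_classes <- function(tree, foreground = NULL) {
  if (is.null(foreground)) return(rep(1L, nrow(tree$edge)))
  tips <- match(foreground, tree$tip.label)
  if (anyNA(tips)) {
    stop("foreground leaves not in tree: ",
         paste(foreground[is.na(tips)], collapse = ", "))
  }
  if (length(tips) == 1) {
    cl <- rep(1L, nrow(tree$edge))
    cl[tree$edge[, 2] == tips] <- 2L
    return(cl)
  }
  mrca <- ape::getMRCA(tree, tips)
  desc <- clade_nodes(tree, mrca)
  below <- intersect(desc, seq_along(tree$tip.label))
  if (!setequal(below, tips)) {
    stop("foreground set is not monophyletic on the stored orientation")
  }
  cl <- rep(1L, nrow(tree$edge))
  cl[tree$edge[, 2] %in% desc] <- 2L
  cl
}

# All nodes of the clade rooted at `node` (including it).
clade_nodes <- function(tree, node) {
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  out
}

prep_likelihood_data <- function(tree, ca, foreground = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  miss <- setdiff(tree$tip.label, ca$ids)
  if (length(miss)) {
    stop("tree leaves absent from alignment: ", paste(miss, collapse = ", "))
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  pat <- codon_patterns(ca, tree$tip.label)
  masks <- codon_masks()
  list(tree = tree,
       edges = tree$edge - 1L,
       edge_class = edge_classes(tree, foreground) - 1L,
       tips = pat$tips, weights = pat$weights, nsites = pat$nsites,
       single = masks$single + 0L, ti = masks$ti + 0L, ns = masks$ns + 0L)
}

#' Pruning log-likelihood under the GY94 model
#'
#' Felsenstein-pruning log-likelihood of a codon alignment on a fixed
#' tree, with one omega per branch class. The tree's `edge.length` are
#' the branch lengths (expected substitutions per codon). The alignment
#' is expected to be gap-masked already (see [mask_gapped_columns()]);
#' remaining non-sense cells are treated as fully ambiguous.
#'
#' @param tree `phylo` tree (rooted or unrooted) whose tips match
#'   alignment ids.
#' @param ca A [codon_alignment()].
#' @param kappa Transition/transversion ratio.
#' @param omega Either a single omega or, with `foreground`, a length-2
#'   vector `c(background, foreground)`.
#' @param freqs A `codon_frequencies` object, or a model name passed to
#'   [build_codon_freqs()] with this alignment.
#' @param foreground Leaf ids spanning the foreground clade (its internal
#'   edges plus the stem edge take `omega[2]`).
#' @return Log-likelihood (numeric scalar).
#' @export
pruning_loglik <- function(tree, ca, kappa, omega, freqs = "F3x4",
                           foreground = NULL) {
  if (is.character(freqs)) freqs <- build_codon_freqs(ca, freqs)
  if (length(omega) > 1 && is.null(foreground)) {
    stop("multiple omegas need a foreground clade")
  }
  d <- prep_likelihood_data(tree, ca, foreground)
  if (is.null(d$tree$edge.length)) stop("tree has no branch lengths")
  res <- cpp_gy94_loglik(d$tips, d$weights, d$edges, d$tree$edge.length,
                         d$edge_class, kappa, as.numeric(omega),
                         as_pi(freqs), d$single, d$ti, d$ns, FALSE)
  res$loglik
}
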