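# Synthetic-data generators. Every generator is a pure function of its
# spec and seed, so each analysis stage can be validated on inputs with
# known truth: codon alignments evolved under branch-specific omega
# (optionally with distinct omegas on TPS/TPP column blocks), gene models
# with prescribed intron counts, and expression matrices realising
# prescribed duplicate-gene fates.

#' Default simulation tree
#'
#' A balanced 8-taxon tree of total depth 1.0 expected substitutions per
#' codon: small enough for fast likelihood work, deep enough that omega
#' is identifiable.
#'
#' @param n_taxa Number of tips (a power of 2 gives a balanced shape).
#' @param depth Root-to-tip path length.
#' @return A `phylo` tree with tip labels `t1 ... tn`.
#' @export
sim_default_tree <- function(n_taxa = 8, depth = 1.0) {
  balanced <- abs(log2(n_taxa) - round(log2(n_taxa))) < 1e-9
  tree <- ape::stree(n_taxa, type = if (balanced) "balanced" else "left")
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  tree$edge.length <- rep(1, nrow(tree$edge))
  # scale so the deepest root-to-tip path equals `depth`
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length *
    depth / max(depths[seq_len(n_taxa)])
  tree
}

#' Specification for a codon-alignment simulation
#'
#' @param tree `phylo` with branch lengths.
#' @param kappa Transition/transversion ratio.
#' @param omega Single omega, or `c(background, foreground)` with a
#'   `foreground` clade.
#' @param foreground Leaf ids of the foreground clade (edges inside it
#'   plus the stem evolve under `omega[2]`).
#' @param freqs `codon_frequencies`, or `NULL` for the package's default
#'   mildly AT-rich root distribution (F3x4 with A/T 0.3, C/G 0.2 at
#'   every position).
#' @param n_codons Alignment length in codons.
#' @param domains Optional list `list(TPS = c(len, omega), TPP = c(len,
#'   omega))`: contiguous column blocks (TPS block first, matching the
#'   N-terminal TPS / C-terminal TPP architecture) evolved under
#'   block-specific omegas; overrides `omega` per block.
#' @param seed Mandatory integer seed.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(tree, kappa = 2, omega = 0.2,
                            foreground = NULL, freqs = NULL,
                            n_codons = 300, domains = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (any(c(kappa, omega) < 0)) stop("rates must be non-negative")
  if (is.null(freqs)) freqs <- default_sim_freqs()
  structure(list(tree = tree, kappa = kappa, omega = omega,
                 foreground = foreground, freqs = freqs,
                 n_codons = n_codons, domains = domains,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

default_sim_freqs <- function() {
  tb <- codon_tables()
  ntf <- c(T = 0.3, C = 0.2, A = 0.3, G = 0.2)
  cd <- do.call(rbind, strsplit(tb$codons, ""))
  pi <- ntf[cd[, 1]] * ntf[cd[, 2]] * ntf[cd[, 3]]
  pi <- pi / sum(pi)
  structure(list(model = "F3x4", pi = stats::setNames(pi, tb$codons)),
            class = "codon_frequencies")
}

# Evolve one column block under a fixed per-class omega set. The tree
# must already be in postorder with edge_class aligned to its edge rows.
sim_block <- function(d_tree, kappa, omegas, edge_class, pi, n_codons) {
  masks <- codon_masks()
  ntip <- length(d_tree$tip.label)
  nnode <- ntip + d_tree$Nnode
  root <- d_tree$edge[nrow(d_tree$edge), 1]
  states <- matrix(NA_integer_, nnode, n_codons)
  states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)
  # distinct (class, length) combinations share a transition matrix
  key <- paste(edge_class, signif(d_tree$edge.length, 12))
  Pcache <- new.env(parent = emptyenv())
  for (e in rev(seq_len(nrow(d_tree$edge)))) {  # preorder: parent known
    p <- d_tree$edge[e, 1]; c <- d_tree$edge[e, 2]
    k <- key[e]
    P <- Pcache[[k]]
    if (is.null(P)) {
      P <- cpp_gy94_pmat(kappa, omegas[edge_class[e]], pi,
                         masks$single + 0L, masks$ti + 0L, masks$ns + 0L,
                         d_tree$edge.length[e])
      Pcache[[k]] <- P
    }
    par_states <- states[p, ]
    child <- integer(n_codons)
    for (s in unique(par_states)) {
      idx <- which(par_states == s)
      child[idx] <- sample.int(61, length(idx), replace = TRUE,
                               prob = P[s, ])
    }
    states[c, ] <- child
  }
  list(tips = states[seq_len(ntip), , drop = FALSE],
       labels = d_tree$tip.label)
}

#' Simulate a codon alignment under GY94
#'
#' Draws root codons from the equilibrium distribution and evolves them
#' along the tree, each edge sampling from the transition matrix of its
#' branch class. With a `domains` layout, the TPS and TPP column blocks
#' are evolved under their own omegas. Deterministic given the spec seed;
#' simulated alignments contain no gaps and no stop codons.
#'
#' @param spec A [simulation_spec()].
#' @return A [codon_alignment()] with attribute `truth` (the spec).
#' @export
simulate_codon_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  tb <- codon_tables()
  pi <- as_pi(spec$freqs)
  post_tree <- ape::reorder.phylo(spec$tree, "postorder")
  ecl <- edge_classes(post_tree, spec$foreground)
  blocks <- if (is.null(spec$domains)) {
    list(list(n = spec$n_codons, omega = spec$omega))
  } else {
    lapply(spec$domains, function(b) list(n = b[1], omega = b[-1]))
  }
  mats <- lapply(blocks, function(b) {
    omegas <- if (length(b$omega) >= max(ecl)) b$omega
              else rep(b$omega[1], max(ecl))
    sim_block(post_tree, spec$kappa, omegas, ecl, pi, b$n)
  })
  tipmat <- do.call(cbind, lapply(mats, `[[`, "tips"))
  lab <- mats[[1]]$labels
  out <- matrix(tb$codons[tipmat], nrow = nrow(tipmat),
                dimnames = list(lab, NULL))
  # return rows in the tree's tip.label order as given by the user
  out <- out[spec$tree$tip.label, , drop = FALSE]
  ca <- codon_alignment(out)
  attr(ca, "truth") <- spec
  ca
}

random_cds_codons <- function(n) {
  tb <- codon_tables()
  non_met_stop <- setdiff(tb$codons, "ATG")
  c("ATG", sample(non_met_stop, n - 1, replace = TRUE))
}

#' Simulate gene models with prescribed intron counts
#'
#' Generates, per class, gene models whose protein-coding region carries
#' the rule's intron count (default: 16 for class I, 2 for class II, the
#' structural signature of the family). Exon lengths are 60-300 nt with
#' a total CDS that is a multiple of 3; intron lengths are 80-2000 nt.
#' Returns the genome sequences and gene records; [write_gene_models()]
#' and [write_fasta()] serialise them as GFF3/FASTA.
#'
#' @param n_per_class Named vector, e.g. `c(I = 3, II = 5)`.
#' @param intron_rule Named vector class -> intron count.
#' @param seed Mandatory seed.
#' @param minus_strand_fraction Fraction of genes placed on the minus
#'   strand.
#' @return List with `records` (gene_record list), `genome` (named
#'   chromosome sequences) and `truth` (data frame gene_id, class,
#'   intron_count).
#' @export
simulate_gene_models <- function(n_per_class = c(I = 2, II = 2),
                                 intron_rule = c(I = 16L, II = 2L),
                                 seed, minus_strand_fraction = 0.3) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  set.seed(seed)
  records <- list()
  genome <- character(0)
  truth <- list()
  gi <- 0
  for (cl in names(n_per_class)) {
    n_introns <- intron_rule[[cl]]
    for (k in seq_len(n_per_class[[cl]])) {
      gi <- gi + 1
      id <- sprintf("SynTPS%d", gi)
      chrom <- sprintf("chr%d", gi)
      n_exons <- n_introns + 1L
      exon_len <- sample(60:300, n_exons, replace = TRUE)
      # pad the last exon so the CDS length is a multiple of 3
      rem <- sum(exon_len) %% 3
      if (rem != 0) exon_len[n_exons] <- exon_len[n_exons] + (3 - rem)
      intron_len <- if (n_introns > 0) sample(80:2000, n_introns,
                                              replace = TRUE) else integer(0)
      start <- sample(1000:5000, 1)
      starts <- integer(n_exons); ends <- integer(n_exons)
      pos <- start
      for (e in seq_len(n_exons)) {
        starts[e] <- pos
        ends[e] <- pos + exon_len[e] - 1L
        pos <- ends[e] + 1L + if (e <= n_introns) intron_len[e] else 0L
      }
      strand <- if (stats::runif(1) < minus_strand_fraction) "-" else "+"
      cds_cod <- random_cds_codons(sum(exon_len) / 3)
      cds <- paste0(cds_cod, collapse = "")
      # lay the CDS onto the genome strand-aware
      glen <- ends[n_exons] + 500L
      chrom_seq <- paste0(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                          collapse = "")
      placed <- if (strand == "+") cds else revcomp(cds)
      offset <- 0
      for (e in seq_len(n_exons)) {
        piece <- substr(placed, offset + 1, offset + exon_len[e])
        substr(chrom_seq, starts[e], ends[e]) <- piece
        offset <- offset + exon_len[e]
      }
      iv <- cbind(start = starts, end = ends)
      if (strand == "-") iv <- iv[rev(seq_len(n_exons)), , drop = FALSE]
      genome[chrom] <- chrom_seq
      records[[id]] <- gene_record(
        gene_id = id, cds = cds, chromosome = chrom,
        start = start, end = ends[n_exons], strand = strand,
        exons = iv, cds_intervals = iv, class_label = cl,
        validate_translation = FALSE)
      truth[[id]] <- data.frame(gene_id = id, class = cl,
                                intron_count = n_introns,
                                stringsAsFactors = FALSE)
    }
  }
  list(records = records, genome = genome,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Simulate an expression presence/absence matrix with prescribed fates
#'
#' Realises each duplicate pair's prescribed fate as a presence/absence
#' pattern over the conditions, then flips calls independently with the
#' given miscall probability. `shared_expression`: both copies expressed
#' everywhere; `nonfunctionalization_candidate`: one copy silent
#' everywhere; `subfunctionalization_candidate`: one copy broad, the
#' other restricted to a strict subset; `divergent`: the two copies
#' expressed in complementary halves of the conditions.
#'
#' @param pairs Data frame with columns `gene1`, `gene2`, `fate`.
#' @param conditions Character vector of condition labels.
#' @param noise Miscall probability in `[0, 0.5)`.
#' @param seed Mandatory seed.
#' @return An [expression_matrix()] with attribute `truth` = `pairs`.
#' @export
simulate_expression_matrix <- function(pairs,
                                       conditions = paste0("cond", 1:6),
                                       noise = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (noise < 0 || noise >= 0.5) stop("noise must be in [0, 0.5)")
  set.seed(seed)
  nc <- length(conditions)
  if (nc < 4) stop("need at least 4 conditions to realise all fates")
  genes <- c(rbind(pairs$gene1, pairs$gene2))
  m <- matrix(0L, length(genes), nc, dimnames = list(genes, conditions))
  for (k in seq_len(nrow(pairs))) {
    g1 <- pairs$gene1[k]; g2 <- pairs$gene2[k]
    fate <- pairs$fate[k]
    if (fate == "shared_expression") {
      m[g1, ] <- 1L; m[g2, ] <- 1L
    } else if (fate == "nonfunctionalization_candidate") {
      m[g1, ] <- 1L; m[g2, ] <- 0L
    } else if (fate == "subfunctionalization_candidate") {
      m[g1, ] <- 1L
      m[g2, ] <- 0L
      m[g2, seq_len(max(1, nc %/% 3))] <- 1L
    } else if (fate == "divergent") {
      half <- nc %/% 2
      m[g1, ] <- 0L; m[g2, ] <- 0L
      m[g1, seq_len(half)] <- 1L
      m[g2, (half + 1):nc] <- 1L
    } else {
      stop("unknown fate: ", fate)
    }
  }
  if (noise > 0) {
    flip <- matrix(stats::runif(length(m)) < noise, nrow(m))
    m[flip] <- 1L - m[flip]
  }
  em <- expression_matrix(m)
  attr(em, "truth") <- pairs
  em
}
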