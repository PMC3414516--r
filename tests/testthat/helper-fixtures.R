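# Shared fixture builders. Everything is generated in code; seeds are
# fixed so runs are reproducible.

toy_protein_alignment <- function() {
  protein_alignment(c(s1 = "MKV-LE", s2 = "MKVALE", s3 = "MRVALD"))
}

# A small gap-free codon alignment simulated on the default 8-taxon tree.
sim_small_codon_alignment <- function(n_codons = 60, seed = 42,
                                      omega = 0.2, kappa = 2) {
  tr <- sim_default_tree(8, 1.0)
  simulate_codon_alignment(
    simulation_spec(tr, kappa = kappa, omega = omega,
                    n_codons = n_codons, seed = seed))
}

translate_rows <- function(ca) {
  seqs <- apply(ca$mat, 1, function(r) translate_cds(paste0(r, collapse = "")))
  protein_alignment(seqs)
}

two_taxon_pair <- function(n_codons, t = 0.3, omega = 0.2, kappa = 2,
                           seed = 1) {
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
  ca <- simulate_codon_alignment(
    simulation_spec(tr, kappa = kappa, omega = omega,
                    n_codons = n_codons, seed = seed))
  list(s1 = ca$mat["a", ], s2 = ca$mat["b", ])
}

# Exhaustive-summation likelihood oracle for a 4-taxon tree
# ((t1,t2),t3,t4) with one inner node: sums over all 61^2 internal
# codon assignments.
exhaustive_loglik_4taxa <- function(tree_text, ca, kappa, omega, freqs) {
  # tree_text must be ((t1:a,t2:b):c,t3:d,t4:e); -- one inner node + root
  tr <- ape::read.tree(text = tree_text)
  Q <- gy94_rate_matrix(kappa, omega, freqs)
  pi <- attr(Q, "pi")
  len <- stats::setNames(tr$edge.length,
                         ifelse(tr$edge[, 2] <= 4,
                                tr$tip.label[tr$edge[, 2]], "inner"))
  P <- lapply(len, function(t) transition_matrix(Q, t))
  tb <- sense_codons()
  ll <- 0
  for (col in seq_len(ncol(ca$mat))) {
    s <- match(ca$mat[, col], tb)
    names(s) <- rownames(ca$mat)
    tot <- 0
    for (r in 1:61) {
      for (u in 1:61) {
        tot <- tot + pi[r] * P$inner[r, u] *
          P$t1[u, s["t1"]] * P$t2[u, s["t2"]] *
          P$t3[r, s["t3"]] * P$t4[r, s["t4"]]
      }
    }
    ll <- ll + log(unname(tot))
  }
  ll
}
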