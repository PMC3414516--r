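---
title: "Models and methods behind tpsevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tpsevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpsevol)
```

## The scientific setting

Plant trehalose-6-phosphate synthase (TPS) proteins carry an N-terminal
TPS (synthase) domain and a C-terminal TPP (phosphatase) domain, and the
gene family splits into two classes with sharply different gene
structures: class I genes carry 16 introns in the protein-coding region,
class II genes carry 2. tpsevol packages the analyses used to study how
such a family evolves — gene-structure classification, protein identity
statistics, catalytic-residue conservation, pairwise dN/dS with a
TPS/TPP domain partition, branch-specific codon-model tests, and
tree-based duplication and duplicate-fate analysis — together with
simulators that give every stage inputs with known truth.

## The codon substitution model

The likelihood machinery uses the Goldman–Yang (GY94) model on the 61
sense codons of the standard nuclear code (stop codons are excluded from
the state space; terminal stops are trimmed at ingestion and internal
stops are hard errors). For codons $i \ne j$ differing at exactly one
position,

$$
q_{ij} = \pi_j \,\kappa^{\mathbb{1}[\text{transition}]}\,
               \omega^{\mathbb{1}[\text{nonsynonymous}]},
$$

zero for multi-position changes, diagonal fixed by rows summing to zero,
and the generator scaled so that $-\sum_i \pi_i q_{ii} = 1$: branch
lengths are expected substitutions per codon. Because the chain is
reversible, $P(t) = e^{Qt}$ is computed by eigendecomposition in the
$\pi^{1/2}$-symmetrised basis; tiny negative entries from roundoff are
clipped and rows renormalised.

Equilibrium frequencies come from the alignment under `equal`, `F1x4`,
`F3x4` (default, the position-specific product used by most codon-model
software) or `empirical_codon`; zero-count categories are floored at a
pseudo-frequency of 1e-6 and renormalised so no sense codon becomes
unreachable.

### Likelihood and fitting

`pruning_loglik()` runs Felsenstein pruning over compressed site
patterns with per-node rescaling (C++/Armadillo). `fit_branch_model()`
maximises the likelihood over $\kappa$, one or two $\omega$ values and
all branch lengths with bounded L-BFGS-B: branch-length derivatives are
analytic (a combined down-pass/up-pass yields
$\partial \ln L/\partial t_e$ for every edge in roughly twice the cost
of one evaluation), while the two or three rate parameters use central
finite differences on the log scale. Bounds are
$\omega \in [10^{-6}, 50]$, $\kappa \in [10^{-3}, 100]$,
$t \in [10^{-6}, 50]$ (the tiny lower bound on $t$ keeps the numerical
machinery away from the $t = 0$ boundary). The default is one informed
start (the supplied tree's branch lengths, $\kappa = 2$,
$\omega = 0.2$) plus two jittered restarts; calibration studies in the
tests and the acceptance script use the single informed start, a choice
made because the one- and two-ratio surfaces at these problem sizes are
in practice unimodal and the analytic-gradient optimiser reaches the
same optimum from the informed start.

In the two-ratio model the foreground class is every edge inside the
designated clade **plus its stem edge**, the clade-labelling convention
of branch-model software; $\kappa$ is shared across branches and branch
lengths are re-optimised under each model. The LRT compares
$2\Delta\ell$ to $\chi^2_1$ (one extra $\omega$); a marginally negative
statistic from optimiser noise is clipped to zero. Fits carry a data
checksum so tests between fits of different data are refused.

Gap handling for tree-likelihood work defaults to complete deletion
(every column containing a gap or ambiguity is dropped); the retained
`"none"` mode treats non-sense cells as fully ambiguous tips and its
log-likelihoods are not comparable across gap policies.

## Pairwise rate estimation

`ng86_pair()` is classical Nei–Gojobori counting: per-position
synonymous-site fractions normalised over viable (non-stop) single-step
neighbours (so $S + N = 3L$ exactly), equal-weight averaging over all
minimal mutational pathways that avoid stops, and Jukes–Cantor
correction of $p_S$ and $p_N$. Proportions at or above 3/4 are flagged
`saturated`; $d_S = 0$ yields an `undefined_dS0` flag, never an
infinite ratio.

`yn00_pair()` is a YN00-flavoured weighted variant: $\kappa$ is
estimated from fourfold-degenerate third positions with K80 formulas
(falling back to all third positions, then to 1, with flags), and both
site counting and pathway averaging are weighted by
$\kappa^{\mathbb 1[\text{ti}]} \times f(\text{position, target
nucleotide})$ under F3x4 frequencies computed from the pair. Distances
are corrected with the same Jukes–Cantor transform as NG86. That choice
is deliberate: the package's contract is that with equal frequencies and
$\kappa = 1$ the weighted estimator coincides with NG86 to machine
precision, which pins down a common correction; $\omega$ likewise does
not enter pathway weights. The estimator is therefore not a
re-implementation of any particular program — it is validated instead
by parameter recovery on GY94 simulations (median $\hat\omega$ within
[0.15, 0.25] for truth 0.2 at 500 codons) and by its NG86 limit.

Domain-partitioned scatters (`domain_rate_scatter()`) use pairwise
deletion within each domain, flag undefined pairs rather than dropping
them, and exclude pairs with $d_S > 3$ (a saturation guard) from the
paired analysis; `paired_domain_test()` is a paired two-sided t-test on
$\omega_{TPP} - \omega_{TPS}$.

## Trees and family evolution

Pairwise protein distances are maximum-likelihood divergences under the
published Jones–Taylor–Thornton replacement model (exchangeabilities and
frequencies inlined as constants; the implementation is cross-checked in
the tests against an independent library). Trees come from standard
neighbour joining; bootstrap support resamples alignment columns and
scores the bipartitions of the point-estimate tree. ML topology search
is deliberately out of scope — downstream analyses accept any supplied
Newick topology, which is what the branch-model results actually depend
on.

Duplicate pairs are operationalised as same-species cherries; deeper
within-species clades are reported (as polytomy members) but not
auto-paired. Duplication mechanism follows a tandem rule (same
chromosome, facing-end distance at most 100 kb by default — the rule is
configurable because adjacency thresholds are a judgement call) and
otherwise a user-supplied paralogous-block table. The ancestral-lineage
count at the monocot–dicot split finds maximal single-side clades,
merges opposite-side sister pairs into one orthologous group, and counts
groups — a minimum count under duplication/loss parsimony; one-sided
subclades deliberately count as their own (loss-implying) group.

Expression-based fates use a strict decision rule over conditions
assayed in both copies: both broad → `shared_expression`; one silent →
`nonfunctionalization_candidate`; one broad and one restricted to a
strict non-empty subset → `subfunctionalization_candidate`; anything
else → `divergent`. "Broad" means expressed in every assayed condition;
no majority thresholds are applied, matching the absolute reading of
presence/absence assays.

## What the simulators emulate — and what they do not

`simulate_codon_alignment()` draws root codons from $\pi$ and evolves
them edge by edge from the exact transition matrices, honouring
branch-class $\omega$ and optional contiguous TPS/TPP column blocks
(N-terminal TPS block first, matching the domain architecture). The
default tree is an 8-taxon balanced tree of depth 1.0
substitutions/codon — fast and identifiable; non-power-of-two taxon
counts use a ladder shape scaled to the same depth. The default root
frequencies are a mildly AT-rich F3x4 profile (A/T 0.3, C/G 0.2 per
position), a realistic composition for plant nuclear genes. The
simulators generate no indels, no alignment error, no recombination and
no rate heterogeneity across sites beyond the domain blocks — so green
tests demonstrate correctness of the estimators under the assumed model,
not robustness to real-data misspecification.

`simulate_gene_models()` writes gene models with prescribed intron
counts (exons 60–300 nt summing to a multiple of 3, introns 80–2000 nt,
a configurable fraction on the minus strand), and
`simulate_expression_matrix()` realises prescribed duplicate fates with
an optional independent miscall probability. Every generator requires an
explicit seed and is a pure function of spec + seed.

## Problem sizes and numerical choices

The validation studies run at these sizes, chosen to make each effect
clearly detectable at desk scale: likelihood correctness on 4 taxa × 3
columns against exhaustive $61^2$ summation (tolerance 1e-10); LRT null
calibration with 200 one-ratio simulations (8 taxa, 300 codons,
$\omega = 0.1$, $\kappa = 2$) with the empirical 5% rejection rate
required to fall in [0.02, 0.09]; two-ratio recovery of the contrast
$\omega = 0.065$ vs $0.35$ over 20 replicates of 500 codons (median
within ±30%, ordering in ≥95%); domain relaxation of $\omega = 0.08$
vs $0.14$ (500 + 300 codons, 20 taxa) detected at $p < 0.01$ in ≥90% of
50 replicates; and exact closed loops for gene structure and expression
fates. The noisy-fate example uses four assay conditions: with a 5%
miscall rate the chance that a pair's 2 × 4 calls survive untouched is
$0.95^8 \approx 0.66$, and rule robustness lifts expected recovery to
about 0.82, which is why the four-condition layout (and not a wider one)
supports the ≥80% recovery statement.

Other numerical details: site patterns are compressed before pruning;
per-node partial likelihoods are rescaled per pattern; optimiser
convergence uses the L-BFGS-B relative tolerance (`factr = 1e7`) on top
of the analytic gradients; K80 $\kappa$ estimates with non-positive log
arguments fall back as described and are flagged; NJ ties are resolved
by the underlying implementation deterministically, and bootstrap seeds
are stored on the returned tree.

## Known limitations

The branch-model machinery implements one- and two-ratio models only (no
site or branch-site models) and codon frequencies are treated as fixed
quantities, not free parameters, in the parameter count. The weighted
pairwise estimator shares the limitations of all counting methods:
a small upward bias for $\omega$ at moderate divergence and instability
when very few sites are compared. The t-test on pairwise identities and
on per-pair $\omega$ differences reproduces standard practice but
ignores the non-independence of pairs sharing a sequence; treat its
p-values as descriptive. Tables printed by published analyses of real
families depend on unstated settings (frequency model, gap treatment,
$\kappa$ handling), so reproductions should be expected to be close
rather than bit-identical, and every report written by the pipeline
embeds the settings used.
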