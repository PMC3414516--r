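# Duplication-mechanism calls (tandem vs block-based duplication) and
# duplicate-gene fate classification from expression presence/absence
# patterns.

#' Classify the mechanism of a duplicate pair
#'
#' Tandem: both genes on one chromosome within the tandem distance rule
#' (default 100 kb between the facing ends of the two gene spans).
#' Otherwise, if the two genes fall into a pair of paralogous regions of
#' the block table, the block's mechanism is returned (default
#' `whole_genome_block`, the signature of whole-genome/segmental
#' duplication). Missing coordinates give `unknown`, not an error.
#'
#' @param gene1,gene2 Gene ids (same species).
#' @param gene_table Data frame with columns gene_id, chromosome, start,
#'   end.
#' @param block_table Optional data frame of paralogous segments:
#'   columns `chromA`, `startA`, `endA`, `chromB`, `startB`, `endB`,
#'   optional `mechanism`.
#' @param tandem_max_bp Tandem distance rule in bp (default 1e5).
#' @return One of `"tandem"`, `"segmental"`, `"whole_genome_block"`,
#'   `"unknown"`.
#' @export
classify_duplication_mechanism <- function(gene1, gene2, gene_table,
                                           block_table = NULL,
                                           tandem_max_bp = 1e5) {
  row_of <- function(g) {
    r <- gene_table[gene_table$gene_id == g, , drop = FALSE]
    if (nrow(r) != 1) NULL else r
  }
  r1 <- row_of(gene1); r2 <- row_of(gene2)
  coords_ok <- function(r) {
    !is.null(r) && !is.na(r$chromosome) && !is.na(r$start) && !is.na(r$end)
  }
  if (coords_ok(r1) && coords_ok(r2) && r1$chromosome == r2$chromosome) {
    gap <- max(r1$start, r2$start) - min(r1$end, r2$end)
    if (gap <= tandem_max_bp) return("tandem")
  }
  if (!is.null(block_table) && coords_ok(r1) && coords_ok(r2)) {
    inside <- function(r, chrom, s, e) {
      r$chromosome == chrom && r$start >= s && r$end <= e
    }
    for (k in seq_len(nrow(block_table))) {
      b <- block_table[k, ]
      hit <- (inside(r1, b$chromA, b$startA, b$endA) &&
                inside(r2, b$chromB, b$startB, b$endB)) ||
             (inside(r2, b$chromA, b$startA, b$endA) &&
                inside(r1, b$chromB, b$startB, b$endB))
      if (hit) {
        return(if (!is.null(b$mechanism) && !is.na(b$mechanism))
                 as.character(b$mechanism) else "whole_genome_block")
      }
    }
  }
  "unknown"
}

#' Classify the evolutionary fate of a duplicate pair from expression
#'
#' Decision rule over the conditions assayed in both genes:
#' both expressed everywhere -> `shared_expression` (redundancy); one
#' expressed nowhere -> `nonfunctionalization_candidate` (possible
#' pseudogene); one expressed in every assayed condition while the other
#' is restricted to a strict non-empty subset ->
#' `subfunctionalization_candidate`; any other pattern -> `divergent`.
#' A gene absent from the matrix gives `unknown`.
#'
#' @param gene1,gene2 Gene ids.
#' @param em An [expression_matrix()].
#' @return Fate label.
#' @export
classify_duplicate_fate <- function(gene1, gene2, em) {
  if (!(gene1 %in% rownames(em)) || !(gene2 %in% rownames(em))) {
    return("unknown")
  }
  e1 <- unclass(em)[gene1, ]
  e2 <- unclass(em)[gene2, ]
  use <- e1 != "missing" & e2 != "missing"
  if (!any(use)) return("unknown")
  x1 <- e1[use] == "expressed"
  x2 <- e2[use] == "expressed"
  if (all(x1) && all(x2)) return("shared_expression")
  if (!any(x1) || !any(x2)) return("nonfunctionalization_candidate")
  broad_restricted <- function(b, r) all(b) && any(r) && !all(r)
  if (broad_restricted(x1, x2) || broad_restricted(x2, x1)) {
    return("subfunctionalization_candidate")
  }
  "divergent"
}

#' Duplicate-pair report: mechanism and fate
#'
#' @param pairs A `duplicate_pairs` data frame (see
#'   [find_species_duplicate_pairs()]).
#' @param gene_table Gene coordinate table.
#' @param em Optional [expression_matrix()].
#' @param block_table Optional paralogous-block table.
#' @param tandem_max_bp Tandem rule.
#' @return The pairs data frame with `mechanism` and `fate` columns.
#' @export
annotate_duplicate_pairs <- function(pairs, gene_table, em = NULL,
                                     block_table = NULL,
                                     tandem_max_bp = 1e5) {
  pairs$mechanism <- vapply(seq_len(nrow(pairs)), function(k) {
    classify_duplication_mechanism(pairs$gene1[k], pairs$gene2[k],
                                   gene_table, block_table, tandem_max_bp)
  }, character(1))
  pairs$fate <- if (is.null(em)) rep("unknown", nrow(pairs)) else
    vapply(seq_len(nrow(pairs)), function(k) {
      classify_duplicate_fate(pairs$gene1[k], pairs$gene2[k], em)
    }, character(1))
  pairs
}
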