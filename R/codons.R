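# Codon-level bookkeeping: the 61 sense codons of the standard nuclear code,
# translation, and the single-nucleotide neighbour structure used by the
# counting estimators and the GY94 rate matrix.

.tps <- new.env(parent = emptyenv())

NT <- c("T", "C", "A", "G")

#' @keywords internal
codon_tables <- function() {
  if (!is.null(.tps$codons)) {
    return(list(codons = .tps$codons, aa = .tps$aa, stops = .tps$stops))
  }
  all64 <- apply(expand.grid(NT, NT, NT, stringsAsFactors = FALSE)[, 3:1],
                 1, paste0, collapse = "")
  aa64 <- vapply(all64, function(cd) {
    seqinr::translate(unlist(strsplit(tolower(cd), "")))
  }, character(1))
  stops <- all64[aa64 == "*"]
  codons <- all64[aa64 != "*"]
  .tps$codons <- codons
  .tps$aa <- aa64[aa64 != "*"]
  .tps$stops <- stops
  list(codons = codons, aa = .tps$aa, stops = stops)
}

#' The 61 sense codons of the standard nuclear code
#'
#' Codons are ordered T < C < A < G by position (the ordering used by the
#' rate matrices and the simulator). Stop codons (TAA, TAG, TGA) are
#' excluded from the state space throughout the package.
#'
#' @return Character vector of 61 codons.
#' @export
sense_codons <- function() codon_tables()$codons

#' @rdname sense_codons
#' @return For `codon_amino_acids()`, the one-letter amino acid encoded by
#'   each sense codon, in the same order.
#' @export
codon_amino_acids <- function() codon_tables()$aa

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# For each sense codon, its single-nucleotide neighbours: target codon,
# changed position, target nucleotide, transition flag, synonymous flag,
# and whether the target is a stop (stops are excluded from "viable").
codon_neighbours <- function() {
  if (!is.null(.tps$neigh)) return(.tps$neigh)
  tb <- codon_tables()
  aa_of <- stats::setNames(c(tb$aa, rep("*", length(tb$stops))),
                           c(tb$codons, tb$stops))
  neigh <- lapply(tb$codons, function(cd) {
    nts <- strsplit(cd, "")[[1]]
    out <- list()
    for (pos in 1:3) {
      for (to in setdiff(NT, nts[pos])) {
        tgt <- nts
        tgt[pos] <- to
        tgt <- paste0(tgt, collapse = "")
        out[[length(out) + 1L]] <- list(
          target = tgt, pos = pos, to = to,
          ti = is_transition(nts[pos], to),
          stop = aa_of[[tgt]] == "*",
          syn = aa_of[[tgt]] == aa_of[[cd]]
        )
      }
    }
    out
  })
  names(neigh) <- tb$codons
  .tps$neigh <- neigh
  neigh
}

# 61 x 61 logical masks for the GY94 generator: single-step pairs,
# transition pairs, nonsynonymous pairs.
codon_masks <- function() {
  if (!is.null(.tps$masks)) return(.tps$masks)
  tb <- codon_tables()
  n <- length(tb$codons)
  single <- matrix(FALSE, n, n, dimnames = list(tb$codons, tb$codons))
  ti <- single
  ns <- single
  neigh <- codon_neighbours()
  for (i in seq_len(n)) {
    for (nb in neigh[[i]]) {
      if (nb$stop) next
      j <- match(nb$target, tb$codons)
      single[i, j] <- TRUE
      ti[i, j] <- nb$ti
      ns[i, j] <- !nb$syn
    }
  }
  .tps$masks <- list(single = single, ti = ti, ns = ns)
  .tps$masks
}

# Codons whose third position is fourfold degenerate (used for the
# kappa estimate in the YN00-style estimator).
fourfold_codons <- function() {
  if (!is.null(.tps$fourfold)) return(.tps$fourfold)
  tb <- codon_tables()
  neigh <- codon_neighbours()
  ff <- vapply(tb$codons, function(cd) {
    nb3 <- Filter(function(x) x$pos == 3, neigh[[cd]])
    length(nb3) == 3 && all(vapply(nb3, function(x) x$syn && !x$stop, logical(1)))
  }, logical(1))
  .tps$fourfold <- tb$codons[ff]
  .tps$fourfold
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("sequence length ", n, " is not a multiple of 3")
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

#' Translate a coding sequence
#'
#' Translates a CDS under the standard nuclear genetic code. A terminal
#' stop codon is trimmed silently; an internal stop codon is an error
#' (a gene carrying one must be handled explicitly as a pseudogene
#' upstream, it is never translated through).
#'
#' @param cds Nucleotide string (A/C/G/T), length a multiple of 3.
#' @param code Genetic code identifier; only `"standard"` is supported.
#' @return Amino-acid string, one residue per codon.
#' @examples
#' translate_cds("ATGTTTTAA")  # "MF", terminal stop trimmed
#' @export
translate_cds <- function(cds, code = "standard") {
  code <- match.arg(code)
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) {
    stop("invalid sequence: non-ACGT symbol in CDS")
  }
  cods <- split_codons(cds)
  tb <- codon_tables()
  aa_of <- stats::setNames(c(tb$aa, rep("*", length(tb$stops))),
                           c(tb$codons, tb$stops))
  aa <- aa_of[cods]
  n <- length(aa)
  if (n > 0 && aa[n] == "*") {
    aa <- aa[-n]
    n <- n - 1L
  }
  if (any(aa == "*")) {
    stop("premature stop codon at codon ",
         which(aa == "*")[1], " of the coding sequence")
  }
  paste0(aa, collapse = "")
}

# Strip one terminal stop codon if present; error on internal stops is
# left to translate_cds.
trim_terminal_stop <- function(cds) {
  cds <- toupper(cds)
  cods <- split_codons(cds)
  tb <- codon_tables()
  n <- length(cods)
  if (n > 0 && cods[n] %in% tb$stops) cods <- cods[-n]
  paste0(cods, collapse = "")
}
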