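# Alignment containers and codon-level plumbing: protein alignments,
# codon alignments obtained by back-translation, gap masking, and the
# TPS/TPP domain partition.

#' Protein alignment container
#'
#' A light container for a gapped multiple protein alignment: a character
#' matrix of single residues with one row per sequence. Gaps are `-`.
#'
#' @param seqs Named character vector of equal-length gapped sequences,
#'   or a character matrix of single characters with rownames.
#' @return An object of class `protein_alignment`.
#' @export
protein_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      stop("sequences must carry unique names")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      stop("aligned rows differ in length: ", paste(unique(lens), collapse = ", "))
    }
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("alignment rows must carry unique ids")
  }
  structure(list(ids = rownames(m), mat = m), class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("Protein alignment:", length(x$ids), "sequences x",
      ncol(x$mat), "columns\n")
  invisible(x)
}

alignment_strings <- function(pa) {
  stats::setNames(apply(pa$mat, 1, paste0, collapse = ""), pa$ids)
}

#' Codon alignment container
#'
#' A codon alignment is a character matrix of 3-letter codon cells (gap
#' cells are `"---"`), one row per gene, typically produced by
#' [back_translate()].
#'
#' @param mat Character matrix of codon cells with rownames.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(mat) {
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop("codon alignment rows must carry unique ids")
  }
  tb <- codon_tables()
  # ambiguity codes (N) are legal cells; masking treats them as gaps
  ok <- mat == "---" | mat %in% tb$codons | grepl("N", mat, fixed = TRUE)
  if (!all(ok)) {
    bad <- unique(mat[!ok])
    stop("invalid codon cells: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(ids = rownames(mat), mat = mat), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$ids), "sequences x",
      ncol(x$mat), "codon columns\n")
  invisible(x)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each aligned residue to its source codon, so that codon models can
#' be applied to a protein-guided alignment. Every row's non-gap cells
#' concatenate back to its stop-trimmed CDS (a round trip that is checked).
#'
#' @param pa A [protein_alignment()].
#' @param cds_map Named character vector or list mapping each alignment id
#'   to its unaligned CDS (a terminal stop codon is trimmed).
#' @return A [codon_alignment()].
#' @export
back_translate <- function(pa, cds_map) {
  miss <- setdiff(pa$ids, names(cds_map))
  if (length(miss)) stop("no CDS for: ", paste(miss, collapse = ", "))
  ncols <- ncol(pa$mat)
  out <- matrix("---", nrow = length(pa$ids), ncol = ncols,
                dimnames = list(pa$ids, NULL))
  for (id in pa$ids) {
    row <- pa$mat[id, ]
    if (nchar(cds_map[[id]]) %% 3 != 0) {
      stop("backtranslation error for ", id, ": CDS length ",
           nchar(cds_map[[id]]), " is not a multiple of 3")
    }
    cds <- trim_terminal_stop(cds_map[[id]])
    cods <- split_codons(cds)
    res_idx <- which(row != "-")
    if (length(res_idx) != length(cods)) {
      stop("backtranslation error for ", id, ": ", length(res_idx),
           " aligned residues vs ", length(cods), " codons")
    }
    aa <- translate_cds(cds)
    aa_chars <- strsplit(aa, "")[[1]]
    mism <- which(aa_chars != row[res_idx] & row[res_idx] != "X")
    if (length(mism)) {
      k <- mism[1]
      stop("translation mismatch for ", id, " at residue ", k, ": codon ",
           cods[k], " encodes ", aa_chars[k], " but alignment has ",
           row[res_idx][k])
    }
    out[id, res_idx] <- cods
  }
  codon_alignment(out)
}

#' Mask gapped or ambiguous columns of a codon alignment
#'
#' `complete_deletion` (the CODEML `cleandata` analogue, and the default
#' used for branch-model fits) removes every column in which any row is a
#' gap or ambiguous cell. `pairwise_deletion` instead returns, for every
#' unordered sequence pair, the column indices at which both cells are
#' unambiguous sense codons; it is the policy used by the pairwise rate
#' estimators.
#'
#' @param ca A [codon_alignment()].
#' @param policy `"complete_deletion"` or `"pairwise_deletion"`.
#' @return For complete deletion, a codon alignment; for pairwise
#'   deletion, a named list of integer column-index vectors keyed by
#'   `"id1|id2"`.
#' @export
mask_gapped_columns <- function(ca,
                                policy = c("complete_deletion",
                                           "pairwise_deletion")) {
  policy <- match.arg(policy)
  tb <- codon_tables()
  ok <- matrix(ca$mat %in% tb$codons, nrow = nrow(ca$mat))
  if (policy == "complete_deletion") {
    keep <- which(apply(ok, 2, all))
    if (length(keep) == 0) {
      stop("empty alignment: every column contains a gap or ambiguous cell")
    }
    out <- codon_alignment(ca$mat[, keep, drop = FALSE])
    attr(out, "kept_columns") <- keep
    out
  } else {
    ids <- ca$ids
    res <- list()
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1):length(ids)) {
        res[[paste(ids[i], ids[j], sep = "|")]] <-
          which(ok[i, ] & ok[j, ])
      }
    }
    res
  }
}

#' Define a TPS/TPP domain partition over codon columns
#'
#' Plant TPS proteins carry an N-terminal TPS (synthase) domain and a
#' C-terminal TPP (phosphatase) domain; rate analyses are run per domain.
#' Ranges are half-open `[start, end)` in codon-column coordinates and the
#' two domains must not overlap.
#'
#' @param tps,tpp Integer vectors `c(start, end)` (half-open) or explicit
#'   column index vectors.
#' @param n_columns Total codon columns of the target alignment.
#' @param note Free-text provenance note.
#' @return An object of class `domain_partition`: a named list of integer
#'   column sets.
#' @export
domain_partition <- function(tps, tpp, n_columns, note = "") {
  expand <- function(x) {
    if (length(x) == 2 && x[2] > x[1] + 1) seq.int(x[1], x[2] - 1L) else as.integer(x)
  }
  tps <- expand(tps); tpp <- expand(tpp)
  if (length(intersect(tps, tpp))) stop("TPS and TPP column sets overlap")
  if (any(c(tps, tpp) < 1) || any(c(tps, tpp) > n_columns)) {
    stop("partition indices outside alignment bounds [1, ", n_columns, "]")
  }
  structure(list(TPS = as.integer(tps), TPP = as.integer(tpp),
                 n_columns = as.integer(n_columns), note = note),
            class = "domain_partition")
}

subset_columns <- function(ca, cols) {
  codon_alignment(ca$mat[, cols, drop = FALSE])
}
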