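# Gene records and gene-structure analysis. Class I plant TPS genes carry
# 16 introns in the protein-coding region and class II genes carry 2; the
# intron count therefore corroborates the phylogenetic class split.

#' Construct a gene record
#'
#' One family member: identifiers, sequences and gene-model geometry.
#' Coordinates are 1-based inclusive (GFF3 convention); `exons` and
#' `cds_intervals` are two-column matrices in transcription order
#' (minus-strand genes run from high to low coordinates).
#'
#' @param gene_id,species,chromosome,strand,class_label Identifiers and
#'   annotation; `class_label` is `"I"`, `"II"` or `"unknown"`.
#' @param taxon_side `"monocot"`, `"dicot"` or `NA`.
#' @param cds,protein Optional sequences; when both are given the CDS must
#'   translate to the protein (terminal stop trimmed).
#' @param start,end Genomic span, or `NA`.
#' @param exons,cds_intervals Interval matrices (may be `NULL`).
#' @param validate_translation Verify `translate(cds) == protein`.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(gene_id, species = NA_character_,
                        taxon_side = NA_character_,
                        cds = NULL, protein = NULL,
                        chromosome = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        strand = NA_character_,
                        exons = NULL, cds_intervals = NULL,
                        class_label = "unknown",
                        validate_translation = TRUE) {
  if (!is.null(cds)) {
    cds <- trim_terminal_stop(cds)
    if (nchar(cds) %% 3 != 0) stop("CDS of ", gene_id, " is not a multiple of 3")
    if (validate_translation) {
      tr <- translate_cds(cds)
      if (is.null(protein)) {
        protein <- tr
      } else if (tr != protein) {
        stop("CDS of ", gene_id, " does not translate to the stated protein")
      }
    }
  }
  check_iv <- function(iv, what) {
    if (is.null(iv)) return(NULL)
    iv <- matrix(as.integer(iv), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
    srt <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(srt) > 1 && any(srt[-1, 1] <= srt[-nrow(srt), 2])) {
      stop("invalid gene model: overlapping ", what, " in ", gene_id)
    }
    iv
  }
  structure(list(gene_id = gene_id, species = species,
                 taxon_side = taxon_side, cds = cds, protein = protein,
                 chromosome = chromosome, start = start, end = end,
                 strand = strand,
                 exons = check_iv(exons, "exons"),
                 cds_intervals = check_iv(cds_intervals, "CDS intervals"),
                 class_label = class_label),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat("Gene record", x$gene_id,
      if (!is.na(x$species)) paste0("(", x$species, ")") else "",
      "class", x$class_label, "\n")
  if (!is.null(x$exons)) cat("  exons:", nrow(x$exons), "\n")
  invisible(x)
}

#' Count introns of a gene model
#'
#' Counts the gaps between consecutive intervals of the chosen region.
#' For `protein_coding` (the default, matching intron counts taken within
#' the protein-coding region) CDS intervals are used when present,
#' otherwise the exon intervals clipped to the CDS span; for
#' `full_transcript` the exon intervals are used as-is.
#'
#' @param g A [gene_record()].
#' @param region `"protein_coding"` or `"full_transcript"`.
#' @return A `gene_structure_summary`: gene id, exon/intron counts,
#'   intron lengths and summed interval length.
#' @export
count_introns <- function(g, region = c("protein_coding", "full_transcript")) {
  region <- match.arg(region)
  iv <- if (region == "protein_coding") {
    if (!is.null(g$cds_intervals)) {
      g$cds_intervals
    } else if (!is.null(g$exons)) {
      g$exons  # no separate CDS annotation: exons stand in for the CDS
    } else {
      stop("gene ", g$gene_id, " has no intervals for region ", region)
    }
  } else {
    if (is.null(g$exons)) stop("gene ", g$gene_id, " has no exon intervals")
    g$exons
  }
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
    stop("invalid gene model: overlapping intervals in ", g$gene_id)
  }
  n <- nrow(iv)
  intron_len <- if (n > 1) iv[-1, 1] - iv[-n, 2] - 1L else integer(0)
  structure(list(gene_id = g$gene_id, exon_count = n,
                 intron_count = n - 1L,
                 intron_lengths = as.integer(intron_len),
                 cds_length = sum(iv[, 2] - iv[, 1] + 1L),
                 region = region),
            class = "gene_structure_summary")
}

#' @export
print.gene_structure_summary <- function(x, ...) {
  cat(x$gene_id, ": ", x$exon_count, " exons, ", x$intron_count,
      " introns (", x$region, ")\n", sep = "")
  invisible(x)
}

#' Classify a gene by intron count
#'
#' Applies the structural rule of the family: class I genes carry 16
#' introns in the protein-coding region, class II genes carry 2. A count
#' matching no rule entry returns `"unknown"`.
#'
#' @param s A `gene_structure_summary` from [count_introns()], or a bare
#'   intron count.
#' @param rule Named integer vector mapping class to expected intron count.
#' @return `"I"`, `"II"` or `"unknown"`.
#' @export
classify_by_structure <- function(s, rule = c(I = 16L, II = 2L)) {
  count <- if (inherits(s, "gene_structure_summary")) s$intron_count else s
  hit <- names(rule)[rule == count]
  if (length(hit) == 1) hit else "unknown"
}

#' Summarise gene structures as a table
#'
#' @param records List of [gene_record()] objects.
#' @param rule Passed to [classify_by_structure()].
#' @return Data frame with gene_id, exon_count, intron_count,
#'   inferred_class.
#' @export
gene_structure_table <- function(records, rule = c(I = 16L, II = 2L)) {
  rows <- lapply(records, function(g) {
    s <- count_introns(g)
    data.frame(gene_id = s$gene_id, exon_count = s$exon_count,
               intron_count = s$intron_count,
               inferred_class = classify_by_structure(s, rule),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
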