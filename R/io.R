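# Readers and writers for the standard interchange formats: FASTA
# (sequences), GFF3 (gene models), Newick (trees), TSV tables
# (gene table, expression matrix, domain partition, clade tags) and
# relaxed PHYLIP (codon alignments).

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param type `"nt"` or `"aa"`.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, type = c("nt", "aa")) {
  type <- match.arg(type)
  seqs <- seqinr::read.fasta(path, seqtype = if (type == "nt") "DNA" else "AA",
                             as.string = TRUE, forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(seqs, as.character, character(1))),
                  names(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 70)
  invisible(path)
}

#' Read a protein alignment from FASTA
#'
#' @param path Aligned FASTA file.
#' @return A [protein_alignment()].
#' @export
read_protein_alignment <- function(path) {
  protein_alignment(read_fasta(path, "aa"))
}

#' Write a codon alignment in relaxed PHYLIP format
#'
#' @param ca A [codon_alignment()].
#' @param path Output file.
#' @export
write_phylip <- function(ca, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nchar_row <- ncol(ca$mat) * 3L
  writeLines(sprintf(" %d %d", length(ca$ids), nchar_row), con)
  for (id in ca$ids) {
    writeLines(paste0(id, "  ", paste0(ca$mat[id, ], collapse = "")), con)
  }
  invisible(path)
}

#' Read a codon alignment from FASTA or relaxed PHYLIP
#'
#' @param path Input file; format inferred from the first character
#'   (`>` means FASTA).
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(trimws(first), ">")) {
    seqs <- read_fasta(path, "nt")
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    body <- lines[-1]
    parts <- regmatches(body, regexpr("^\\S+", body))
    seqs <- stats::setNames(
      gsub("\\s", "", substring(body, nchar(parts) + 1L)), parts)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1 || lens[1] %% 3 != 0) {
    stop("codon alignment rows must share a length divisible by 3")
  }
  mat <- do.call(rbind, lapply(seqs, split_codons))
  rownames(mat) <- names(seqs)
  codon_alignment(mat)
}

#' Read a gene table
#'
#' Tab-separated table with columns `gene_id`, `species`, `side`
#' (monocot/dicot), `chromosome`, `start`, `end`, `strand`, `class`.
#' Missing values may be empty or `NA`.
#'
#' @param path TSV file.
#' @return A data frame.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("gene_id", "species", "side", "chromosome", "start", "end",
            "strand", "class")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  tab
}

#' Read an expression presence/absence matrix
#'
#' Genes in rows, conditions in columns. Calls are coded
#' `1`/`expressed`, `0`/`not_expressed`, and `NA`/`missing`.
#'
#' @param path TSV file with a gene-id first column.
#' @return Character matrix with values `expressed`, `not_expressed`,
#'   `missing`; class `expression_matrix`.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, row.names = 1,
                           na.strings = c("NA", ""))
  m <- as.matrix(tab)
  expression_matrix(m)
}

#' Construct an expression matrix from calls
#'
#' @param m Matrix (genes x conditions) of calls: `expressed` /
#'   `not_expressed` / `missing`, or `1` / `0` / `NA`.
#' @return Character matrix of class `expression_matrix`.
#' @export
expression_matrix <- function(m) {
  conv <- matrix("missing", nrow(m), ncol(m), dimnames = dimnames(m))
  conv[m == 1 | m == "expressed"] <- "expressed"
  conv[m == 0 | m == "not_expressed"] <- "not_expressed"
  conv[is.na(m)] <- "missing"
  structure(conv, class = c("expression_matrix", "matrix"))
}

#' Write an expression matrix as TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output file.
#' @export
write_expression_matrix <- function(em, path) {
  num <- matrix(NA_integer_, nrow(em), ncol(em), dimnames = dimnames(em))
  num[unclass(em) == "expressed"] <- 1L
  num[unclass(em) == "not_expressed"] <- 0L
  df <- data.frame(gene_id = rownames(em), num, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a domain partition table
#'
#' TSV with columns `name`, `start_col`, `end_col`; half-open codon-column
#' ranges for the `TPS` and `TPP` domains.
#'
#' @param path TSV file.
#' @param n_columns Number of codon columns of the target alignment.
#' @return A [domain_partition()].
#' @export
read_domain_partition <- function(path, n_columns) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  get_range <- function(nm) {
    row <- tab[tab$name == nm, , drop = FALSE]
    if (nrow(row) != 1) stop("partition table needs exactly one '", nm, "' row")
    c(row$start_col, row$end_col)
  }
  domain_partition(get_range("TPS"), get_range("TPP"), n_columns,
                   note = paste("read from", basename(path)))
}

#' Read clade tags
#'
#' Sidecar table mapping clade tags (such as A, B1, B2) to member leaf
#' ids: columns `tag`, `gene_id`.
#'
#' @param path TSV file.
#' @return Named list of leaf-id vectors.
#' @export
read_clade_tags <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(tab$gene_id, tab$tag)
}

#' Read gene models from GFF3
#'
#' Extracts `exon` and `CDS` features per gene and returns one
#' [gene_record()] per gene id found. Gene ids are taken from the
#' `ID=`/`Parent=` attributes with trailing transcript suffixes kept as-is.
#'
#' @param path GFF3 file.
#' @param genome Optional named character vector of chromosome sequences,
#'   used to extract spliced CDS sequence.
#' @return Named list of `gene_record` objects.
#' @export
read_gene_models <- function(path, genome = NULL) {
  gff <- ape::read.gff(path)
  gff$attributes <- as.character(gff$attributes)
  parent <- sub(".*Parent=([^;]+).*", "\\1", gff$attributes)
  parent[!grepl("Parent=", gff$attributes)] <- NA
  id <- sub(".*ID=([^;]+).*", "\\1", gff$attributes)
  id[!grepl("ID=", gff$attributes)] <- NA
  gene_of <- ifelse(is.na(parent), id, parent)
  keep <- gff$type %in% c("exon", "CDS")
  gff <- gff[keep, ]
  gene_of <- gene_of[keep]
  out <- list()
  for (g in unique(gene_of)) {
    sub <- gff[gene_of == g, ]
    exon <- sub[sub$type == "exon", c("start", "end")]
    cds <- sub[sub$type == "CDS", c("start", "end")]
    strand <- as.character(sub$strand[1])
    chrom <- as.character(sub$seqid[1])
    mk <- function(df) {
      if (nrow(df) == 0) return(NULL)
      iv <- as.matrix(df[order(df$start), , drop = FALSE])
      if (strand == "-") iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
      iv
    }
    cds_seq <- NULL
    if (!is.null(genome) && nrow(cds) > 0 && chrom %in% names(genome)) {
      iv <- as.matrix(cds[order(cds$start), , drop = FALSE])
      pieces <- apply(iv, 1, function(r) substr(genome[[chrom]], r[1], r[2]))
      s <- paste0(pieces, collapse = "")
      if (strand == "-") s <- revcomp(s)
      cds_seq <- s
    }
    out[[g]] <- gene_record(
      gene_id = g, species = NA_character_,
      chromosome = chrom, strand = strand,
      start = min(sub$start), end = max(sub$end),
      exons = mk(exon), cds_intervals = mk(cds),
      cds = cds_seq, validate_translation = FALSE)
  }
  out
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste0(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
}

#' Write a GFF3 file for a set of gene models
#'
#' @param records Named list of `gene_record` objects.
#' @param path Output file.
#' @export
write_gene_models <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (rec in records) {
    base <- function(type, s, e, attr) {
      sprintf("%s\ttpsevol\t%s\t%d\t%d\t.\t%s\t.\t%s",
              rec$chromosome, type, s, e, rec$strand, attr)
    }
    writeLines(base("gene", rec$start, rec$end,
                    paste0("ID=", rec$gene_id)), con)
    ex <- rec$exons[order(rec$exons[, 1]), , drop = FALSE]
    for (k in seq_len(nrow(ex))) {
      writeLines(base("exon", ex[k, 1], ex[k, 2],
                      paste0("Parent=", rec$gene_id)), con)
    }
    if (!is.null(rec$cds_intervals)) {
      cd <- rec$cds_intervals[order(rec$cds_intervals[, 1]), , drop = FALSE]
      for (k in seq_len(nrow(cd))) {
        writeLines(base("CDS", cd[k, 1], cd[k, 2],
                        paste0("Parent=", rec$gene_id)), con)
      }
    }
  }
  invisible(path)
}
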