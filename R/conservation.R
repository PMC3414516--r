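# Protein-level conservation statistics: pairwise identity matrices,
# within/between-class identity distributions with an independent-sample
# t-test, and catalytic-residue conservation mapped from a reference
# enzyme (the E. coli OtsA outgroup in the TPS study).

#' Percent identity of two aligned rows
#'
#' The default denominator counts only columns where both sequences are
#' ungapped, the convention under which between-class identities of
#' distantly related domains remain interpretable; the full alignment
#' length and the shorter ungapped sequence length are available for
#' sensitivity analysis.
#'
#' @param pa A [protein_alignment()].
#' @param i,j Sequence ids.
#' @param denominator `"both_ungapped"`, `"alignment_length"` or
#'   `"shorter_seq"`.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(pa, i, j,
                              denominator = c("both_ungapped",
                                              "alignment_length",
                                              "shorter_seq")) {
  denominator <- match.arg(denominator)
  if (!all(c(i, j) %in% pa$ids)) stop("ids not present in alignment")
  a <- pa$mat[i, ]; b <- pa$mat[j, ]
  both <- a != "-" & b != "-"
  matches <- sum(a == b & both)
  den <- switch(denominator,
                both_ungapped = sum(both),
                alignment_length = length(a),
                shorter_seq = min(sum(a != "-"), sum(b != "-")))
  if (den == 0) stop("undefined identity: zero comparable positions for ",
                     i, " vs ", j)
  100 * matches / den
}

#' Pairwise identity matrix
#'
#' @param pa A [protein_alignment()] with at least two sequences.
#' @param denominator Passed to [pairwise_identity()].
#' @return Symmetric matrix of percent identities with a 100 diagonal;
#'   class `identity_matrix` with the gap policy stored as an attribute.
#' @export
identity_matrix <- function(pa, denominator = "both_ungapped") {
  n <- length(pa$ids)
  if (n < 2) stop("need at least two sequences")
  m <- diag(100, n)
  dimnames(m) <- list(pa$ids, pa$ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <-
        pairwise_identity(pa, pa$ids[i], pa$ids[j], denominator)
    }
  }
  structure(m, class = c("identity_matrix", "matrix"),
            denominator = denominator)
}

#' Within- and between-class identity distributions
#'
#' Splits all unordered pairs into I-I, II-II and I-II distributions and
#' summarises each as a boxplot would (n, min, quartiles, median, max).
#'
#' @param m An [identity_matrix()].
#' @param class_map Named vector mapping every id to `"I"` or `"II"`.
#' @return List with `distributions` (named list of numeric vectors) and
#'   `summary` (data frame).
#' @export
group_identity_stats <- function(m, class_map) {
  ids <- rownames(m)
  miss <- setdiff(ids, names(class_map))
  if (length(miss)) stop("missing class for: ", paste(miss, collapse = ", "))
  dists <- list("I-I" = numeric(0), "II-II" = numeric(0),
                "I-II" = numeric(0))
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cls <- sort(c(class_map[[ids[i]]], class_map[[ids[j]]]))
      key <- if (cls[1] == cls[2]) paste(cls[1], cls[2], sep = "-")
             else "I-II"
      dists[[key]] <- c(dists[[key]], m[i, j])
    }
  }
  summ <- do.call(rbind, lapply(names(dists), function(k) {
    v <- dists[[k]]
    if (length(v) == 0) {
      data.frame(group = k, n = 0L, min = NA, q1 = NA, median = NA,
                 q3 = NA, max = NA)
    } else {
      q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
      data.frame(group = k, n = length(v), min = q[1], q1 = q[2],
                 median = q[3], q3 = q[4], max = q[5])
    }
  }))
  list(distributions = dists, summary = summ)
}

#' Independent two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] returning the group-comparison
#' record used throughout the package. The degenerate case of two
#' zero-variance samples with equal means is defined as t = 0, p = 1
#' rather than an error.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return List of class `group_comparison`: per-group summaries, t
#'   statistic, degrees of freedom, two-sided p, and the variant used.
#' @export
independent_t_test <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per group")
  if (!all(is.finite(c(a, b)))) stop("non-finite values")
  summarise <- function(v) {
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
    list(n = length(v), min = q[1], q1 = q[2], median = q[3], q3 = q[4],
         max = q[5])
  }
  if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
    res <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                p.value = 1)
  } else {
    tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
    res <- list(statistic = unname(tt$statistic),
                parameter = unname(tt$parameter), p.value = tt$p.value)
  }
  structure(list(groups = list(a = summarise(a), b = summarise(b)),
                 t = res$statistic, df = res$parameter, p = res$p.value,
                 variant = variant, paired = FALSE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(if (isTRUE(x$paired)) "Paired" else "Independent-sample",
      "t-test (", x$variant, "): t = ", format(x$t, digits = 5),
      ", df = ", format(x$df, digits = 5),
      ", p = ", format.pval(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Column-permutation null for the class identity contrast
#'
#' Optional companion to the t-test on within- vs between-class
#' identities (which ignores the non-independence of pairs sharing a
#' sequence): residues are shuffled across sequences independently
#' within each column, destroying sequence-level class structure while
#' preserving column composition, and the t statistic is recomputed per
#' replicate. Off by default in the pipeline.
#'
#' @param pa A [protein_alignment()].
#' @param class_map Named vector id -> class (`I`/`II`).
#' @param n_perm Number of permutation replicates.
#' @param seed Seed for the shuffles.
#' @param denominator Passed to [identity_matrix()].
#' @return List: observed t, permutation p-value, replicate statistics.
#' @export
group_identity_permutation_test <- function(pa, class_map, n_perm = 199,
                                            seed = 1,
                                            denominator = "both_ungapped") {
  stat_of <- function(p) {
    m <- identity_matrix(p, denominator)
    st <- group_identity_stats(m, class_map)
    within <- c(st$distributions[["I-I"]], st$distributions[["II-II"]])
    between <- st$distributions[["I-II"]]
    abs(independent_t_test(within, between)$t)
  }
  obs <- stat_of(pa)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(r) {
    shuffled <- apply(pa$mat, 2, sample)
    rownames(shuffled) <- pa$ids
    stat_of(protein_alignment(shuffled))
  }, numeric(1))
  list(observed_t = obs,
       p = (1 + sum(perm >= obs)) / (n_perm + 1),
       permuted_t = perm)
}

#' Catalytic-residue conservation by class
#'
#' Maps reference-residue positions (1-based indices into the ungapped
#' reference sequence, e.g. the six UDP-glucose-contacting residues of
#' E. coli OtsA) through the reference row's gaps to alignment columns,
#' and counts, per class, the positions at which every class member
#' carries the reference residue ("absolute" conservation).
#'
#' @param pa A [protein_alignment()] containing the reference row.
#' @param ref_id Id of the reference sequence.
#' @param ref_positions 1-based residue indices in the reference.
#' @param class_map Named vector id -> class; the reference id itself is
#'   ignored when absent from the map.
#' @return List with `table` (data frame: position, reference residue,
#'   class, conserved flag) and `counts` (named vector of absolutely
#'   conserved positions per class).
#' @export
catalytic_site_conservation <- function(pa, ref_id, ref_positions,
                                        class_map) {
  if (!ref_id %in% pa$ids) stop("reference ", ref_id, " not in alignment")
  ref_row <- pa$mat[ref_id, ]
  res_cols <- which(ref_row != "-")
  if (any(ref_positions < 1 | ref_positions > length(res_cols))) {
    stop("reference position out of range (reference has ",
         length(res_cols), " residues)")
  }
  cols <- res_cols[ref_positions]
  classes <- sort(unique(unlist(class_map[names(class_map) != ref_id])))
  rows <- list()
  for (k in seq_along(ref_positions)) {
    ref_res <- ref_row[cols[k]]
    for (cl in classes) {
      members <- names(class_map)[unlist(class_map) == cl]
      members <- intersect(members, pa$ids)
      conserved <- all(pa$mat[members, cols[k]] == ref_res)
      rows[[length(rows) + 1L]] <- data.frame(
        ref_position = ref_positions[k], ref_residue = ref_res,
        alignment_column = cols[k], class = cl, conserved = conserved,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  counts <- vapply(classes, function(cl) {
    sum(tab$conserved[tab$class == cl])
  }, integer(1))
  list(table = tab, counts = counts)
}
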