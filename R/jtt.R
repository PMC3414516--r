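# The Jones-Taylor-Thornton (1992) empirical amino-acid replacement
# model: published exchangeability counts (lower triangle, amino acids in
# ARNDCQEGHILKMFPSTWYV order) and equilibrium frequencies, plus pairwise
# maximum-likelihood distances under the model.

JTT_AA <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")

# exchangeabilities, lower triangle filled column-wise
JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475,
  9, 11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74,
  101, 64, 126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10,
  15, 503, 232, 8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15,
  59, 38, 4, 46, 31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115,
  209, 62, 323, 26, 597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20,
  119, 26, 12, 9, 181, 18, 5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14,
  5, 24, 201, 33, 55, 8, 47, 16, 56, 45, 33, 40, 115, 73, 46, 8, 573,
  11, 229, 21, 479, 89, 10, 40, 245, 9, 32, 961, 14, 388, 248, 102, 59,
  25, 52, 24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16, 29, 226, 24,
  18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477, 35, 63,
  38, 12, 21, 112, 71, 25, 16)

JTT_FREQ <- c(0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752,
              0.061830, 0.073152, 0.022944, 0.053761, 0.091904, 0.058676,
              0.023826, 0.040126, 0.050901, 0.068765, 0.058565, 0.014261,
              0.032102, 0.066005)

# Normalised JTT generator (rows sum to zero, -sum(pi_i q_ii) = 1) and
# its symmetric-basis eigendecomposition.
jtt_model <- function() {
  if (!is.null(.tps$jtt)) return(.tps$jtt)
  S <- matrix(0, 20, 20, dimnames = list(JTT_AA, JTT_AA))
  S[lower.tri(S)] <- JTT_EXCH
  S <- S + t(S)
  pi <- JTT_FREQ / sum(JTT_FREQ)
  Q <- S * rep(pi, each = 20)  # q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))
  sq <- sqrt(pi)
  B <- (sq * Q) %*% diag(1 / sq)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  .tps$jtt <- list(pi = stats::setNames(pi, JTT_AA), Q = Q,
                   eval = eg$values, evec = eg$vectors, sq = sq)
  .tps$jtt
}

jtt_pmat <- function(t) {
  m <- jtt_model()
  P <- (1 / m$sq * m$evec) %*% (exp(m$eval * t) * t(m$evec)) %*% diag(m$sq)
  P[P < 0] <- 0
  dimnames(P) <- list(JTT_AA, JTT_AA)
  P
}

#' Pairwise maximum-likelihood distance under the JTT model
#'
#' Maximises the two-sequence likelihood `prod(pi_i P_ij(t))` over the
#' divergence time t for one pair of gapped protein rows, using the
#' columns at which both sequences are ungapped. Distances are capped at
#' 10 substitutions per site.
#'
#' @param seq_i,seq_j Gapped amino-acid strings or character vectors.
#' @param cap Upper bound on the distance.
#' @return ML distance in substitutions per site.
#' @export
jtt_distance <- function(seq_i, seq_j, cap = 10) {
  a <- if (length(seq_i) == 1) strsplit(toupper(seq_i), "")[[1]] else toupper(seq_i)
  b <- if (length(seq_j) == 1) strsplit(toupper(seq_j), "")[[1]] else toupper(seq_j)
  keep <- a %in% JTT_AA & b %in% JTT_AA
  if (!any(keep)) stop("no comparable (both-ungapped) columns")
  ia <- match(a[keep], JTT_AA)
  ib <- match(b[keep], JTT_AA)
  counts <- table(ia, ib)
  rows <- as.integer(rownames(counts))
  cols <- as.integer(colnames(counts))
  nll <- function(t) {
    P <- jtt_pmat(t)
    lp <- log(pmax(P[rows, cols, drop = FALSE], 1e-300))
    -sum(counts * lp)
  }
  if (all(ia == ib)) return(0)
  opt <- stats::optimize(nll, c(1e-8, cap), tol = 1e-8)
  min(opt$minimum, cap)
}

#' JTT distance matrix of a protein alignment
#'
#' @param pa A [protein_alignment()].
#' @param cap Per-pair distance cap.
#' @return Symmetric `dist`-compatible matrix.
#' @export
jtt_distance_matrix <- function(pa, cap = 10) {
  n <- length(pa$ids)
  m <- matrix(0, n, n, dimnames = list(pa$ids, pa$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- jtt_distance(pa$mat[i, ], pa$mat[j, ], cap)
    }
  }
  m
}
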