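# The Goldman-Yang (1994) codon substitution model: equilibrium codon
# frequencies, the instantaneous rate matrix parameterised by kappa
# (transition/transversion ratio) and omega (dN/dS), and transition
# probability matrices via eigendecomposition in the symmetrised basis.

#' Equilibrium codon frequencies
#'
#' Builds the 61-codon equilibrium distribution from a codon alignment.
#' `F3x4` (the CODEML default) multiplies position-specific nucleotide
#' frequencies and renormalises over sense codons; `F1x4` uses overall
#' nucleotide frequencies; `empirical_codon` uses observed codon counts;
#' `equal` gives 1/61. Zero-frequency categories are floored at a small
#' pseudo-frequency before renormalisation so no sense codon becomes
#' unreachable.
#'
#' @param ca A [codon_alignment()] (ignored for `"equal"`).
#' @param model One of `"F3x4"`, `"F1x4"`, `"empirical_codon"`, `"equal"`.
#' @param floor Pseudo-frequency for zero-count categories.
#' @return Object of class `codon_frequencies`: named 61-vector `pi`
#'   summing to 1, plus the model label.
#' @export
build_codon_freqs <- function(ca = NULL,
                              model = c("F3x4", "F1x4", "empirical_codon",
                                        "equal"),
                              floor = 1e-6) {
  model <- match.arg(model)
  tb <- codon_tables()
  codons <- tb$codons
  if (model == "equal") {
    pi <- rep(1 / 61, 61)
  } else {
    if (is.null(ca)) stop("frequency model ", model, " needs an alignment")
    cells <- ca$mat[ca$mat %in% codons]
    if (length(cells) == 0) stop("alignment holds no unambiguous codons")
    if (model == "empirical_codon") {
      cnt <- table(factor(cells, levels = codons))
      pi <- pmax(as.numeric(cnt) / sum(cnt), floor)
    } else {
      chars <- do.call(rbind, strsplit(cells, ""))
      posfreq <- if (model == "F3x4") {
        t(apply(chars, 2, function(col) {
          f <- table(factor(col, levels = NT))
          pmax(as.numeric(f) / sum(f), floor)
        }))
      } else {
        f <- table(factor(as.vector(chars), levels = NT))
        matrix(rep(pmax(as.numeric(f) / sum(f), floor), each = 3), nrow = 3)
      }
      posfreq <- posfreq / rowSums(posfreq)
      cd <- do.call(rbind, strsplit(codons, ""))
      pi <- posfreq[1, match(cd[, 1], NT)] *
        posfreq[2, match(cd[, 2], NT)] *
        posfreq[3, match(cd[, 3], NT)]
    }
  }
  pi <- pi / sum(pi)
  structure(list(model = model, pi = stats::setNames(pi, codons)),
            class = "codon_frequencies")
}

#' @export
print.codon_frequencies <- function(x, ...) {
  cat("Codon frequencies (", x$model, "), range ",
      format(min(x$pi), digits = 3), " - ",
      format(max(x$pi), digits = 3), "\n", sep = "")
  invisible(x)
}

as_pi <- function(freqs) {
  if (inherits(freqs, "codon_frequencies")) freqs$pi else freqs
}

#' GY94 instantaneous rate matrix
#'
#' `q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]` for codon
#' pairs differing at one position (0 otherwise), diagonal set so rows sum
#' to zero, and the matrix scaled so that `-sum(pi_i q_ii) = 1`: branch
#' lengths are then expected substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param omega dN/dS ratio (>= 0).
#' @param freqs A `codon_frequencies` object or bare 61-vector.
#' @return 61 x 61 matrix of class `gy94_rate_matrix` with attributes
#'   `pi`, `kappa`, `omega`.
#' @export
gy94_rate_matrix <- function(kappa, omega, freqs) {
  if (kappa < 0 || omega < 0) stop("kappa and omega must be non-negative")
  pi <- as_pi(freqs)
  if (max(pi) > 1 - 1e-9) stop("degenerate codon frequencies: all mass on one codon")
  masks <- codon_masks()
  Q <- matrix(0, 61, 61, dimnames = list(names(pi), names(pi)))
  Q[masks$single] <- rep(pi, each = 61)[masks$single] *
    ifelse(masks$ti[masks$single], kappa, 1) *
    ifelse(masks$ns[masks$single], omega, 1)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("rate matrix normalisation failed")
  Q <- Q / scale
  structure(Q, class = c("gy94_rate_matrix", "matrix"),
            pi = pi, kappa = kappa, omega = omega)
}

#' Transition probability matrix of a codon model
#'
#' `P(t) = exp(Qt)` computed by eigendecomposition in the
#' `sqrt(pi)`-symmetrised basis (the GY94 chain is reversible). Rows sum
#' to 1; tiny negative entries from roundoff are clipped to 0.
#'
#' @param Q A [gy94_rate_matrix()].
#' @param t Branch length (>= 0), expected substitutions per codon.
#' @return 61 x 61 stochastic matrix.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop("branch length must be non-negative")
  pi <- attr(Q, "pi")
  sq <- sqrt(pi)
  B <- (sq * unclass(Q)) %*% diag(1 / sq)  # diag(sq) %*% Q %*% diag(1/sq)
  B <- (B + t(B)) / 2                      # enforce symmetry before eigen
  eg <- eigen(B, symmetric = TRUE)
  P <- (1 / sq * eg$vectors) %*% (exp(eg$values * t) * t(eg$vectors)) %*%
    diag(sq)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}
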