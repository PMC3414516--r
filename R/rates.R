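# Counting-based pairwise dN/dS estimation. ng86_* implements classical
# Nei-Gojobori (1986) counting with equal-weight averaging over minimal
# mutational pathways; yn00_pair is a YN00-flavoured variant that weights
# site counting and pathway averaging by a transition/transversion ratio
# (estimated from fourfold-degenerate sites, K80 formulas) and by
# position-specific nucleotide frequencies (F3x4). With equal frequencies
# and kappa fixed at 1 the weighted estimator reduces exactly to NG86.

# Per-codon neighbour attributes unrolled to arrays for vectorised
# weighted site counting: dimensions 61 codons x 9 single-nt changes.
neighbour_arrays <- function() {
  if (!is.null(.tps$narr)) return(.tps$narr)
  neigh <- codon_neighbours()
  n <- length(neigh)
  ti <- syn <- stopm <- matrix(FALSE, n, 9)
  pos <- ntidx <- matrix(1L, n, 9)
  for (i in seq_len(n)) {
    for (k in seq_len(9)) {
      nb <- neigh[[i]][[k]]
      ti[i, k] <- nb$ti; syn[i, k] <- nb$syn; stopm[i, k] <- nb$stop
      pos[i, k] <- nb$pos; ntidx[i, k] <- match(nb$to, NT)
    }
  }
  .tps$narr <- list(ti = ti, syn = syn, stop = stopm, pos = pos,
                    ntidx = ntidx)
  .tps$narr
}

# Synonymous-site fraction per sense codon under mutation weights
# kappa^ti * f[pos, nt]; per-position normalisation over non-stop
# neighbours, so s + n = 3 for every codon.
site_fractions <- function(kappa = 1, posfreq = NULL) {
  ar <- neighbour_arrays()
  w <- ifelse(ar$ti, kappa, 1)
  if (!is.null(posfreq)) {
    w <- w * posfreq[cbind(as.vector(ar$pos), as.vector(ar$ntidx))]
  }
  w[ar$stop] <- 0
  s <- numeric(nrow(w))
  for (p in 1:3) {
    sel <- ar$pos == p
    wp <- w * sel
    num <- rowSums(wp * ar$syn)
    den <- rowSums(wp)
    s <- s + ifelse(den > 0, num / den, 0)
  }
  s
}

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' Nei-Gojobori site counting for a single sense codon: each position
#' contributes the fraction of its viable (non-stop) single-nucleotide
#' changes that are synonymous, so the fractions always sum to 3.
#'
#' @param codon A sense codon string.
#' @return Named numeric vector `c(s = ..., n = ...)` with `s + n == 3`.
#' @examples
#' ng86_sites("TTT")  # s = 1/3: only TTT -> TTC is synonymous
#' @export
ng86_sites <- function(codon) {
  tb <- codon_tables()
  codon <- toupper(codon)
  i <- match(codon, tb$codons)
  if (is.na(i)) stop("not a sense codon: ", codon)
  s <- site_fractions()[i]
  c(s = s, n = 3 - s)
}

# Minimal mutational pathways between two codons, cached: each pathway is
# a data frame of steps (syn, ti, pos, ntidx), stop-crossing pathways
# removed. If every minimal pathway crosses a stop codon the unfiltered
# set is returned with attribute through_stop = TRUE.
codon_pathways <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (is.null(.tps$paths)) .tps$paths <- new.env(parent = emptyenv())
  hit <- .tps$paths[[key]]
  if (!is.null(hit)) return(hit)
  tb <- codon_tables()
  aa_of <- stats::setNames(c(tb$aa, rep("*", length(tb$stops))),
                           c(tb$codons, tb$stops))
  n1 <- strsplit(c1, "")[[1]]; n2 <- strsplit(c2, "")[[1]]
  diffs <- which(n1 != n2)
  perms <- switch(length(diffs),
                  list(diffs),
                  list(diffs, rev(diffs)),
                  {
                    idx <- list(c(1,2,3), c(1,3,2), c(2,1,3),
                                c(2,3,1), c(3,1,2), c(3,2,1))
                    lapply(idx, function(o) diffs[o])
                  })
  build <- function(order_) {
    cur <- n1
    steps <- list()
    valid <- TRUE
    for (p in order_) {
      prev <- paste0(cur, collapse = "")
      cur[p] <- n2[p]
      nxt <- paste0(cur, collapse = "")
      if (aa_of[[nxt]] == "*" && nxt != c2) valid <- FALSE
      steps[[length(steps) + 1L]] <- c(
        syn = aa_of[[prev]] == aa_of[[nxt]] &&
          aa_of[[prev]] != "*" && aa_of[[nxt]] != "*",
        ti = is_transition(n1[p], n2[p]),
        pos = p, ntidx = match(n2[p], NT),
        stop_step = aa_of[[nxt]] == "*")
      valid <- valid && aa_of[[nxt]] != "*"
    }
    list(steps = do.call(rbind, steps), valid = valid)
  }
  all_paths <- lapply(perms, build)
  ok <- Filter(function(p) p$valid, all_paths)
  through_stop <- length(ok) == 0
  if (through_stop) ok <- all_paths
  res <- structure(lapply(ok, `[[`, "steps"), through_stop = through_stop)
  .tps$paths[[key]] <- res
  res
}

# Weighted pathway-average difference counts for one codon pair.
path_diff_counts <- function(c1, c2, kappa = 1, posfreq = NULL) {
  paths <- codon_pathways(c1, c2)
  w <- vapply(paths, function(st) {
    wt <- prod(ifelse(st[, "ti"] == 1, kappa, 1))
    if (!is.null(posfreq)) {
      wt <- wt * prod(posfreq[cbind(st[, "pos"], st[, "ntidx"])])
    }
    wt
  }, numeric(1))
  w <- w / sum(w)
  sd <- sum(w * vapply(paths, function(st) sum(st[, "syn"]), numeric(1)))
  nd_tot <- nrow(paths[[1]])
  c(sd = sd, nd = nd_tot - sd, through_stop = attr(paths, "through_stop"))
}

as_codon_vec <- function(x) {
  if (length(x) == 1 && nchar(x) > 3) x <- split_codons(x)
  toupper(x)
}

count_pair <- function(s1, s2, kappa = 1, posfreq = NULL) {
  tb <- codon_tables()
  i1 <- match(s1, tb$codons); i2 <- match(s2, tb$codons)
  if (anyNA(i1) || anyNA(i2)) stop("non-sense codon in compared sequences")
  sfrac <- site_fractions(kappa, posfreq)
  S <- (sum(sfrac[i1]) + sum(sfrac[i2])) / 2
  N <- 3 * length(s1) - S
  diff <- which(s1 != s2)
  Sd <- Nd <- 0
  through_stop <- FALSE
  if (length(diff)) {
    keys <- paste(s1[diff], s2[diff])
    agg <- table(keys)
    for (k in names(agg)) {
      pr <- strsplit(k, " ")[[1]]
      cnt <- path_diff_counts(pr[1], pr[2], kappa, posfreq)
      Sd <- Sd + agg[[k]] * cnt[["sd"]]
      Nd <- Nd + agg[[k]] * cnt[["nd"]]
      through_stop <- through_stop || cnt[["through_stop"]] > 0
    }
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, through_stop = through_stop)
}

jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

finish_estimate <- function(ids, method, cnt, kappa, flags = character()) {
  pS <- cnt$Sd / cnt$S
  pN <- cnt$Nd / cnt$N
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  if (is.na(dS) || is.na(dN)) flags <- c(flags, "saturated")
  omega <- NA_real_
  if (!is.na(dS) && !is.na(dN)) {
    if (dS == 0) flags <- c(flags, "undefined_dS0") else omega <- dN / dS
  }
  if (cnt$through_stop) flags <- c(flags, "pathway_through_stop")
  structure(list(ids = ids, method = method, S = cnt$S, N = cnt$N,
                 Sd = cnt$Sd, Nd = cnt$Nd, dS = dS, dN = dN,
                 omega = omega, kappa = kappa, flags = unique(flags)),
            class = "pairwise_rate_estimate")
}

#' @export
print.pairwise_rate_estimate <- function(x, ...) {
  cat(x$method, " estimate", if (!is.null(x$ids)) paste0(" (", paste(x$ids, collapse = " vs "), ")"),
      ": dN = ", format(x$dN, digits = 5), ", dS = ", format(x$dS, digits = 5),
      ", omega = ", format(x$omega, digits = 5),
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Nei-Gojobori pairwise dN/dS
#'
#' Classical NG86 counting on two gap-free codon sequences: site
#' fractions averaged over the two sequences, differences averaged with
#' equal weight over all minimal mutational pathways that avoid stop
#' codons, and Jukes-Cantor distance correction. Proportions >= 3/4 are
#' flagged `saturated`; dS = 0 gives the `undefined_dS0` flag instead of
#' an infinite ratio.
#'
#' @param seq1,seq2 Codon strings or codon vectors of equal length,
#'   sense codons only.
#' @param ids Optional pair labels.
#' @return A `pairwise_rate_estimate`.
#' @export
ng86_pair <- function(seq1, seq2, ids = NULL) {
  s1 <- as_codon_vec(seq1); s2 <- as_codon_vec(seq2)
  if (length(s1) != length(s2)) stop("sequences differ in codon count")
  cnt <- count_pair(s1, s2, kappa = 1, posfreq = NULL)
  finish_estimate(ids, "NG86", cnt, kappa = 1)
}

# K80 transition/transversion rate ratio from two aligned nucleotide
# vectors; NA when the log arguments are non-positive.
kappa_k80 <- function(n1, n2) {
  if (length(n1) == 0) return(NA_real_)
  purine <- c("A", "G")
  diff <- n1 != n2
  ti <- diff & ((n1 %in% purine) == (n2 %in% purine))
  P <- mean(ti); Q <- mean(diff & !ti)
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  at <- -0.5 * log(w1) + 0.25 * log(w2)
  bt <- -0.25 * log(w2)
  if (bt <= 0) return(NA_real_)
  at / bt
}

pair_posfreq <- function(s1, s2) {
  chars <- rbind(do.call(rbind, strsplit(s1, "")),
                 do.call(rbind, strsplit(s2, "")))
  f <- t(apply(chars, 2, function(col) {
    tab <- table(factor(col, levels = NT))
    as.numeric(tab) / sum(tab)
  }))
  # floor zero categories so weights never vanish entirely
  f <- pmax(f, 1e-6)
  f / rowSums(f)
}

#' YN00-style weighted pairwise dN/dS
#'
#' A frequency- and kappa-weighted counting estimator in the spirit of
#' Yang & Nielsen (2000): kappa is estimated from fourfold-degenerate
#' third positions with K80 formulas (falling back to all third
#' positions, then to 1), site counting and minimal-pathway averaging are
#' weighted by `kappa^transition x f(position, target nucleotide)` under
#' F3x4 frequencies from the pair, and kappa/omega are re-evaluated until
#' omega is stable. With `freqs = "equal"` and `kappa = 1` the estimator
#' coincides with [ng86_pair()].
#'
#' @param seq1,seq2 Codon strings or vectors, equal length, sense only.
#' @param freqs `"F3x4"` (position-specific frequencies from the pair) or
#'   `"equal"`.
#' @param kappa Fix kappa instead of estimating it.
#' @param tol,max_iter Convergence control for the omega iteration.
#' @param ids Optional pair labels.
#' @return A `pairwise_rate_estimate` (fields include the kappa used).
#' @export
yn00_pair <- function(seq1, seq2, freqs = c("F3x4", "equal"), kappa = NULL,
                      tol = 1e-8, max_iter = 10, ids = NULL) {
  freqs <- match.arg(freqs)
  s1 <- as_codon_vec(seq1); s2 <- as_codon_vec(seq2)
  if (length(s1) != length(s2)) stop("sequences differ in codon count")
  posfreq <- if (freqs == "F3x4") pair_posfreq(s1, s2) else NULL
  flags <- character()
  if (is.null(kappa)) {
    ff <- fourfold_codons()
    sel <- s1 %in% ff & s2 %in% ff
    k <- kappa_k80(substr(s1[sel], 3, 3), substr(s2[sel], 3, 3))
    if (!is.finite(k) || k <= 0) {
      k <- kappa_k80(substr(s1, 3, 3), substr(s2, 3, 3))
      flags <- c(flags, "kappa_from_all_third_positions")
    }
    if (!is.finite(k) || k <= 0) {
      k <- 1
      flags <- c(flags, "kappa_fallback_1")
    }
    kappa <- k
  }
  omega_prev <- Inf
  est <- NULL
  for (it in seq_len(max_iter)) {
    cnt <- count_pair(s1, s2, kappa = kappa, posfreq = posfreq)
    est <- finish_estimate(ids, "YN00", cnt, kappa, flags)
    om <- if (is.na(est$omega)) -1 else est$omega
    if (abs(om - omega_prev) < tol) break
    omega_prev <- om
  }
  est
}

#' Domain-partitioned pairwise rate table
#'
#' For every unordered sequence pair, estimates omega separately on the
#' TPS- and TPP-domain columns (pairwise deletion within each domain).
#' Undefined estimates (zero comparable columns, dS = 0, saturation, or
#' dS above the saturation guard) are flagged, not silently dropped.
#'
#' @param ca A [codon_alignment()].
#' @param part A [domain_partition()] over the alignment's columns.
#' @param method `"YN00"` (default) or `"NG86"`.
#' @param ds_max Saturation guard: pairs with dS above this value are
#'   marked invalid for plotting/testing (default 3).
#' @return Data frame of class `domain_rate_table` with one row per pair:
#'   ids, omega/dS/dN per domain, validity flags.
#' @export
domain_rate_scatter <- function(ca, part, method = c("YN00", "NG86"),
                                ds_max = 3) {
  method <- match.arg(method)
  estimator <- if (method == "YN00") yn00_pair else ng86_pair
  tb <- codon_tables()
  ok <- matrix(ca$mat %in% tb$codons, nrow = nrow(ca$mat))
  ids <- ca$ids
  rows <- list()
  for (i in seq_len(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      rec <- list(id1 = ids[i], id2 = ids[j])
      for (dom in c("TPS", "TPP")) {
        cols <- intersect(part[[dom]], which(ok[i, ] & ok[j, ]))
        if (length(cols) == 0) {
          rec[[paste0("omega_", dom)]] <- NA_real_
          rec[[paste0("dS_", dom)]] <- NA_real_
          rec[[paste0("dN_", dom)]] <- NA_real_
          rec[[paste0("flag_", dom)]] <- "no_comparable_columns"
          next
        }
        est <- estimator(ca$mat[i, cols], ca$mat[j, cols],
                         ids = c(ids[i], ids[j]))
        flag <- if (length(est$flags)) paste(est$flags, collapse = ";") else ""
        if (!is.na(est$dS) && est$dS > ds_max) {
          flag <- paste0(flag, if (nzchar(flag)) ";", "dS_above_guard")
        }
        rec[[paste0("omega_", dom)]] <- est$omega
        rec[[paste0("dS_", dom)]] <- est$dS
        rec[[paste0("dN_", dom)]] <- est$dN
        rec[[paste0("flag_", dom)]] <- flag
      }
      rows[[length(rows) + 1L]] <- as.data.frame(rec, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$valid <- !is.na(out$omega_TPS) & !is.na(out$omega_TPP) &
    !grepl("dS_above_guard|saturated", paste(out$flag_TPS, out$flag_TPP))
  class(out) <- c("domain_rate_table", "data.frame")
  attr(out, "method") <- method
  out
}

#' Paired test of domain rate relaxation
#'
#' Paired two-sided t-test on the per-pair differences
#' `omega_TPP - omega_TPS` over pairs with both estimates defined. A
#' positive mean difference indicates a more relaxed selective constraint
#' on the TPP (phosphatase) domain.
#'
#' @param tab A `domain_rate_table` from [domain_rate_scatter()].
#' @return A `group_comparison` (t, df, p, paired).
#' @export
paired_domain_test <- function(tab) {
  use <- tab[tab$valid, ]
  if (nrow(use) < 2) stop("need at least two pairs with both domain estimates")
  d <- use$omega_TPP - use$omega_TPS
  summarise <- function(v) {
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE)
    list(n = length(v), min = q[1], q1 = q[2], median = q[3], q3 = q[4],
         max = q[5])
  }
  if (all(d == 0)) {
    res <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
  } else {
    tt <- stats::t.test(d)
    res <- list(statistic = unname(tt$statistic),
                parameter = unname(tt$parameter), p.value = tt$p.value)
  }
  structure(list(groups = list(omega_TPS = summarise(use$omega_TPS),
                               omega_TPP = summarise(use$omega_TPP)),
                 mean_difference = mean(d),
                 t = res$statistic, df = res$parameter, p = res$p.value,
                 variant = "paired", paired = TRUE),
            class = "group_comparison")
}
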