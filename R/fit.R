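# Branch-model fitting: maximum likelihood over kappa, one or two omega
# values, and all branch lengths, on a fixed topology; likelihood-ratio
# tests between the nested one-ratio and two-ratio models; and the
# tree x region analysis suite.

data_digest <- function(d) {
  # cheap checksum guarding LRTs against comparing fits of different data
  paste(nrow(d$tips), length(d$weights), sum(d$weights),
        sum(as.numeric(d$tips) * seq_along(d$tips)) %% 1e9,
        paste(sort(d$tree$tip.label), collapse = ","), sep = "|")
}

#' Fit a one-ratio or two-ratio GY94 branch model
#'
#' Maximises the pruning log-likelihood over kappa, the omega value(s)
#' and all branch lengths, by bounded quasi-Newton (L-BFGS-B) with
#' analytic branch-length derivatives, multi-start. Under the two-ratio
#' model every edge inside the foreground clade plus its stem edge takes
#' the foreground omega; all other edges share the background omega.
#' Kappa is shared across branches. Branch lengths are (re)optimised
#' under each model.
#'
#' @param tree `phylo` topology; existing `edge.length` seed the
#'   optimiser, otherwise 0.1 per edge is used.
#' @param ca A [codon_alignment()].
#' @param model `"one_ratio"` or `"two_ratio"`.
#' @param foreground Leaf ids of the foreground clade (two-ratio only).
#' @param freq_model Codon frequency model (default `"F3x4"`), or a
#'   ready `codon_frequencies` object.
#' @param gap_policy `"complete_deletion"` (default) drops every column
#'   containing a gap/ambiguity before fitting; `"none"` keeps columns
#'   and treats non-sense cells as ambiguous.
#' @param n_starts Optimiser starts: one informed start plus jittered
#'   restarts (default 3).
#' @param seed Seed for the restart jitter (logged in the fit).
#' @param control List: `maxit` (default 500), `omega_bounds`
#'   (`c(1e-6, 50)`), `kappa_bounds` (`c(1e-3, 100)`), `t_bounds`
#'   (`c(1e-6, 50)`), `start` (optional named list with `kappa`, `omega`,
#'   `t`).
#' @return Object of class `branch_model_fit`.
#' @export
fit_branch_model <- function(tree, ca, model = c("one_ratio", "two_ratio"),
                             foreground = NULL,
                             freq_model = "F3x4",
                             gap_policy = c("complete_deletion", "none"),
                             n_starts = 3, seed = NULL,
                             control = list()) {
  model <- match.arg(model)
  gap_policy <- match.arg(gap_policy)
  if (model == "two_ratio" && is.null(foreground)) {
    stop("two_ratio model needs a foreground clade")
  }
  if (model == "one_ratio") foreground <- NULL
  ctl <- utils::modifyList(
    list(maxit = 500, omega_bounds = c(1e-6, 50),
         kappa_bounds = c(1e-3, 100), t_bounds = c(1e-6, 50),
         start = NULL), control)
  if (gap_policy == "complete_deletion") {
    ca <- mask_gapped_columns(ca, "complete_deletion")
  }
  freqs <- if (inherits(freq_model, "codon_frequencies")) freq_model
           else build_codon_freqs(ca, freq_model)
  pi <- as_pi(freqs)
  d <- prep_likelihood_data(tree, ca, foreground)
  n_omega <- if (model == "two_ratio") 2L else 1L
  nedge <- nrow(d$edges)

  negll <- function(par, grad = FALSE) {
    kappa <- exp(par[1])
    omegas <- exp(par[2:(1 + n_omega)])
    t <- par[(2 + n_omega):length(par)]
    res <- cpp_gy94_loglik(d$tips, d$weights, d$edges, t, d$edge_class,
                           kappa, omegas, pi, d$single, d$ti, d$ns, grad)
    res
  }
  fn <- function(par) -negll(par)$loglik
  gr <- function(par) {
    res <- negll(par, grad = TRUE)
    g_rate <- numeric(1 + n_omega)
    h <- 1e-5
    for (k in seq_len(1 + n_omega)) {
      up <- par; up[k] <- up[k] + h
      dn <- par; dn[k] <- dn[k] - h
      g_rate[k] <- (negll(up)$loglik - negll(dn)$loglik) / (2 * h)
    }
    -c(g_rate, res$grad_t)
  }

  t0 <- if (!is.null(d$tree$edge.length)) pmax(d$tree$edge.length, 1e-4)
        else rep(0.1, nedge)
  base_start <- list(kappa = 2, omega = rep(0.2, n_omega), t = t0)
  if (!is.null(ctl$start)) base_start <- utils::modifyList(base_start, ctl$start)
  if (!is.null(seed)) set.seed(seed)
  starts <- list(base_start)
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1]] <- list(
        kappa = base_start$kappa * exp(stats::runif(1, -1, 1)),
        omega = pmin(pmax(base_start$omega *
                            exp(stats::runif(n_omega, -1.5, 1.5)),
                          ctl$omega_bounds[1]), ctl$omega_bounds[2]),
        t = pmin(pmax(base_start$t * exp(stats::runif(nedge, -0.7, 0.7)),
                      ctl$t_bounds[1]), ctl$t_bounds[2]))
    }
  }
  lower <- c(log(ctl$kappa_bounds[1]), rep(log(ctl$omega_bounds[1]), n_omega),
             rep(ctl$t_bounds[1], nedge))
  upper <- c(log(ctl$kappa_bounds[2]), rep(log(ctl$omega_bounds[2]), n_omega),
             rep(ctl$t_bounds[2], nedge))
  best <- NULL
  diag_counts <- integer(0)
  for (st in starts) {
    par0 <- c(log(st$kappa), log(st$omega), st$t)
    par0 <- pmin(pmax(par0, lower), upper)
    opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = ctl$maxit, factr = 1e7))
    diag_counts <- c(diag_counts, opt$counts[1])
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  converged <- best$convergence == 0
  if (!converged) {
    warning("branch-model optimiser did not report convergence (code ",
            best$convergence, ")")
  }
  par <- best$par
  kappa_hat <- exp(par[1])
  omega_hat <- exp(par[2:(1 + n_omega)])
  names(omega_hat) <- if (n_omega == 2) c("background", "foreground") else "all"
  t_hat <- par[(2 + n_omega):length(par)]
  fitted_tree <- d$tree
  fitted_tree$edge.length <- t_hat

  structure(list(model = model,
                 omega_by_class = omega_hat,
                 kappa = kappa_hat,
                 freqs = freqs,
                 branch_lengths = t_hat,
                 tree = fitted_tree,
                 foreground = foreground,
                 loglik = -best$value,
                 n_free_params = nedge + 1L + n_omega,
                 converged = converged,
                 iterations = diag_counts,
                 n_starts = length(starts),
                 seed = seed,
                 gap_policy = gap_policy,
                 nsites = d$nsites,
                 npatterns = length(d$weights),
                 data_digest = data_digest(d)),
            class = "branch_model_fit")
}

#' @export
print.branch_model_fit <- function(x, ...) {
  cat("GY94 branch model (", x$model, "), ", length(x$tree$tip.label),
      " taxa, ", x$nsites, " codons\n", sep = "")
  cat("  lnL = ", format(x$loglik, digits = 10), "\n", sep = "")
  cat("  kappa = ", format(x$kappa, digits = 5), "\n", sep = "")
  for (nm in names(x$omega_by_class)) {
    cat("  omega (", nm, ") = ", format(x$omega_by_class[[nm]], digits = 5),
        "\n", sep = "")
  }
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  invisible(x)
}

#' @export
summary.branch_model_fit <- function(object, ...) {
  print(object)
  cat("  free parameters:", object$n_free_params,
      "| frequency model:", object$freqs$model,
      "| gap policy:", object$gap_policy, "\n")
  cat("  tree length:", format(sum(object$branch_lengths), digits = 5),
      "substitutions/codon\n")
  invisible(object)
}

#' @export
coef.branch_model_fit <- function(object, ...) {
  c(kappa = object$kappa,
    stats::setNames(object$omega_by_class,
                    paste0("omega_", names(object$omega_by_class))))
}

#' @export
logLik.branch_model_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free_params,
            nobs = object$nsites, class = "logLik")
}

#' @export
simulate.branch_model_fit <- function(object, nsim = 1, seed = NULL,
                                      n_codons = object$nsites, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  lapply(seq_len(nsim), function(k) {
    spec <- simulation_spec(
      tree = object$tree, kappa = object$kappa,
      omega = unname(object$omega_by_class),
      foreground = object$foreground,
      freqs = object$freqs, n_codons = n_codons,
      seed = seed + k - 1L)
    simulate_codon_alignment(spec)
  })
}

#' @export
plot.branch_model_fit <- function(x, ...) {
  cls <- edge_classes(x$tree, x$foreground)
  ape::plot.phylo(x$tree, edge.color = c("black", "firebrick")[cls],
                  main = paste0("GY94 ", x$model, " fit"), ...)
  lab <- paste0(names(x$omega_by_class), ": omega=",
                signif(x$omega_by_class, 3), collapse = "   ")
  graphics::mtext(lab, side = 1, line = 0.5, cex = 0.8)
  invisible(x)
}

#' Likelihood-ratio test between nested branch-model fits
#'
#' Compares twice the log-likelihood difference to a chi-squared
#' distribution with degrees of freedom equal to the difference in free
#' parameter counts (1 for two-ratio vs one-ratio). Both fits must come
#' from the same data (verified by checksum). A marginally negative
#' statistic from optimiser noise is clipped to 0.
#'
#' @param fit0 Null fit (fewer parameters).
#' @param fit1 Alternative fit.
#' @return Object of class `lrt_result`: lnL0, lnL1, statistic, df, p.
#' @export
likelihood_ratio_test <- function(fit0, fit1) {
  if (fit0$data_digest != fit1$data_digest) {
    stop("fits are not of the same data (checksum mismatch)")
  }
  df <- fit1$n_free_params - fit0$n_free_params
  if (df < 1) stop("fit1 must have more free parameters than fit0")
  stat <- max(0, 2 * (fit1$loglik - fit0$loglik))
  structure(list(lnL0 = fit0$loglik, lnL1 = fit1$loglik,
                 statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("LRT: 2*dlnL = ", format(x$statistic, digits = 6), ", df = ", x$df,
      ", p = ", format.pval(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Branch-model suite over trees and sequence regions
#'
#' For each supplied tree (with its foreground clade and optional leaf
#' subset) and each region (full length, TPS domain, TPP domain), fits
#' the one-ratio and two-ratio models and runs the LRT, emitting a
#' summary table in the shape of a selection-analysis report.
#'
#' @param ca A [codon_alignment()] of the full gene set.
#' @param trees List of specs: each a list with `label`, `tree` (phylo),
#'   `foreground` (leaf ids), optional `subset` (leaf ids to retain).
#' @param part A [domain_partition()], or `NULL` for full length only.
#' @param freq_model,gap_policy,n_starts,seed Passed to
#'   [fit_branch_model()].
#' @return Data frame: tree, region, model, parameter estimates, lnL,
#'   statistic, df, p; attribute `fits` holds the fit objects.
#' @export
run_table1_suite <- function(ca, trees, part = NULL, freq_model = "F3x4",
                             gap_policy = "complete_deletion",
                             n_starts = 3, seed = NULL) {
  regions <- list(full_length = seq_len(ncol(ca$mat)))
  if (!is.null(part)) {
    regions$TPS <- part$TPS
    regions$TPP <- part$TPP
  }
  rows <- list()
  fits <- list()
  for (ts in trees) {
    for (rg in names(regions)) {
      sub <- ca
      if (!is.null(ts$subset)) {
        sub <- codon_alignment(sub$mat[ts$subset, , drop = FALSE])
      }
      sub <- subset_columns(sub, regions[[rg]])
      tree <- ts$tree
      if (!is.null(ts$subset)) {
        tree <- ape::keep.tip(tree, intersect(tree$tip.label, ts$subset))
      }
      f0 <- fit_branch_model(tree, sub, "one_ratio",
                             freq_model = freq_model,
                             gap_policy = gap_policy,
                             n_starts = n_starts, seed = seed)
      f1 <- fit_branch_model(tree, sub, "two_ratio",
                             foreground = ts$foreground,
                             freq_model = freq_model,
                             gap_policy = gap_policy,
                             n_starts = n_starts, seed = seed)
      lrt <- likelihood_ratio_test(f0, f1)
      key <- paste(ts$label, rg, sep = ".")
      fits[[key]] <- list(one_ratio = f0, two_ratio = f1, lrt = lrt)
      rows[[length(rows) + 1L]] <- data.frame(
        tree = ts$label, region = rg, model = "one_ratio",
        estimates = sprintf("omega = %.5f for all branches",
                            f0$omega_by_class[["all"]]),
        lnL = f0$loglik, statistic = NA_real_, df = NA_integer_,
        p = NA_real_, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        tree = ts$label, region = rg, model = "two_ratio",
        estimates = sprintf(
          "omega_bg = %.5f, omega_fg = %.5f",
          f1$omega_by_class[["background"]],
          f1$omega_by_class[["foreground"]]),
        lnL = f1$loglik, statistic = lrt$statistic, df = lrt$df,
        p = lrt$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  attr(out, "settings") <- list(freq_model = freq_model,
                                gap_policy = gap_policy,
                                n_starts = n_starts, seed = seed)
  out
}
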