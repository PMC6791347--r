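# Maximum-likelihood fitting of the branch-category GY94 model, and the
# likelihood-ratio test against neutrality (omega = 1) for a focal
# category. Optimization is a bounded coordinate cycle: branch lengths are
# updated jointly by L-BFGS-B with analytic gradients (the spectral factors
# are fixed within the block, so each step is one pruning pass), then
# (kappa, free omegas) by L-BFGS-B with numerical gradients. Cycles repeat
# until the log-likelihood improves by less than `tol`.

.OMEGA_BOUNDS <- c(1e-4, 10)
.KAPPA_BOUNDS <- c(0.1, 20)
.BLEN_BOUNDS <- c(1e-6, 50)

.optimize_blens <- function(pat, pl, eigs, t0, pi, maxit = 25L) {
  lt0 <- log(pmin(pmax(t0, .BLEN_BOUNDS[1]), .BLEN_BOUNDS[2]))
  fn <- function(lt) {
    r <- .loglik_core(pat, pl, eigs, exp(lt), pi)
    if (!is.finite(r$loglik)) return(1e12)
    -r$loglik
  }
  gr <- function(lt) {
    t <- exp(lt)
    r <- .loglik_core(pat, pl, eigs, t, pi, want_grad = TRUE)
    if (!is.finite(r$loglik) || length(r$grad) == 0L)
      return(rep(0, length(lt)))
    -r$grad * t                      # chain rule for the log scale
  }
  o <- stats::optim(lt0, fn, gr, method = "L-BFGS-B",
                    lower = log(.BLEN_BOUNDS[1]), upper = log(.BLEN_BOUNDS[2]),
                    control = list(maxit = maxit))
  list(t = exp(o$par), nll = o$value)
}

.optimize_rates <- function(pat, pl, t, pi, kappa0, omega0, free_om,
                            fixed_om, maxit = 25L) {
  # parameter vector: log kappa, log omega for each free category
  p0 <- c(log(kappa0), log(omega0[free_om]))
  build_om <- function(p) {
    om <- fixed_om
    om[free_om] <- exp(p[-1L])
    om
  }
  fn <- function(p) {
    eigs <- .category_eigens(exp(p[1L]), build_om(p)[pl$cat_levels], pi)
    r <- .loglik_core(pat, pl, eigs, t, pi)
    if (!is.finite(r$loglik)) return(1e12)
    -r$loglik
  }
  lower <- c(log(.KAPPA_BOUNDS[1]), rep(log(.OMEGA_BOUNDS[1]), length(free_om)))
  upper <- c(log(.KAPPA_BOUNDS[2]), rep(log(.OMEGA_BOUNDS[2]), length(free_om)))
  o <- stats::optim(p0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                    control = list(maxit = maxit))
  list(kappa = exp(o$par[1L]), omega = build_om(o$par), nll = o$value)
}

.fit_one_start <- function(pat, pl, pi, kappa, omega, free_om, fixed_om, t,
                           max_cycles, tol, inner_maxit = 25L) {
  nll <- Inf
  converged <- FALSE
  cycles <- 0L
  for (cyc in seq_len(max_cycles)) {
    cycles <- cyc
    eigs <- .category_eigens(kappa, omega[pl$cat_levels], pi)
    b <- .optimize_blens(pat, pl, eigs, t, pi, maxit = inner_maxit)
    t <- b$t
    r <- .optimize_rates(pat, pl, t, pi, kappa, omega, free_om, fixed_om,
                         maxit = inner_maxit)
    kappa <- r$kappa
    omega <- r$omega
    new_nll <- r$nll
    if (is.finite(nll) && nll - new_nll < tol) {
      nll <- min(nll, new_nll)
      converged <- TRUE
      break
    }
    nll <- new_nll
  }
  list(kappa = kappa, omega = omega, t = t, nll = nll,
       converged = converged, cycles = cycles)
}

#' Fit a branch-category codon model by maximum likelihood
#'
#' Maximizes the [codon_log_likelihood()] over kappa, the omega of each free
#' category, and all branch lengths. Equilibrium frequencies are F3x4
#' estimates from the alignment and are held fixed (the codeml convention).
#' Optimization is a bounded coordinate cycle over (branch lengths) and
#' (kappa, omegas), run from several deterministic omega starts; the best
#' start is polished to convergence.
#'
#' @param aln a [codon_alignment()].
#' @param ltree a [labeled_tree()]; its edge lengths are the starting values
#'   and are re-estimated.
#' @param free_categories categories whose omega is estimated; defaults to
#'   all categories on the tree.
#' @param fixed_values named list: optional `omega` (named vector of fixed
#'   omegas for non-free categories; default 1) and `kappa` start (default 2).
#' @param opts list of optimizer options: `starts` (omega start values,
#'   default `c(0.1, 1, 2)`), `max_cycles` (default 30), `tol` (default
#'   1e-6), `probe_cycles` (cycles per start before picking the best,
#'   default 2).
#' @return a `BranchModelFit`: list with `kappa`, `omega` (per category),
#'   `loglik`, `tree` (edge lengths at the optimum), `categories`,
#'   `free_categories`, `npar`, `converged`, `cycles`, `codon_freqs`.
#' @export
fit_branch_model <- function(aln, ltree, free_categories = NULL,
                             fixed_values = list(), opts = list()) {
  starts <- opts$starts %||% c(0.1, 1, 2)
  max_cycles <- opts$max_cycles %||% 30L
  tol <- opts$tol %||% 1e-6
  probe <- opts$probe_cycles %||% 2L
  pi <- opts$codon_freqs %||% f3x4_frequencies(aln)

  pat <- .site_patterns(aln)
  pl <- .tree_plumbing(ltree)
  lev <- pl$cat_levels
  if (is.null(free_categories)) free_categories <- lev
  if (!all(free_categories %in% lev))
    stop("free categories not on tree: ",
         paste(setdiff(free_categories, lev), collapse = ", "))
  fixed_om <- stats::setNames(rep(1, length(lev)), lev)
  if (!is.null(fixed_values$omega)) {
    nm <- names(fixed_values$omega)
    fixed_om[nm] <- fixed_values$omega
  }
  kappa0 <- fixed_values$kappa %||% 2
  t0 <- pmin(pmax(pl$edge_len, 0.05), 5)

  # probe each deterministic start briefly, then polish the best
  probes <- lapply(starts, function(w0) {
    om0 <- fixed_om
    om0[free_categories] <- w0
    .fit_one_start(pat, pl, pi, kappa0, om0, free_categories, fixed_om, t0,
                   max_cycles = probe, tol = tol)
  })
  best <- probes[[which.min(vapply(probes, `[[`, numeric(1), "nll"))]]
  fit <- .fit_one_start(pat, pl, pi, best$kappa, best$omega,
                        free_categories, fixed_om, best$t,
                        max_cycles = max_cycles, tol = tol)

  tr <- pl$tree
  tr$edge.length[pl$order] <- fit$t
  structure(list(
    kappa = fit$kappa,
    omega = fit$omega[lev],
    loglik = -fit$nll,
    tree = labeled_tree(tr, ltree$categories),
    categories = lev,
    free_categories = free_categories,
    codon_freqs = pi,
    npar = 1L + length(free_categories) + length(fit$t),
    converged = fit$converged,
    cycles = fit$cycles), class = "BranchModelFit")
}

#' @export
print.BranchModelFit <- function(x, ...) {
  cat("Branch-model fit: log-likelihood", sprintf("%.3f", x$loglik),
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat("  kappa =", sprintf("%.3f", x$kappa), "\n")
  for (k in x$categories) {
    cat(sprintf("  omega[%s] = %.4f%s\n", k, x$omega[[k]],
                if (k %in% x$free_categories) "" else " (fixed)"))
  }
  invisible(x)
}

#' Likelihood-ratio test of neutral evolution for a branch category
#'
#' Compares a fit in which the focal category's omega is free (alternative)
#' with the nested fit in which it is fixed at 1 (null); 2 * (l_alt -
#' l_null), clamped at 0, is referred to the chi-squared upper tail with
#' one degree of freedom per fixed category.
#'
#' @param fit_alt,fit_null `BranchModelFit` objects; the null must be the
#'   alternative with one or more focal omegas fixed to 1.
#' @return an `LRTResult`: list with `statistic`, `df`, `p_value`, and the
#'   focal categories tested.
#' @export
lrt_neutral <- function(fit_alt, fit_null) {
  if (!identical(fit_alt$categories, fit_null$categories))
    stop("fits use different category sets")
  focal <- setdiff(fit_alt$free_categories, fit_null$free_categories)
  extra <- setdiff(fit_null$free_categories, fit_alt$free_categories)
  if (length(extra) > 0L || length(focal) == 0L)
    stop("fits are not nested: null must fix a subset of the alternative's ",
         "free omegas at 1")
  if (any(abs(unlist(fit_null$omega[focal]) - 1) > 1e-12))
    stop("null fit does not fix the focal omega(s) at 1")
  stat <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  df <- length(focal)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 focal = focal), class = "LRTResult")
}

#' @export
print.LRTResult <- function(x, ...) {
  cat(sprintf("LRT vs neutrality (%s): 2*dlnL = %.4f, df = %d, p = %.4g\n",
              paste(x$focal, collapse = ","), x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Two-ratio test of one branch category against neutrality
#'
#' Convenience wrapper reproducing the per-category testing design: the
#' tree's categories are collapsed to focal vs background, the alternative
#' fit estimates both omegas, the null fixes the focal omega at 1 (keeping
#' the background omega free), and the two fits are compared by
#' [lrt_neutral()] with df = 1.
#'
#' @param aln a [codon_alignment()].
#' @param ltree a [labeled_tree()].
#' @param focal the category to test.
#' @param opts optimizer options, see [fit_branch_model()].
#' @return list with `omega` (focal ML estimate), `omega_background`,
#'   `kappa`, `lrt` (an `LRTResult`), `fit_alt`, `fit_null`.
#' @export
test_branch_category <- function(aln, ltree, focal, opts = list()) {
  if (!focal %in% ltree$categories)
    stop("category not on tree: ", focal)
  two <- labeled_tree(ltree$tree,
                      ifelse(ltree$categories == focal, focal, "background"))
  fit_alt <- fit_branch_model(aln, two, opts = opts)
  null_opts <- opts
  null_opts$starts <- fit_alt$omega[["background"]]
  fit_null <- fit_branch_model(
    aln, fit_alt$tree, free_categories = "background",
    fixed_values = list(omega = c(stats::setNames(1, focal)),
                        kappa = fit_alt$kappa),
    opts = null_opts)
  lrt <- lrt_neutral(fit_alt, fit_null)
  list(omega = fit_alt$omega[[focal]],
       omega_background = fit_alt$omega[["background"]],
       kappa = fit_alt$kappa, lrt = lrt,
       fit_alt = fit_alt, fit_null = fit_null)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
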