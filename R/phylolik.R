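## tip-state matrix (patterns x tips) in the tree's tip order
.tip_states <- function(msa, tree) {
  idx <- match(tree$tip.label, msa$labels)
  if (anyNA(idx) || length(tree$tip.label) != length(msa$labels))
    stop("tree leaf set must equal the alignment's sequence labels")
  msa$patterns[, idx, drop = FALSE]
}

## invariant-class likelihood per pattern: sum of pi over states compatible
## with a constant column (gaps/X are wildcards); 0 if no state fits
.invariant_class <- function(patterns, freqs) {
  apply(patterns, 1L, function(row) {
    obs <- unique(row[row > 0L])
    if (length(obs) == 0L) 1
    else if (length(obs) == 1L) freqs[obs]
    else 0
  })
}

.postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  storage.mode(tr$edge) <- "integer"
  tr
}

#' Per-site-pattern log-likelihood of an alignment on a tree
#'
#' Computes per-pattern log-likelihoods by the pruning algorithm under the
#' +I+G mixture: `p_inv * L0 + ((1 - p_inv)/k) * sum_c L(rate r_c/(1 -
#' p_inv))`, where `L0` is the invariant-class likelihood (equilibrium
#' frequency of the constant state, with gaps and `X` as wildcards). The
#' result does not depend on where the pruning is rooted (the model is
#' reversible).
#'
#' @param tree a `phylo` with branch lengths; leaf set must equal the
#'   alignment's labels.
#' @param msa an [aa_msa].
#' @param model a [subst_model].
#' @return numeric vector of per-pattern log-likelihoods with attributes
#'   `weights` (pattern multiplicities) and `loglik` (weighted total).
#' @export
site_loglik <- function(tree, msa, model) {
  stopifnot(inherits(msa, "aa_msa"), inherits(model, "subst_model"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (model$p_inv >= 1) stop("'p_inv' must be < 1 for inference")
  tr <- .postorder(tree)
  ts <- .tip_states(msa, tr)
  res <- plik_full(tr$edge, tr$edge.length, ape::Ntip(tr), ts, msa$weights,
                   model$eig$U, model$eig$Uinv, model$eig$lambda,
                   model$freqs, mixture_rates(model), model$p_inv,
                   .invariant_class(ts, model$freqs))
  structure(as.numeric(res$site_loglik),
            weights = msa$weights, loglik = res$loglik)
}

.ml_control <- function(control = list()) {
  d <- list(tol = 1e-4, max_rounds = 20L, gtol = 1e-4, min_bl = 1e-8,
            max_bl = 10, init_bl = 0.1, outer_rounds = 5L,
            alpha_bounds = c(0.02, 100), pinv_max = 0.99,
            alpha_tol = 0.005, pinv_tol = 0.003)
  d[names(control)] <- control
  d
}

#' Maximum-likelihood fit of branch lengths and rate parameters on a
#' fixed topology
#'
#' Optimizes all branch lengths of `tree` (topology fixed) and, optionally,
#' the gamma shape `alpha` and the invariant fraction `p_inv`, by cyclic
#' one-dimensional search: golden-section optimization of each branch in
#' preorder sweeps that keep partial likelihoods current (so each
#' one-dimensional problem is the exact profile likelihood), interleaved
#' with bounded scalar optimization of `alpha` (log scale) and `p_inv`.
#' The total log-likelihood is non-decreasing across iterations; if the
#' improvement never falls below `tol` within the iteration budget the
#' best-so-far fit is returned with `converged = FALSE` (no error).
#'
#' Bounds: branch lengths in `[1e-8, 10]`, `alpha` in `[0.02, 100]`,
#' `p_inv` in `[0, 0.99]`.
#'
#' @param tree a `phylo` giving the topology; existing branch lengths are
#'   used as starting values, otherwise all branches start at
#'   `control$init_bl`.
#' @param msa an [aa_msa].
#' @param model a [subst_model]; its `alpha`/`p_inv` are starting values.
#' @param optimize_alpha,optimize_pinv fit the rate parameters (`TRUE`) or
#'   hold them at the model's values (`FALSE`).
#' @param control list overriding optimization settings (`tol`,
#'   `max_rounds`, `gtol`, `outer_rounds`, bounds, ...).
#' @return an object of class `phylo_ml`: the tree with fitted branch
#'   lengths, the fitted model, the total and per-pattern log-likelihoods,
#'   and a convergence flag.
#' @export
optimize_tree <- function(tree, msa, model,
                          optimize_alpha = TRUE, optimize_pinv = TRUE,
                          control = list()) {
  stopifnot(inherits(msa, "aa_msa"), inherits(model, "subst_model"))
  ctl <- .ml_control(control)
  tr <- .postorder(tree)
  if (is.null(tr$edge.length))
    tr$edge.length <- rep(ctl$init_bl, nrow(tr$edge))
  ts <- .tip_states(msa, tr)
  l0 <- .invariant_class(ts, model$freqs)
  ntip <- ape::Ntip(tr)

  fit_branches <- function(el, m, rounds) {
    plik_optim(tr$edge, el, ntip, ts, msa$weights,
               m$eig$U, m$eig$Uinv, m$eig$lambda, m$freqs,
               mixture_rates(m), m$p_inv, l0,
               ctl$tol, as.integer(rounds), ctl$min_bl, ctl$max_bl, ctl$gtol)
  }
  eval_full <- function(el, m) {
    plik_full(tr$edge, el, ntip, ts, msa$weights,
              m$eig$U, m$eig$Uinv, m$eig$lambda, m$freqs,
              mixture_rates(m), m$p_inv, l0)$loglik
  }

  el <- pmin(pmax(tr$edge.length, ctl$min_bl), ctl$max_bl)
  m <- model
  ll <- -Inf
  converged <- FALSE
  iters <- 0L
  outer <- if (optimize_alpha || optimize_pinv) ctl$outer_rounds else 1L
  for (it in seq_len(outer)) {
    iters <- it
    fb <- fit_branches(el, m, ctl$max_rounds)
    el <- fb$el
    ll_new <- fb$loglik
    if (optimize_alpha) {
      opt <- stats::optimize(function(la) {
        m2 <- m; m2$alpha <- exp(la)
        eval_full(el, m2)
      }, log(ctl$alpha_bounds), maximum = TRUE, tol = ctl$alpha_tol)
      m$alpha <- exp(opt$maximum)
      ll_new <- max(ll_new, opt$objective)
    }
    if (optimize_pinv) {
      opt <- stats::optimize(function(pv) {
        m2 <- m; m2$p_inv <- pv
        eval_full(el, m2)
      }, c(0, ctl$pinv_max), maximum = TRUE, tol = ctl$pinv_tol)
      m$p_inv <- opt$maximum
      ll_new <- max(ll_new, opt$objective)
    }
    if (is.finite(ll) && ll_new - ll < ctl$tol) {
      ll <- max(ll, ll_new)
      converged <- TRUE
      break
    }
    ll <- ll_new
    if (!optimize_alpha && !optimize_pinv) {
      converged <- fb$converged
      break
    }
  }
  final <- plik_full(tr$edge, el, ntip, ts, msa$weights,
                     m$eig$U, m$eig$Uinv, m$eig$lambda, m$freqs,
                     mixture_rates(m), m$p_inv, l0)
  tr$edge.length <- as.numeric(el)
  structure(list(
    tree = tr, model = m,
    loglik = final$loglik,
    site_loglik = as.numeric(final$site_loglik),
    weights = msa$weights, n_sites = msa$n_sites,
    alpha = m$alpha, p_inv = m$p_inv,
    converged = converged, iterations = iters,
    optimized = c(alpha = optimize_alpha, p_inv = optimize_pinv)
  ), class = "phylo_ml")
}

#' @export
print.phylo_ml <- function(x, ...) {
  cat(sprintf(
    "ML fit on fixed topology (%d leaves): logL = %.4f\n", ape::Ntip(x$tree),
    x$loglik))
  cat(sprintf("  %s model, alpha = %.4g%s, p_inv = %.4g%s%s\n",
              x$model$name, x$alpha,
              if (x$optimized[["alpha"]]) " (fitted)" else "",
              x$p_inv,
              if (x$optimized[["p_inv"]]) " (fitted)" else "",
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @export
logLik.phylo_ml <- function(object, ...) {
  df <- nrow(object$tree$edge) + sum(object$optimized)
  structure(object$loglik, df = df, nobs = object$n_sites, class = "logLik")
}

#' @export
coef.phylo_ml <- function(object, ...) {
  c(alpha = object$alpha, p_inv = object$p_inv,
    stats::setNames(object$tree$edge.length,
                    paste0("edge", seq_along(object$tree$edge.length))))
}

#' Simulate alignments from a fitted model
#'
#' Draws new alignments of the fitted size along the fitted tree under the
#' fitted substitution model (parametric bootstrap).
#'
#' @param object a `phylo_ml` fit.
#' @param nsim number of alignments.
#' @param seed integer seed; replicate `i` uses `seed + i - 1`.
#' @param ... unused.
#' @return a list of [aa_msa] objects (length `nsim`).
#' @export
simulate.phylo_ml <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim), function(i)
    simulate_alignment(object$tree, object$model, object$n_sites,
                       as.integer(seed) + i - 1L))
}
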