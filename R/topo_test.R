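#' Exhaustive constrained topology test
#'
#' The package's central fitting function. Given an aligned protein
#' alignment and an OTU constraint (a partition of the leaves into
#' supertaxa with fixed within-OTU subtrees), it enumerates every unrooted
#' topology over the OTUs (or takes a supplied candidate list), expands
#' each to a full leaf-level tree, fits branch lengths and rate parameters
#' by maximum likelihood for each topology, applies the AU, KH and SH
#' tests by RELL resampling, ranks topologies by the scaled
#' log-likelihood deficit `delta_logl/se`, and classifies each topology
#' into a duplication-timing scenario.
#'
#' @param msa an [aa_msa] (or a FASTA path).
#' @param constraint an [otu_constraint] (or a JSON path).
#' @param topologies optional list of OTU-level `phylo` candidates; by
#'   default all `(2k-5)!!` topologies over the OTU names are enumerated.
#' @param model a [subst_model]; starting values for fitted parameters.
#' @param rell a [rell_config] controlling the resampling tests.
#' @param rules a [scenario_rules] set; `NULL` skips classification.
#' @param optimize_alpha,optimize_pinv fit the gamma shape / invariant
#'   fraction per topology (default) or hold them fixed.
#' @param share_rates if `TRUE`, `alpha` and `p_inv` are fitted once on
#'   the first candidate topology and then held fixed across topologies
#'   (faster; the default refits them per topology).
#' @param tests run the AU/KH/SH tests (`TRUE`); `FALSE` computes only the
#'   ranking, which is sufficient to identify the ML topology.
#' @param control optimization settings passed to [optimize_tree()].
#' @param verbose print progress.
#' @return an object of class `topo_test` with elements `table` (the
#'   ranked `topo_test_table`), `site_loglik` (the
#'   [site_loglik_matrix]), `fits` (per-topology `phylo_ml` fits),
#'   `supertrees`, `constraint`, `rell`, `rules` and `call`.
#' @seealso [summary.topo_test()], [plot.topo_test()], [run_pipeline()]
#' @export
topo_test <- function(msa, constraint, topologies = NULL,
                      model = subst_model("JTT", alpha = 1, k = 4L,
                                          p_inv = 0.1),
                      rell = rell_config(),
                      rules = duplication_rules(),
                      optimize_alpha = TRUE, optimize_pinv = TRUE,
                      share_rates = FALSE, tests = TRUE,
                      control = list(), verbose = FALSE) {
  if (is.character(msa)) msa <- read_msa_fasta(msa)
  if (is.character(constraint)) constraint <- read_constraint(constraint)
  stopifnot(inherits(msa, "aa_msa"), inherits(constraint, "otu_constraint"))
  if (!setequal(msa$labels, unlist(constraint$otus)))
    stop("alignment labels must equal the constraint's leaf set")
  otu_names <- names(constraint$otus)
  supertrees <- if (is.null(topologies)) {
    enumerate_topologies(otu_names)
  } else {
    for (t in topologies)
      if (!setequal(t$tip.label, otu_names))
        stop("candidate topology leaf set must equal the OTU names")
    topologies
  }
  full <- lapply(supertrees, expand_constrained, constraint = constraint)

  fit_one <- function(tr, m, oa, op)
    optimize_tree(tr, msa, m, optimize_alpha = oa, optimize_pinv = op,
                  control = control)
  fits <- vector("list", length(full))
  m <- model
  if (share_rates && (optimize_alpha || optimize_pinv)) {
    fits[[1]] <- fit_one(full[[1]], m, optimize_alpha, optimize_pinv)
    m <- fits[[1]]$model
    optimize_alpha <- optimize_pinv <- FALSE
  }
  for (i in seq_along(full)) {
    if (is.null(fits[[i]]))
      fits[[i]] <- fit_one(full[[i]], m, optimize_alpha, optimize_pinv)
    if (verbose && i %% 10 == 0)
      message(sprintf("  fitted %d/%d topologies", i, length(full)))
  }

  sl <- site_loglik_matrix(
    do.call(rbind, lapply(fits, `[[`, "site_loglik")),
    msa$weights,
    vapply(supertrees, ape::write.tree, ""))
  labels <- if (is.null(rules)) NULL else
    vapply(supertrees, classify_topology, "", rules = rules)
  tab <- build_table(sl, rell, scenario_labels = labels, tests = tests)
  structure(list(
    table = tab, site_loglik = sl, fits = fits, supertrees = supertrees,
    constraint = constraint, rell = rell, rules = rules,
    n_sites = msa$n_sites, call = match.call()
  ), class = "topo_test")
}

#' @export
print.topo_test <- function(x, n = 10L, ...) {
  cat(sprintf(
    "Constrained topology test: %d topologies over %d OTUs, %d sites\n",
    nrow(x$table), length(x$constraint$otus), x$n_sites))
  nc <- sum(!vapply(x$fits, `[[`, TRUE, "converged"))
  if (nc > 0) cat(sprintf("  (%d fits did not converge)\n", nc))
  print(x$table, n = n, ...)
  invisible(x)
}

#' Scenario-level summary of a topology test
#'
#' @param object a `topo_test` fit.
#' @param alpha rejection level for the "not rejected" call.
#' @param ... unused.
#' @return a `summary.topo_test` object wrapping the [scenario_support()]
#'   table and headline quantities.
#' @export
summary.topo_test <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  structure(list(
    n_topologies = nrow(tab),
    n_within_1se = sum(tab$within_1se),
    ml_tree = tab$tree[1],
    ml_scenario = tab$scenario[1],
    support = if (all(is.na(tab$scenario))) NULL else
      scenario_support(tab, alpha = alpha),
    alpha = alpha
  ), class = "summary.topo_test")
}

#' @export
print.summary.topo_test <- function(x, ...) {
  cat(sprintf("%d topologies evaluated; %d within 1 SE of the ML tree\n",
              x$n_topologies, x$n_within_1se))
  cat(sprintf("ML topology: %s", x$ml_tree))
  if (!is.na(x$ml_scenario)) cat(sprintf("  [%s]", x$ml_scenario))
  cat("\n")
  if (!is.null(x$support)) {
    cat(sprintf("Scenario support (alpha = %g):\n", x$alpha))
    print(x$support, row.names = FALSE)
  }
  invisible(x)
}

#' Plot the scaled log-likelihood deficit by rank
#'
#' Base-graphics plot of `delta_logl/se` against rank, colored by
#' scenario, with the within-1-SE band marked.
#'
#' @param x a `topo_test` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.topo_test <- function(x, ...) {
  tab <- x$table
  scen <- factor(ifelse(is.na(tab$scenario), "other", tab$scenario))
  cols <- stats::setNames(
    grDevices::hcl.colors(max(3L, nlevels(scen)), "Dark 3")[seq_len(nlevels(scen))],
    levels(scen))
  ratio <- pmin(tab$ratio, max(tab$ratio[is.finite(tab$ratio)]) * 1.05)
  graphics::plot(tab$rank, ratio, pch = 19, col = cols[as.character(scen)],
                 xlab = "rank", ylab = "delta logL / SE", ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  graphics::legend("topleft", legend = levels(scen), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}
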