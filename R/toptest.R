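#' RELL resampling configuration
#'
#' Settings for resampling estimated log-likelihoods (RELL): per-site
#' log-likelihoods are resampled instead of re-optimizing trees. Defaults
#' follow the classic multiscale-bootstrap implementation: ten scales
#' 0.5-1.4 and 10,000 replicates per scale.
#'
#' @param B replicates per scale (>= 100).
#' @param scales resampling scale factors; must include 1.0 (the KH and SH
#'   tests use the unit scale).
#' @param seed integer seed; replicate draws are derived per scale from it
#'   by a fixed offset, and draws are shared across trees within a
#'   replicate, so adding a tree never changes existing replicates.
#' @return an object of class `rell_config`.
#' @export
rell_config <- function(B = 10000L, scales = seq(0.5, 1.4, by = 0.1),
                        seed = 1L) {
  B <- as.integer(B)
  if (B < 100L) stop("'B' must be at least 100")
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("'scales' must be positive and finite")
  if (!any(abs(scales - 1) < 1e-9))
    stop("scale 1.0 must be present (KH/SH use it)")
  structure(list(B = B, scales = as.numeric(scales), seed = as.integer(seed)),
            class = "rell_config")
}

#' Per-tree site log-likelihood matrix
#'
#' Container pairing each candidate topology's per-pattern log-likelihoods
#' (at that topology's optimized parameters) with the shared pattern
#' multiplicities. Rows are trees, columns are site patterns.
#'
#' @param loglik numeric matrix (trees x patterns) of per-pattern
#'   log-likelihoods.
#' @param weights pattern multiplicities (shared across trees).
#' @param trees character vector of Newick strings, one per row.
#' @return an object of class `site_loglik_matrix` with per-tree totals and
#'   canonical topology strings.
#' @export
site_loglik_matrix <- function(loglik, weights, trees) {
  loglik <- as.matrix(loglik)
  if (ncol(loglik) != length(weights))
    stop("number of patterns differs between 'loglik' and 'weights'")
  if (nrow(loglik) != length(trees))
    stop("one tree string required per row of 'loglik'")
  if (any(!is.finite(loglik))) stop("non-finite site log-likelihoods")
  structure(list(
    loglik = loglik, weights = as.numeric(weights),
    trees = as.character(trees),
    canonical = vapply(trees, function(s) canonical_form(s), "",
                       USE.NAMES = FALSE),
    total = as.numeric(loglik %*% weights),
    n_sites = sum(weights)
  ), class = "site_loglik_matrix")
}

#' @export
print.site_loglik_matrix <- function(x, ...) {
  cat(sprintf("Site log-likelihoods: %d trees x %d patterns (%g sites)\n",
              nrow(x$loglik), ncol(x$loglik), x$n_sites))
  invisible(x)
}

## index of the ML tree; ties broken by lowest canonical string
.ml_index <- function(sl) {
  best <- which(sl$total >= max(sl$total) - 1e-12)
  best[order(sl$canonical[best])][1]
}

#' Log-likelihood deficit and its standard error per topology
#'
#' For each tree `i`, `delta_logl = logL_ML - logL_i >= 0` and
#' `se = sqrt( n/(n-1) * sum_sites (d_s - mean(d))^2 )` where `d_s` is the
#' per-site log-likelihood difference between tree `i` and the ML tree
#' (expanded over pattern multiplicities) and `n` the number of sites.
#' The ML tree's SE is reported as 0.
#'
#' @param sl a [site_loglik_matrix] with at least two trees.
#' @return data frame with columns `delta_logl`, `se` and logical `is_ml`.
#' @export
delta_and_se <- function(sl) {
  stopifnot(inherits(sl, "site_loglik_matrix"))
  if (nrow(sl$loglik) < 2L)
    stop("at least two trees are required to compute the deficit")
  ml <- .ml_index(sl)
  n <- sl$n_sites
  w <- sl$weights
  d <- sweep(-sl$loglik, 2L, sl$loglik[ml, ], `+`)    # d[i,p] = ml_p - i_p
  delta <- as.numeric(d %*% w)
  dbar <- delta / n
  ss <- as.numeric((d - dbar)^2 %*% w)
  se <- sqrt(n / (n - 1) * ss)
  se[ml] <- 0
  data.frame(delta_logl = delta, se = se,
             is_ml = seq_len(nrow(sl$loglik)) == ml)
}

#' RELL replicate totals at one resampling scale
#'
#' Draws `round(scale * n)` sites per replicate (pattern indices with
#' replacement, probability proportional to multiplicity) and returns each
#' tree's resampled total log-likelihood. The same site draws are reused
#' across all trees within a replicate; an identical seed yields identical
#' replicates.
#'
#' @param sl a [site_loglik_matrix].
#' @param cfg a [rell_config].
#' @param scale positive resampling scale factor.
#' @return trees x `B` matrix of replicate total log-likelihoods.
#' @export
rell_resample <- function(sl, cfg, scale = 1) {
  stopifnot(inherits(sl, "site_loglik_matrix"), inherits(cfg, "rell_config"))
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be positive")
  m <- max(1L, as.integer(round(scale * sl$n_sites)))
  set.seed(cfg$seed + as.integer(round(1000 * scale)))
  counts <- stats::rmultinom(cfg$B, m, prob = sl$weights / sl$n_sites)
  sl$loglik %*% counts
}

## replicate totals at every configured scale (list keyed by scale)
.rell_all_scales <- function(sl, cfg) {
  out <- lapply(cfg$scales, function(s) rell_resample(sl, cfg, s))
  names(out) <- format(cfg$scales)
  out
}

.unit_scale <- function(cfg) which(abs(cfg$scales - 1) < 1e-9)[1]

#' One-sided Kishino-Hasegawa test per topology
#'
#' For tree `i` versus the ML tree, the unit-scale replicate differences
#' `T_ML - T_i` are centered on their own mean and the p-value is the
#' proportion of centered replicates at least as large as the observed
#' `delta_logl_i` (one-sided). The ML tree gets p = 1. The classical
#' normal approximation (observed deficit against `Normal(0, SE^2)`) is
#' available via `method = "normal"`.
#'
#' @param sl a [site_loglik_matrix].
#' @param cfg a [rell_config].
#' @param method `"rell"` (centered resampling, default) or `"normal"`.
#' @param replicates optional precomputed unit-scale replicate matrix
#'   (from [rell_resample()]), to share draws across tests.
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
kh_test <- function(sl, cfg, method = c("rell", "normal"),
                    replicates = NULL) {
  method <- match.arg(method)
  ds <- delta_and_se(sl)
  if (method == "normal") {
    p <- stats::pnorm(ds$delta_logl / ifelse(ds$se > 0, ds$se, Inf),
                      lower.tail = FALSE)
    p[ds$is_ml] <- 1
    return(p)
  }
  Tm <- if (is.null(replicates)) rell_resample(sl, cfg, 1) else replicates
  ml <- which(ds$is_ml)
  vapply(seq_len(nrow(sl$loglik)), function(i) {
    dstar <- Tm[ml, ] - Tm[i, ]
    mean(dstar - mean(dstar) >= ds$delta_logl[i])
  }, 0)
}

#' Shimodaira-Hasegawa test per topology
#'
#' Each tree's unit-scale replicate totals are centered by that tree's
#' replicate mean; the null distribution for every tree is the replicate
#' maximum over all candidate trees. `p_i` is the proportion of replicates
#' in which `max_j S_jb - S_ib` reaches the observed `delta_logl_i`. By
#' construction the ML tree gets p = 1 and `p_SH >= p_KH` for every tree
#' on the same replicate set.
#'
#' @inheritParams kh_test
#' @return numeric vector of p-values in `[0, 1]`.
#' @export
sh_test <- function(sl, cfg, replicates = NULL) {
  ds <- delta_and_se(sl)
  Tm <- if (is.null(replicates)) rell_resample(sl, cfg, 1) else replicates
  S <- Tm - rowMeans(Tm)
  M <- apply(S, 2L, max)
  vapply(seq_len(nrow(sl$loglik)), function(i)
    mean(M - S[i, ] >= ds$delta_logl[i]), 0)
}

#' Approximately unbiased (AU) test per topology
#'
#' Multiscale bootstrap: at each resampling scale `r` the bootstrap
#' proportion `BP_r` is the fraction of replicates in which the tree
#' attains the maximum total log-likelihood. The probit-transformed
#' proportions `z_r = qnorm(1 - BP_r)` are fitted against
#' `z_r = d*sqrt(r) + c/sqrt(r)` by weighted least squares (weights from
#' the binomial variance of `BP_r`), and `p_AU = 1 - pnorm(d - c)`.
#' Proportions are clamped to `[1/(B+1), 1 - 1/(B+1)]` before the probit.
#' A tree with fewer than two non-degenerate scales (BP strictly inside
#' (0, 1)) is reported as 0 or 1 by the sign of its degenerate
#' proportions and flagged.
#'
#' @param sl a [site_loglik_matrix].
#' @param cfg a [rell_config] with at least three scales.
#' @param replicates optional precomputed list of replicate matrices, one
#'   per scale (from [rell_resample()]).
#' @return numeric vector of p-values with logical attribute `degenerate`.
#' @export
au_test <- function(sl, cfg, replicates = NULL) {
  if (length(cfg$scales) < 3L)
    stop("the AU test needs at least three resampling scales")
  reps <- if (is.null(replicates)) .rell_all_scales(sl, cfg) else replicates
  ntree <- nrow(sl$loglik)
  bp <- vapply(reps, function(Tm) {
    M <- apply(Tm, 2L, max)
    rowMeans(Tm == rep(M, each = nrow(Tm)))
  }, numeric(ntree))
  if (is.null(dim(bp))) bp <- matrix(bp, nrow = ntree)  # single tree safety
  r <- cfg$scales
  eps <- 1 / (cfg$B + 1)
  p <- numeric(ntree)
  degen <- logical(ntree)
  X <- cbind(sqrt(r), 1 / sqrt(r))
  for (i in seq_len(ntree)) {
    bpi <- bp[i, ]
    if (sum(bpi > 0 & bpi < 1) < 2L) {
      p[i] <- if (mean(bpi) > 0.5) 1 else 0
      degen[i] <- TRUE
      next
    }
    bpc <- pmin(pmax(bpi, eps), 1 - eps)
    z <- stats::qnorm(1 - bpc)
    wls <- cfg$B * stats::dnorm(z)^2 / (bpc * (1 - bpc))
    beta <- solve(crossprod(X, wls * X), crossprod(X, wls * z))
    p[i] <- stats::pnorm(beta[1] - beta[2], lower.tail = FALSE)
  }
  structure(p, degenerate = degen, bp = bp)
}

#' Ranked topology-test table
#'
#' Assembles the per-topology results: log-likelihood deficit and its SE,
#' the scaled deficit `delta_logl/se` (defined as 0 for the ML tree), the
#' AU/KH/SH p-values, an optional scenario label, and a `within_1se` flag
#' marking topologies whose scaled deficit is at most 1. Rows are sorted
#' ascending by the scaled deficit with the ML tree ranked first.
#'
#' @param sl a [site_loglik_matrix].
#' @param cfg a [rell_config].
#' @param scenario_labels optional character vector of per-tree scenario
#'   labels (in the row order of `sl`).
#' @param tests compute the AU/KH/SH p-values (`TRUE`) or leave them `NA`
#'   (`FALSE`, useful when only the ranking is needed).
#' @param kh_method passed to [kh_test()].
#' @return a `data.frame` of class `topo_test_table` with columns `rank`,
#'   `tree`, `delta_logl`, `se`, `ratio`, `p_au`, `p_kh`, `p_sh`,
#'   `scenario`, `within_1se` (plus `au_degenerate`).
#' @export
build_table <- function(sl, cfg = rell_config(), scenario_labels = NULL,
                        tests = TRUE, kh_method = "rell") {
  if (nrow(sl$loglik) == 1L) {
    ## a single candidate is trivially the ML tree
    tab <- data.frame(
      rank = 1L, tree = sl$trees, delta_logl = 0, se = 0, ratio = 0,
      p_au = if (tests) 1 else NA_real_,
      p_kh = if (tests) 1 else NA_real_,
      p_sh = if (tests) 1 else NA_real_,
      scenario = if (is.null(scenario_labels)) NA_character_ else
        scenario_labels,
      within_1se = TRUE, au_degenerate = if (tests) TRUE else NA,
      is_ml = TRUE, stringsAsFactors = FALSE)
    class(tab) <- c("topo_test_table", "data.frame")
    return(tab)
  }
  ds <- delta_and_se(sl)
  ntree <- nrow(sl$loglik)
  ratio <- ifelse(ds$is_ml, 0, ifelse(ds$se > 0, ds$delta_logl / ds$se,
                                      ifelse(ds$delta_logl > 0, Inf, 0)))
  if (tests) {
    reps <- .rell_all_scales(sl, cfg)
    unit <- reps[[.unit_scale(cfg)]]
    p_au <- au_test(sl, cfg, replicates = reps)
    p_kh <- kh_test(sl, cfg, method = kh_method, replicates = unit)
    p_sh <- sh_test(sl, cfg, replicates = unit)
    au_degen <- attr(p_au, "degenerate")
  } else {
    p_au <- p_kh <- p_sh <- rep(NA_real_, ntree)
    au_degen <- rep(NA, ntree)
  }
  if (is.null(scenario_labels)) scenario_labels <- rep(NA_character_, ntree)
  tab <- data.frame(
    tree = sl$trees, delta_logl = ds$delta_logl, se = ds$se, ratio = ratio,
    p_au = as.numeric(p_au), p_kh = p_kh, p_sh = p_sh,
    scenario = scenario_labels, within_1se = ratio <= 1,
    au_degenerate = au_degen, is_ml = ds$is_ml,
    stringsAsFactors = FALSE
  )
  key <- ratio
  key[ds$is_ml] <- -Inf                   # the ML tree is always rank 1
  ord <- order(key, ds$delta_logl, sl$canonical)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(ntree), tab)
  rownames(tab) <- NULL
  class(tab) <- c("topo_test_table", "data.frame")
  tab
}

#' @export
print.topo_test_table <- function(x, n = 10L, digits = 3, ...) {
  cat(sprintf("Topology test table: %d topologies (sorted by delta_logl/se)\n",
              nrow(x)))
  y <- as.data.frame(x)[seq_len(min(n, nrow(x))),
                        c("rank", "tree", "scenario", "delta_logl", "se",
                          "ratio", "p_au", "p_kh", "p_sh")]
  y$delta_logl <- ifelse(x$is_ml[seq_len(nrow(y))], "ML",
                         format(round(y$delta_logl, 2)))
  print(format(y, digits = digits), row.names = FALSE)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}

#' Write the ranked table as TSV and JSON
#'
#' @param tab a `topo_test_table` from [build_table()].
#' @param path output path; `.tsv` appended for the TSV and `.json` for
#'   the JSON if `path` has no extension.
#' @return the paths written, invisibly.
#' @export
write_topo_table <- function(tab, path) {
  base <- sub("\\.(tsv|json)$", "", path)
  cols <- c("rank", "tree", "delta_logl", "se", "ratio", "p_au", "p_kh",
            "p_sh", "scenario", "within_1se")
  out <- as.data.frame(tab)[, cols]
  tsv <- paste0(base, ".tsv")
  json <- paste0(base, ".json")
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(out, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv, json))
}
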