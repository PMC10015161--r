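## small handmade site-loglik fixtures (trees are arbitrary distinct
## 4-leaf topologies; the tests exercise the resampling arithmetic)
topo4 <- c("((A,B),C,D);", "((A,C),B,D);", "((A,D),B,C);")

make_sl <- function(loglik, weights = rep(1, ncol(loglik)),
                    trees = topo4[seq_len(nrow(loglik))]) {
  site_loglik_matrix(loglik, weights, trees)
}

test_that("delta and SE match a direct spreadsheet-style recomputation", {
  set.seed(21)
  L <- matrix(rnorm(3 * 8, mean = -3), 3, 8)
  w <- c(2, 1, 3, 1, 1, 2, 1, 4)
  sl <- make_sl(L, w)
  ds <- delta_and_se(sl)

  ## independent arithmetic: expand patterns to sites, plain loops
  expand <- rep(seq_len(8), times = w)
  totals <- apply(L[, expand], 1, sum)
  ml <- which.max(totals)
  n <- length(expand)
  for (i in 1:3) {
    d <- L[ml, expand] - L[i, expand]
    expect_equal(ds$delta_logl[i], sum(d), tolerance = 1e-12)
    if (i != ml)
      expect_equal(ds$se[i], sqrt(n / (n - 1) * sum((d - mean(d))^2)),
                   tolerance = 1e-12)
  }
  expect_identical(which(ds$is_ml), ml)
  expect_equal(ds$se[ml], 0)
  expect_error(delta_and_se(make_sl(L[1, , drop = FALSE], w)), "two trees")
})

test_that("degenerate deficit cases behave as defined", {
  ## duplicated ML row: delta = 0 and SE = 0
  L <- rbind(a = seq(-2, -9), b = seq(-2, -9))
  sl <- make_sl(L, trees = c("((A,B),C,D);", "((B,A),D,C);"))
  ds <- delta_and_se(sl)
  expect_equal(ds$delta_logl, c(0, 0))
  expect_equal(ds$se, c(0, 0))
  expect_identical(sum(ds$is_ml), 1L)

  ## constant per-site difference c: SE = 0, delta = n * c
  L2 <- rbind(seq(-2, -9), seq(-2, -9) - 0.25)
  ds2 <- delta_and_se(make_sl(L2, trees = topo4[1:2]))
  expect_equal(ds2$delta_logl[2], 8 * 0.25, tolerance = 1e-12)
  expect_equal(ds2$se[2], 0, tolerance = 1e-9)
})

test_that("RELL replicates are deterministic with expected moments", {
  set.seed(22)
  L <- matrix(rnorm(3 * 30, -3), 3, 30)
  w <- sample(1:3, 30, replace = TRUE)
  sl <- make_sl(L, w)
  cfg <- rell_config(B = 4000, seed = 5)

  r1 <- rell_resample(sl, cfg, 1)
  r2 <- rell_resample(sl, cfg, 1)
  expect_identical(r1, r2)
  expect_identical(dim(r1), c(3L, 4000L))

  ## bootstrap mean property at scale 1: replicate mean ~ observed total
  n <- sum(w)
  for (i in 1:3) {
    mu <- sl$total[i]
    sd_site <- sqrt(sum(w * (L[i, ] - mu / n)^2) / n)
    se_rep <- sqrt(n) * sd_site / sqrt(cfg$B)
    expect_lt(abs(mean(r1[i, ]) - mu), 3 * se_rep)
  }

  ## identical rows give identical replicate totals
  sl_eq <- make_sl(rbind(L[1, ], L[1, ]), w, trees = topo4[1:2])
  r_eq <- rell_resample(sl_eq, cfg, 1)
  expect_equal(r_eq[1, ], r_eq[2, ])

  ## scaled replicates draw round(scale * n) sites
  r_half <- rell_resample(sl, cfg, 0.5)
  expect_false(identical(r_half, r1))
  expect_error(rell_config(B = 50), "at least 100")
  expect_error(rell_config(scales = c(0.5, 0.8)), "scale 1.0")
})

test_that("KH test semantics: ML tree, symmetric null, normal variant", {
  set.seed(23)
  base <- rnorm(400, -3)
  ## tree 2 differs by mean-zero noise: observed delta near 0 -> p ~ 0.5
  L <- rbind(base, base + 0.3 * (rnorm(400)))
  L[2, ] <- L[2, ] - (sum(L[2, ]) - sum(base)) / 400  # force delta ~ 0
  sl <- make_sl(L, trees = topo4[1:2])
  cfg <- rell_config(B = 5000, seed = 6)
  p <- kh_test(sl, cfg)
  ml <- which(delta_and_se(sl)$is_ml)
  expect_equal(p[ml], 1)
  expect_gt(min(p), 0.4)   # both trees are statistically indistinguishable

  ## duplicated ML row
  sl_eq <- make_sl(rbind(base, base), trees = topo4[1:2])
  expect_equal(kh_test(sl_eq, cfg), c(1, 1))

  ## normal approximation variant is monotone in delta/SE
  pn <- kh_test(sl, cfg, method = "normal")
  expect_true(all(pn >= 0 & pn <= 1))
  expect_equal(pn[ml], 1)
})

test_that("SH test dominates KH and is exact for extreme trees", {
  set.seed(24)
  for (seed in 1:5) {
    set.seed(seed)
    L <- matrix(rnorm(4 * 200, -3, 0.5), 4, 200)
    sl <- make_sl(L, trees = c(topo4, "((B,C),A,D);"))
    cfg <- rell_config(B = 1000, seed = seed)
    unit <- rell_resample(sl, cfg, 1)
    p_kh <- kh_test(sl, cfg, replicates = unit)
    p_sh <- sh_test(sl, cfg, replicates = unit)
    expect_true(all(p_sh >= p_kh - 1e-12))
    expect_true(all(p_sh >= 0 & p_sh <= 1))
    expect_equal(p_sh[which(delta_and_se(sl)$is_ml)], 1)
  }

  ## enormous deficit: p -> 0
  set.seed(25)
  L <- rbind(rnorm(100, -3, 0.1), rnorm(100, -3, 0.1) - 5)
  sl <- make_sl(L, trees = topo4[1:2])
  expect_equal(sh_test(sl, rell_config(B = 1000, seed = 1))[2], 0)
})

test_that("AU test handles dominant, hopeless and contested trees", {
  cfg <- rell_config(B = 1000, seed = 7)
  set.seed(26)
  ## tree 1 dominates at every scale; tree 2 never wins
  L <- rbind(rnorm(200, -3, 0.2), rnorm(200, -3, 0.2) - 1)
  sl <- make_sl(L, trees = topo4[1:2])
  p <- au_test(sl, cfg)
  expect_equal(p[1], 1)
  expect_equal(p[2], 0)
  expect_true(all(attr(p, "degenerate")))

  ## contested trees get interior p-values
  set.seed(27)
  base <- rnorm(500, -3, 0.6)
  L2 <- rbind(base,
              base + rnorm(500, 0, 0.25),
              base + rnorm(500, 0, 0.25) - 0.002)
  sl2 <- make_sl(L2)
  p2 <- au_test(sl2, cfg)
  expect_true(all(p2 > 0 & p2 < 1))
  expect_true(all(!attr(p2, "degenerate")))
  expect_error(au_test(sl2, rell_config(scales = c(0.5, 1))), "three")
})

test_that("the ranked table is sorted with the ML tree first", {
  set.seed(28)
  base <- rnorm(300, -3, 0.5)
  ## trees constructed so exactly 3 of 5 fall within one SE of the ML tree:
  ## two near-ties (small deficit, comparable per-site spread) and two
  ## clearly worse trees (deficit many times the spread)
  near_tie <- function() {
    e <- rnorm(300, 0, 0.02)
    base + (e - mean(e)) - 0.001      # delta = 0.3, SE ~ 0.35 -> ratio < 1
  }
  L <- rbind(base, near_tie(), near_tie(),
             base - 0.10 + rnorm(300, 0, 0.3),
             base - 0.15 + rnorm(300, 0, 0.3))
  trees5 <- c(topo4, "((B,C),A,D);", "((B,D),A,C);")
  sl <- make_sl(L, trees = trees5)
  cfg <- rell_config(B = 1000, seed = 8)
  tab <- build_table(sl, cfg)
  expect_s3_class(tab, "topo_test_table")
  expect_identical(tab$rank, 1:5)
  expect_true(tab$is_ml[1])
  expect_equal(tab$ratio[1], 0)
  expect_true(!is.unsorted(tab$ratio))
  expect_identical(sum(tab$within_1se), 3L)
  expect_true(all(tab$p_sh >= tab$p_kh - 1e-12))
  ## every p-value is a probability
  expect_true(all(unlist(tab[, c("p_au", "p_kh", "p_sh")]) >= 0))
  expect_true(all(unlist(tab[, c("p_au", "p_kh", "p_sh")]) <= 1))
})

test_that("a single candidate tree yields the trivial one-row table", {
  L <- matrix(rnorm(20, -3), 1, 20)
  sl <- make_sl(L, trees = topo4[1])
  tab <- build_table(sl, rell_config(B = 100, seed = 1))
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$delta_logl, 0)
  expect_equal(tab$ratio, 0)
  expect_equal(c(tab$p_au, tab$p_kh, tab$p_sh), c(1, 1, 1))
})

test_that("tables round-trip to TSV and JSON", {
  set.seed(29)
  L <- matrix(rnorm(3 * 50, -3), 3, 50)
  tab <- build_table(make_sl(L), rell_config(B = 200, seed = 2),
                     scenario_labels = c("a", "b", "c"))
  base <- tempfile()
  paths <- write_topo_table(tab, base)
  tsv <- utils::read.delim(paste0(base, ".tsv"))
  expect_identical(nrow(tsv), 3L)
  expect_identical(names(tsv)[1:5],
                   c("rank", "tree", "delta_logl", "se", "ratio"))
  js <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(js$delta_logl, tab$delta_logl, tolerance = 1e-12)
})
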