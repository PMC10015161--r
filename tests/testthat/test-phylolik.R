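test_that("two-leaf Poisson likelihoods match the closed form", {
  m <- subst_model("Poisson", k = 1)
  tr <- parse_newick("(A:0.13,B:0.22);")
  t_total <- 0.35
  paa <- 1 / 20 + (19 / 20) * exp(-20 * t_total / 19)
  pab <- 1 / 20 - (1 / 20) * exp(-20 * t_total / 19)

  same <- msa_from_strings(c(A = "A", B = "A"))
  diff <- msa_from_strings(c(A = "A", B = "C"))
  expect_equal(as.numeric(site_loglik(tr, same, m)), log(paa / 20),
               tolerance = 1e-10)
  expect_equal(as.numeric(site_loglik(tr, diff, m)), log(pab / 20),
               tolerance = 1e-10)
})

test_that("pruning equals the brute-force sum over ancestral states", {
  ## 3-leaf tree (one internal vertex), plain model
  m3 <- subst_model("JTT", k = 1)
  tr3 <- parse_newick("(s1:0.2,s2:0.08,s3:0.31);")
  msa3 <- random_msa(3, 40, seed = 11, gap_prob = 0.1)
  expect_equal(as.numeric(site_loglik(tr3, msa3, m3)),
               brute_force_site_loglik(tr3, msa3, m3),
               tolerance = 1e-10)

  ## 4-leaf tree (two internal vertices), full +I+G mixture, gaps and X
  m4 <- subst_model("JTT", alpha = 0.6, k = 4, p_inv = 0.2)
  tr4 <- parse_newick("((s1:0.15,s2:0.3):0.12,s3:0.05,s4:0.4);")
  msa4 <- random_msa(4, 25, seed = 12, gap_prob = 0.15)
  got <- as.numeric(site_loglik(tr4, msa4, m4))
  want <- brute_force_site_loglik(tr4, msa4, m4)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("pattern probabilities are normalized", {
  ## all 20^n patterns for n = 2 and 3 (no +I, no gaps) sum to one
  m <- subst_model("JTT", alpha = 0.9, k = 4, p_inv = 0)
  tr2 <- parse_newick("(s1:0.1,s2:0.3);")
  grid2 <- expand.grid(a = 1:20, b = 1:20)
  msa2 <- aa_msa(matrix(AA[t(as.matrix(grid2))], nrow = 2,
                        dimnames = list(c("s1", "s2"), NULL)))
  expect_equal(sum(exp(site_loglik(tr2, msa2, m)) * attr(
    site_loglik(tr2, msa2, m), "weights")), 1, tolerance = 1e-10)

  tr3 <- parse_newick("(s1:0.07,s2:0.2,s3:0.5);")
  grid3 <- expand.grid(a = 1:20, b = 1:20, c = 1:20)
  msa3 <- aa_msa(matrix(AA[t(as.matrix(grid3))], nrow = 3,
                        dimnames = list(c("s1", "s2", "s3"), NULL)))
  sl3 <- site_loglik(tr3, msa3, m)
  expect_equal(sum(exp(sl3) * attr(sl3, "weights")), 1, tolerance = 1e-10)
})

test_that("the likelihood is invariant to the pruning root", {
  m <- subst_model("JTT", alpha = 0.8, k = 4, p_inv = 0.15)
  fx <- gene_family_fixture("post_split", n_per_otu = 2, n_sites = 200,
                            seed = 13)
  base <- attr(site_loglik(fx$tree, fx$msa, m), "loglik")
  for (tip in c("Cyc.1", "OG.2", "Ost-1.1")) {
    rerooted <- ape::unroot(ape::root(fx$tree, outgroup = tip,
                                      resolve.root = TRUE))
    expect_equal(attr(site_loglik(rerooted, fx$msa, m), "loglik"), base,
                 tolerance = 1e-8)
  }
})

test_that("constant patterns on a zero-length tree recover the frequencies", {
  m <- subst_model("JTT", k = 1)
  tr <- parse_newick("(s1:0,s2:0,s3:0);")
  msa <- msa_from_strings(c(s1 = "A", s2 = "A", s3 = "A"))
  expect_equal(as.numeric(site_loglik(tr, msa, m)), log(m$freqs[1]),
               tolerance = 1e-12)
})

test_that("optimization is deterministic and column duplication doubles logL", {
  m <- subst_model("JTT", alpha = 1, k = 4, p_inv = 0.1)
  fx <- gene_family_fixture("post_split", n_per_otu = 1, n_sites = 400,
                            seed = 14)
  f1 <- optimize_tree(fx$tree, fx$msa, m)
  f2 <- optimize_tree(fx$tree, fx$msa, m)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
  expect_identical(f1$tree$edge.length, f2$tree$edge.length)

  doubled <- aa_msa(cbind(fx$msa$seq, fx$msa$seq))
  f3 <- optimize_tree(fx$tree, doubled, m)
  expect_equal(f3$loglik, 2 * f1$loglik, tolerance = 1e-6)
  expect_equal(f3$alpha, f1$alpha, tolerance = 1e-6)
  expect_equal(f3$p_inv, f1$p_inv, tolerance = 1e-6)
  expect_equal(f3$tree$edge.length, f1$tree$edge.length, tolerance = 1e-6)
})

test_that("fitting improves on the starting tree and respects bounds", {
  m <- subst_model("JTT", alpha = 1, k = 4, p_inv = 0.1)
  fx <- gene_family_fixture("pre_split", n_per_otu = 1, n_sites = 300,
                            seed = 15)
  start <- fx$tree
  start$edge.length[] <- 0.5
  before <- attr(site_loglik(start, fx$msa, m), "loglik")
  fit <- optimize_tree(start, fx$msa, m)
  expect_gt(fit$loglik, before)
  expect_true(all(fit$tree$edge.length >= 1e-8 - 1e-12))
  expect_true(all(fit$tree$edge.length <= 10 + 1e-12))
  expect_true(fit$alpha >= 0.02 && fit$alpha <= 100)
  expect_true(fit$p_inv >= 0 && fit$p_inv <= 0.99)
})

test_that("likelihoods agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  fx <- gene_family_fixture("post_split", n_per_otu = 1, n_sites = 300,
                            seed = 3)
  m <- subst_model("JTT", alpha = 0.8, k = 4, p_inv = 0.15)
  mine <- attr(site_loglik(fx$tree, fx$msa, m), "loglik")
  pd <- phangorn::phyDat(as.matrix(fx$msa), type = "AA")
  ref <- phangorn::pml(fx$tree, pd, model = "JTT", k = 4, shape = 0.8,
                       inv = 0.15)$logLik
  expect_equal(mine, ref, tolerance = 1e-8)
})
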