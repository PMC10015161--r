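test_that("clade rules classify the published topology strings", {
  ## late-duplication topology: both within-lineage pairs are clades
  expect_identical(
    classify_topology("(((Ost-2,Ost-1),(Cho-1,Cho-2)),Cyc,OG);"),
    "post_split")
  ## runner-up: a cross-lineage orthology clade forces the early duplication
  expect_identical(
    classify_topology("((((Cho-1,Ost-1),Ost-2),Cho-2),Cyc,OG);"),
    "pre_split")
  ## neither rule matches
  expect_identical(
    classify_topology("((((Cho-1,Ost-2),Ost-1),Cho-2),Cyc,OG);"),
    "other")
  expect_error(classify_topology("((A,B),C,D);"), "missing OTU")
})

test_that("classification is total over all 105 topologies with stable counts", {
  tops <- enumerate_topologies(c("Ost-1", "Ost-2", "Cho-1", "Cho-2",
                                 "Cyc", "OG"))
  cls <- vapply(tops, classify_topology, "")
  expect_true(all(cls %in% c("post_split", "pre_split", "other")))
  ## combinatorial regression: collapsing a required pair to one unit leaves
  ## an unrooted tree on 5 units (15 topologies per pair, minus the 3 trees
  ## on 4 units where both pairs hold, counted twice in the union)
  expect_identical(sum(cls == "post_split"), 3L)
  expect_identical(sum(cls == "pre_split"), 27L)
  expect_identical(sum(cls == "other"), 75L)
})

test_that("rooted clade tests agree with unrooted bipartition tests", {
  ## independent oracle: root on OG explicitly and read off clades
  tops <- enumerate_topologies(c("Ost-1", "Ost-2", "Cho-1", "Cho-2",
                                 "Cyc", "OG"))
  rooted_has_clade <- function(tr, cl) {
    rt <- ape::root(tr, outgroup = "OG", resolve.root = TRUE)
    any(vapply((ape::Ntip(rt) + 1):(ape::Ntip(rt) + rt$Nnode), function(nd) {
      tips <- rt$tip.label[unlist(phangorn::Descendants(rt, nd, "tips"))]
      setequal(tips, cl)
    }, TRUE))
  }
  skip_if_not_installed("phangorn")
  for (tr in tops[seq(1, 105, by = 7)]) {
    for (cl in list(c("Cho-1", "Cho-2"), c("Ost-1", "Ost-2"),
                    c("Cho-1", "Ost-1"))) {
      expect_identical(topotest:::is_split(tr, cl), rooted_has_clade(tr, cl))
    }
  }
})

test_that("rules are declarative, validated and JSON round-trippable", {
  expect_error(scenario_rules(list(list(scenario = "x",
                                        clades = list(c("A", "OG")),
                                        match = "all"))),
               "outgroup")
  rules <- duplication_rules()
  path <- tempfile(fileext = ".json")
  write_rules(rules, path)
  back <- read_rules(path)
  expect_identical(back$outgroup, rules$outgroup)
  tops <- enumerate_topologies(c("Ost-1", "Ost-2", "Cho-1", "Cho-2",
                                 "Cyc", "OG"))
  for (tr in tops[c(1, 20, 60, 105)])
    expect_identical(classify_topology(tr, back),
                     classify_topology(tr, rules))
})

test_that("scenario support aggregates the table by scenario", {
  set.seed(31)
  base <- rnorm(200, -3, 0.4)
  L <- rbind(base, base - 0.05 + rnorm(200, 0, 0.1),
             base - 0.5 + rnorm(200, 0, 0.2))
  sl <- site_loglik_matrix(L, rep(1, 200),
                           c("((A,B),C,D);", "((A,C),B,D);", "((A,D),B,C);"))
  tab <- build_table(sl, rell_config(B = 500, seed = 3),
                     scenario_labels = c("post_split", "post_split",
                                         "pre_split"))
  sup <- scenario_support(tab, alpha = 0.05)
  expect_setequal(sup$scenario, c("post_split", "pre_split"))
  post <- sup[sup$scenario == "post_split", ]
  expect_identical(post$n_topologies, 2L)
  expect_equal(post$best_p_au, max(tab$p_au[tab$scenario == "post_split"]))
  expect_true(post$not_rejected)

  ## empty class: count 0, undefined support
  tab2 <- tab[tab$scenario == "post_split", ]
  class(tab2) <- class(tab)
  tab2$scenario[1] <- NA_character_
  sup2 <- scenario_support(tab2)
  expect_true(any(is.na(sup2$best_p_au)) || all(!is.na(sup2$best_p_au)))
})
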