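## ten six-OTU topology strings in the printed display style
## (trifurcating root with the outgroup last), used as round-trip cases
ranked_trees <- c(
  "(((Ost-2,Ost-1),(Cho-1,Cho-2)),Cyc,OG);",
  "((((Cho-1,Ost-1),Ost-2),Cho-2),Cyc,OG);",
  "((((Cho-2,Cho-1),Ost-2),Ost-1),Cyc,OG);",
  "((((Ost-2,Cho-2),Ost-1),Cho-1),Cyc,OG);",
  "(((Ost-2,Cho-2),(Cho-1,Ost-1)),Cyc,OG);",
  "((((Cho-2,Cho-1),Ost-1),Ost-2),Cyc,OG);",
  "((((Ost-2,Cho-2),Cho-1),Ost-1),Cyc,OG);",
  "((((Ost-2,Ost-1),Cho-1),Cho-2),Cyc,OG);",
  "((((Cho-1,Ost-1),Cho-2),Ost-2),Cyc,OG);",
  "((((Cho-1,Ost-1),Ost-2),Cyc),Cho-2,OG);")

test_that("newick parsing validates input and keeps the display root", {
  tr <- parse_newick(ranked_trees[1])
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label,
                  c("Ost-1", "Ost-2", "Cho-1", "Cho-2", "Cyc", "OG"))
  root <- ape::Ntip(tr) + 1L
  expect_identical(sum(tr$edge[, 1] == root), 3L)  # trifurcating display root

  tr2 <- parse_newick("(A,B);")
  expect_identical(ape::Ntip(tr2), 2L)

  expect_error(parse_newick("((A,B),C;"), "unbalanced")
  expect_error(parse_newick("(A,B))C;"), "position")
  expect_error(parse_newick("(A,B)"), "';'")
  expect_error(parse_newick("((A,A),B);"), "duplicate")

  ## parse -> write -> parse keeps the canonical topology
  for (s in ranked_trees) {
    rt <- parse_newick(ape::write.tree(parse_newick(s)))
    expect_identical(canonical_form(rt), canonical_form(s))
  }
})

test_that("canonical form identifies unrooted topologies", {
  expect_identical(canonical_form("((A,B),C,D);"),
                   canonical_form("((B,A),D,C);"))
  expect_false(canonical_form("((A,B),C,D);") ==
                 canonical_form("((A,C),B,D);"))

  ## brute force over every rooting of a random 10-leaf tree
  tr <- random_tree(10, seed = 42)
  forms <- character()
  for (tip in tr$tip.label)
    forms <- c(forms, canonical_form(ape::root(tr, outgroup = tip)))
  for (node in ape::Ntip(tr) + seq_len(tr$Nnode)[-1])
    forms <- c(forms, canonical_form(ape::root(tr, node = node)))
  expect_identical(length(unique(forms)), 1L)
  expect_identical(unique(forms), canonical_form(tr))
})

test_that("enumeration yields (2k-5)!! distinct topologies", {
  counts <- c(`3` = 1, `4` = 3, `5` = 15, `6` = 105, `7` = 945)
  for (k in 3:7) {
    tops <- enumerate_topologies(paste0("t", 1:k))
    expect_identical(length(tops), as.integer(counts[[as.character(k)]]))
    if (k <= 6) {
      forms <- vapply(tops, canonical_form, "")
      expect_identical(anyDuplicated(forms), 0L)
    }
  }
  expect_error(enumerate_topologies(c("a", "b")), "at least 3")
  expect_error(enumerate_topologies(c("a", "b", "b")), "unique")
})

test_that("constrained expansion and collapse are inverse over all 105", {
  fx <- gene_family_fixture("post_split", n_per_otu = 2, n_sites = 10,
                            seed = 1)
  cons <- fx$constraint
  tops <- enumerate_topologies(names(cons$otus))
  for (st in tops) {
    full <- expand_constrained(st, cons)
    expect_setequal(full$tip.label, unlist(cons$otus))
    back <- collapse_to_otus(full, cons)
    expect_identical(canonical_form(back), canonical_form(st))
  }
  ## expanded leaf set equals the simulated alignment's labels
  expect_setequal(expand_constrained(fx$supertree, cons)$tip.label,
                  fx$msa$labels)
})

test_that("single-leaf OTU expansion is the identity", {
  cons <- otu6_constraint()
  st <- parse_newick("(((Ost-2,Ost-1),(Cho-1,Cho-2)),Cyc,OG);")
  expect_identical(canonical_form(expand_constrained(st, cons)),
                   canonical_form(st))
})

test_that("constraints validate membership and round-trip through JSON", {
  expect_error(otu_constraint(list(A = c("x", "y"), B = "x"),
                              list(A = "(x,y);", B = "x;")),
               "partition")
  expect_error(otu_constraint(list(A = c("x", "y"), B = "z"),
                              list(A = "(x,w);", B = "z;")),
               "does not match")
  cons <- gene_family_fixture("pre_split", n_per_otu = 3, n_sites = 10,
                              seed = 2)$constraint
  path <- tempfile(fileext = ".json")
  write_constraint(cons, path)
  back <- read_constraint(path)
  expect_identical(lapply(back$otus, sort), lapply(cons$otus, sort))
  for (nm in names(cons$otus))
    expect_identical(canonical_form(parse_newick(back$subtrees[[nm]])),
                     canonical_form(parse_newick(cons$subtrees[[nm]])))
})
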