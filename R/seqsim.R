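#' Simulate an amino-acid alignment along a tree
#'
#' Evolves sites along `tree` under the same +I+G mixture the likelihood
#' machinery assumes, so simulation and inference share one model
#' definition. Per column: a root state is drawn from the equilibrium
#' frequencies; with probability `p_inv` the column is invariant (the root
#' state is copied unchanged to every leaf); otherwise one of the `k`
#' discrete gamma categories is assigned uniformly and states evolve along
#' each branch via the transition kernel for branch length x category
#' rate, with category rates divided by `(1 - p_inv)` so the whole mixture
#' has mean rate 1. Gaps are never simulated.
#'
#' @param tree a `phylo` with non-negative, finite branch lengths.
#' @param model a [subst_model]; its `alpha`, `k` and `p_inv` are the
#'   simulation parameters.
#' @param n_sites number of alignment columns (>= 1).
#' @param seed integer RNG seed; fully determines the output.
#' @return an [aa_msa] with one row per tree leaf, with the invariant-site
#'   flags and category assignments attached as attributes
#'   `"invariant"` and `"category"`.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"))
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0))
    stop("tree must have finite, non-negative branch lengths")
  if (ape::Ntip(tree) < 1L) stop("tree has no leaves")
  if (n_sites < 1L || n_sites != round(n_sites))
    stop("'n_sites' must be a positive integer")
  n_sites <- as.integer(n_sites)
  set.seed(as.integer(seed))

  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  pinv <- model$p_inv
  rates <- mixture_rates(model)
  k <- model$k

  invariant <- stats::runif(n_sites) < pinv
  category <- sample.int(k, n_sites, replace = TRUE)
  category[invariant] <- NA_integer_

  states <- matrix(NA_integer_, nnode, n_sites)
  root <- ntip + 1L
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE,
                               prob = model$freqs)
  tr <- ape::reorder.phylo(tree, "postorder")
  edges <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]  # preorder
  elen <- tr$edge.length[rev(seq_len(nrow(tr$edge)))]

  var_idx <- which(!invariant)
  for (r in seq_len(nrow(edges))) {
    par <- edges[r, 1L]; child <- edges[r, 2L]
    out <- states[par, ]                      # invariant columns copy through
    for (c in seq_len(k)) {
      cols <- var_idx[category[var_idx] == c]
      if (!length(cols)) next
      P <- transition_matrix(model, elen[r], rates[c])
      ps <- states[par, cols]
      for (s in unique(ps)) {
        sel <- cols[ps == s]
        out[sel] <- sample.int(20L, length(sel), replace = TRUE, prob = P[s, ])
      }
    }
    states[child, ] <- out
  }

  m <- matrix(AA_ALPHABET[states[seq_len(ntip), , drop = FALSE]], nrow = ntip)
  rownames(m) <- tree$tip.label
  msa <- aa_msa(m)
  attr(msa, "invariant") <- invariant
  attr(msa, "category") <- category
  msa
}

## ladder subtree string over labels with given edge lengths; no trailing ';'
.ladder_newick <- function(labels, tip_length, inner_length) {
  if (length(labels) == 1L) return(sprintf("%s:%g", labels, tip_length))
  s <- sprintf("(%s:%g,%s:%g)", labels[1], tip_length, labels[2], tip_length)
  for (i in seq(3L, length.out = length(labels) - 2L))
    s <- sprintf("(%s:%g,%s:%g)", s, inner_length, labels[i], tip_length)
  s
}

.ladder_topology <- function(labels) {
  if (length(labels) == 1L) return(labels)
  s <- sprintf("(%s,%s)", labels[1], labels[2])
  for (i in seq(3L, length.out = length(labels) - 2L))
    s <- sprintf("(%s,%s)", s, labels[i])
  s
}

#' Six-OTU gene-family fixture under a duplication-timing scenario
#'
#' Builds a synthetic gene-family data set mirroring the structure of a
#' vitellogenin-style duplication problem: six OTUs — two osteichthyan
#' paralog groups (`Ost-1`, `Ost-2`), two chondrichthyan paralog groups
#' (`Cho-1`, `Cho-2`), a cyclostome group (`Cyc`) and an outgroup (`OG`).
#' Under `"post_split"` the generating tree places the two chondrichthyan
#' groups as sisters and the two osteichthyan groups as sisters
#' (duplication after the lineage split, independently in each lineage);
#' under `"pre_split"` the paralog groups pair across lineages
#' (`Ost-1`+`Cho-1` and `Ost-2`+`Cho-2`), i.e. the duplication preceded
#' the split.
#'
#' @param scenario `"post_split"` or `"pre_split"`.
#' @param n_per_otu leaves per OTU (single integer or named vector over the
#'   six OTU names); default 2, keeping fixtures at desk scale.
#' @param tip_length terminal branch length (substitutions/site).
#' @param speciation_length length of speciation-scale internal branches
#'   (OTU stems, within-OTU internals, deep internal edges).
#' @param duplication_length length of the two branches subtending the
#'   paralog clades created by the duplication.
#' @param model a [subst_model] used for simulation (defaults to
#'   JTT + I + G4 with `alpha = 1`, `p_inv = 0.2`).
#' @param n_sites alignment columns to simulate (default 1195).
#' @param seed integer RNG seed.
#' @return a list of class `gene_family_fixture` with elements `msa`,
#'   `tree` (full generating tree with branch lengths), `supertree`
#'   (OTU-level generating topology), `constraint` ([otu_constraint]),
#'   `scenario`, `model` and `seed`.
#' @export
gene_family_fixture <- function(scenario = c("post_split", "pre_split"),
                                n_per_otu = 2L,
                                tip_length = 0.2,
                                speciation_length = 0.1,
                                duplication_length = 0.15,
                                model = subst_model("JTT", alpha = 1,
                                                    k = 4L, p_inv = 0.2),
                                n_sites = 1195L,
                                seed = 1L) {
  scenario <- match.arg(scenario)
  otus <- c("Ost-1", "Ost-2", "Cho-1", "Cho-2", "Cyc", "OG")
  if (length(n_per_otu) == 1L) {
    n_per_otu <- stats::setNames(rep(as.integer(n_per_otu), 6L), otus)
  } else {
    if (!setequal(names(n_per_otu), otus))
      stop("named 'n_per_otu' must cover exactly: ", paste(otus, collapse = " "))
    n_per_otu <- vapply(otus, function(o) as.integer(n_per_otu[[o]]), 1L)
    names(n_per_otu) <- otus
  }
  if (any(n_per_otu < 1L)) stop("each OTU needs at least one leaf")

  leaves <- lapply(otus, function(o) {
    if (n_per_otu[[o]] == 1L) o else paste0(o, ".", seq_len(n_per_otu[[o]]))
  })
  names(leaves) <- otus
  sub_bl <- vapply(otus, function(o)
    .ladder_newick(leaves[[o]], tip_length, speciation_length), "")
  sub_topo <- vapply(otus, function(o)
    paste0(.ladder_topology(leaves[[o]]), ";"), "")

  s <- speciation_length; d <- duplication_length
  pair <- function(a, b, len) sprintf("(%s:%g,%s:%g):%g",
                                      sub_bl[[a]], s, sub_bl[[b]], s, len)
  core <- if (scenario == "post_split") {
    sprintf("(%s,%s)", pair("Ost-1", "Ost-2", d), pair("Cho-1", "Cho-2", d))
  } else {
    sprintf("(%s,%s)", pair("Ost-1", "Cho-1", d), pair("Ost-2", "Cho-2", d))
  }
  full_nwk <- sprintf("(%s:%g,%s:%g,%s:%g);", core, s,
                      sub_bl[["Cyc"]], s, sub_bl[["OG"]], 2 * s)
  tree <- parse_newick(full_nwk)

  super_nwk <- if (scenario == "post_split")
    "(((Ost-1,Ost-2),(Cho-1,Cho-2)),Cyc,OG);" else
    "(((Ost-1,Cho-1),(Ost-2,Cho-2)),Cyc,OG);"
  supertree <- parse_newick(super_nwk)

  constraint <- otu_constraint(leaves, as.list(sub_topo))
  msa <- simulate_alignment(tree, model, n_sites, seed)
  structure(list(msa = msa, tree = tree, supertree = supertree,
                 constraint = constraint, scenario = scenario,
                 model = model, seed = as.integer(seed)),
            class = "gene_family_fixture")
}

#' @export
print.gene_family_fixture <- function(x, ...) {
  cat(sprintf("Gene-family fixture (%s): %d leaves, %d sites, seed %d\n",
              x$scenario, length(x$msa$labels), x$msa$n_sites, x$seed))
  invisible(x)
}

#' Write a gene-family fixture to disk
#'
#' Writes the alignment (FASTA), the true generating tree (Newick), the
#' OTU constraint (JSON) and a JSON record of the simulation settings.
#'
#' @param fixture a [gene_family_fixture()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "gene_family_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_msa_fasta(fixture$msa, file.path(dir, "alignment.fasta"))
  ape::write.tree(fixture$tree, file.path(dir, "true_tree.nwk"))
  write_constraint(fixture$constraint, file.path(dir, "constraint.json"))
  m <- fixture$model
  jsonlite::write_json(list(scenario = fixture$scenario, seed = fixture$seed,
                            n_sites = fixture$msa$n_sites, model = m$name,
                            alpha = m$alpha, k = m$k, p_inv = m$p_inv),
                       file.path(dir, "fixture.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
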