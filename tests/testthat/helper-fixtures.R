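## Shared fixtures and independent oracles, built in code at test time.

AA <- topotest:::AA_ALPHABET

## small alignment from a character vector of equal-length strings
msa_from_strings <- function(x) {
  m <- do.call(rbind, strsplit(x, ""))
  rownames(m) <- names(x)
  aa_msa(m)
}

## random alignment matrix over the 20-letter alphabet (optionally with
## gaps/ambiguity), labels s1..sn
random_msa <- function(ntax, nsites, seed, gap_prob = 0) {
  set.seed(seed)
  m <- matrix(sample(AA, ntax * nsites, replace = TRUE), ntax, nsites)
  if (gap_prob > 0) {
    hit <- matrix(stats::runif(ntax * nsites) < gap_prob, ntax, nsites)
    m[hit] <- sample(c("-", "X"), sum(hit), replace = TRUE)
  }
  rownames(m) <- paste0("s", seq_len(ntax))
  aa_msa(m)
}

random_tree <- function(ntax, seed, min_bl = 0.05, max_bl = 0.4) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(ntax, tip.label = paste0("s", seq_len(ntax))))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

## ---------------------------------------------------------------------------
## independent likelihood oracle: explicit sum over all ancestral-state
## assignments at the internal vertices (feasible for <= 4 leaves), with the
## same +I+G mixture definition as the package

brute_force_site_loglik <- function(tree, msa, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  root <- tr$edge[nrow(tr$edge), 1]
  internals <- sort(unique(tr$edge[, 1]))
  stopifnot(length(internals) <= 2)   # 20^m assignments
  idx <- match(tr$tip.label, msa$labels)
  pats <- msa$patterns[, idx, drop = FALSE]
  rates <- topotest:::mixture_rates(model)
  pinv <- model$p_inv
  freqs <- model$freqs

  lik_cat <- function(P_list, pattern) {
    grid <- do.call(expand.grid, rep(list(1:20), length(internals)))
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      assign_map <- stats::setNames(as.integer(grid[g, ]), internals)
      pr <- freqs[assign_map[[as.character(root)]]]
      for (e in seq_len(nrow(tr$edge))) {
        a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
        sa <- assign_map[[as.character(a)]]
        P <- P_list[[e]]
        if (b <= ntip) {
          sb <- pattern[b]
          pr <- pr * if (sb == 0) 1 else P[sa, sb]
        } else {
          pr <- pr * P[sa, assign_map[[as.character(b)]]]
        }
      }
      tot <- tot + pr
    }
    tot
  }

  vapply(seq_len(nrow(pats)), function(p) {
    pattern <- pats[p, ]
    mix <- 0
    for (c in seq_along(rates)) {
      P_list <- lapply(seq_len(nrow(tr$edge)), function(e)
        transition_matrix(model, tr$edge.length[e], rates[c]))
      mix <- mix + (1 - pinv) / length(rates) * lik_cat(P_list, pattern)
    }
    if (pinv > 0) {
      obs <- unique(pattern[pattern > 0])
      l0 <- if (length(obs) == 0) 1 else if (length(obs) == 1) freqs[obs] else 0
      mix <- mix + pinv * l0
    }
    log(mix)
  }, 0)
}

## match branch lengths between two trees with the same unrooted topology,
## keyed by the bipartition (child-side tip set) of each edge
matched_branch_lengths <- function(tr_ref, tr_fit) {
  key <- function(tr) {
    tr <- ape::reorder.phylo(tr, "postorder")
    ntip <- ape::Ntip(tr)
    below <- vector("list", max(tr$edge))
    for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
    for (r in seq_len(nrow(tr$edge)))
      below[[tr$edge[r, 1]]] <- c(below[[tr$edge[r, 1]]],
                                  below[[tr$edge[r, 2]]])
    all <- sort(tr$tip.label)
    k <- vapply(tr$edge[, 2], function(b) {
      s <- sort(below[[b]])
      comp <- setdiff(all, s)
      ## orient each split deterministically
      if (paste(s, collapse = ",") < paste(comp, collapse = ","))
        paste(s, collapse = ",") else paste(comp, collapse = ",")
    }, "")
    stats::setNames(tr$edge.length, k)
  }
  a <- key(tr_ref); b <- key(tr_fit)
  stopifnot(setequal(names(a), names(b)))
  cbind(ref = a, fit = b[names(a)])
}

## six single-leaf OTU constraint over the standard OTU names
otu6_constraint <- function() {
  nm <- c("Ost-1", "Ost-2", "Cho-1", "Cho-2", "Cyc", "OG")
  otu_constraint(stats::setNames(as.list(nm), nm),
                 stats::setNames(as.list(paste0(nm, ";")), nm))
}
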