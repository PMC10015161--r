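#' Declarative duplication-timing scenario rules
#'
#' A rule set classifies an OTU-level topology by clade membership after
#' rooting on the outgroup OTU. Each rule names a scenario, lists required
#' clades (subsets of the OTU names, never containing the outgroup), and
#' states whether all clades (`match = "all"`) or at least one
#' (`match = "any"`) must be present; rules are tried in order and the
#' first match wins, with `"other"` as the fall-through.
#'
#' The default rule set encodes the two timings of a gene duplication
#' relative to a lineage split, for the six-OTU scheme
#' `Ost-1`, `Ost-2`, `Cho-1`, `Cho-2`, `Cyc`, `OG`:
#' * `post_split` — both within-lineage paralog pairs are clades
#'   (`{Cho-1, Cho-2}` and `{Ost-1, Ost-2}`): each lineage duplicated its
#'   gene independently after the split.
#' * `pre_split` — at least one cross-lineage ortholog pair is a clade
#'   (`{Cho-1, Ost-1}` or `{Cho-2, Ost-2}`): a single cross-split orthology
#'   clade already forces the duplication before the split.
#'
#' @param rules list of rules, each a list with elements `scenario`
#'   (character), `clades` (list of character vectors) and `match`
#'   (`"all"` or `"any"`).
#' @param outgroup name of the outgroup OTU used for rooting.
#' @return an object of class `scenario_rules`.
#' @export
scenario_rules <- function(rules, outgroup = "OG") {
  for (r in rules) {
    stopifnot(is.character(r$scenario), is.list(r$clades),
              r$match %in% c("all", "any"))
    if (any(vapply(r$clades, function(cl) outgroup %in% cl, TRUE)))
      stop("the outgroup OTU must not appear inside a required clade")
  }
  structure(list(rules = rules, outgroup = outgroup),
            class = "scenario_rules")
}

#' @rdname scenario_rules
#' @export
duplication_rules <- function(outgroup = "OG") {
  scenario_rules(list(
    list(scenario = "post_split",
         clades = list(c("Cho-1", "Cho-2"), c("Ost-1", "Ost-2")),
         match = "all"),
    list(scenario = "pre_split",
         clades = list(c("Cho-1", "Ost-1"), c("Cho-2", "Ost-2")),
         match = "any")
  ), outgroup = outgroup)
}

#' @export
print.scenario_rules <- function(x, ...) {
  cat(sprintf("Scenario rules (%d rules, outgroup '%s'):\n",
              length(x$rules), x$outgroup))
  for (r in x$rules)
    cat(sprintf("  %s [%s]: %s\n", r$scenario, r$match,
                paste(vapply(r$clades, function(cl)
                  paste0("{", paste(cl, collapse = ","), "}"), ""),
                  collapse = " ")))
  invisible(x)
}

#' Classify an OTU-level topology into a duplication-timing scenario
#'
#' Roots the tree on the outgroup OTU and tests each rule's required
#' clades. Because the substitution model is reversible, rooting on the
#' outgroup and testing clades is equivalent to testing bipartition
#' membership on the unrooted tree with the outgroup on the far side,
#' which is how the test is implemented.
#'
#' @param tr a `phylo` (or Newick string) whose tips are exactly the OTU
#'   names the rules refer to, including the outgroup.
#' @param rules a [scenario_rules] set (default [duplication_rules()]).
#' @return the matched scenario name, or `"other"`.
#' @export
classify_topology <- function(tr, rules = duplication_rules()) {
  stopifnot(inherits(rules, "scenario_rules"))
  if (is.character(tr)) tr <- parse_newick(tr)
  need <- unique(c(rules$outgroup,
                   unlist(lapply(rules$rules, function(r) unlist(r$clades)))))
  missing <- setdiff(need, tr$tip.label)
  if (length(missing))
    stop("tree is missing OTU leaf/leaves: ", paste(missing, collapse = " "))
  ## a clade under outgroup rooting == a bipartition not containing OG
  has_clade <- function(cl) {
    if (rules$outgroup %in% setdiff(tr$tip.label, cl)) is_split(tr, cl)
    else FALSE
  }
  for (r in rules$rules) {
    hits <- vapply(r$clades, has_clade, TRUE)
    if ((r$match == "all" && all(hits)) || (r$match == "any" && any(hits)))
      return(r$scenario)
  }
  "other"
}

#' Scenario-level support summary
#'
#' Aggregates a ranked topology table by scenario: the number of
#' topologies, the best (largest) AU and KH p-values, the number of
#' topologies within one SE of the ML tree, and whether the scenario is
#' rejected at level `alpha` (a scenario is "not rejected" iff its best AU
#' p-value is at least `alpha`).
#'
#' @param tab a `topo_test_table` from [build_table()] with scenario
#'   labels filled in.
#' @param alpha rejection level (default 0.05).
#' @return data frame with one row per scenario, sorted by best AU
#'   p-value; empty scenario classes get count 0 and `NA` support.
#' @export
scenario_support <- function(tab, alpha = 0.05) {
  stopifnot(inherits(tab, "topo_test_table"))
  scen <- unique(tab$scenario)
  rows <- lapply(scen, function(s) {
    sub <- tab[tab$scenario %in% s, , drop = FALSE]
    data.frame(
      scenario = s,
      n_topologies = nrow(sub),
      best_p_au = if (all(is.na(sub$p_au))) NA_real_ else
        max(sub$p_au, na.rm = TRUE),
      best_p_kh = if (all(is.na(sub$p_kh))) NA_real_ else
        max(sub$p_kh, na.rm = TRUE),
      n_within_1se = sum(sub$within_1se),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$not_rejected <- !is.na(out$best_p_au) & out$best_p_au >= alpha
  out[order(-out$best_p_au, out$scenario), , drop = FALSE]
}

#' Read / write scenario rules as JSON
#'
#' @param rules a [scenario_rules] object.
#' @param path file path.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "scenario_rules"))
  jsonlite::write_json(list(outgroup = rules$outgroup, rules = rules$rules),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  x <- jsonlite::read_json(path)
  rules <- lapply(x$rules, function(r)
    list(scenario = r$scenario,
         clades = lapply(r$clades, function(cl) unlist(cl, use.names = FALSE)),
         match = r$match))
  scenario_rules(rules, outgroup = x$outgroup)
}
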