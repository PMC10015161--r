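#' Parse a Newick tree string
#'
#' Thin validating wrapper around [ape::read.tree()]: checks parenthesis
#' balance (reporting the offending character position), the terminating
#' semicolon, and label uniqueness, and returns an `ape` `phylo` object.
#' A top-level trifurcation is preserved as the display root.
#'
#' @param text a single Newick string ending in `";"`.
#' @return a `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || substring(text, nchar(text)) != ";")
    stop("Newick string must end in ';'")
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced '(': ", depth, " unclosed at end of string")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = " "))
  tr
}

## adjacency list over node ids 1..(ntip + nnode) of a phylo
.adjacency <- function(tr) {
  n <- max(tr$edge)
  adj <- vector("list", n)
  for (r in seq_len(nrow(tr$edge))) {
    a <- tr$edge[r, 1L]; b <- tr$edge[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Canonical form of an unrooted tree topology
#'
#' Produces a string that identifies the unrooted topology: two trees have
#' equal canonical forms if and only if they are the same unrooted
#' topology, regardless of where they are rooted for display and of the
#' order in which children are written. Branch lengths are ignored.
#'
#' The form is obtained by rooting at the internal vertex adjacent to the
#' lexicographically smallest leaf label and sorting children recursively
#' by the smallest leaf label in each subtree.
#'
#' @param tr a `phylo` object (or a Newick string, parsed first).
#' @return a single Newick-style string.
#' @export
canonical_form <- function(tr) {
  if (is.character(tr)) tr <- parse_newick(tr)
  ntip <- ape::Ntip(tr)
  labs <- tr$tip.label
  if (ntip == 1L) return(paste0(labs, ";"))
  if (ntip == 2L) return(paste0("(", paste(sort(labs), collapse = ","), ");"))
  adj <- .adjacency(tr)
  ## collapse a degree-2 display root so rooted and unrooted input agree
  deg <- lengths(adj)
  for (v in which(deg == 2L)) {
    nb <- adj[[v]]
    adj[[nb[1]]] <- c(setdiff(adj[[nb[1]]], v), nb[2])
    adj[[nb[2]]] <- c(setdiff(adj[[nb[2]]], v), nb[1])
    adj[[v]] <- integer()
  }
  start_leaf <- which(labs == min(labs))[1]
  root <- adj[[start_leaf]][1]
  rec <- function(v, parent) {
    if (v <= ntip) return(list(str = labs[v], min = labs[v]))
    kids <- setdiff(adj[[v]], parent)
    parts <- lapply(kids, rec, parent = v)
    ord <- order(vapply(parts, `[[`, "", "min"))
    parts <- parts[ord]
    list(str = paste0("(", paste(vapply(parts, `[[`, "", "str"),
                                 collapse = ","), ")"),
         min = parts[[1]]$min)
  }
  kids <- adj[[root]]
  parts <- lapply(kids, rec, parent = root)
  parts <- parts[order(vapply(parts, `[[`, "", "min"))]
  paste0("(", paste(vapply(parts, `[[`, "", "str"), collapse = ","), ");")
}

## internal edge-list tree used during enumeration: tips 1..k, internals k+1..
.edges_to_newick <- function(edges, labels) {
  k <- length(labels)
  n <- max(edges)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  root <- adj[[1L]][1]                    # internal vertex next to tip 1
  rec <- function(v, parent) {
    if (v <= k) return(labels[v])
    kids <- setdiff(adj[[v]], parent)
    paste0("(", paste(vapply(kids, rec, "", parent = v), collapse = ","), ")")
  }
  paste0("(", paste(vapply(adj[[root]], rec, "", parent = root),
                    collapse = ","), ");")
}

#' Enumerate all unrooted binary topologies over a label set
#'
#' Generates every distinct unrooted binary tree topology on `k >= 3`
#' labels by stepwise leaf addition: each new leaf is attached to every
#' edge of every smaller tree. The count is the double factorial
#' `(2k - 5)!!` (3 labels: 1; 4: 3; 5: 15; 6: 105; 7: 945).
#'
#' @param labels character vector of `k >= 3` unique leaf names.
#' @return a list of `phylo` objects without branch lengths.
#' @export
enumerate_topologies <- function(labels) {
  labels <- as.character(labels)
  k <- length(labels)
  if (k < 3L) stop("need at least 3 labels to enumerate unrooted topologies")
  if (anyDuplicated(labels)) stop("labels must be unique")
  base <- matrix(c(k + 1L, 1L, k + 1L, 2L, k + 1L, 3L),
                 ncol = 2L, byrow = TRUE)
  trees <- list(base)
  nxt <- k + 2L
  for (tip in seq(4L, length.out = max(0L, k - 3L))) {
    out <- vector("list", length(trees) * (2L * tip - 5L))
    j <- 0L
    for (ed in trees) {
      for (r in seq_len(nrow(ed))) {
        new <- rbind(ed[-r, , drop = FALSE],
                     c(ed[r, 1L], nxt), c(nxt, ed[r, 2L]), c(nxt, tip))
        j <- j + 1L
        out[[j]] <- new
      }
    }
    trees <- out
    nxt <- nxt + 1L
  }
  lapply(trees, function(ed) parse_newick(.edges_to_newick(ed, labels)))
}

#' OTU constraint: leaf partition plus fixed within-OTU subtrees
#'
#' @param otus named list; each element is the character vector of leaf
#'   labels belonging to that OTU. Names are the OTU names.
#' @param subtrees named list of Newick strings (same names as `otus`),
#'   each resolving the internal topology of its OTU. Single-leaf OTUs may
#'   use the bare label (`"x;"`).
#' @return an object of class `otu_constraint`.
#' @export
otu_constraint <- function(otus, subtrees) {
  stopifnot(is.list(otus), is.list(subtrees))
  if (is.null(names(otus)) || anyDuplicated(names(otus)))
    stop("'otus' must have unique names")
  if (!setequal(names(otus), names(subtrees)))
    stop("'otus' and 'subtrees' must cover the same OTU names")
  all_leaves <- unlist(otus, use.names = FALSE)
  if (anyDuplicated(all_leaves))
    stop("OTU membership must be a partition: duplicated leaf label(s)")
  for (nm in names(otus)) {
    lv <- .subtree_leaves(subtrees[[nm]])
    if (!setequal(lv, otus[[nm]]))
      stop("subtree of OTU '", nm, "' does not match its membership")
  }
  structure(list(otus = otus, subtrees = subtrees), class = "otu_constraint")
}

.subtree_leaves <- function(nwk) {
  nwk <- trimws(nwk)
  if (!grepl("\\(", nwk)) return(sub(";$", "", nwk))
  parse_newick(nwk)$tip.label
}

#' @export
print.otu_constraint <- function(x, ...) {
  cat(sprintf("OTU constraint over %d OTUs (%d leaves)\n",
              length(x$otus), length(unlist(x$otus))))
  invisible(x)
}

#' Expand an OTU-level supertree to a full leaf-level tree
#'
#' Replaces each OTU leaf of `supertree` with the fixed subtree recorded
#' in the constraint; collapsing the result back with [collapse_to_otus()]
#' recovers the supertree topology.
#'
#' @param supertree a `phylo` whose tips are OTU names.
#' @param constraint an [otu_constraint].
#' @return a `phylo` over the full leaf set (no branch lengths).
#' @export
expand_constrained <- function(supertree, constraint) {
  stopifnot(inherits(constraint, "otu_constraint"))
  if (!setequal(supertree$tip.label, names(constraint$otus)))
    stop("supertree leaf set must equal the OTU-name set")
  nwk <- ape::write.tree(supertree)
  for (nm in supertree$tip.label) {
    sub <- sub(";\\s*$", "", trimws(constraint$subtrees[[nm]]))
    ## replace the OTU-name token only where it is a complete leaf label
    nwk <- gsub(paste0("(?<=[(,])", .rx_escape(nm), "(?=[,):;])"),
                sub, nwk, perl = TRUE)
  }
  parse_newick(nwk)
}

.rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", x)

## all non-trivial splits (bipartitions) of an unrooted tree, as the set of
## tip labels on the child side of each internal edge
tree_splits <- function(tr) {
  ntip <- ape::Ntip(tr)
  tr <- ape::reorder.phylo(tr, "postorder")
  n <- ntip + tr$Nnode
  below <- vector("list", n)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (r in seq_len(nrow(tr$edge))) {
    a <- tr$edge[r, 1L]; b <- tr$edge[r, 2L]
    below[[a]] <- c(below[[a]], below[[b]])
  }
  sides <- below[tr$edge[, 2L]]
  sides[vapply(sides, length, 1L) >= 2L &
          vapply(sides, length, 1L) <= ntip - 2L]
}

## is the label set S one side of a split (or a single leaf)?
is_split <- function(tr, s) {
  s <- as.character(s)
  if (length(s) == 1L) return(s %in% tr$tip.label)
  comp <- setdiff(tr$tip.label, s)
  for (side in tree_splits(tr))
    if (setequal(side, s) || setequal(side, comp)) return(TRUE)
  FALSE
}

#' Collapse a full tree to its OTU-level supertree
#'
#' Verifies that each OTU's leaf set forms one side of a bipartition of
#' the unrooted tree (i.e. the OTU is a clade under some rooting) and
#' returns the induced topology over the OTU names.
#'
#' @param tr a `phylo` over the full leaf set.
#' @param constraint an [otu_constraint].
#' @return a `phylo` whose tips are the OTU names.
#' @export
collapse_to_otus <- function(tr, constraint) {
  stopifnot(inherits(constraint, "otu_constraint"))
  if (!setequal(tr$tip.label, unlist(constraint$otus)))
    stop("tree leaf set does not match the constraint's leaf set")
  for (nm in names(constraint$otus))
    if (!is_split(tr, constraint$otus[[nm]]))
      stop("OTU '", nm, "' is not monophyletic in the tree")
  reps <- vapply(constraint$otus, `[[`, "", 1L)
  sub <- ape::keep.tip(tr, unname(reps))
  sub$tip.label <- names(reps)[match(sub$tip.label, reps)]
  sub$edge.length <- NULL
  sub
}

#' Read / write candidate-topology list files (one Newick per line)
#'
#' @param path file path.
#' @return for the reader, a list of `phylo` objects.
#' @export
read_tree_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lapply(lines[nzchar(lines)], parse_newick)
}

#' @rdname read_tree_list
#' @param trees list of `phylo` objects.
#' @export
write_tree_list <- function(trees, path) {
  writeLines(vapply(trees, ape::write.tree, ""), path)
  invisible(path)
}

#' Serialize / load an OTU constraint as JSON
#'
#' @param constraint an [otu_constraint].
#' @param path file path.
#' @export
write_constraint <- function(constraint, path) {
  stopifnot(inherits(constraint, "otu_constraint"))
  jsonlite::write_json(list(otus = constraint$otus,
                            subtrees = constraint$subtrees),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_constraint
#' @export
read_constraint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  otus <- lapply(x$otus, as.character)
  subtrees <- as.list(x$subtrees)
  otu_constraint(otus, subtrees)
}
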