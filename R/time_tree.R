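#' Time-trees with absolute node ages
#'
#' A `time_tree` is an [ape::phylo] object carrying a `node.ages` vector
#' (millions of years before present, Ma) indexed by ape node number
#' (tips `1..Ntip`, internals `Ntip+1..Ntip+Nnode`). Node ages are the
#' primary representation: every branch length equals
#' `age(parent) - age(child)` and is therefore non-negative. Extant tips sit
#' at age 0; fossil tips have positive ages. Trees without age semantics
#' (branch lengths in expected substitutions per site) are kept as plain
#' `phylo` objects.
#'
#' @param phy an `ape::phylo` object with branch lengths.
#' @param tip_ages named numeric vector of tip ages (Ma). Names must match
#'   `phy$tip.label`; tips absent from the vector are assumed extant (age 0).
#'   `NULL` means all tips extant.
#' @param tol tolerance (Ma) for consistency between the supplied tip ages
#'   and the root-to-tip path lengths.
#' @return an object of class `c("time_tree", "phylo")`.
#' @export
as_time_tree <- function(phy, tip_ages = NULL, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < -tol)) stop("negative branch length in input tree")
  phy$edge.length[phy$edge.length < 0] <- 0
  ntip <- length(phy$tip.label)
  ages_at_tips <- rep(0, ntip)
  names(ages_at_tips) <- phy$tip.label
  if (!is.null(tip_ages)) {
    if (is.null(names(tip_ages))) stop("tip_ages must be named")
    unknown <- setdiff(names(tip_ages), phy$tip.label)
    if (length(unknown)) stop("tip_ages for unknown taxa: ",
                              paste(unknown, collapse = ", "))
    ages_at_tips[names(tip_ages)] <- tip_ages
  }
  depth <- ape::node.depth.edgelength(phy)   # distance from root, all nodes
  root_candidates <- depth[seq_len(ntip)] + ages_at_tips
  if (diff(range(root_candidates)) > tol)
    stop("tip ages inconsistent with edge lengths (spread ",
         format(diff(range(root_candidates))), " Ma > tol)")
  root_age <- mean(root_candidates)
  ages <- root_age - depth
  ages[seq_len(ntip)] <- ages_at_tips       # exact at tips
  phy$node.ages <- ages
  class(phy) <- c("time_tree", "phylo")
  validate_time_tree(phy, tol = tol)
  phy
}

validate_time_tree <- function(tree, tol = 1e-6) {
  ages <- tree$node.ages
  dur <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  if (any(dur < -tol)) stop("parent younger than child: invalid time_tree")
  invisible(tree)
}

#' @export
print.time_tree <- function(x, ...) {
  cat("Time-tree with", length(x$tip.label), "tips; root age",
      format(root_age(x), digits = 6), "Ma;",
      sum(tip_ages(x) > 0), "fossil tips\n")
  invisible(x)
}

#' Node age accessors
#'
#' @param tree a `time_tree`.
#' @return `node_ages()`: ages (Ma) for all nodes in ape numbering;
#'   `tip_ages()`: named ages of the tips; `root_age()`: the root age.
#' @export
node_ages <- function(tree) {
  stopifnot(inherits(tree, "time_tree"))
  tree$node.ages
}

#' @rdname node_ages
#' @export
tip_ages <- function(tree) {
  a <- node_ages(tree)[seq_along(tree$tip.label)]
  names(a) <- tree$tip.label
  a
}

#' @rdname node_ages
#' @export
root_age <- function(tree) {
  node_ages(tree)[length(tree$tip.label) + 1L]
}

#' Read a Newick tree, optionally as a time-tree
#'
#' Whitespace in labels is normalised to underscores on read (the NEXUS
#' dialect convention). When `tip_ages` is supplied (possibly all zero) the
#' result is a `time_tree` with node ages computed so that every root-to-tip
#' path length equals `root_age - tip_age`; otherwise a plain `phylo` with
#' branch lengths in their original units is returned.
#'
#' @param text Newick string; exactly one of `text`/`file` must be given.
#' @param file path to a Newick file.
#' @param tip_ages named numeric vector of tip ages (Ma), or `NULL`.
#' @param tol age-consistency tolerance in Ma.
#' @return a `time_tree` (if `tip_ages` given) or `phylo`.
#' @export
read_newick <- function(text = NULL, file = NULL, tip_ages = NULL, tol = 1e-6) {
  if (is.null(text) == is.null(file)) stop("supply exactly one of text/file")
  phy <- if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(phy)) stop("malformed Newick input")
  phy$tip.label <- gsub("[[:space:]]+", "_", phy$tip.label)
  if (is.null(tip_ages)) return(phy)
  as_time_tree(phy, tip_ages = tip_ages, tol = tol)
}

#' Write a tree to Newick
#'
#' For a `time_tree`, edge lengths are re-derived from node ages
#' (`age(parent) - age(child)`); for a plain `phylo` the stored lengths are
#' used.
#'
#' @param tree a `time_tree` or `phylo` (at least 2 tips).
#' @param file optional output path; when `NULL` the string is returned.
#' @param digits decimal precision of edge lengths.
#' @return the Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  if (length(tree$tip.label) < 2)
    stop("degenerate tree with < 2 tips cannot be written")
  phy <- sync_edge_lengths(tree)
  class(phy) <- "phylo"
  s <- ape::write.tree(phy, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

sync_edge_lengths <- function(tree) {
  if (inherits(tree, "time_tree")) {
    a <- tree$node.ages
    tree$edge.length <- pmax(a[tree$edge[, 1]] - a[tree$edge[, 2]], 0)
  }
  tree
}

#' Read trees from a NEXUS TREES block
#'
#' Translate tables are supported (via [ape::read.nexus]).
#'
#' @param file path to a NEXUS file with a TREES block.
#' @return a list of `phylo` objects (class `multiPhylo`).
#' @export
read_nexus_trees <- function(file) {
  tr <- ape::read.nexus(file)
  if (inherits(tr, "phylo")) tr <- structure(list(tr), class = "multiPhylo")
  tr
}

#' Read tip dates from a two-column CSV
#'
#' @param file CSV with columns `taxon` and `age` (Ma).
#' @return named numeric vector of ages.
#' @export
read_tip_dates <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("taxon", "age") %in% names(d)))
    stop("tip-date CSV needs columns taxon, age")
  stats::setNames(as.numeric(d$age), gsub("[[:space:]]+", "_", d$taxon))
}

#' Prune a time-tree to a subset of taxa
#'
#' Returns the induced subtree: degree-2 nodes are suppressed and node ages
#' of retained nodes are unchanged.
#'
#' @param tree a `time_tree`.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return a `time_tree`.
#' @export
prune_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "time_tree"))
  if (length(keep) == 0) stop("keep set is empty")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2)
    stop("pruning to a single tip leaves no tree; keep at least 2 taxa")
  ta <- tip_ages(tree)
  phy <- sync_edge_lengths(tree)
  class(phy) <- "phylo"
  phy <- ape::keep.tip(phy, keep)
  as_time_tree(phy, tip_ages = ta[phy$tip.label], tol = 1e-6)
}

#' Graft a subtree onto a terminal branch
#'
#' Replaces tip `at_tip` by `subtree`, attaching the subtree root at
#' `attach_age` on the original terminal branch (which is thereby shortened).
#' All original tip ages are preserved; the new tips carry the ages assigned
#' in `subtree`.
#'
#' @param tree a `time_tree`.
#' @param at_tip tip label to replace.
#' @param subtree a `time_tree` whose root age equals `attach_age`.
#' @param attach_age age (Ma) of the new node, strictly between the tip's age
#'   and its parent's age.
#' @param tol age tolerance.
#' @return a `time_tree`.
#' @export
graft_subtree <- function(tree, at_tip, subtree, attach_age, tol = 1e-6) {
  stopifnot(inherits(tree, "time_tree"), inherits(subtree, "time_tree"))
  i <- match(at_tip, tree$tip.label)
  if (is.na(i)) stop("unknown tip: ", at_tip)
  if (any(subtree$tip.label %in% tree$tip.label[-i]))
    stop("subtree tip labels collide with existing tips")
  parent <- tree$edge[tree$edge[, 2] == i, 1]
  t_tip <- tree$node.ages[i]
  t_par <- tree$node.ages[parent]
  if (!(attach_age > t_tip && attach_age < t_par))
    stop("attach_age must lie strictly between tip age (", t_tip,
         ") and parent age (", t_par, ")")
  if (abs(root_age(subtree) - attach_age) > tol)
    stop("subtree root age (", root_age(subtree),
         ") does not equal attach_age (", attach_age, ")")
  new_tip_ages <- c(tip_ages(tree)[-i], tip_ages(subtree))
  phy <- sync_edge_lengths(tree)
  class(phy) <- "phylo"
  # zero the pendant edge so the connecting branch is exactly root.edge
  phy$edge.length[phy$edge[, 2] == i] <- 0
  sub <- sync_edge_lengths(subtree)
  class(sub) <- "phylo"
  sub$root.edge <- t_par - attach_age
  out <- ape::bind.tree(phy, sub, where = i)
  as_time_tree(out, tip_ages = new_tip_ages[out$tip.label], tol = max(tol, 1e-6))
}

#' Most recent common ancestor
#'
#' @param tree a `phylo` or `time_tree`.
#' @param taxa character vector of tip labels (one or more).
#' @return node number of the MRCA (the tip itself for a single taxon).
#' @export
mrca_node <- function(tree, taxa) {
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx)) stop("unknown taxa: ",
                       paste(taxa[is.na(idx)], collapse = ", "))
  if (length(unique(idx)) == 1L) return(unique(idx))
  ape::getMRCA(tree, unique(idx))
}

#' Path length between two tips
#'
#' On a `time_tree` the result is in Ma; on a substitutions-per-site tree it
#' is in substitutions per site.
#'
#' @param tree a `phylo` or `time_tree`.
#' @param a,b tip labels.
#' @return numeric path length.
#' @export
path_length <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  if (is.na(ia) || is.na(ib)) stop("unknown tip label")
  phy <- sync_edge_lengths(tree)
  if (ia == ib) return(0)
  m <- ape::getMRCA(phy, c(ia, ib))
  depth <- ape::node.depth.edgelength(phy)
  depth[ia] + depth[ib] - 2 * depth[m]
}

#' Branch table of a time-tree
#'
#' @param tree a `time_tree`.
#' @return data.frame with one row per edge: `parent`, `child` (ape node
#'   numbers), `child_label` (tip label or `NA`), `parent_age`, `child_age`,
#'   `duration` (Ma).
#' @export
branches <- function(tree) {
  stopifnot(inherits(tree, "time_tree"))
  a <- tree$node.ages
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  data.frame(
    parent = tree$edge[, 1],
    child = child,
    child_label = ifelse(child <= ntip, tree$tip.label[pmin(child, ntip)], NA),
    parent_age = a[tree$edge[, 1]],
    child_age = a[child],
    duration = a[tree$edge[, 1]] - a[child],
    stringsAsFactors = FALSE
  )
}
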