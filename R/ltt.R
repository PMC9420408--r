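#' Keep only each species' latest occurrence
#'
#' For species represented by multiple terminal branches (OTUs from distinct
#' occurrence age ranges), retains only the tip with the smallest age
#' (ties broken by the lexicographically lowest OTU label) and prunes the
#' rest, so the lineage count at time 0 equals the number of extant species.
#'
#' @param tree a `time_tree`.
#' @param species named character vector: tip label -> species. Must cover
#'   all tips.
#' @return a `time_tree` with one tip per species.
#' @export
keep_latest_occurrences <- function(tree, species) {
  miss <- setdiff(tree$tip.label, names(species))
  if (length(miss)) stop("species map missing tips: ",
                         paste(miss, collapse = ", "))
  ta <- tip_ages(tree)
  keep <- vapply(split(names(ta), species[names(ta)]), function(tips) {
    tips[order(ta[tips], tips)][1]
  }, "")
  if (length(keep) == length(tree$tip.label)) return(tree)
  prune_taxa(tree, unname(keep))
}

#' Number of lineages alive at a time slice
#'
#' An edge `(p, c)` is counted iff `age(p) > t >= age(c)`: a node exactly at
#' the slice age counts as already split, and a fossil tip is counted at its
#' own age but not at younger slices. Above the root age the count is 0.
#'
#' @param tree a `time_tree`.
#' @param t slice age (Ma, >= 0).
#' @return integer lineage count.
#' @export
lineage_count_at <- function(tree, t) {
  if (t < 0) stop("t must be >= 0")
  a <- tree$node.ages
  sum(a[tree$edge[, 1]] > t & a[tree$edge[, 2]] <= t)
}

#' Assign branches to geographic zones from a discrete reconstruction
#'
#' A branch is confidently assignable to zone `z` iff the modal
#' reconstructed states of its parent and child nodes are both `z`, each
#' with probability at least `threshold`. Where the endpoints differ the
#' transition is assumed to occur along the branch, which is excluded from
#' every unambiguous subset (`NA`). Tip rows in the reconstruction are
#' degenerate on the coded zone, so tip branches use the tip's coded zone as
#' the child state.
#'
#' @param tree a `time_tree`.
#' @param zone_recon `marginal_recon` of the zone character on `tree`.
#' @param threshold modal probability required of both endpoints.
#' @return integer vector per edge (zone code 0-based), `NA` = ambiguous.
#' @export
assign_branch_zones <- function(tree, zone_recon, threshold = 0.9) {
  M <- zone_recon$prob
  top <- max.col(M, ties.method = "first")
  topp <- M[cbind(seq_len(nrow(M)), top)]
  p <- tree$edge[, 1]; ch <- tree$edge[, 2]
  z <- ifelse(top[p] == top[ch] & topp[p] >= threshold & topp[ch] >= threshold,
              top[ch] - 1L, NA_integer_)
  as.integer(z)
}

#' Time-slice lineage table with zone subsetting
#'
#' Lineage counts at fixed increments from the present back to the root age,
#' for the full tree and per geographic zone (plus an `ambiguous` column for
#' branches whose zone assignment is uncertain). At every slice the zone
#' counts and the ambiguous count partition the total.
#'
#' @param tree a `time_tree`.
#' @param branch_zones optional per-edge zone codes from
#'   [assign_branch_zones]; `NULL` gives total counts only.
#' @param step slice increment in Ma (default 0.5, half-million years).
#' @param zones zone codes to report; default the codes present.
#' @return data.frame of class `ltt_table`: `age`, `total`, one `zone_*`
#'   column per zone, `ambiguous`.
#' @export
ltt_table <- function(tree, branch_zones = NULL, step = 0.5, zones = NULL) {
  stopifnot(step > 0)
  ages <- seq(0, root_age(tree), by = step)
  a <- tree$node.ages
  pa <- a[tree$edge[, 1]]; ca <- a[tree$edge[, 2]]
  out <- data.frame(age = ages,
                    total = vapply(ages, function(t)
                      sum(pa > t & ca <= t), 0L))
  if (!is.null(branch_zones)) {
    if (length(branch_zones) != nrow(tree$edge))
      stop("branch_zones must have one entry per edge")
    if (is.null(zones)) zones <- sort(unique(branch_zones[!is.na(branch_zones)]))
    for (z in zones)
      out[[paste0("zone_", z)]] <- vapply(ages, function(t)
        sum(pa > t & ca <= t & !is.na(branch_zones) & branch_zones == z), 0L)
    out$ambiguous <- vapply(ages, function(t)
      sum(pa > t & ca <= t & is.na(branch_zones)), 0L)
  }
  class(out) <- c("ltt_table", "data.frame")
  out
}

#' Percent diversity decline between two counts
#'
#' `100 * (from - to) / from`, optionally floored to an integer to support
#' "declined by a minimum of x percent" statements.
#'
#' @param count_from lineage count at the earlier slice (> 0).
#' @param count_to lineage count at the later slice.
#' @param floor floor the percentage to an integer.
#' @return percent decline.
#' @export
percent_decline <- function(count_from, count_to, floor = FALSE) {
  if (count_from <= 0) stop("count_from must be positive")
  pct <- 100 * (count_from - count_to) / count_from
  if (floor) base::floor(pct) else pct
}
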