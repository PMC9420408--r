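# Shared fixtures and independent oracles, built in code at test time.

# random non-ultrametric time-tree: rtree topology, tip ages read off the
# depths so the tree is internally consistent and carries fossil tips
rand_time_tree <- function(n) {
  phy <- ape::rtree(n)
  d <- ape::node.depth.edgelength(phy)[seq_len(n)]
  as_time_tree(phy, tip_ages = stats::setNames(max(d) - d, phy$tip.label))
}

# ultrametric (all-extant) time-tree
coal_time_tree <- function(n, depth = NULL) {
  phy <- ape::rcoal(n)
  if (!is.null(depth)) {
    cur <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * depth / cur
  }
  as_time_tree(phy, tip_ages = stats::setNames(rep(0, n), phy$tip.label))
}

# exhaustive-enumeration oracle for the Mk likelihood and node marginals:
# sums the joint probability over every assignment of interior states
brute_mk <- function(tree, states, model) {
  phy <- paleoASR:::sync_edge_lengths(tree)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  k <- model$k
  Ps <- lapply(seq_len(nrow(phy$edge)),
               function(e) transition_probs(model, phy$edge.length[e]))
  ints <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(0:(k - 1)), length(ints))))
  s <- states[phy$tip.label]
  tot <- 0
  margs <- matrix(0, nn, k)
  for (g in seq_len(nrow(grid))) {
    asg <- integer(nn)
    asg[ints] <- grid[g, ]
    pr <- 1 / k
    for (e in seq_len(nrow(phy$edge))) {
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      if (ch <= ntip) {
        if (!is.na(s[ch])) pr <- pr * Ps[[e]][asg[p] + 1, s[ch] + 1]
      } else pr <- pr * Ps[[e]][asg[p] + 1, asg[ch] + 1]
    }
    tot <- tot + pr
    for (v in ints) margs[v, asg[v] + 1] <- margs[v, asg[v] + 1] + pr
  }
  list(ll = log(tot), marg = margs / tot)
}

# exhaustive minimal-window HDI oracle
brute_hdi <- function(x, mass) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  best <- NULL
  bw <- Inf
  for (i in seq_len(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < bw) { bw <- w; best <- c(x[i], x[i + m - 1]) }
  }
  best
}

# small random binary character matrix
rand_char_matrix <- function(ntax, nchar, taxa = paste0("t", seq_len(ntax))) {
  char_matrix(matrix(sample(0:1, ntax * nchar, TRUE), ntax,
                     dimnames = list(taxa, NULL)))
}
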