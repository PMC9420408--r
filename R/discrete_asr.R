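#' Symmetric Mk model for discrete characters
#'
#' The rate matrix is `Q = r * (A - diag(rowSums(A)))` where `A` is the
#' adjacency of allowed moves: all off-diagonal pairs for an unordered
#' character, only neighbouring states (`|i - j| = 1`) for an ordered one.
#' `r` is the per-allowed-move rate (expected changes per Ma per allowed
#' transition), which keeps ordered and unordered characters comparable.
#'
#' @param k number of states (>= 2); states are coded `0..k-1`.
#' @param ordered logical; restrict moves to adjacent states.
#' @param rate per-allowed-move rate `r > 0`.
#' @return an object of class `mk_model` with elements `k`, `ordered`,
#'   `rate`, `Q` and a cached symmetric eigendecomposition.
#' @export
mk_model <- function(k, ordered = FALSE, rate = 1) {
  stopifnot(k >= 2, rate > 0)
  A <- matrix(1, k, k) - diag(k)
  if (ordered) {
    A <- matrix(0, k, k)
    idx <- seq_len(k - 1)
    A[cbind(idx, idx + 1)] <- 1
    A[cbind(idx + 1, idx)] <- 1
  }
  Q <- rate * (A - diag(rowSums(A)))
  e <- eigen(Q, symmetric = TRUE)
  structure(list(k = k, ordered = ordered, rate = rate, Q = Q,
                 evec = e$vectors, eval = e$values),
            class = "mk_model")
}

#' Transition probability matrix of an Mk model
#'
#' `exp(Q t)` via the symmetric eigendecomposition; rows sum to 1.
#'
#' @param model an [mk_model].
#' @param t elapsed time (Ma), `t >= 0`.
#' @return `k x k` stochastic matrix.
#' @export
transition_probs <- function(model, t) {
  if (t < 0) stop("t must be >= 0")
  V <- model$evec
  P <- V %*% (exp(model$eval * t) * t(V))
  P[P < 0] <- 0
  P / rowSums(P)
}

## tip partial likelihoods: one row per tip, '?'/NA -> all ones
tip_partials <- function(tree, states, k) {
  ntip <- length(tree$tip.label)
  if (is.null(names(states))) stop("states must be named by taxon")
  missing_tips <- setdiff(tree$tip.label, names(states))
  if (length(missing_tips)) stop("states missing for: ",
                                 paste(missing_tips, collapse = ", "))
  L <- matrix(1, ntip, k)
  s <- states[tree$tip.label]
  obs <- !is.na(s)
  if (any(s[obs] < 0 | s[obs] >= k)) stop("state out of range 0..k-1")
  L[obs, ] <- 0
  L[cbind(which(obs), s[obs] + 1L)] <- 1
  L
}

## per-edge transition matrices, list indexed by edge row
edge_probs <- function(tree, model) {
  phy <- sync_edge_lengths(tree)
  lapply(phy$edge.length, function(t) transition_probs(model, t))
}

## pruning pass: returns list(down = partials matrix, logscale, order info)
mk_down_pass <- function(tree, states, model) {
  phy <- sync_edge_lengths(tree)
  k <- model$k
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  P <- lapply(po$edge.length, function(t) transition_probs(model, t))
  D <- matrix(1, nn, k)
  D[seq_len(ntip), ] <- tip_partials(phy, states, k)
  msg <- vector("list", nrow(po$edge))   # scaled message per (postorder) edge
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; c <- po$edge[e, 2]
    m <- as.vector(P[[e]] %*% D[c, ])
    sm <- sum(m)
    if (sm <= 0) stop("zero likelihood encountered (impossible data)")
    m <- m / sm
    logscale <- logscale + log(sm)
    msg[[e]] <- m
    D[p, ] <- D[p, ] * m
  }
  list(D = D, msg = msg, P = P, edge = po$edge, logscale = logscale,
       ntip = ntip, nn = nn)
}

#' Log-likelihood of a discrete character on a time-tree
#'
#' Felsenstein pruning with a uniform root prior over the `k` states (also
#' the stationary distribution of the symmetric Mk model). Missing tips
#' (`NA`) contribute all-ones partials.
#'
#' @param tree a `time_tree` (branch durations in Ma).
#' @param states named integer vector (`0..k-1` or `NA`) covering all tips.
#' @param model an [mk_model].
#' @return log-likelihood (natural log).
#' @export
tree_log_likelihood <- function(tree, states, model) {
  dp <- mk_down_pass(tree, states, model)
  root <- dp$ntip + 1L
  log(sum(dp$D[root, ] / model$k)) + dp$logscale
}

#' Maximum-likelihood rate for one character
#'
#' One-dimensional bounded maximisation of [tree_log_likelihood] over the
#' per-allowed-move rate, on the log scale.
#'
#' @param tree a `time_tree`.
#' @param states named integer vector of tip states (with `NA` for missing).
#' @param k number of states.
#' @param ordered logical.
#' @param interval rate search bracket.
#' @param tol relative optimisation tolerance.
#' @return list with `rate`, `log_likelihood`, `model`.
#' @export
fit_rate <- function(tree, states, k, ordered = FALSE,
                     interval = c(1e-6, 1e3), tol = 1e-8) {
  obs <- states[!is.na(states)]
  if (length(unique(obs)) <= 1)
    stop("character is invariant (or all-missing): no rate information")
  f <- function(lr) tree_log_likelihood(tree, states,
                                        mk_model(k, ordered, exp(lr)))
  op <- stats::optimize(f, interval = log(interval), maximum = TRUE, tol = tol)
  r <- exp(op$maximum)
  list(rate = r, log_likelihood = op$objective,
       model = mk_model(k, ordered, r))
}

## outside-inside marginals at a fixed model; returns node x k matrix
mk_marginals_fixed <- function(tree, states, model) {
  dp <- mk_down_pass(tree, states, model)
  k <- model$k
  root <- dp$ntip + 1L
  U <- matrix(0, dp$nn, k)
  U[root, ] <- 1 / k
  ne <- nrow(dp$edge)
  # children messages grouped by parent for sibling products
  for (e in ne:1) {                       # reverse postorder = preorder
    p <- dp$edge[e, 1]; c <- dp$edge[e, 2]
    sibs <- which(dp$edge[, 1] == p)
    other <- rep(1, k)
    for (e2 in sibs) if (e2 != e) other <- other * dp$msg[[e2]]
    up <- U[p, ] * other
    U[c, ] <- as.vector(t(dp$P[[e]]) %*% up)
    su <- sum(U[c, ])
    if (su > 0) U[c, ] <- U[c, ] / su
  }
  M <- dp$D * U
  M / rowSums(M)
}

#' Marginal ancestral state reconstruction
#'
#' Per-node marginal state probabilities for one discrete character,
#' integrating over all other nodes (outside-inside algorithm, equivalent to
#' re-rooting at each node). In `"ML"` mode the rate is fixed at its MLE; in
#' `"mcmc"` mode the rate is sampled by a log-scale random-walk Metropolis
#' under a uniform prior and node marginals are averaged over the retained
#' samples (adaptive step tuned toward 0.3 acceptance during burn-in).
#'
#' @param tree a `time_tree`.
#' @param states named integer tip states (`0..k-1`, `NA` for missing).
#' @param k number of states.
#' @param ordered logical.
#' @param mode `"ML"` or `"mcmc"`.
#' @param n_samples retained MCMC samples (default 3500).
#' @param seed RNG seed for `"mcmc"` mode.
#' @param rate_max upper bound of the uniform rate prior.
#' @return object of class `marginal_recon`: list with `prob` (node-by-state
#'   matrix, rows sum to 1; rows `1..Ntip` are the tips), `rate`,
#'   `log_likelihood`, `k`, `ordered`, `mode` and (mcmc) `rate_samples`.
#' @export
marginal_asr <- function(tree, states, k, ordered = FALSE,
                         mode = c("ML", "mcmc"), n_samples = 3500,
                         seed = NULL, rate_max = 1e3) {
  mode <- match.arg(mode)
  fit <- fit_rate(tree, states, k, ordered)
  if (mode == "ML") {
    M <- mk_marginals_fixed(tree, states, fit$model)
    out <- list(prob = M, rate = fit$rate,
                log_likelihood = fit$log_likelihood,
                k = k, ordered = ordered, mode = mode)
    class(out) <- "marginal_recon"
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  ll <- function(r) tree_log_likelihood(tree, states, mk_model(k, ordered, r))
  r <- fit$rate
  lp <- ll(r)
  step <- 0.5
  n_burn <- 500L
  acc_window <- 0L
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  Msum <- matrix(0, nn, k)
  rs <- numeric(n_samples)
  for (it in seq_len(n_burn + n_samples)) {
    r2 <- r * exp(stats::rnorm(1, 0, step))
    if (r2 < rate_max) {
      lp2 <- ll(r2)
      # Jacobian of the log-rate walk under a uniform prior on the rate
      if (log(stats::runif(1)) < lp2 - lp + log(r2) - log(r)) {
        r <- r2; lp <- lp2
        acc_window <- acc_window + 1L
      }
    }
    if (it <= n_burn && it %% 50L == 0L) {
      rate_acc <- acc_window / 50
      step <- step * exp(rate_acc - 0.3)
      acc_window <- 0L
    }
    if (it > n_burn) {
      i <- it - n_burn
      rs[i] <- r
      Msum <- Msum + mk_marginals_fixed(tree, states, mk_model(k, ordered, r))
    }
  }
  out <- list(prob = Msum / n_samples, rate = mean(rs),
              log_likelihood = fit$log_likelihood, k = k, ordered = ordered,
              mode = mode, rate_samples = rs)
  class(out) <- "marginal_recon"
  out
}

#' @export
print.marginal_recon <- function(x, ...) {
  cat("Marginal reconstruction (", x$mode, "): k = ", x$k,
      if (x$ordered) " (ordered)" else " (unordered)",
      ", rate = ", format(x$rate, digits = 4),
      ", lnL = ", format(x$log_likelihood, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Node probability table
#'
#' Long-format table of marginal state probabilities, one row per node and
#' state, mirroring the node probability tables of discrete-trait ASR
#' toolkits.
#'
#' @param recon a `marginal_recon`.
#' @param character_id identifier written in the `character` column.
#' @param file optional CSV output path.
#' @return data.frame with columns `node`, `character`, `state`,
#'   `probability`.
#' @export
node_probability_table <- function(recon, character_id = 1L, file = NULL) {
  nn <- nrow(recon$prob)
  d <- data.frame(
    node = rep(seq_len(nn), each = recon$k),
    character = character_id,
    state = rep(0:(recon$k - 1), nn),
    probability = as.vector(t(recon$prob))
  )
  if (!is.null(file)) utils::write.csv(d, file, row.names = FALSE)
  d
}

#' Unambiguous synapomorphies
#'
#' A branch is reported for a character when the parent's and child's modal
#' states both reach probability `threshold` and differ. Reported in the
#' conventional "character.state" notation (the derived, child state). The
#' root has no parent branch and is never reported.
#'
#' @param recons list of `marginal_recon` objects (one per character), or a
#'   single reconstruction.
#' @param tree the `time_tree` the reconstructions were computed on.
#' @param threshold minimal modal probability `p*` (0.5 < p* <= 1),
#'   default 0.9.
#' @param character_ids optional labels for the characters.
#' @return data.frame with columns `character`, `parent`, `child`,
#'   `parent_state`, `child_state`, `label` ("char.state").
#' @export
unambiguous_synapomorphies <- function(recons, tree, threshold = 0.9,
                                       character_ids = NULL) {
  if (inherits(recons, "marginal_recon")) recons <- list(recons)
  stopifnot(threshold > 0.5, threshold <= 1)
  if (is.null(character_ids)) character_ids <- seq_along(recons)
  out <- list()
  for (j in seq_along(recons)) {
    M <- recons[[j]]$prob
    top <- max.col(M, ties.method = "first")
    topp <- M[cbind(seq_len(nrow(M)), top)]
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
      if (topp[p] >= threshold && topp[c] >= threshold && top[p] != top[c]) {
        out[[length(out) + 1L]] <- data.frame(
          character = character_ids[j], parent = p, child = c,
          parent_state = top[p] - 1L, child_state = top[c] - 1L,
          label = paste0(character_ids[j], ".", top[c] - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(character = character(0), parent = integer(0),
                      child = integer(0), parent_state = integer(0),
                      child_state = integer(0), label = character(0)))
  do.call(rbind, out)
}
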