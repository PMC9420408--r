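#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km (via
#' [geosphere::distHaversine]).
#'
#' @param a,b points as `c(lon, lat)` in decimal degrees, or 2-column
#'   matrices.
#' @return distance(s) in km.
#' @export
geodesic_km <- function(a, b) {
  geosphere::distHaversine(a, b, r = 6371)
}

#' Unwrap longitudes into a continuous chart
#'
#' Maps longitudes to `(center - 180, center + 180]` so that point sets
#' straddling the dateline become contiguous before planar Brownian-motion
#' fitting; [wrap_longitude] is the inverse applied to outputs.
#'
#' @param lon longitudes in degrees.
#' @param center chart centre meridian (degrees).
#' @return unwrapped longitudes.
#' @export
unwrap_longitudes <- function(lon, center = 0) {
  out <- (lon - center) %% 360
  out[out > 180] <- out[out > 180] - 360
  # boundary: keep +180, not -180
  out[out == -180] <- 180
  out + center
}

#' @rdname unwrap_longitudes
#' @export
wrap_longitude <- function(lon) {
  out <- lon %% 360
  out[out > 180] <- out[out > 180] - 360
  out[out == -180] <- 180
  out
}

## sequential REML contrasts for one or more traits on a time_tree.
## Returns list(contrasts = matrix (n-1 or fewer) x p of normalised
## contrasts, anc = down-pass conditional means, extra = down-pass extra
## variance scalars). Handles polytomies and zero-length branches.
bm_down_pass <- function(tree, X) {
  phy <- sync_edge_lengths(tree)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  p <- ncol(X)
  po <- ape::reorder.phylo(phy, "postorder")
  m <- matrix(0, nn, p)
  m[seq_len(ntip), ] <- X[phy$tip.label, , drop = FALSE]
  v <- rep(0, nn)
  seen <- rep(FALSE, nn)
  seen[seq_len(ntip)] <- TRUE
  contrasts <- list()
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    tv <- po$edge.length[e] + v[ch]
    if (!seen[par]) {
      m[par, ] <- m[ch, ]
      v[par] <- tv
      seen[par] <- TRUE
    } else {
      cv <- v[par] + tv
      d <- m[par, ] - m[ch, ]
      if (cv < 1e-12) {
        if (any(abs(d) > 1e-8))
          stop("zero-variance contrast with differing values: inconsistent data")
        # coincident nodes: no information, skip contrast
      } else {
        contrasts[[length(contrasts) + 1L]] <- d / sqrt(cv)
        w1 <- 1 / v[par]; w2 <- 1 / tv
        if (!is.finite(w1)) { # current node estimate exact
          v[par] <- 0
        } else if (!is.finite(w2)) {
          m[par, ] <- m[ch, ]; v[par] <- 0
        } else {
          m[par, ] <- (w1 * m[par, ] + w2 * m[ch, ]) / (w1 + w2)
          v[par] <- 1 / (w1 + w2)
        }
      }
    }
  }
  U <- if (length(contrasts)) do.call(rbind, contrasts)
       else matrix(0, 0, p)
  list(anc = m, extra = v, contrasts = U)
}

## marginal (all-data) means and variance scalars via an above-message pass
bm_marginals <- function(tree, X) {
  phy <- sync_edge_lengths(tree)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  p <- ncol(X)
  dp <- bm_down_pass(tree, X)
  po <- ape::reorder.phylo(phy, "postorder")
  edge <- po$edge; elen <- po$edge.length
  # down-message per edge: (mean, var) of child conditional + branch
  dm <- dp$anc[edge[, 2], , drop = FALSE]
  dv <- dp$extra[edge[, 2]] + elen
  root <- ntip + 1L
  am <- matrix(0, nn, p); av <- rep(Inf, nn)   # above messages
  M <- matrix(0, nn, p); V <- rep(0, nn)       # marginals
  M[root, ] <- dp$anc[root, ]; V[root] <- dp$extra[root]
  for (e in nrow(edge):1) {                    # preorder
    par <- edge[e, 1]; ch <- edge[e, 2]
    prec <- 0; wm <- rep(0, p)
    if (is.finite(av[par]) ) {
      if (av[par] < 1e-12) { prec <- Inf; wm <- am[par, ] }
      else { prec <- prec + 1 / av[par]; wm <- wm + am[par, ] / av[par] }
    }
    if (is.finite(prec)) {
      sibs <- which(edge[, 1] == par & edge[, 2] != ch)
      for (e2 in sibs) {
        if (dv[e2] < 1e-12) { prec <- Inf; wm <- dm[e2, ]; break }
        prec <- prec + 1 / dv[e2]
        wm <- wm + dm[e2, ] / dv[e2]
      }
    }
    if (!is.finite(prec)) { am[ch, ] <- wm; av[ch] <- elen[e] }
    else if (prec == 0) { av[ch] <- Inf }
    else { am[ch, ] <- wm / prec; av[ch] <- 1 / prec + elen[e] }
    # combine with the node's own down-pass conditional
    if (ch > ntip) {
      if (dp$extra[ch] < 1e-12) { M[ch, ] <- dp$anc[ch, ]; V[ch] <- 0 }
      else if (!is.finite(av[ch])) { M[ch, ] <- dp$anc[ch, ]; V[ch] <- dp$extra[ch] }
      else if (av[ch] < 1e-12) { M[ch, ] <- am[ch, ]; V[ch] <- 0 }
      else {
        w1 <- 1 / dp$extra[ch]; w2 <- 1 / av[ch]
        M[ch, ] <- (w1 * dp$anc[ch, ] + w2 * am[ch, ]) / (w1 + w2)
        V[ch] <- 1 / (w1 + w2)
      }
    } else {
      M[ch, ] <- dp$anc[ch, ]; V[ch] <- 0    # tips are data
    }
  }
  list(mean = M, var_scalar = V)
}

#' Confidence ellipse parameters from a covariance matrix
#'
#' Semi-axes are `sqrt(eigenvalues x chi^2_2 quantile at `level`)`;
#' orientation is the angle of the major axis from the lon axis.
#'
#' @param cov 2x2 symmetric PSD covariance (deg^2).
#' @param level confidence level (default 0.68).
#' @return named vector `semi_major`, `semi_minor`, `angle_deg`.
#' @export
confidence_ellipse <- function(cov, level = 0.68) {
  e <- eigen(cov, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  q <- stats::qchisq(level, df = 2)
  c(semi_major = sqrt(ev[1] * q), semi_minor = sqrt(ev[2] * q),
    angle_deg = atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi)
}

#' Bivariate Brownian-motion ancestral geocoordinates
#'
#' Fits a homogeneous-rate bivariate Brownian motion to tip (lon, lat)
#' points on a time-tree: the 2x2 rate matrix is estimated by REML from
#' phylogenetically independent contrasts, ancestral means are the GLS
#' estimates (computed by a two-pass pruning recursion; means do not depend
#' on the rate), and each node's covariance is its Brownian conditional
#' variance scalar times the rate matrix. Longitudes are unwrapped about
#' `center` before fitting and node means re-wrapped on output.
#'
#' @param tree a `time_tree` with >= 3 tips.
#' @param points matrix/data.frame with rownames = tip labels and columns
#'   lon, lat (degrees), one row per tip.
#' @param level confidence level of the reported ellipses.
#' @param center chart centre meridian; `NULL` = spherical centroid of the
#'   tip points.
#' @return object of class `geo_recon`: data.frame `nodes` (node, age,
#'   mean_lon, mean_lat, var_lon, cov_lonlat, var_lat, semi_major,
#'   semi_minor, angle_deg), plus attributes `sigma` (2x2 deg^2/Ma REML rate),
#'   `log_likelihood` (REML), `level`, `center`.
#' @export
fit_bm_asr <- function(tree, points, level = 0.68, center = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  points <- as.matrix(points)
  if (length(tree$tip.label) < 3) stop("need >= 3 tips")
  miss <- setdiff(tree$tip.label, rownames(points))
  if (length(miss)) stop("missing coordinates for: ",
                         paste(miss, collapse = ", "))
  X <- points[tree$tip.label, 1:2, drop = FALSE]
  if (is.null(center)) center <- unname(geocentroid(X)[1])
  X[, 1] <- unwrap_longitudes(X[, 1], center)
  dp <- bm_down_pass(tree, X)
  U <- dp$contrasts
  if (nrow(U) < 2) stop("not enough contrasts to estimate the rate matrix")
  sigma <- crossprod(U) / nrow(U)          # REML estimate, deg^2/Ma
  mg <- bm_marginals(tree, X)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  covs <- lapply(seq_len(nn), function(i) mg$var_scalar[i] * sigma)
  ell <- t(vapply(covs, confidence_ellipse, numeric(3), level = level))
  nodes <- data.frame(
    node = seq_len(nn),
    label = c(tree$tip.label, rep(NA, tree$Nnode)),
    age = tree$node.ages,
    mean_lon = wrap_longitude(mg$mean[, 1]),
    mean_lat = mg$mean[, 2],
    var_lon = vapply(covs, function(s) s[1, 1], 0),
    cov_lonlat = vapply(covs, function(s) s[1, 2], 0),
    var_lat = vapply(covs, function(s) s[2, 2], 0),
    semi_major = ell[, 1], semi_minor = ell[, 2], angle_deg = ell[, 3],
    stringsAsFactors = FALSE
  )
  # REML log-likelihood: contrasts are iid N(0, sigma)
  ld <- determinant(sigma, logarithm = TRUE)$modulus
  qf <- sum(U %*% solve(sigma) * U)
  ll <- -0.5 * (nrow(U) * (2 * log(2 * pi) + ld) + qf)
  structure(list(nodes = nodes, sigma = sigma, log_likelihood = as.numeric(ll),
                 level = level, center = center),
            class = "geo_recon")
}

#' @export
print.geo_recon <- function(x, ...) {
  cat("Geocoordinates reconstruction:", sum(is.na(x$nodes$label)),
      "internal nodes; REML rate (deg^2/Ma): lon",
      format(x$sigma[1, 1], digits = 4), ", lat",
      format(x$sigma[2, 2], digits = 4), "\n")
  invisible(x)
}

## centroid point per tip from an occurrence table (+ optional extant samples)
tip_centroids <- function(tree, occurrences) {
  occ <- validate_occurrences(occurrences)
  pts <- matrix(NA_real_, length(tree$tip.label), 2,
                dimnames = list(tree$tip.label, c("lon", "lat")))
  for (tx in tree$tip.label) {
    o <- occ[occ$taxon == tx, , drop = FALSE]
    if (nrow(o) == 0) stop("no occurrence for tip ", tx)
    pts[tx, ] <- geocentroid(cbind(o$lon, o$lat))
  }
  pts
}

#' First-pass reconstruction on the bundled-tip tree
#'
#' Multi-locality tips (and extant range samples) are collapsed to their
#' spherical geocentroids and [fit_bm_asr] is applied. Deterministic: the
#' REML/GLS path involves no sampling.
#'
#' @param tree a `time_tree` whose tips all appear in `occurrences`.
#' @param occurrences occurrence table covering every tip (fossil localities
#'   and extant range sample points alike).
#' @param level,center passed to [fit_bm_asr].
#' @return a `geo_recon`.
#' @export
first_pass <- function(tree, occurrences, level = 0.68, center = NULL) {
  fit_bm_asr(tree, tip_centroids(tree, occurrences), level = level,
             center = center)
}

#' Distance-to-time scaling factor of a tip
#'
#' `s = (age(parent) - age(tip)) / d` where `d` is the great-circle distance
#' (km) from the tip's geocentroid to its parent node's first-pass mean
#' position. When `d = 0` the scaling factor is undefined and `NA` is
#' returned; callers fall back to the global median across tips.
#'
#' @param tree a `time_tree`.
#' @param recon first-pass `geo_recon` on the same tree.
#' @param tip tip label.
#' @param tip_point the tip's geocentroid `c(lon, lat)`; default: the tip
#'   mean stored in `recon`.
#' @return list with `tip`, `s` (Ma/km or `NA`), `dt` (Ma), `d` (km).
#' @export
scaling_factor <- function(tree, recon, tip, tip_point = NULL) {
  i <- match(tip, tree$tip.label)
  if (is.na(i)) stop("unknown tip: ", tip)
  parent <- tree$edge[tree$edge[, 2] == i, 1]
  dt <- tree$node.ages[parent] - tree$node.ages[i]
  if (is.null(tip_point))
    tip_point <- unlist(recon$nodes[i, c("mean_lon", "mean_lat")])
  pm <- unlist(recon$nodes[parent, c("mean_lon", "mean_lat")])
  d <- geodesic_km(tip_point, pm)
  s <- if (d > 0) dt / d else NA_real_
  list(tip = tip, s = s, dt = dt, d = d)
}

#' Split a two-locality tip (rule a)
#'
#' The terminal is bifurcated; both new tips retain the original tip age and
#' carry one locality each. The new node's age is the tip age plus the
#' geographic distance between the two localities scaled to time
#' (`d * s * distance_fraction`), clamped below the parent age by
#' `eps_frac` of the original branch duration.
#'
#' @param tree a `time_tree`.
#' @param tip tip label to split.
#' @param loc_a,loc_b localities as `c(lon, lat)`.
#' @param s scaling factor (Ma/km).
#' @param labels labels of the two new tips.
#' @param distance_fraction fraction of the scaled distance placed between
#'   the node and each tip (default 1: node age = tip age + d*s).
#' @param eps_frac clamp margin as a fraction of the original branch
#'   duration.
#' @return list with `tree` (expanded `time_tree`), `node_age`, `clamped`.
#' @export
split_two_locality_tip <- function(tree, tip, loc_a, loc_b, s,
                                   labels = paste0(tip, "__", 1:2),
                                   distance_fraction = 1, eps_frac = 0.01) {
  i <- match(tip, tree$tip.label)
  if (is.na(i)) stop("unknown tip: ", tip)
  parent <- tree$edge[tree$edge[, 2] == i, 1]
  t0 <- tree$node.ages[i]; tp <- tree$node.ages[parent]
  eps <- eps_frac * (tp - t0)
  d <- geodesic_km(loc_a, loc_b)
  target <- t0 + d * s * distance_fraction
  if (d == 0) target <- t0 + eps        # degenerate bifurcation
  node_age <- min(target, tp - eps)
  clamped <- node_age < target
  sub <- two_tip_subtree(labels, t0, node_age)
  list(tree = graft_subtree(tree, tip, sub, node_age),
       node_age = node_age, clamped = clamped)
}

two_tip_subtree <- function(labels, tip_age, root_age) {
  len <- max(root_age - tip_age, 0)
  phy <- ape::read.tree(text = sprintf("(%s:%.15g,%s:%.15g);", labels[1], len,
                                       labels[2], len))
  as_time_tree(phy, tip_ages = stats::setNames(rep(tip_age, 2), labels))
}

#' Neighbor joining on a locality distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj]) with negative branch lengths
#' clamped to zero and the deficit transferred to the adjacent branch so
#' tip-to-tip path lengths are preserved (standard practice).
#'
#' @param D symmetric distance matrix (zero diagonal) or `dist`.
#' @param labels optional labels overriding `dimnames`.
#' @return an unrooted `phylo` with branch lengths; attribute `clamped`
#'   reports how many edges were clamped.
#' @export
nj_tree <- function(D, labels = NULL) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix not symmetric")
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  if (is.null(rownames(D))) stop("distance matrix needs labels")
  if (nrow(D) < 3) stop("need >= 3 labels for neighbor joining")
  phy <- ape::nj(stats::as.dist(D))
  clamped <- 0L
  repeat {
    neg <- which(phy$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[which.min(phy$edge.length[neg])]
    deficit <- phy$edge.length[e]
    phy$edge.length[e] <- 0
    # transfer to the sibling branch (same parent), preserving path lengths
    sib <- which(phy$edge[, 1] == phy$edge[e, 1] & seq_along(phy$edge.length) != e)
    if (length(sib)) {
      j <- sib[which.max(phy$edge.length[sib])]
      phy$edge.length[j] <- phy$edge.length[j] + deficit
    }
    clamped <- clamped + 1L
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  attr(phy, "clamped") <- clamped
  phy
}

#' Root an unrooted locality tree on the closest-to-parent terminal
#'
#' The locality with the shortest geodesic distance to the parent node's
#' first-pass mean position is found (ties broken by lowest locality label)
#' and the tree is rooted at the midpoint of that terminal branch.
#'
#' @param nj unrooted `phylo` with locality tip labels.
#' @param parent_mean `c(lon, lat)` of the parent node.
#' @param localities matrix with rownames = tip labels, columns lon, lat.
#' @return rooted `phylo`; attribute `root_tip` records the chosen locality.
#' @export
root_on_closest <- function(nj, parent_mean, localities) {
  loc <- as.matrix(localities)[nj$tip.label, , drop = FALSE]
  d <- geodesic_km(loc, matrix(parent_mean, nrow(loc), 2, byrow = TRUE))
  best <- nj$tip.label[order(d, nj$tip.label)][1]
  i <- match(best, nj$tip.label)
  len <- nj$edge.length[nj$edge[, 2] == i]
  rooted <- phytools::reroot(nj, node.number = i, position = len / 2)
  attr(rooted, "root_tip") <- best
  rooted
}

#' Nonparametric rate smoothing to a flush-tipped tree
#'
#' Assigns relative node ages (root age 1, all tips age 0) minimising
#' Sanderson's nonparametric rate-smoothing objective: the sum over edges of
#' squared differences between an edge's local rate (length / duration) and
#' its parent edge's rate, with the root term taken as squared deviations of
#' the root children's rates from their mean. Optimisation is over
#' logit-transformed age fractions (each node's age as a fraction of its
#' parent's), initialised from mean node-to-tip depths.
#'
#' @param phy rooted `phylo` with branch lengths (>= 2 tips).
#' @return list with `tree` (a `time_tree` with relative ages, root = 1),
#'   `objective` (minimised value), `rates` (per-edge local rates).
#' @export
nprs_ultrametricize <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  if (ntip < 2) stop("need >= 2 tips")
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  if (sum(phy$edge.length) <= 0) {
    # pathological all-zero input: ages by uniform interpolation on depth
    depth <- ape::node.depth(phy, method = 1)   # counts, tips = 1
    ages <- (depth - 1) / max(depth - 1)
    ages[seq_len(ntip)] <- 0
    tt <- phy
    tt$node.ages <- ages
    tt$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
    class(tt) <- c("time_tree", "phylo")
    return(list(tree = tt, objective = 0,
                rates = rep(0, nrow(phy$edge))))
  }
  internals <- setdiff((ntip + 1L):nn, root)
  parent_of <- integer(nn)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  # preorder over internal nodes so parents are evaluated first
  pre <- ape::reorder.phylo(phy, "cladewise")$edge[, 2]
  pre_int <- pre[pre > ntip]
  # initial ages: mean distance to descendant tips, as fraction of parent's
  depth_to_tips <- numeric(nn)
  cnt <- integer(nn)
  po <- ape::reorder.phylo(phy, "postorder")
  acc <- rep(0, nn); cnt <- integer(nn); cnt[seq_len(ntip)] <- 1L
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    acc[p] <- acc[p] + acc[ch] + po$edge.length[e] * cnt[ch]
    cnt[p] <- cnt[p] + cnt[ch]
  }
  meand <- acc / cnt                     # mean node-to-tip path length
  init_frac <- vapply(pre_int, function(v) {
    f <- meand[v] / max(meand[parent_of[v]], 1e-9)
    min(max(f, 0.02), 0.98)
  }, 0)
  ages_from_theta <- function(theta) {
    frac <- 1 / (1 + exp(-theta))
    ages <- numeric(nn)
    ages[root] <- 1
    for (i in seq_along(pre_int)) {
      v <- pre_int[i]
      ages[v] <- ages[parent_of[v]] * frac[i]
    }
    ages
  }
  edge_par <- match(phy$edge[, 1], phy$edge[, 2])  # parent edge index or NA
  root_children <- which(is.na(edge_par))
  objective <- function(theta) {
    ages <- ages_from_theta(theta)
    dur <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
    r <- phy$edge.length / pmax(dur, 1e-9)
    inner <- which(!is.na(edge_par))
    val <- sum((r[inner] - r[edge_par[inner]])^2)
    val + sum((r[root_children] - mean(r[root_children]))^2)
  }
  if (length(pre_int) == 0) {            # single internal node (the root)
    ages <- numeric(nn); ages[root] <- 1
  } else if (length(pre_int) == 1L) {
    op <- stats::optimize(function(th) objective(th), interval = c(-8, 8),
                          tol = 1e-12)
    ages <- ages_from_theta(op$minimum)
  } else {
    theta0 <- log(init_frac / (1 - init_frac))
    op <- stats::optim(theta0, objective, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
    op2 <- stats::optim(op$par, objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- if (op2$value < op$value) op2 else op
    ages <- ages_from_theta(best$par)
  }
  tt <- phy
  tt$node.ages <- ages
  tt$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  class(tt) <- c("time_tree", "phylo")
  dur <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  list(tree = tt, objective = objective_value(phy, ages, edge_par),
       rates = phy$edge.length / pmax(dur, 1e-9))
}

objective_value <- function(phy, ages, edge_par) {
  dur <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  r <- phy$edge.length / pmax(dur, 1e-9)
  inner <- which(!is.na(edge_par))
  root_children <- which(is.na(edge_par))
  sum((r[inner] - r[edge_par[inner]])^2) +
    sum((r[root_children] - mean(r[root_children]))^2)
}

#' Split a multi-locality tip (rule b)
#'
#' For a tip bundling three or more localities (two are delegated to the
#' equivalent two-locality arithmetic): geodesic distance matrix ->
#' neighbor joining -> rooting on the closest-to-parent locality -> NPRS
#' flush-tipped transform -> km-to-Ma scaling with the tip's scaling factor
#' -> grafting so that every new tip sits at the original tip age. The
#' subtree's depth in km is twice the mean root-to-tip path of the rooted
#' locality tree, so the two-locality case (depth = the full inter-locality
#' distance) is reproduced exactly at n = 2.
#'
#' @param tree a `time_tree`.
#' @param tip tip label to split.
#' @param localities matrix with rownames = locality labels, columns lon,
#'   lat; one row per locality.
#' @param s scaling factor (Ma/km).
#' @param parent_mean `c(lon, lat)` first-pass mean of the tip's parent.
#' @param eps_frac clamp margin as a fraction of the original branch
#'   duration.
#' @return list with `tree`, `attach_age`, `clamped`, `root_tip`.
#' @export
split_multi_locality_tip <- function(tree, tip, localities, s, parent_mean,
                                     eps_frac = 0.01) {
  localities <- as.matrix(localities)
  n <- nrow(localities)
  if (n < 2) stop("need >= 2 localities")
  i <- match(tip, tree$tip.label)
  if (is.na(i)) stop("unknown tip: ", tip)
  parent <- tree$edge[tree$edge[, 2] == i, 1]
  t0 <- tree$node.ages[i]; tp <- tree$node.ages[parent]
  eps <- eps_frac * (tp - t0)
  if (n == 2) {
    out <- split_two_locality_tip(tree, tip, localities[1, ], localities[2, ],
                                  s, labels = rownames(localities),
                                  eps_frac = eps_frac)
    return(list(tree = out$tree, attach_age = out$node_age,
                clamped = out$clamped, root_tip = NA_character_))
  }
  D <- outer(seq_len(n), seq_len(n), function(a, b)
    geodesic_km(localities[a, , drop = FALSE], localities[b, , drop = FALSE]))
  dimnames(D) <- list(rownames(localities), rownames(localities))
  if (max(D) == 0) {
    # all localities identical: degenerate near-zero subtree
    sub <- star_subtree(rownames(localities), t0, t0 + eps)
    return(list(tree = graft_subtree(tree, tip, sub, t0 + eps),
                attach_age = t0 + eps, clamped = FALSE,
                root_tip = NA_character_))
  }
  un <- nj_tree(D)
  rooted <- root_on_closest(un, parent_mean, localities)
  sm <- nprs_ultrametricize(rooted)
  rel <- sm$tree
  # scale: relative root age 1 -> km depth = 2 x mean root-to-tip path
  depth_km <- 2 * mean(ape::node.depth.edgelength(rooted)[seq_len(n)])
  target <- t0 + depth_km * s
  attach_age <- min(target, tp - eps)
  attach_age <- max(attach_age, t0 + eps)
  clamped <- attach_age < target
  sub_ages <- t0 + rel$node.ages * (attach_age - t0)
  sub <- rel
  sub$node.ages <- sub_ages
  sub$edge.length <- sub_ages[sub$edge[, 1]] - sub_ages[sub$edge[, 2]]
  list(tree = graft_subtree(tree, tip, sub, attach_age),
       attach_age = attach_age, clamped = clamped,
       root_tip = attr(rooted, "root_tip"))
}

star_subtree <- function(labels, tip_age, root_age) {
  phy <- ape::read.tree(text = paste0("(", paste0(labels, ":",
         sprintf("%.15g", max(root_age - tip_age, 0)), collapse = ","), ");"))
  as_time_tree(phy, tip_ages = stats::setNames(rep(tip_age, length(labels)),
                                               labels))
}

#' Expand every multi-locality tip of a tree
#'
#' Driver for the second-pass input: applies [split_two_locality_tip] /
#' [split_multi_locality_tip] to every tip with two or more occurrence rows,
#' using per-tip scaling factors from the first pass (tips with zero
#' parent-distance fall back to the global median factor). New tips are
#' labelled `taxon__locality_id`.
#'
#' @param tree a `time_tree`.
#' @param occurrences occurrence table covering every tip.
#' @param recon first-pass `geo_recon` on `tree`.
#' @param eps_frac clamp margin.
#' @return list with `tree` (expanded `time_tree`), `points` (matrix of
#'   per-tip coordinates for the expanded tree), `scaling` (data.frame of
#'   per-tip factors), `log` (data.frame of split events).
#' @export
expand_tree_by_localities <- function(tree, occurrences, recon,
                                      eps_frac = 0.01) {
  occ <- validate_occurrences(occurrences)
  tips <- tree$tip.label
  cent <- tip_centroids(tree, occ)
  sf <- lapply(tips, function(tx) scaling_factor(tree, recon, tx,
                                                 tip_point = cent[tx, ]))
  s_all <- vapply(sf, function(x) x$s, 0)
  s_med <- stats::median(s_all, na.rm = TRUE)
  if (!is.finite(s_med)) s_med <- 1e-4   # no informative tip at all
  scaling <- data.frame(tip = tips, s = s_all,
                        dt = vapply(sf, function(x) x$dt, 0),
                        d = vapply(sf, function(x) x$d, 0),
                        fallback = !is.finite(s_all))
  scaling$s[!is.finite(scaling$s)] <- s_med
  out <- tree
  pts <- list()
  log <- list()
  for (tx in tips) {
    o <- occ[occ$taxon == tx, , drop = FALSE]
    if (nrow(o) == 1) {
      pts[[tx]] <- c(o$lon, o$lat)
      next
    }
    i0 <- match(tx, out$tip.label)
    par0 <- out$edge[out$edge[, 2] == i0, 1]
    if (out$node.ages[par0] - out$node.ages[i0] <= 1e-8) {
      # zero-length terminal branch: nothing to shorten, keep the centroid
      pts[[tx]] <- unname(geocentroid(cbind(o$lon, o$lat)))
      log[[tx]] <- data.frame(tip = tx, n_localities = nrow(o),
                              attach_age = NA_real_, clamped = NA,
                              stringsAsFactors = FALSE)
      next
    }
    labs <- paste0(tx, "__", o$locality_id)
    loc <- cbind(lon = o$lon, lat = o$lat)
    rownames(loc) <- labs
    i <- match(tx, tree$tip.label)
    parent <- tree$edge[tree$edge[, 2] == i, 1]
    pm <- unlist(recon$nodes[parent, c("mean_lon", "mean_lat")])
    s <- scaling$s[scaling$tip == tx]
    res <- split_multi_locality_tip(out, tx, loc, s, pm, eps_frac = eps_frac)
    out <- res$tree
    for (j in seq_len(nrow(o))) pts[[labs[j]]] <- c(o$lon[j], o$lat[j])
    log[[tx]] <- data.frame(tip = tx, n_localities = nrow(o),
                            attach_age = res$attach_age,
                            clamped = res$clamped, stringsAsFactors = FALSE)
  }
  points <- do.call(rbind, pts)
  colnames(points) <- c("lon", "lat")
  list(tree = out, points = points[out$tip.label, , drop = FALSE],
       scaling = scaling,
       log = if (length(log)) do.call(rbind, log) else NULL)
}

#' Second-pass reconstruction on the expanded tree
#'
#' [fit_bm_asr] on the locality-expanded tree where every tip carries a
#' single coordinate pair. With no multi-locality tips the result equals the
#' first pass.
#'
#' @param tree expanded `time_tree`.
#' @param points per-tip coordinates (rownames = tip labels).
#' @param level,center passed to [fit_bm_asr].
#' @return a `geo_recon`.
#' @export
second_pass <- function(tree, points, level = 0.68, center = NULL) {
  fit_bm_asr(tree, points, level = level, center = center)
}

#' Write a node reconstruction table
#'
#' @param recon a `geo_recon`.
#' @param file CSV path.
#' @return the node table, invisibly.
#' @export
write_geo_recon <- function(recon, file) {
  utils::write.csv(recon$nodes, file, row.names = FALSE)
  invisible(recon$nodes)
}
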