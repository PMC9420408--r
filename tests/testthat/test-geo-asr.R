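test_that("geodesic distances match closed forms", {
  expect_equal(geodesic_km(c(12, 34), c(12, 34)), 0)
  expect_equal(geodesic_km(c(0, 0), c(180, 0)), pi * 6371, tolerance = 1e-6)
  expect_equal(geodesic_km(c(0, 0), c(0, 90)), pi * 6371 / 2, tolerance = 1e-6)
})

test_that("longitude unwrapping is a chart change with exact round trip", {
  expect_equal(unwrap_longitudes(c(-170, 0, 180), 0), c(-170, 0, 180))
  u <- unwrap_longitudes(c(170, -170), 180)
  expect_equal(u, c(170, 190))
  expect_equal(mean(u), 180)
  set.seed(3)
  lons <- stats::runif(200, -179.99, 180)
  for (ctr in c(0, 90, 180, -120))
    expect_equal(wrap_longitude(unwrap_longitudes(lons, ctr)), lons,
                 tolerance = 1e-10)
})

test_that("BM reconstruction matches the cherry closed form and GLS identities", {
  # two-tip closed form through a near-zero outgroup-free cherry
  tt <- as_time_tree(ape::read.tree(text = "(A:1,B:3);"),
                     tip_ages = c(A = 2, B = 0))
  mg <- paleoASR:::bm_marginals(tt, rbind(A = c(0, 0), B = c(10, 4)))
  expect_equal(mg$mean[3, ], c((0 / 1 + 10 / 3) / (1 / 1 + 1 / 3),
                               (0 / 1 + 4 / 3) / (1 / 1 + 1 / 3)),
               tolerance = 1e-12)
  # equal branches: midpoint
  tt2 <- as_time_tree(ape::read.tree(text = "(A:2,B:2);"),
                      tip_ages = c(A = 0, B = 0))
  mg2 <- paleoASR:::bm_marginals(tt2, rbind(A = c(0, 0), B = c(10, 0)))
  expect_equal(mg2$mean[3, ], c(5, 0))
  # star tree (fossil tips at staggered ages so durations differ):
  # inverse-duration-weighted average of the tips
  star <- as_time_tree(ape::read.tree(text = "(A:1,B:2,C:4);"),
                       tip_ages = c(A = 3, B = 2, C = 0))
  pts <- rbind(A = c(0, 0), B = c(6, 3), C = c(12, -9))
  r <- fit_bm_asr(star, pts)
  w <- 1 / c(1, 2, 4)
  expect_equal(unname(unlist(r$nodes[4, c("mean_lon", "mean_lat")])),
               c(sum(w * pts[, 1]) / sum(w), sum(w * pts[, 2]) / sum(w)),
               tolerance = 1e-9)
  # tip means equal the observations
  expect_equal(unname(as.matrix(r$nodes[1:3, c("mean_lon", "mean_lat")])),
               unname(pts), tolerance = 1e-12)
})

test_that("reconstruction is translation-equivariant in longitude", {
  set.seed(31)
  tt <- coal_time_tree(20, depth = 30)
  pts <- simulate_geo_bm(tt, diag(c(2, 1)), c(0, 10), seed = 32)
  r0 <- fit_bm_asr(tt, pts, center = 0)
  shift <- 15
  pts2 <- pts
  pts2[, 1] <- pts[, 1] + shift
  r1 <- fit_bm_asr(tt, pts2, center = 0)
  expect_equal(r1$nodes$mean_lon, r0$nodes$mean_lon + shift, tolerance = 1e-8)
  expect_equal(r1$nodes$mean_lat, r0$nodes$mean_lat, tolerance = 1e-8)
  expect_equal(r1$sigma, r0$sigma, tolerance = 1e-10)
})

test_that("REML agrees with independent-contrast estimates on binary trees", {
  set.seed(33)
  phy <- ape::rcoal(40)
  tt <- as_time_tree(phy, tip_ages = stats::setNames(rep(0, 40), phy$tip.label))
  x <- phytools::fastBM(phy, sig2 = 3)
  y <- phytools::fastBM(phy, sig2 = 1)
  dp <- paleoASR:::bm_down_pass(tt, cbind(x, y)[phy$tip.label, ])
  expect_equal(unname(crossprod(dp$contrasts)[1, 1] / nrow(dp$contrasts)),
               mean(ape::pic(x, phy)^2), tolerance = 1e-10)
  # marginal means equal the re-rooted ML states from an external toolkit
  mg <- paleoASR:::bm_marginals(tt, cbind(x, y)[phy$tip.label, ])
  fa <- phytools::fastAnc(phy, x)
  expect_equal(unname(mg$mean[41:79, 1]), unname(as.numeric(fa)),
               tolerance = 1e-8)
})

test_that("first pass equals raw-point BM when every tip is single-locality", {
  set.seed(35)
  tt <- coal_time_tree(10, depth = 20)
  pts <- simulate_geo_bm(tt, diag(c(4, 1)), c(0, 0), seed = 36)
  occ <- data.frame(taxon = rownames(pts), locality_id = "L1",
                    lon = pts[, 1], lat = pts[, 2],
                    age_min = 0, age_max = 0)
  fp <- first_pass(tt, occ)
  direct <- fit_bm_asr(tt, pts)
  expect_equal(fp$nodes$mean_lon, direct$nodes$mean_lon, tolerance = 1e-9)
  # a two-locality tip enters as its centroid
  occ2 <- occ
  extra <- occ[1, ]; extra$locality_id <- "L2"; extra$lon <- extra$lon + 10
  occ2 <- rbind(occ2, extra)
  fp2 <- first_pass(tt, occ2)
  expect_equal(fp2$nodes$mean_lon[1],
               geocentroid(rbind(c(occ[1, "lon"], occ[1, "lat"]),
                                 c(extra$lon, extra$lat)))[["lon"]],
               tolerance = 1e-9)
  # deterministic: same inputs, same outputs
  expect_identical(fp$nodes, first_pass(tt, occ)$nodes)
})

test_that("scaling factors divide branch duration by parent distance", {
  tt <- read_newick(text = "((A:2,B:2):1,C:3);", tip_ages = c(A = 0, B = 0, C = 0))
  pts <- rbind(A = c(0, 0), B = c(12, 0), C = c(0, 20))
  occ <- data.frame(taxon = rownames(pts), locality_id = "L1",
                    lon = pts[, 1], lat = pts[, 2], age_min = 0, age_max = 0)
  fp <- first_pass(tt, occ)
  sf <- scaling_factor(tt, fp, "A")
  expect_equal(sf$dt, 2)
  expect_equal(sf$s, sf$dt / sf$d)
  expect_gt(sf$s, 0)
  # explicit arithmetic: 2 Ma over 1000 km
  sf2 <- scaling_factor(tt, fp, "A", tip_point = c(0, 0))
  pm <- unlist(fp$nodes[5, c("mean_lon", "mean_lat")])
  expect_equal(sf2$s, 2 / geodesic_km(c(0, 0), pm))
  # zero distance: undefined factor flagged as NA
  fp0 <- fp
  fp0$nodes$mean_lon[5] <- 0; fp0$nodes$mean_lat[5] <- 0
  expect_true(is.na(scaling_factor(tt, fp0, "A", tip_point = c(0, 0))$s))
})

test_that("two-locality splits place the node at the scaled distance", {
  tt <- read_newick(text = "((A:5,B:15):10,C:20);",
                    tip_ages = c(A = 10, B = 0, C = 5))
  # d ~ 500 km, s = 0.002 -> node at 11.0 (parent at 15, no clamping)
  loc_a <- c(0, 0)
  loc_b <- c(500 / 111.19493, 0)   # ~500 km along the equator
  d <- geodesic_km(loc_a, loc_b)
  out <- split_two_locality_tip(tt, "A", loc_a, loc_b, s = 0.002)
  expect_equal(out$node_age, 10 + d * 0.002, tolerance = 1e-9)
  expect_false(out$clamped)
  expect_equal(unname(tip_ages(out$tree)[c("A__1", "A__2")]), c(10, 10))
  # overshoot is clamped below the parent
  out2 <- split_two_locality_tip(tt, "A", loc_a, c(90, 0), s = 0.05)
  expect_true(out2$clamped)
  expect_lt(out2$node_age, 15)
  # identical localities: degenerate bifurcation just above the tip
  out3 <- split_two_locality_tip(tt, "A", loc_a, loc_a, s = 0.002)
  expect_equal(out3$node_age, 10 + 0.01 * 5, tolerance = 1e-9)
})

test_that("neighbor joining matches the three-point formula and additive matrices", {
  D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy <- nj_tree(D)
  cd <- ape::cophenetic.phylo(phy)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(cd), unname(D), tolerance = 1e-12)
  lens <- stats::setNames(phy$edge.length[match(1:3, phy$edge[, 2])],
                          phy$tip.label)
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 1, 2))
  # permuting labels gives an isomorphic tree
  perm <- c("C", "A", "B")
  phy2 <- nj_tree(D[perm, perm])
  expect_equal(ape::cophenetic.phylo(phy2)[c("A", "B", "C"), c("A", "B", "C")],
               cd, tolerance = 1e-12)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("rooting picks the closest-to-parent locality at its branch midpoint", {
  loc <- rbind(L1 = c(0, 0), L2 = c(1, 0), L3 = c(10, 0))
  D <- outer(1:3, 1:3, function(i, j)
    geodesic_km(loc[i, , drop = FALSE], loc[j, , drop = FALSE]))
  dimnames(D) <- list(rownames(loc), rownames(loc))
  un <- nj_tree(D)
  r <- root_on_closest(un, parent_mean = c(11, 0), localities = loc)
  expect_equal(attr(r, "root_tip"), "L3")
  expect_true(ape::is.rooted(r))
  # rooting preserves pairwise path lengths
  expect_equal(ape::cophenetic.phylo(r)[rownames(loc), rownames(loc)],
               ape::cophenetic.phylo(un)[rownames(loc), rownames(loc)],
               tolerance = 1e-9)
  # exact tie: lowest label wins
  loc2 <- rbind(La = c(0, 0), Lb = c(4, 0), Lc = c(2, 3))
  D2 <- outer(1:3, 1:3, function(i, j)
    geodesic_km(loc2[i, , drop = FALSE], loc2[j, , drop = FALSE]))
  dimnames(D2) <- list(rownames(loc2), rownames(loc2))
  r2 <- root_on_closest(nj_tree(D2), parent_mean = c(2, 0), localities = loc2)
  expect_equal(attr(r2, "root_tip"), "La")
})

test_that("NPRS recovers clock-like inputs and flushes all tips", {
  set.seed(41)
  for (n in c(5, 9, 14)) {
    phy <- ape::rcoal(n)
    res <- nprs_ultrametricize(phy)
    expect_lt(res$objective, 1e-8)
    depth <- ape::node.depth.edgelength(phy)
    rel <- (max(depth) - depth) / max(depth)
    expect_lt(max(abs(res$tree$node.ages - rel)), 1e-6)
  }
  # two-tip tree, lengths 1 and 3: single free age, tips flush
  phy2 <- ape::read.tree(text = "(A:1,B:3);")
  res2 <- nprs_ultrametricize(phy2)
  expect_equal(unname(res2$tree$node.ages[1:2]), c(0, 0))
  expect_equal(unname(res2$tree$node.ages[3]), 1)
  # a non-clock tree still comes out flush-tipped
  phy3 <- ape::rtree(8)
  res3 <- nprs_ultrametricize(phy3)
  expect_lt(max(abs(res3$tree$node.ages[1:8])), 1e-8)
  expect_true(all(res3$tree$edge.length >= -1e-9))
})

test_that("rule (b) degenerates to rule (a) arithmetic for two localities", {
  tt <- read_newick(text = "((A:5,B:15):10,C:20);",
                    tip_ages = c(A = 10, B = 0, C = 5))
  loc <- rbind(A__p = c(0, 0), A__q = c(3, 0))
  s <- 0.002
  via_b <- split_multi_locality_tip(tt, "A", loc, s, parent_mean = c(1, 0))
  d <- geodesic_km(loc[1, ], loc[2, ])
  expect_equal(via_b$attach_age, 10 + d * s, tolerance = 1e-9)
  expect_equal(sort(unname(tip_ages(via_b$tree)[c("A__p", "A__q")])), c(10, 10))
})

test_that("multi-locality splits run the full NJ + NPRS + scaling pipeline", {
  tt <- read_newick(text = "((A:5,B:15):35,C:50);",
                    tip_ages = c(A = 10, B = 0, C = 0))
  # three collinear equatorial localities at lon 0, 1, 10
  loc <- rbind(A__1 = c(0, 0), A__2 = c(1, 0), A__3 = c(10, 0))
  out <- split_multi_locality_tip(tt, "A", loc, s = 0.002,
                                  parent_mean = c(-5, 0))
  expect_setequal(out$tree$tip.label, c("A__1", "A__2", "A__3", "B", "C"))
  expect_equal(unname(tip_ages(out$tree)[paste0("A__", 1:3)]), rep(10, 3))
  expect_equal(out$root_tip, "A__1")   # closest to the parent at lon -5
  # rooting on the closest-to-parent locality makes it the subtree outgroup:
  # A__2 and A__3 join below the attachment node
  m23 <- mrca_node(out$tree, c("A__2", "A__3"))
  m12 <- mrca_node(out$tree, c("A__1", "A__2"))
  expect_lt(out$tree$node.ages[m23], out$tree$node.ages[m12])
  expect_equal(out$tree$node.ages[m12], out$attach_age, tolerance = 1e-9)
  # tip count accounting: original tips - 1 + n localities
  expect_equal(length(out$tree$tip.label), 3 - 1 + 3)
  # identical localities: degenerate near-zero subtree
  same <- rbind(A__1 = c(2, 2), A__2 = c(2, 2), A__3 = c(2, 2))
  out2 <- split_multi_locality_tip(tt, "A", same, s = 0.002,
                                   parent_mean = c(0, 0))
  expect_equal(unname(tip_ages(out2$tree)[paste0("A__", 1:3)]), rep(10, 3))
  expect_lt(out2$attach_age - 10, 0.1)
})

test_that("tree expansion preserves original tip ages and feeds the second pass", {
  ds <- simulate_dataset(sim_config(seed = 55, crown_age = 40,
                                    extant_points = 2, n_characters = 2))
  fp <- first_pass(ds$tree, ds$occurrences)
  ex <- expand_tree_by_localities(ds$tree, ds$occurrences, fp)
  common <- intersect(ds$tree$tip.label, ex$tree$tip.label)
  expect_equal(unname(tip_ages(ex$tree)[common]),
               unname(tip_ages(ds$tree)[common]), tolerance = 1e-6)
  expect_true(all(branches(ex$tree)$duration >= -1e-9))
  expect_equal(nrow(ex$points), length(ex$tree$tip.label))
  sp <- second_pass(ex$tree, ex$points)
  expect_s3_class(sp, "geo_recon")
  # second pass == first pass when nothing is split
  occ1 <- ds$occurrences[!duplicated(ds$occurrences$taxon), ]
  fp1 <- first_pass(ds$tree, occ1)
  ex1 <- expand_tree_by_localities(ds$tree, occ1, fp1)
  expect_identical(ex1$tree$tip.label, ds$tree$tip.label)
  sp1 <- second_pass(ex1$tree, ex1$points)
  expect_equal(sp1$nodes$mean_lon, fp1$nodes$mean_lon, tolerance = 1e-9)
})

test_that("ellipse areas grow with node age on a comb tree", {
  # comb (caterpillar) tree with uniform extant tips: deeper = more uncertain
  comb <- ape::read.tree(text = "(((((a:1,b:1):1,c:2):1,d:3):1,e:4):1,f:5);")
  tt <- as_time_tree(comb, tip_ages = stats::setNames(rep(0, 6), comb$tip.label))
  set.seed(61)
  pts <- simulate_geo_bm(tt, diag(c(3, 1)), c(0, 0), seed = 62)
  r <- fit_bm_asr(tt, pts)
  ints <- r$nodes[is.na(r$nodes$label), ]
  area <- pi * ints$semi_major * ints$semi_minor
  ord <- order(ints$age)
  expect_true(all(diff(area[ord]) > -1e-12))
  # ellipse axes come from the covariance eigenvalues at the chi-square quantile
  cv <- matrix(c(ints$var_lon[1], ints$cov_lonlat[1],
                 ints$cov_lonlat[1], ints$var_lat[1]), 2)
  expect_equal(unname(confidence_ellipse(cv, 0.68)[1]),
               sqrt(eigen(cv)$values[1] * stats::qchisq(0.68, 2)))
})
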