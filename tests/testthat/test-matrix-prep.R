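test_that("concatenation with duplication balances partitions and fills gaps", {
  set.seed(1)
  m1 <- rand_char_matrix(5, 83)
  m2 <- rand_char_matrix(5, 28)
  m3 <- rand_char_matrix(5, 17)
  cc <- concat_with_duplication(list(m1, m2, m3), c(1, 3, 5))
  expect_equal(cc$partition_sizes, c(83, 84, 85))
  expect_equal(max(cc$partition_sizes), 85)
  expect_equal(ncol(cc$matrix$states), sum(cc$partition_sizes))
  # duplicated columns are flagged so statistics can deduplicate
  expect_equal(sum(is.na(cc$matrix$dup_of)), 83 + 28 + 17)
  # identity for a single matrix with factor 1
  one <- concat_with_duplication(list(m1), 1)
  expect_equal(one$matrix$states, m1$states)
  # a taxon absent from matrix 2 gets all-missing cells in that block
  m2b <- char_matrix(m2$states[1:4, , drop = FALSE])
  cc2 <- concat_with_duplication(list(m1, m2b), c(1, 1))
  gap <- cc2$matrix$states["t5", cc2$matrix$partition == 2]
  expect_true(all(is.na(gap)))
  # per-taxon missing fraction in a duplicated block equals the source's
  frac <- function(x) mean(is.na(x))
  for (tx in rownames(m2$states))
    expect_equal(frac(cc$matrix$states[tx, cc$matrix$partition == 2]),
                 frac(m2$states[tx, ]))
})

test_that("invariant columns are removed exactly when one observed state remains", {
  m <- char_matrix(rbind(t1 = c(0L, 0L, 0L, NA),
                         t2 = c(0L, 1L, NA, NA),
                         t3 = c(NA, NA, NA, NA),
                         t4 = c(0L, 0L, 0L, NA)))
  out <- remove_invariant_columns(m)
  expect_equal(out$removed, c(1L, 3L, 4L))   # single-state, single-state, all-missing
  expect_equal(ncol(out$matrix$states), 1)
  expect_equal(unname(out$matrix$states[, 1]), c(0L, 1L, NA, 0L))
})

test_that("the default zone scheme reproduces the published bins and tiles the circle", {
  sch <- zone_scheme()
  expect_equal(nrow(sch), 5)
  expect_equal(assign_zone(-80), 2L)   # eastern North America / Caribbean
  expect_equal(assign_zone(10), 3L)    # Europe and Africa
  expect_equal(assign_zone(170), 0L)   # Far East, west of the dateline
  expect_equal(assign_zone(-170), 0L)  # Far East, east of the dateline
  expect_equal(assign_zone(130), 0L)   # boundary belongs to its lower bound
  expect_equal(assign_zone(-160), 1L)
  expect_equal(assign_zone(180), 0L)
  expect_error(assign_zone(-180), "lon")
  # total and single-valued over the whole circle
  set.seed(2)
  lons <- c(stats::runif(2000, -179.999, 180), 180, -25, 60, -100, -160, 130)
  z <- assign_zone(lons)
  expect_true(all(z %in% 0:4))
  expect_equal(length(z), length(lons))
  # a scheme that does not tile the circle is rejected
  expect_error(zone_scheme(lon_min = c(0, 90), lon_max = c(90, 300),
                           codes = 0:1, names = c("a", "b")), "tile")
})

test_that("the zone character is appended ordered, with nulls for wide ranges", {
  m <- rand_char_matrix(4, 3, taxa = c("w", "x", "y", "z"))
  zc <- append_zone_character(m, c(w = 2L, x = 3L, y = NA, z = 2L))
  expect_equal(ncol(zc$states), 4)
  expect_true(zc$ordered[4])
  expect_equal(zc$partition[4], max(m$partition) + 1L)
  expect_equal(unname(zc$states[, 4]), c(2L, 3L, NA, 2L))
  expect_warning(append_zone_character(m, c(w = 2L, x = 2L, y = 2L, z = 2L)),
                 "invariant")
  expect_error(append_zone_character(m, c(w = 9L)), "outside")
})

test_that("multi-locality taxa split into OTUs with the oldest range keeping codes", {
  m <- char_matrix(rbind(Metaxytherium_floridanum = c(1L, 0L, 2L),
                         Pezosiren_portelli = c(0L, 1L, 0L),
                         Crenatosiren_olseni = c(1L, 1L, NA)))
  occ <- data.frame(
    taxon = c("Metaxytherium_floridanum", "Metaxytherium_floridanum",
              "Pezosiren_portelli",
              "Crenatosiren_olseni", "Crenatosiren_olseni", "Crenatosiren_olseni"),
    locality_id = c("Hillsborough", "Alachua", "only",
                    "L1", "L2", "L3"),
    lon = c(-82.3, -82.4, -77.8, -81, -80, -79),
    lat = c(27.9, 29.7, 18.1, 33, 32, 31),
    age_min = c(11.95, 9.3, 45, 28, 26, 24),
    age_max = c(14.6, 11.95, 46, 30, 28, 26),
    stringsAsFactors = FALSE)
  out <- split_multilocality_otus(m, occ)
  ex <- out$expansion
  # the published example: two OTUs, original coding on the 11.95-14.6 range
  mf <- ex[ex$taxon == "Metaxytherium_floridanum", ]
  expect_equal(nrow(mf), 2)
  expect_equal(mf$coding[mf$age_max == 14.6], "ORIGINAL")
  expect_equal(mf$coding[mf$age_max == 11.95], "ALL_MISSING")
  # a single-locality taxon: one OTU, untouched label, no constraint
  expect_true("Pezosiren_portelli" %in% rownames(out$matrix$states))
  expect_false("Pezosiren_portelli" %in% names(out$constraints))
  # three ranges: three OTUs, one constraint of size 3, two all-missing rows
  co <- ex[ex$taxon == "Crenatosiren_olseni", ]
  expect_equal(nrow(co), 3)
  expect_equal(sum(co$coding == "ALL_MISSING"), 2)
  expect_length(out$constraints[["Crenatosiren_olseni"]], 3)
  miss_rows <- co$otu[co$coding == "ALL_MISSING"]
  expect_true(all(is.na(out$matrix$states[miss_rows, ])))
  # row accounting: one row per distinct age range, one ORIGINAL per taxon
  expect_equal(nrow(out$matrix$states), 2 + 1 + 3)
  expect_equal(sum(ex$coding == "ORIGINAL"), 3)
  # uniform tip-age priors come straight from the ranges
  expect_equal(sort(unique(co$age_min)), c(24, 26, 28))
  # a taxon without occurrences is an error
  expect_error(split_multilocality_otus(m, occ[occ$taxon != "Pezosiren_portelli", ]),
               "without occurrences")
  # reference MrBayes block renders constraints and calibrations
  blk <- mrbayes_calibration_block(ex, out$constraints)
  expect_true(any(grepl("constraint", blk)))
  expect_true(any(grepl("uniform\\(11.95,14.6\\)", blk)))
})

test_that("geocentroids are spherical means, not naive longitude averages", {
  expect_equal(unname(geocentroid(rbind(c(13, -7)))), c(13, -7))
  expect_equal(unname(geocentroid(rbind(c(0, 0), c(10, 0)))), c(5, 0),
               tolerance = 1e-9)
  ctr <- geocentroid(rbind(c(179, 0), c(-179, 0)))
  expect_equal(unname(ctr[1]), 180)
  expect_equal(unname(ctr[2]), 0)
  expect_error(geocentroid(rbind(c(0, 0), c(180, 0))), "antipodal")
})

test_that("NEXUS matrices round trip through write and read", {
  set.seed(5)
  m <- rand_char_matrix(6, 12)
  m$states[2, 3] <- NA
  f <- tempfile(fileext = ".nex")
  write_nexus_matrix(m, f)
  back <- read_nexus_matrix(f)
  expect_equal(unname(back$states), unname(m$states))
  expect_equal(rownames(back$states), rownames(m$states))
})
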