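#' Discrete character matrices
#'
#' A `char_matrix` stores taxa-by-characters discrete states as an integer
#' matrix (`NA` = missing, written as `?`), with per-character metadata:
#' `ordered` flag, `partition` id, `source` matrix id, and `dup_of` (index of
#' the character a duplicated column repeats, `NA` for originals) so that
#' downstream statistics can deduplicate columns that exist only to balance
#' partition sizes.
#'
#' @param states integer matrix (taxa x characters) with `NA` for missing;
#'   rownames are taxon labels.
#' @param ordered logical vector per character (recycled).
#' @param partition integer partition id per character (recycled).
#' @param source character source-matrix id per character (recycled).
#' @param dup_of integer index of the duplicated original column or `NA`.
#' @return object of class `char_matrix`.
#' @export
char_matrix <- function(states, ordered = FALSE, partition = 1L,
                        source = "m1", dup_of = NA_integer_) {
  states <- as.matrix(states)
  if (is.null(rownames(states))) stop("states needs taxon rownames")
  if (anyDuplicated(rownames(states))) stop("duplicate taxon labels")
  storage.mode(states) <- "integer"
  if (any(states < 0 | states > 9, na.rm = TRUE))
    stop("states must be in 0..9 (or NA)")
  nc <- ncol(states)
  obj <- list(states = states,
              ordered = rep_len(as.logical(ordered), nc),
              partition = rep_len(as.integer(partition), nc),
              source = rep_len(as.character(source), nc),
              dup_of = rep_len(as.integer(dup_of), nc))
  class(obj) <- "char_matrix"
  obj
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Character matrix:", nrow(x$states), "taxa x", ncol(x$states),
      "characters;", length(unique(x$partition)), "partition(s);",
      sum(x$ordered), "ordered\n")
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$states)

#' Read a NEXUS DATA block as a char_matrix
#'
#' Parsing is delegated to [ape::read.nexus.data]; symbols outside `0..9`
#' are rejected and `?`/`-` become `NA`.
#'
#' @param file NEXUS file path.
#' @param ordered logical vector (or indices) of ordered characters.
#' @return a `char_matrix`.
#' @export
read_nexus_matrix <- function(file, ordered = FALSE) {
  raw <- ape::read.nexus.data(file)
  taxa <- gsub("[[:space:]]+", "_", names(raw))
  nch <- length(raw[[1]])
  m <- matrix(NA_integer_, length(raw), nch, dimnames = list(taxa, NULL))
  for (i in seq_along(raw)) {
    s <- raw[[i]]
    s[s %in% c("?", "-", "N", "n")] <- NA
    if (any(!is.na(s) & !grepl("^[0-9]$", s)))
      stop("non 0-9 symbol in matrix: ", file)
    m[i, ] <- as.integer(s)
  }
  if (is.logical(ordered)) ord <- rep_len(ordered, nch)
  else { ord <- rep(FALSE, nch); ord[ordered] <- TRUE }
  char_matrix(m, ordered = ord)
}

#' Write a char_matrix as a NEXUS DATA block
#'
#' Emits a SYMBOLS line, `MISSING=?`, and one `charset` comment per
#' partition.
#'
#' @param x a `char_matrix`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_nexus_matrix <- function(x, file) {
  m <- x$states
  sym <- sort(unique(as.vector(m[!is.na(m)])))
  rows <- apply(m, 1, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS", "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
    sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
            paste(sym, collapse = " ")),
    "  MATRIX"), con)
  writeLines(sprintf("    %s  %s", format(rownames(m)), rows), con)
  writeLines(c("  ;", "END;"), con)
  for (p in unique(x$partition)) {
    idx <- range(which(x$partition == p))
    writeLines(sprintf("[charset partition%d = %d-%d;]", p, idx[1], idx[2]), con)
  }
  invisible(file)
}

#' Concatenate character matrices with duplication balancing
#'
#' Each input matrix's character block is repeated `factors[i]` times so that
#' partition sizes become comparable (upweighting the likelihood signal of
#' small matrices in tree search). Taxon sets are unioned; cells of taxa
#' absent from a source matrix are missing. Duplicated columns carry
#' `dup_of` metadata pointing at the original column so ancestral-state
#' statistics can use each character once.
#'
#' @param matrices list of `char_matrix` objects.
#' @param factors positive integer duplication factor per matrix.
#' @return list with `matrix` (the concatenated `char_matrix`) and
#'   `partition_sizes` (characters per partition, one per source matrix).
#' @export
concat_with_duplication <- function(matrices, factors) {
  stopifnot(length(matrices) == length(factors), all(factors >= 1))
  taxa <- unique(unlist(lapply(matrices, function(m) rownames(m$states))))
  blocks <- list(); ords <- list(); parts <- list(); srcs <- list(); dups <- list()
  sizes <- integer(length(matrices))
  offset <- 0L
  for (i in seq_along(matrices)) {
    mi <- matrices[[i]]
    nc <- ncol(mi$states)
    full <- matrix(NA_integer_, length(taxa), nc,
                   dimnames = list(taxa, NULL))
    full[rownames(mi$states), ] <- mi$states
    f <- as.integer(factors[i])
    rep_cols <- rep(seq_len(nc), f)
    blocks[[i]] <- full[, rep_cols, drop = FALSE]
    ords[[i]] <- rep(mi$ordered, f)
    parts[[i]] <- rep(i, nc * f)
    srcs[[i]] <- rep(if (length(unique(mi$source)) == 1) mi$source[1]
                     else paste0("m", i), nc * f)
    d <- rep(NA_integer_, nc * f)
    if (f > 1) d[-seq_len(nc)] <- offset + rep_cols[-seq_len(nc)]
    dups[[i]] <- d
    sizes[i] <- nc * f
    offset <- offset + nc * f
  }
  out <- char_matrix(do.call(cbind, blocks), ordered = unlist(ords),
                     partition = unlist(parts), source = unlist(srcs),
                     dup_of = unlist(dups))
  list(matrix = out, partition_sizes = sizes)
}

#' Remove invariant character columns
#'
#' A column is removed iff the set of observed (non-missing) states has size
#' <= 1 (this includes all-missing columns). Variable coding for
#' ascertainment bias presupposes variability in every column.
#'
#' @param x a `char_matrix`.
#' @return list with `matrix` (filtered `char_matrix`) and `removed`
#'   (indices of dropped columns).
#' @export
remove_invariant_columns <- function(x) {
  keep <- apply(x$states, 2, function(col) length(unique(col[!is.na(col)])) > 1)
  out <- x
  out$states <- x$states[, keep, drop = FALSE]
  out$ordered <- x$ordered[keep]
  out$partition <- x$partition[keep]
  out$source <- x$source[keep]
  out$dup_of <- x$dup_of[keep]
  list(matrix = out, removed = which(!keep))
}

#' Longitudinal zone scheme
#'
#' Ordered, contiguous longitudinal zones tiling the circle. The default is
#' the five-zone scheme used for coding fossil sea-cow localities:
#' (0) 130 to -160 (Far East Asia and Beringia, crossing the dateline),
#' (1) -160 to -100 (western North America), (2) -100 to -25 (eastern North
#' America, South America, Caribbean), (3) -25 to 60 (Europe and Africa),
#' (4) 60 to 130 (Pan Asia excluding the Far East). Intervals are half-open
#' `[lon_min, lon_max)`: a boundary longitude belongs to the zone whose
#' lower bound it equals.
#'
#' @param lon_min,lon_max numeric vectors of zone bounds (degrees); exactly
#'   one zone may cross the dateline (`lon_min > lon_max`).
#' @param codes integer zone codes forming the ordered transformation series.
#' @param names zone names.
#' @return data.frame of class `zone_scheme`.
#' @export
zone_scheme <- function(lon_min = c(130, -160, -100, -25, 60),
                        lon_max = c(-160, -100, -25, 60, 130),
                        codes = 0:4,
                        names = c("Far East Asia & Beringia",
                                  "western North America",
                                  "eastern NA, South America & Caribbean",
                                  "Europe & Africa",
                                  "Pan Asia")) {
  width <- ifelse(lon_max >= lon_min, lon_max - lon_min,
                  360 - lon_min + lon_max)
  if (abs(sum(width) - 360) > 1e-9)
    stop("zones do not tile the circle (widths sum to ", sum(width), ")")
  if (sum(lon_min > lon_max) > 1)
    stop("more than one dateline-crossing zone")
  z <- data.frame(code = as.integer(codes), lon_min = lon_min,
                  lon_max = lon_max, name = names,
                  stringsAsFactors = FALSE)
  class(z) <- c("zone_scheme", "data.frame")
  z
}

#' Bin a longitude into its zone
#'
#' Total and single-valued on `(-180, 180]`; the dateline-crossing zone is
#' the union `[lon_min, 180] U (-180, lon_max)`.
#'
#' @param lon longitude(s) in `(-180, 180]` degrees.
#' @param scheme a [zone_scheme].
#' @return integer zone code(s).
#' @export
assign_zone <- function(lon, scheme = zone_scheme()) {
  if (any(lon <= -180 | lon > 180)) stop("lon must lie in (-180, 180]")
  vapply(lon, function(x) {
    hit <- with(scheme, ifelse(lon_min <= lon_max,
                               x >= lon_min & x < lon_max,
                               x >= lon_min | x < lon_max))
    if (sum(hit) != 1L) stop("zone scheme is not a partition at lon ", x)
    scheme$code[hit]
  }, integer(1))
}

#' Append the biogeographic zone character
#'
#' Adds one ordered character column (its own partition) coding each taxon's
#' longitudinal zone; taxa with unknown or straddling ranges get `?` (e.g. a
#' wide-ranging extant taxon coded with a null datum to avoid confounding the
#' contiguity of the ordered series). A warning is emitted when the new
#' column is invariant (it would be dropped by variable coding).
#'
#' @param x a `char_matrix`.
#' @param zones named integer vector taxon -> zone code, `NA` for null.
#'   Taxa absent from `zones` get `?`.
#' @param scheme the [zone_scheme] the codes come from.
#' @return a `char_matrix` with one extra column.
#' @export
append_zone_character <- function(x, zones, scheme = zone_scheme()) {
  taxa <- rownames(x$states)
  col <- rep(NA_integer_, length(taxa))
  if (length(zones)) {
    known <- intersect(names(zones), taxa)
    bad <- setdiff(zones[known][!is.na(zones[known])], scheme$code)
    if (length(bad)) stop("zone codes outside scheme: ",
                          paste(bad, collapse = ", "))
    col[match(known, taxa)] <- zones[known]
  }
  if (length(unique(col[!is.na(col)])) <= 1)
    warning("zone character is invariant; variable coding would drop it")
  out <- x
  out$states <- cbind(x$states, zone = col)
  out$ordered <- c(x$ordered, TRUE)
  out$partition <- c(x$partition, max(x$partition) + 1L)
  out$source <- c(x$source, "zone")
  out$dup_of <- c(x$dup_of, NA_integer_)
  out
}

#' Read / write occurrence tables
#'
#' Occurrence CSVs have columns `taxon`, `locality_id`, `lon`, `lat`,
#' `age_min`, `age_max` (and optionally `map_id`). Longitudes must lie in
#' `(-180, 180]`, latitudes in `[-90, 90]`, and `age_min <= age_max`.
#'
#' @param file CSV path.
#' @return validated data.frame of occurrences.
#' @export
read_occurrences <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_occurrences(d)
}

#' @rdname read_occurrences
#' @param occ occurrence data.frame.
#' @export
validate_occurrences <- function(occ) {
  need <- c("taxon", "locality_id", "lon", "lat", "age_min", "age_max")
  miss <- setdiff(need, names(occ))
  if (length(miss)) stop("occurrences missing columns: ",
                         paste(miss, collapse = ", "))
  occ$taxon <- gsub("[[:space:]]+", "_", occ$taxon)
  if (any(occ$lon <= -180 | occ$lon > 180)) stop("lon outside (-180, 180]")
  if (any(abs(occ$lat) > 90)) stop("lat outside [-90, 90]")
  if (any(occ$age_min > occ$age_max)) stop("age_min > age_max")
  if (anyDuplicated(occ[c("taxon", "locality_id")]))
    stop("duplicate (taxon, locality_id)")
  occ
}

#' Split multi-locality taxa into dated OTUs
#'
#' Localities of each taxon are grouped by identical `(age_min, age_max)`
#' range; a taxon with `n` distinct ranges becomes `n` OTUs. The OTU with the
#' oldest range (ranked by `age_max` descending, then `age_min` descending,
#' then first locality id) keeps the original character coding; all others
#' are recoded all-missing, so morphological distances are forced to be
#' calculated between earliest occurrences. Each split taxon contributes one
#' clade constraint over its OTUs, and every OTU carries a uniform tip-age
#' prior from its range.
#'
#' @param x a `char_matrix` whose taxa all appear in `occurrences`.
#' @param occurrences occurrence data.frame (see [read_occurrences]).
#' @return list with `matrix` (expanded `char_matrix`), `expansion`
#'   (data.frame: `taxon`, `otu`, `age_min`, `age_max`, `coding`,
#'   `locality_ids`), and `constraints` (list of OTU-label sets, one per
#'   split taxon).
#' @export
split_multilocality_otus <- function(x, occurrences) {
  occ <- validate_occurrences(occurrences)
  taxa <- rownames(x$states)
  missing <- setdiff(taxa, occ$taxon)
  if (length(missing)) stop("taxa without occurrences: ",
                            paste(missing, collapse = ", "))
  rows <- list(); exp_rows <- list(); constraints <- list()
  for (tx in taxa) {
    o <- occ[occ$taxon == tx, , drop = FALSE]
    key <- paste(o$age_min, o$age_max)
    grp <- split(o, factor(key, levels = unique(key)))
    # oldest first: age_max desc, then age_min desc, then locality id
    ord <- order(-vapply(grp, function(g) g$age_max[1], 0),
                 -vapply(grp, function(g) g$age_min[1], 0),
                 vapply(grp, function(g) as.character(min(g$locality_id)), ""))
    grp <- grp[ord]
    n <- length(grp)
    labels <- if (n == 1) tx else paste0(tx, "_OTU", seq_len(n))
    for (j in seq_len(n)) {
      g <- grp[[j]]
      coding <- if (j == 1) "ORIGINAL" else "ALL_MISSING"
      cells <- if (j == 1) x$states[tx, ] else rep(NA_integer_, ncol(x$states))
      rows[[labels[j]]] <- cells
      exp_rows[[length(exp_rows) + 1L]] <- data.frame(
        taxon = tx, otu = labels[j],
        age_min = g$age_min[1], age_max = g$age_max[1], coding = coding,
        locality_ids = paste(g$locality_id, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    if (n > 1) constraints[[tx]] <- labels
  }
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  out <- char_matrix(m, ordered = x$ordered, partition = x$partition,
                     source = x$source, dup_of = x$dup_of)
  list(matrix = out,
       expansion = do.call(rbind, exp_rows),
       constraints = constraints)
}

#' MrBayes-style constraint and calibration block (reference output)
#'
#' Renders the OTU clade constraints and uniform tip-age calibrations as a
#' MrBayes command block. Emitted for reference only; never executed here.
#'
#' @param expansion,constraints output of [split_multilocality_otus].
#' @param file optional output path.
#' @return character vector of command lines.
#' @export
mrbayes_calibration_block <- function(expansion, constraints, file = NULL) {
  lines <- c("begin mrbayes;")
  i <- 0L
  for (tx in names(constraints)) {
    i <- i + 1L
    lines <- c(lines, sprintf("  constraint split%d = %s;", i,
                              paste(constraints[[tx]], collapse = " ")))
  }
  if (i > 0)
    lines <- c(lines, sprintf("  prset topologypr = constraints(%s);",
                              paste0("split", seq_len(i), collapse = ",")))
  for (r in seq_len(nrow(expansion))) {
    e <- expansion[r, ]
    cal <- if (e$age_min == e$age_max) sprintf("fixed(%g)", e$age_min)
           else sprintf("uniform(%g,%g)", e$age_min, e$age_max)
    lines <- c(lines, sprintf("  calibrate %s = %s;", e$otu, cal))
  }
  lines <- c(lines, "end;")
  if (!is.null(file)) writeLines(lines, file)
  lines
}

#' Spherical centroid of localities
#'
#' Mean of the unit vectors on the sphere, re-normalised and converted back
#' to lon/lat (the arithmetic mean of longitudes fails across the dateline).
#'
#' @param lonlat 2-column matrix (lon, lat) in degrees, one row per locality.
#' @return numeric `c(lon, lat)`, lon in `(-180, 180]`.
#' @export
geocentroid <- function(lonlat) {
  lonlat <- matrix(as.numeric(lonlat), ncol = 2)
  if (nrow(lonlat) == 0) stop("no localities")
  rad <- pi / 180
  lam <- lonlat[, 1] * rad; phi <- lonlat[, 2] * rad
  v <- c(mean(cos(phi) * cos(lam)), mean(cos(phi) * sin(lam)), mean(sin(phi)))
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("degenerate (antipodal) locality set: zero-norm mean")
  v <- v / nv
  lon <- atan2(v[2], v[1]) / rad
  lat <- asin(max(-1, min(1, v[3]))) / rad
  if (lon <= -180) lon <- lon + 360
  c(lon = lon, lat = lat)
}
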