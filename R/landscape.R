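#' Land-cover raster container
#'
#' A categorical grid of integer class codes on a metric grid. Values are
#' stored as a matrix whose first row is the top of the map; `xll`/`yll`
#' locate the lower-left corner of the grid in the raster's (metric)
#' coordinate system.
#'
#' @param values integer matrix of class codes (`NA` allowed internally for
#'   nodata).
#' @param cell_size_m cell edge length in meters (> 0).
#' @param xll,yll lower-left corner coordinates (meters).
#' @param nodata integer code treated as nodata on file I/O.
#' @return object of class `land_raster`.
#' @export
land_raster <- function(values, cell_size_m, xll = 0, yll = 0, nodata = -9999L) {
  stopifnot(is.matrix(values), cell_size_m > 0)
  values[values == nodata] <- NA
  structure(list(values = values, n_rows = nrow(values), n_cols = ncol(values),
                 cell_size_m = cell_size_m, xll = xll, yll = yll,
                 nodata = nodata),
            class = "land_raster")
}

#' Read / write ESRI ASCII grid (.asc)
#'
#' @param path file path.
#' @return `read_asc`: a `land_raster`; `write_asc`: `path` invisibly.
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(vals))) {
    stop("malformed .asc header in ", path)
  }
  body <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(body, nrow = vals[["nrows"]], ncol = vals[["ncols"]],
              byrow = TRUE)
  land_raster(m, vals[["cellsize"]], vals[["xllcorner"]],
              vals[["yllcorner"]], as.integer(vals[["nodata_value"]]))
}

#' @rdname read_asc
#' @param raster a `land_raster` (or `resistance_surface`).
#' @export
write_asc <- function(raster, path) {
  v <- raster$values
  v[is.na(v)] <- raster$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", raster$n_cols),
               paste("nrows", raster$n_rows),
               paste("xllcorner", raster$xll),
               paste("yllcorner", raster$yll),
               paste("cellsize", raster$cell_size_m),
               paste("NODATA_value", raster$nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default NLCD class-to-group mapping
#'
#' Groups the 30-m NLCD integer codes into the five cover groups used by
#' the resistance hypotheses: developed (21-24), cultivated (81, 82),
#' forest/shrub (41-43, 52), grassland (71), and other (open water, barren,
#' wetlands: 11, 31, 90, 95).
#'
#' @return named character vector: code -> group.
#' @export
default_class_groups <- function() {
  c(`21` = "developed", `22` = "developed", `23` = "developed",
    `24` = "developed",
    `81` = "cultivated", `82` = "cultivated",
    `41` = "forest_shrub", `42` = "forest_shrub", `43` = "forest_shrub",
    `52` = "forest_shrub",
    `71` = "grassland",
    `11` = "other", `31` = "other", `90` = "other", `95` = "other")
}

COVER_GROUPS <- c("developed", "cultivated", "forest_shrub", "grassland",
                  "other")

#' A named resistance hypothesis
#'
#' Assigns `low_value` to the listed land-cover groups and `high_value` to
#' every other group (including "other"); used by [reclassify()].
#'
#' @param name hypothesis label.
#' @param low_groups character subset of
#'   `c("developed","cultivated","forest_shrub","grassland","other")`.
#' @param low_value,high_value resistance values in (0, 1\], `low < high`.
#' @return object of class `resistance_hypothesis`.
#' @export
resistance_hypothesis <- function(name, low_groups, low_value = 0.1,
                                  high_value = 0.9) {
  stopifnot(low_value > 0, high_value <= 1, low_value < high_value,
            all(low_groups %in% COVER_GROUPS))
  structure(list(name = name, low_groups = low_groups,
                 low_value = low_value, high_value = high_value),
            class = "resistance_hypothesis")
}

#' The five landscape permeability hypotheses
#'
#' A: semi-natural cover (grassland + forest/shrub) permeable, human-altered
#' cover resistant. B: woody-substrate cover (developed + cultivated +
#' forest/shrub) permeable, open grassland resistant. Set C: each of
#' developed, cultivated, forest/shrub permeable alone.
#'
#' @param low_value,high_value resistance values assigned to the permeable
#'   and resistant groups.
#' @return named list of five `resistance_hypothesis` objects.
#' @export
hypothesis_set <- function(low_value = 0.1, high_value = 0.9) {
  list(
    A = resistance_hypothesis("A", c("grassland", "forest_shrub"),
                              low_value, high_value),
    B = resistance_hypothesis("B", c("developed", "cultivated", "forest_shrub"),
                              low_value, high_value),
    C_developed = resistance_hypothesis("C_developed", "developed",
                                        low_value, high_value),
    C_cultivated = resistance_hypothesis("C_cultivated", "cultivated",
                                         low_value, high_value),
    C_forest = resistance_hypothesis("C_forest", "forest_shrub",
                                     low_value, high_value)
  )
}

#' Reclassify a land-cover raster into a resistance surface
#'
#' Cells whose cover group is in the hypothesis's `low_groups` get
#' `low_value`; all other cells -- including the "other" group and nodata
#' cells -- get `high_value` (nodata is treated as high resistance rather
#' than a barrier, so data gaps never disconnect the landscape graph).
#'
#' @param raster a `land_raster`.
#' @param class_groups named map code -> group (see
#'   [default_class_groups()]); every non-nodata code must be mapped.
#' @param hyp a `resistance_hypothesis`.
#' @return object of class `resistance_surface` (grid of values in (0,1\]
#'   plus provenance).
#' @export
reclassify <- function(raster, class_groups, hyp) {
  codes <- unique(raster$values[!is.na(raster$values)])
  unmapped <- setdiff(as.character(codes), names(class_groups))
  if (length(unmapped)) {
    stop("unmapped land-cover codes: ", paste(unmapped, collapse = ", "))
  }
  grp <- matrix(class_groups[as.character(raster$values)],
                raster$n_rows, raster$n_cols)
  v <- matrix(hyp$high_value, raster$n_rows, raster$n_cols)
  v[!is.na(grp) & grp %in% hyp$low_groups] <- hyp$low_value
  structure(list(values = v, n_rows = raster$n_rows, n_cols = raster$n_cols,
                 cell_size_m = raster$cell_size_m, xll = raster$xll,
                 yll = raster$yll, nodata = raster$nodata,
                 provenance = list(hypothesis = hyp$name,
                                   low = hyp$low_value, high = hyp$high_value,
                                   aggregation = 1L)),
            class = c("resistance_surface", "land_raster"))
}

#' Aggregate a resistance surface to coarser cells by block means
#'
#' Replaces non-overlapping `factor x factor` blocks by their mean
#' (excluding any NA cells; an all-NA block falls back to the surface's
#' high value). The grid is anchored at the top-left corner; edge blocks
#' may be partial. At the default NLCD resolution (30 m), `factor = 7`
#' yields 210 m cells.
#'
#' @param surface a `resistance_surface`.
#' @param factor integer aggregation factor >= 1.
#' @return aggregated `resistance_surface`.
#' @export
aggregate_mean <- function(surface, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor > surface$n_rows || factor > surface$n_cols) {
    stop("aggregation factor larger than the grid")
  }
  if (factor == 1) return(surface)
  v <- surface$values
  rg <- (seq_len(nrow(v)) - 1) %/% factor
  cg <- (seq_len(ncol(v)) - 1) %/% factor
  vz <- v; vz[is.na(v)] <- 0
  sums <- t(rowsum(t(rowsum(vz, rg)), cg))
  cnts <- t(rowsum(t(rowsum((!is.na(v)) * 1, rg)), cg))
  out <- ifelse(cnts > 0, sums / cnts, surface$provenance$high)
  new_cell <- surface$cell_size_m * factor
  # top-left anchored: recompute yll from the (unchanged) top edge
  top <- surface$yll + surface$n_rows * surface$cell_size_m
  prov <- surface$provenance
  prov$aggregation <- prov$aggregation * factor
  structure(list(values = out, n_rows = nrow(out), n_cols = ncol(out),
                 cell_size_m = new_cell, xll = surface$xll,
                 yll = top - nrow(out) * new_cell, nodata = surface$nodata,
                 provenance = prov),
            class = c("resistance_surface", "land_raster"))
}

#' Build the hypothesis x resistance-value surface suite
#'
#' Five hypotheses crossed with four (low, high) value pairs
#' `(0.1,0.9), (0.1,0.5), (0.3,0.9), (0.3,0.5)` give 20 surfaces, each
#' aggregated by `aggregate_factor`; together with the two
#' isolation-by-distance models these form a 22-model suite.
#'
#' @param raster a `land_raster`.
#' @param class_groups code -> group map.
#' @param value_pairs list of `c(low, high)` pairs.
#' @param aggregate_factor block-mean aggregation factor (default 7).
#' @return named list of 20 `resistance_surface` objects; names encode the
#'   provenance, e.g. `"B_0.1_0.9"`.
#' @export
build_surface_suite <- function(raster, class_groups = default_class_groups(),
                                value_pairs = list(c(0.1, 0.9), c(0.1, 0.5),
                                                   c(0.3, 0.9), c(0.3, 0.5)),
                                aggregate_factor = 7) {
  out <- list()
  for (hyp_name in names(hypothesis_set())) {
    for (vp in value_pairs) {
      hyp <- hypothesis_set(vp[1], vp[2])[[hyp_name]]
      s <- reclassify(raster, class_groups, hyp)
      s <- aggregate_mean(s, aggregate_factor)
      out[[paste(hyp_name, vp[1], vp[2], sep = "_")]] <- s
    }
  }
  out
}

#' Great-circle distance matrix between sites
#'
#' Haversine distances on a sphere of radius 6371.0088 km.
#'
#' @param sites data frame with columns `site_id`, `longitude`, `latitude`
#'   (decimal degrees, WGS84).
#' @return a `dist_matrix` in kilometers.
#' @export
great_circle_matrix <- function(sites) {
  validate_sites(sites)
  s <- nrow(sites)
  coords <- cbind(sites$longitude, sites$latitude)
  m <- matrix(0, s, s)
  if (s > 1) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    d <- geosphere::distHaversine(coords[idx[, 1], , drop = FALSE],
                                  coords[idx[, 2], , drop = FALSE],
                                  r = 6371008.8) / 1000
    m[idx] <- d
    m[idx[, c(2, 1), drop = FALSE]] <- d
  }
  dist_matrix(m, sites$site_id, "km")
}

## ---- effective (circuit-theory) resistance -------------------------------

# graph Laplacian from an undirected edge list with conductances
laplacian_from_edges <- function(i, j, w, n) {
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(W)) - W
}

# effective resistance between the listed nodes of a Laplacian:
# R_ij = (e_i - e_j)' L^+ (e_i - e_j), via one linear solve per node
# against a grounded reference node
resistance_from_laplacian <- function(L, nodes) {
  n <- nrow(L)
  un <- unique(nodes)
  g <- un[length(un)]
  keep <- setdiff(seq_len(n), g)
  red <- match(seq_len(n), keep)              # full -> reduced index
  Lr <- L[keep, keep, drop = FALSE]
  others <- setdiff(un, g)
  # V[, k]: node potentials when 1 A is injected at `others[k]`, ground g
  V <- matrix(0, n, length(un), dimnames = list(NULL, as.character(un)))
  if (length(others)) {
    rhs <- matrix(0, length(keep), length(others))
    rhs[cbind(red[others], seq_along(others))] <- 1
    sol <- tryCatch(
      as.matrix(Matrix::solve(Lr, rhs)),
      error = function(e) stop("effective resistance solve failed ",
                               "(disconnected graph?): ", conditionMessage(e)))
    V[keep, as.character(others)] <- sol
  }
  m <- length(nodes)
  R <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a == b || nodes[a] == nodes[b]) next
    ca <- as.character(nodes[a]); cb <- as.character(nodes[b])
    R[a, b] <- V[nodes[a], ca] + V[nodes[b], cb] -
      V[nodes[a], cb] - V[nodes[b], ca]
  }
  (R + t(R)) / 2
}

#' Effective resistance between nodes of an arbitrary conductance network
#'
#' Small utility around the Laplacian solve used by
#' [resistance_distance()]; handy for checking circuit laws on hand-built
#' graphs.
#'
#' @param edges data frame with columns `i`, `j` (1-based node indices) and
#'   `conductance`.
#' @param n_nodes number of nodes.
#' @param nodes nodes between which resistances are wanted.
#' @return symmetric matrix of effective resistances.
#' @export
effective_resistance <- function(edges, n_nodes, nodes = seq_len(n_nodes)) {
  L <- laplacian_from_edges(edges$i, edges$j, edges$conductance, n_nodes)
  resistance_from_laplacian(L, nodes)
}

# map metric x/y points to cell (node) indices; boundary ties go to the
# lower-index cell
point_to_node <- function(surface, x, y) {
  u <- (x - surface$xll) / surface$cell_size_m
  v <- (y - surface$yll) / surface$cell_size_m
  col <- pmax(1, pmin(surface$n_cols, ceiling(u)))
  row_from_bottom <- pmax(1, pmin(surface$n_rows, ceiling(v)))
  if (any(u < 0 | u > surface$n_cols | v < 0 | v > surface$n_rows)) {
    stop("point outside raster extent")
  }
  row <- surface$n_rows - row_from_bottom + 1
  (row - 1) * surface$n_cols + col
}

# 8-neighbor edge list of a grid of conductances (1/resistance); edge
# conductance = mean of the two cell conductances / center distance in
# cell units (1 rook, sqrt(2) diagonal). `mean_of` = "conductance" (default)
# or "resistance" for the sensitivity alternative.
grid_edges <- function(values, mean_of = c("conductance", "resistance")) {
  mean_of <- match.arg(mean_of)
  nr <- nrow(values); nc <- ncol(values)
  cond <- 1 / values
  id <- function(r, c) (r - 1) * nc + c
  pair_w <- function(c1, c2) {
    if (mean_of == "conductance") (c1 + c2) / 2 else 1 / ((1 / c1 + 1 / c2) / 2)
  }
  es <- list(); k <- 0
  add <- function(r1, c1, r2, c2, dist) {
    a <- id(r1, c1); b <- id(r2, c2)
    w <- pair_w(cond[cbind(r1, c1)], cond[cbind(r2, c2)]) / dist
    k <<- k + 1
    es[[k]] <<- data.frame(i = a, j = b, conductance = w)
  }
  rows <- seq_len(nr); cols <- seq_len(nc)
  # horizontal
  if (nc > 1) {
    rc <- expand.grid(r = rows, c = cols[-nc])
    add(rc$r, rc$c, rc$r, rc$c + 1, 1)
  }
  if (nr > 1) {
    rc <- expand.grid(r = rows[-nr], c = cols)
    add(rc$r, rc$c, rc$r + 1, rc$c, 1)
  }
  if (nr > 1 && nc > 1) {
    rc <- expand.grid(r = rows[-nr], c = cols[-nc])
    add(rc$r, rc$c, rc$r + 1, rc$c + 1, sqrt(2))
    rc <- expand.grid(r = rows[-nr], c = cols[-1])
    add(rc$r, rc$c, rc$r + 1, rc$c - 1, sqrt(2))
  }
  do.call(rbind, es)
}

#' Circuit-theory resistance distances between sampling points
#'
#' The surface is viewed as an electrical network: nodes are cells, edges
#' join 8-neighbors, and each edge's conductance is the mean of the two
#' cell conductances (conductance = 1/resistance) divided by the
#' center-to-center distance in cell units (1 for rook moves, sqrt(2) for
#' diagonals). The distance between two points is the effective resistance
#' between the cells containing them, computed from the graph Laplacian.
#' Points snap to the center of their containing cell.
#'
#' @param surface a `resistance_surface`.
#' @param points data frame with columns `site_id`, `x`, `y` (meters, in
#'   the raster's coordinate system).
#' @param mean_of edge-weight convention: mean of `"conductance"` (default)
#'   or of `"resistance"`.
#' @return a `dist_matrix` (units `"resistance"`).
#' @export
resistance_distance <- function(surface, points,
                                mean_of = c("conductance", "resistance")) {
  stopifnot(all(c("site_id", "x", "y") %in% names(points)))
  nodes <- point_to_node(surface, points$x, points$y)
  edges <- grid_edges(surface$values, match.arg(mean_of))
  L <- laplacian_from_edges(edges$i, edges$j, edges$conductance,
                            surface$n_rows * surface$n_cols)
  R <- resistance_from_laplacian(L, nodes)
  dist_matrix(R, points$site_id, "resistance")
}
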