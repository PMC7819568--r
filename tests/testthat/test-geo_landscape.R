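test_that("great-circle closed forms on the reference sphere", {
  s <- data.frame(site_id = c("o", "e1", "np"),
                  longitude = c(0, 1, 0), latitude = c(0, 0, 90))
  m <- great_circle_matrix(s)
  expect_equal(unname(m["o", "o"]), 0)
  expect_equal(unname(m["o", "e1"]), 2 * pi * 6371.0088 / 360,
               tolerance = 1e-6)
  expect_equal(unname(m["o", "np"]), pi * 6371.0088 / 2, tolerance = 1e-6)
  bad <- data.frame(site_id = "x", longitude = 190, latitude = 0)
  expect_error(great_circle_matrix(bad), "out of range")
})

test_that("ESRI ASCII grid round-trips", {
  r <- land_raster(matrix(c(21L, 71L, 41L, 81L, -9999L, 11L), 2, 3),
                   cell_size_m = 30, xll = 100, yll = 200)
  p <- withr::local_tempfile(fileext = ".asc")
  write_asc(r, p)
  back <- read_asc(p)
  expect_true(all(back$values == r$values, na.rm = TRUE))
  expect_identical(is.na(back$values), is.na(r$values))
  expect_equal(back$cell_size_m, 30)
  expect_equal(back$xll, 100)
  expect_equal(back$yll, 200)
})

test_that("reclassification implements the five cover hypotheses", {
  # one cell per NLCD group: developed, cultivated, forest, grassland, other
  r <- land_raster(matrix(c(22L, 81L, 41L, 71L, 11L), 1, 5),
                   cell_size_m = 30)
  groups <- default_class_groups()
  hs <- hypothesis_set(0.1, 0.9)
  val <- function(h) as.vector(reclassify(r, groups, h)$values)
  # A: grassland and forest low
  expect_equal(val(hs$A), c(0.9, 0.9, 0.1, 0.1, 0.9))
  # B: developed, cultivated, forest low
  expect_equal(val(hs$B), c(0.1, 0.1, 0.1, 0.9, 0.9))
  # Set C singles
  expect_equal(val(hs$C_developed), c(0.1, 0.9, 0.9, 0.9, 0.9))
  expect_equal(val(hs$C_cultivated), c(0.9, 0.1, 0.9, 0.9, 0.9))
  expect_equal(val(hs$C_forest), c(0.9, 0.9, 0.1, 0.9, 0.9))

  r2 <- land_raster(matrix(c(22L, 999L), 1, 2), cell_size_m = 30)
  expect_error(reclassify(r2, groups, hs$A), "unmapped.*999")
  # nodata cells become high resistance, never barriers
  r3 <- land_raster(matrix(c(22L, -9999L), 1, 2), cell_size_m = 30)
  expect_equal(as.vector(reclassify(r3, groups, hs$B)$values), c(0.1, 0.9))
})

test_that("block-mean aggregation averages values and updates geometry", {
  r <- land_raster(matrix(71L, 14, 14), cell_size_m = 30)
  s <- reclassify(r, default_class_groups(), hypothesis_set()$A)
  expect_true(all(s$values == 0.1))
  agg <- aggregate_mean(s, 7)
  expect_equal(dim(agg$values), c(2, 2))
  expect_true(all(agg$values == 0.1))
  expect_equal(agg$cell_size_m, 210)

  s2 <- s
  s2$values <- matrix(rep(c(0.1, 0.9), each = 1), 14, 14)
  s2$values[] <- 0.9
  s2$values[1:7, 1:7] <- 0.1
  agg2 <- aggregate_mean(s2, 7)
  expect_equal(agg2$values[1, 1], 0.1)
  expect_equal(agg2$values[2, 2], 0.9)

  # 2x2 block mean of {0.1, 0.1, 0.9, 0.9} is 0.5
  s3 <- s
  s3$values <- matrix(c(0.1, 0.9, 0.1, 0.9), 2, 2)
  s3$n_rows <- 2; s3$n_cols <- 2
  agg3 <- aggregate_mean(s3, 2)
  expect_equal(agg3$values[1, 1], 0.5)
  expect_error(aggregate_mean(s3, 5), "larger than the grid")
})

test_that("effective resistance obeys circuit laws", {
  # single edge: R = 1/c
  e1 <- data.frame(i = 1, j = 2, conductance = 4)
  expect_equal(effective_resistance(e1, 2)[1, 2], 0.25, tolerance = 1e-12)
  # series: 3-node path of unit conductances, end to end
  path <- data.frame(i = c(1, 2), j = c(2, 3), conductance = 1)
  expect_equal(effective_resistance(path, 3)[1, 3], 2, tolerance = 1e-12)
  # series-parallel: unit triangle
  tri <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3), conductance = 1)
  R <- effective_resistance(tri, 3)
  expect_equal(R[1, 2], 2 / 3, tolerance = 1e-12)
  expect_equal(R[1, 3], 2 / 3, tolerance = 1e-12)
})

test_that("effective resistance matches the dense-Laplacian oracle and is a metric", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    # random connected graph: spanning path plus extra edges
    edges <- data.frame(i = 1:(n - 1), j = 2:n,
                        conductance = runif(n - 1, 0.2, 2))
    extra <- t(combn(n, 2))
    keep <- sample(nrow(extra), 2)
    edges <- rbind(edges, data.frame(i = extra[keep, 1],
                                     j = extra[keep, 2],
                                     conductance = runif(2, 0.2, 2)))
    R <- effective_resistance(edges, n)
    O <- oracle_effective_resistance(edges, n)
    expect_lt(max(abs(R - O)), 1e-10)
    # metric axioms
    expect_true(all(R >= -1e-12))
    expect_equal(R, t(R), tolerance = 1e-12)
    for (a in 1:n) for (b in 1:n) for (cc in 1:n) {
      expect_lte(R[a, b], R[a, cc] + R[cc, b] + 1e-10)
    }
  }
})

test_that("grid resistance grows with separation on a uniform surface", {
  r <- land_raster(matrix(71L, 50, 50), cell_size_m = 100)
  s <- reclassify(r, default_class_groups(), hypothesis_set()$B)
  pts <- data.frame(site_id = c("a", "b", "c", "d"),
                    x = c(550, 1550, 2550, 4050), y = rep(2550, 4))
  R <- resistance_distance(s, pts)
  expect_lt(R["a", "b"], R["a", "c"])
  expect_lt(R["a", "c"], R["a", "d"])
})

test_that("lowering a cell's resistance never increases any distance", {
  r <- land_raster(matrix(71L, 8, 8), cell_size_m = 100)
  s <- reclassify(r, default_class_groups(), hypothesis_set()$B)
  pts <- data.frame(site_id = c("a", "b"), x = c(150, 650), y = c(450, 450))
  R0 <- resistance_distance(s, pts)["a", "b"]
  s$values[4, 4] <- 0.05
  R1 <- resistance_distance(s, pts)["a", "b"]
  expect_lte(R1, R0 + 1e-12)
})

test_that("points outside the extent are rejected", {
  r <- land_raster(matrix(71L, 4, 4), cell_size_m = 100)
  s <- reclassify(r, default_class_groups(), hypothesis_set()$B)
  expect_error(resistance_distance(
    s, data.frame(site_id = "x", x = 1000, y = 100)), "outside")
})

test_that("the surface suite has 20 uniquely-labelled two-level surfaces", {
  r <- land_raster(matrix(sample(c(22L, 81L, 41L, 71L, 11L), 196, TRUE),
                          14, 14), cell_size_m = 30)
  suite <- build_surface_suite(r, aggregate_factor = 7)
  expect_length(suite, 20)
  expect_false(anyDuplicated(names(suite)) > 0)
  for (s in suite) {
    lohi <- c(s$provenance$low, s$provenance$high)
    # aggregated values are means of low/high cells
    expect_true(all(s$values >= lohi[1] - 1e-12 &
                      s$values <= lohi[2] + 1e-12))
  }
  hyps <- unique(vapply(suite, function(s) s$provenance$hypothesis, ""))
  expect_setequal(hyps, c("A", "B", "C_developed", "C_cultivated",
                          "C_forest"))
})
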