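test_that("overlap maps and percentages follow the cellwise-product definition", {
  spec <- tiny_spec()
  a <- manual_binary(spec, c(1, 2, 3, 4))
  b <- manual_binary(spec, c(2, 3, 4, 9))
  expect_equal(unclass(overlap_map(a, a)), unclass(a), ignore_attr = TRUE)
  expect_equal(presence_cells_of(overlap_map(a, b)), c(2, 3, 4))
  expect_equal(overlap_percent(a, a), 100)
  expect_equal(overlap_percent(a, manual_binary(spec, c(10, 11))), 0)
  expect_equal(overlap_percent(a, b), 75)  # 3 of 4 current cells retained
  expect_warning(ov <- overlap_percent(manual_binary(spec, integer(0)), a),
                 "empty current range")
  expect_true(is.nan(ov))
  expect_error(overlap_map(a, manual_binary(tiny_spec(2, 2), 1)),
               "grid mismatch")
})

test_that("occupied-area change uses cos-latitude cell weights", {
  spec <- grid_spec(30, 35, 35.5, 41.5, 1)  # rows centred at 41..36 N
  one36 <- manual_binary(spec, cell_at(spec, 30.5, 36))
  both <- manual_binary(spec, c(cell_at(spec, 30.5, 36),
                                cell_at(spec, 30.5, 41)))
  expect_equal(area_change_percent(one36, one36, spec), 0)
  # adding an equal-area cell at the same latitude doubles the area
  two36 <- manual_binary(spec, cell_at(spec, c(30.5, 31.5), c(36, 36)))
  expect_equal(area_change_percent(one36, two36, spec), 100)
  # closed-form cosine weights for cells at 36 and 41 degrees
  expected <- 100 * (cos(36 * pi / 180) + cos(41 * pi / 180) -
                       cos(36 * pi / 180)) / cos(36 * pi / 180)
  expect_equal(area_change_percent(one36, both, spec), expected)
  expect_gte(area_change_percent(both, one36, spec), -100)
})

test_that("zonal centroids are cos-latitude-weighted presence-cell means", {
  spec <- tiny_spec()  # 0.5 deg cells from (30 E, 38 N)
  single <- manual_binary(spec, cell_at(spec, 30.75, 38.75))
  expect_equal(zonal_centroid(single, spec), c(lon = 30.75, lat = 38.75))
  # cells symmetric about a meridian: centroid on it
  pair <- manual_binary(spec, cell_at(spec, c(30.25, 31.25), c(39.25, 39.25)))
  expect_equal(zonal_centroid(pair, spec)[["lon"]], 30.75)
  # three listed cells: direct weighted arithmetic
  lon <- c(30.25, 30.75, 31.75); lat <- c(38.25, 39.75, 38.75)
  three <- manual_binary(spec, cell_at(spec, lon, lat))
  w <- cos(lat * pi / 180)
  expect_equal(zonal_centroid(three, spec),
               c(lon = sum(w * lon) / sum(w), lat = sum(w * lat) / sum(w)))
  expect_error(zonal_centroid(manual_binary(spec, integer(0)), spec),
               "empty range")
})

test_that("centroid displacement is the haversine distance on a 6371 km sphere", {
  a <- c(lon = 35, lat = 39)
  b <- c(lon = 35, lat = 40)
  d <- centroid_displacement_km(a, b)
  expect_equal(d, 6371 * pi / 180, tolerance = 0.01)  # ~111.19 km
  expect_equal(centroid_displacement_km(a, a), 0)
  expect_equal(centroid_displacement_km(a, b), centroid_displacement_km(b, a))
  skip_if_not_installed("geosphere")
  for (i in 1:5) {
    p <- c(lon = runif(1, 26, 45), lat = runif(1, 36, 42))
    q <- c(lon = runif(1, 26, 45), lat = runif(1, 36, 42))
    expect_equal(centroid_displacement_km(p, q),
                 geosphere::distHaversine(p, q, r = 6371000) / 1000,
                 tolerance = 1e-6)
  }
})

test_that("zonal ellipses reproduce the weighted 2x2 covariance eigensystem", {
  spec <- tiny_spec()
  # cells along one parallel: zero north-south spread, east-west long axis
  row_cells <- manual_binary(spec, cell_at(spec, c(30.25, 30.75, 31.25),
                                           rep(39.25, 3)))
  e <- zonal_ellipse(row_cells, spec)
  expect_equal(e$values[2], 0, tolerance = 1e-10)
  expect_equal(abs(e$vectors[, 1]), c(1, 0), tolerance = 1e-10)
  # four listed cells against a direct closed-form 2x2 oracle
  lon <- c(30.25, 30.75, 31.25, 30.75); lat <- c(38.25, 38.75, 39.25, 39.75)
  m4 <- manual_binary(spec, cell_at(spec, lon, lat))
  e4 <- zonal_ellipse(m4, spec)
  w <- cos(lat * pi / 180); w <- w / sum(w)
  ctr_lon <- sum(w * lon); ctr_lat <- sum(w * lat)
  x <- (lon - ctr_lon) * cos(ctr_lat * pi / 180) * 111.19
  y <- (lat - ctr_lat) * 111.19
  C <- matrix(c(sum(w * x * x), sum(w * x * y),
                sum(w * x * y), sum(w * y * y)), 2, 2)
  expect_equal(e4$values, eigen(C, symmetric = TRUE)$values)
  expect_equal(abs(e4$vectors), abs(eigen(C, symmetric = TRUE)$vectors))
  # single cell: zero matrix with a warning
  expect_warning(e1 <- zonal_ellipse(manual_binary(spec, 3), spec),
                 "single presence cell")
  expect_equal(e1$values, c(0, 0))
})

test_that("an isotropic square block has equal ellipse eigenvalues at the equator-free limit", {
  spec <- grid_spec(30, 33, -1.5, 1.5, 0.5)  # straddles the equator: cos ~ 1
  cells <- cell_at(spec, rep(c(30.75, 31.25, 31.75), 3),
                   rep(c(-0.5, 0, 0.5), each = 3))
  e <- zonal_ellipse(manual_binary(spec, cells), spec)
  expect_equal(e$values[1], e$values[2], tolerance = 1e-4)
})

test_that("same-species turnover reports chained and all-timeline persistence", {
  spec <- tiny_spec()
  nested <- list(
    current = manual_binary(spec, 1:4),
    t1 = manual_binary(spec, 1:3),
    t2 = manual_binary(spec, 1:2))
  tv <- turnover_same_species(list(sp = nested))
  expect_equal(tv$species$current_to_t1, 75)
  expect_equal(tv$species$t1_to_t2, 200 / 3, tolerance = 1e-10)
  expect_equal(tv$species$all_timeline_pct, 50)
  # static ranges: 100 percent everywhere
  static <- list(current = manual_binary(spec, 2:5),
                 t1 = manual_binary(spec, 2:5),
                 t2 = manual_binary(spec, 2:5))
  tv2 <- turnover_same_species(list(sp = static))
  expect_true(all(tv2$species[, 2:4] == 100))
  # range vanishing at the last period: all-timeline persistence 0
  vanish <- list(current = manual_binary(spec, 1:4),
                 t1 = manual_binary(spec, 1:4),
                 t2 = manual_binary(spec, integer(0)))
  expect_equal(turnover_same_species(list(sp = vanish))$species$all_timeline_pct,
               0)
  # all-timeline persistence is bounded by each current-vs-period overlap
  set.seed(31)
  for (trial in 1:10) {
    maps <- list(current = manual_binary(spec, sample(1:20, 8)),
                 t1 = manual_binary(spec, sample(1:20, 8)),
                 t2 = manual_binary(spec, sample(1:20, 8)))
    tvr <- turnover_same_species(list(sp = maps))$species
    ov1 <- suppressWarnings(overlap_percent(maps$current, maps$t1))
    ov2 <- suppressWarnings(overlap_percent(maps$current, maps$t2))
    expect_lte(tvr$all_timeline_pct, min(ov1, ov2) + 1e-9)
  }
  # group averages use the population standard deviation
  two <- list(a = nested, b = static)
  tvg <- turnover_same_species(two)
  expect_equal(tvg$summary$mean[tvg$summary$metric == "all_timeline_pct"], 75)
  expect_equal(tvg$summary$sd[tvg$summary$metric == "all_timeline_pct"], 25)
})

test_that("empty current ranges are excluded from turnover averages", {
  spec <- tiny_spec()
  good <- list(current = manual_binary(spec, 1:2),
               t1 = manual_binary(spec, 1:2))
  bad <- list(current = manual_binary(spec, integer(0)),
              t1 = manual_binary(spec, 1:2))
  expect_message(tv <- turnover_same_species(list(a = good, b = bad)),
                 "empty current range")
  expect_true(is.nan(tv$species$all_timeline_pct[tv$species$species == "b"]))
  expect_equal(tv$summary$mean[tv$summary$metric == "all_timeline_pct"], 100)
})

test_that("range-change records combine the per-species metrics", {
  spec <- tiny_spec()
  cur <- manual_binary(spec, c(1, 2, 6, 7))
  fut <- manual_binary(spec, c(2, 7, 8))
  rc <- range_change(cur, fut, spec, species = "sp", scenario = "A2a",
                     period = "2050")
  expect_equal(rc$overlap_pct, 50)
  expect_equal(rc$n_current, 4)
  expect_equal(rc$n_future, 3)
  expect_equal(rc$displacement_km,
               centroid_displacement_km(zonal_centroid(cur, spec),
                                        zonal_centroid(fut, spec)))
  expect_true(rc$displacement_km >= 0)
})
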