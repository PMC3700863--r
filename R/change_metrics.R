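# mean length of one degree of arc on the sphere used throughout (km)
KM_PER_DEG <- 111.19
EARTH_RADIUS_KM <- 6371

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("grid mismatch between binary maps")
}

# cos-latitude cell weights and centre coordinates for presence cells
presence_geometry <- function(map, spec) {
  cells <- presence_cells_of(map)
  cc <- cell_centers(spec, cells)
  cc$w <- cos(cc$lat * pi / 180)
  cc
}

#' Presence overlap map
#'
#' Cellwise product of two binary maps: 1 exactly where the species is
#' predicted present in both periods.
#'
#' @param current,future `binary_map`s on one grid.
#' @return A `binary_map` of the overlap.
#' @export
overlap_map <- function(current, future) {
  check_same_grid(current, future)
  structure(unclass(current) * unclass(future),
            threshold = NA_real_, species = attr(current, "species"),
            period = NA_character_, scenario = NA_character_,
            class = c("binary_map", "matrix", "array"))
}

#' Percentage of the current range retained in the future
#'
#' `100 * |cells present in both| / |cells present currently|`. An empty
#' current range has no defined overlap; `NaN` is returned with a warning.
#'
#' @param current,future `binary_map`s on one grid.
#' @return Percentage in `[0, 100]`, or `NaN`.
#' @export
overlap_percent <- function(current, future) {
  check_same_grid(current, future)
  cur <- presence_cells_of(current)
  if (!length(cur)) {
    warning("overlap_percent: empty current range")
    return(NaN)
  }
  fut <- presence_cells_of(future)
  100 * length(intersect(cur, fut)) / length(cur)
}

#' Occupied-area change between periods
#'
#' `100 * (area(future) - area(current)) / area(current)` with cell areas
#' weighted by the cosine of the cell-centre latitude, which approximates
#' true area on the geographic grid (unweighted counts distort area by
#' several percent across a 36-42 deg N domain).
#'
#' @param current,future `binary_map`s on one grid.
#' @param spec The [grid_spec()] of the maps.
#' @return Signed percentage (>= -100), or `NaN` for an empty current range.
#' @export
area_change_percent <- function(current, future, spec) {
  check_same_grid(current, future)
  a_cur <- sum(presence_geometry(current, spec)$w)
  if (a_cur <= 0) {
    warning("area_change_percent: empty current range")
    return(NaN)
  }
  a_fut <- sum(presence_geometry(future, spec)$w)
  100 * (a_fut - a_cur) / a_cur
}

#' Zonal centroid of a predicted range
#'
#' Area-weighted (cos-latitude) mean of the presence-cell centre
#' coordinates.
#'
#' @param map A `binary_map`.
#' @param spec The [grid_spec()] of the map.
#' @return Named numeric `c(lon, lat)` in degrees.
#' @export
zonal_centroid <- function(map, spec) {
  g <- presence_geometry(map, spec)
  if (!nrow(g)) stop("zonal_centroid: empty range")
  c(lon = sum(g$w * g$lon) / sum(g$w),
    lat = sum(g$w * g$lat) / sum(g$w))
}

#' Great-circle distance between two centroids
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param c1,c2 Named numeric `c(lon, lat)` in degrees.
#' @return Distance in km.
#' @export
centroid_displacement_km <- function(c1, c2) {
  to_rad <- pi / 180
  dlat <- (c2[["lat"]] - c1[["lat"]]) * to_rad
  dlon <- (c2[["lon"]] - c1[["lon"]]) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(c1[["lat"]] * to_rad) * cos(c2[["lat"]] * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Zonal ellipse of a predicted range
#'
#' Eigendecomposition of the 2x2 cos-latitude-weighted covariance of the
#' presence-cell centres, in a local plane about the centroid scaled to km
#' (`x = dlon * cos(centroid lat) * 111.19`, `y = dlat * 111.19`). The
#' leading eigenvector gives the range's long axis. A single-cell range has
#' no spread; a zero matrix is returned with a warning.
#'
#' @param map A `binary_map`.
#' @param spec The [grid_spec()] of the map.
#' @return List with `values` (eigenvalues, descending, km^2), `vectors`
#'   (columns = eigenvectors in the (east, north) plane), and `centroid`.
#' @export
zonal_ellipse <- function(map, spec) {
  g <- presence_geometry(map, spec)
  if (!nrow(g)) stop("zonal_ellipse: empty range")
  ctr <- c(lon = sum(g$w * g$lon) / sum(g$w),
           lat = sum(g$w * g$lat) / sum(g$w))
  if (nrow(g) == 1) {
    warning("zonal_ellipse: single presence cell, zero covariance")
    return(list(values = c(0, 0), vectors = diag(2), centroid = ctr))
  }
  x <- (g$lon - ctr[["lon"]]) * cos(ctr[["lat"]] * pi / 180) * KM_PER_DEG
  y <- (g$lat - ctr[["lat"]]) * KM_PER_DEG
  w <- g$w / sum(g$w)
  C <- matrix(c(sum(w * x * x), sum(w * x * y),
                sum(w * x * y), sum(w * y * y)), 2, 2)
  e <- eigen(C, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, centroid = ctr)
}

#' Same-species turnover across timelines
#'
#' For each species with binary maps over ordered periods (current first),
#' computes the chained pairwise retention — `overlap_percent(previous,
#' next)` for each consecutive pair — and the all-timeline persistence:
#' the percentage of the current range predicted present in every period.
#' Species with an empty current range are reported `NaN` and excluded
#' from the group averages (mean and population standard deviation).
#'
#' @param maps_by_species Named list (one entry per species) of lists of
#'   `binary_map`s in period order, current first; all entries must cover
#'   the same periods.
#' @param periods Optional period names (defaults to names of the first
#'   species' list).
#' @return List with `species` (data.frame: one row per species, pairwise
#'   percentages and `all_timeline_pct`) and `summary` (data.frame of
#'   group mean and population sd per column).
#' @export
turnover_same_species <- function(maps_by_species, periods = NULL) {
  stopifnot(length(maps_by_species) >= 1)
  np <- length(maps_by_species[[1]])
  stopifnot(np >= 2)
  if (is.null(periods)) periods <- names(maps_by_species[[1]])
  if (is.null(periods)) periods <- paste0("t", seq_len(np) - 1)
  pair_names <- paste0(periods[-np], "_to_", periods[-1])
  rows <- lapply(names(maps_by_species), function(sp) {
    maps <- maps_by_species[[sp]]
    stopifnot(length(maps) == np)
    cur_cells <- presence_cells_of(maps[[1]])
    if (!length(cur_cells)) {
      message("turnover_same_species: empty current range for ", sp,
              "; excluded from averages")
      pct <- rep(NaN, np - 1)
      all_pct <- NaN
    } else {
      pct <- vapply(seq_len(np - 1), function(k)
        suppressWarnings(overlap_percent(maps[[k]], maps[[k + 1]])),
        numeric(1))
      common <- Reduce(intersect, lapply(maps, presence_cells_of))
      all_pct <- 100 * length(common) / length(cur_cells)
    }
    out <- data.frame(species = sp, t(pct), all_timeline_pct = all_pct,
                      stringsAsFactors = FALSE)
    names(out)[2:np] <- pair_names
    out
  })
  tab <- do.call(rbind, rows)
  num_cols <- c(pair_names, "all_timeline_pct")
  pop_sd <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NaN)
    sqrt(mean((x - mean(x))^2))
  }
  summary <- data.frame(
    metric = num_cols,
    mean = vapply(num_cols, function(cn) mean(tab[[cn]][is.finite(tab[[cn]])]),
                  numeric(1)),
    sd = vapply(num_cols, function(cn) pop_sd(tab[[cn]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(species = tab, summary = summary)
}

#' Per-species range-change summary
#'
#' Combines the change metrics for one species and one period pair into a
#' single record: overlap percentage, occupied-area change, the two zonal
#' centroids and the displacement between them.
#'
#' @param current,future `binary_map`s on one grid.
#' @param spec The [grid_spec()] of the maps.
#' @param species,scenario,period Metadata for the output row.
#' @return One-row data.frame.
#' @export
range_change <- function(current, future, spec, species = NA_character_,
                         scenario = NA_character_, period = NA_character_) {
  cur_cells <- presence_cells_of(current)
  fut_cells <- presence_cells_of(future)
  ov <- suppressWarnings(overlap_percent(current, future))
  ac <- suppressWarnings(area_change_percent(current, future, spec))
  if (length(cur_cells) && length(fut_cells)) {
    c1 <- zonal_centroid(current, spec)
    c2 <- zonal_centroid(future, spec)
    disp <- centroid_displacement_km(c1, c2)
  } else {
    c1 <- c2 <- c(lon = NA_real_, lat = NA_real_)
    disp <- NA_real_
  }
  data.frame(species = species, scenario = scenario, period = period,
             n_current = length(cur_cells), n_future = length(fut_cells),
             overlap_pct = ov, area_change_pct = ac,
             lon_current = c1[["lon"]], lat_current = c1[["lat"]],
             lon_future = c2[["lon"]], lat_future = c2[["lat"]],
             displacement_km = disp, stringsAsFactors = FALSE)
}
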