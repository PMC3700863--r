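#' Read occurrence records from CSV
#'
#' Expects columns `species`, `lon`, `lat`, `date`, `source`. Rows with
#' non-numeric or non-finite coordinates, unparseable dates, or an unknown
#' source flag are skipped; the skip count is reported with a message and
#' attached as attribute `n_skipped`.
#'
#' @param path CSV file path.
#' @return Data.frame of valid records (columns `species`, `lon`, `lat`,
#'   `date` as `Date`, `source`).
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("read_occurrences: no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("species", "lon", "lat", "date", "source")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("read_occurrences: missing required columns: ",
         paste(missing_cols, collapse = ", "))
  lon <- suppressWarnings(as.numeric(raw$lon))
  lat <- suppressWarnings(as.numeric(raw$lat))
  date <- suppressWarnings(as.Date(raw$date, format = "%Y-%m-%d"))
  ok <- is.finite(lon) & is.finite(lat) & !is.na(date) &
    nzchar(raw$species) & raw$source %in% c("casual", "bbs", "ringing")
  n_skip <- sum(!ok)
  if (n_skip > 0)
    message("read_occurrences: skipped ", n_skip, " malformed row(s)")
  out <- data.frame(species = raw$species[ok], lon = lon[ok], lat = lat[ok],
                    date = date[ok], source = raw$source[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skip
  out
}

#' Drop systematic-survey records
#'
#' Removes records whose source flag is `bbs` (Breeding Bird Survey) or
#' `ringing` (banding station), keeping only casual observations. This
#' homogenizes sampling effort: survey and ringing sites contribute
#' excessive record counts at fixed locations.
#'
#' @param records Occurrence data.frame.
#' @return Filtered data.frame.
#' @export
filter_sources <- function(records) {
  records[!(records$source %in% c("bbs", "ringing")), , drop = FALSE]
}

#' Seasonal record filter by species group
#'
#' Migratory species keep only breeding-season records, April 15 to July 30
#' inclusive (records outside it likely represent passage, not breeding
#' range). Resident species drop midwinter records, December 1 to January 31
#' inclusive (the window wraps the year boundary), when cold-weather
#' nomadism moves birds off their breeding ranges. All other dates are kept.
#'
#' @param records Occurrence data.frame.
#' @param groups Data.frame with columns `species` and `group`
#'   (`"resident"` or `"migratory"`); every species present in `records`
#'   must be listed.
#' @return Filtered data.frame.
#' @export
filter_season <- function(records, groups) {
  stopifnot(all(c("species", "group") %in% names(groups)))
  if (nrow(records) == 0) return(records)
  grp <- groups$group[match(records$species, groups$species)]
  if (anyNA(grp))
    stop("filter_season: no group assignment for species: ",
         paste(unique(records$species[is.na(grp)]), collapse = ", "))
  bad <- !grp %in% c("resident", "migratory")
  if (any(bad))
    stop("filter_season: unknown group label: ",
         paste(unique(grp[bad]), collapse = ", "))
  md <- format(as.Date(records$date), "%m-%d")
  in_breeding <- md >= "04-15" & md <= "07-30"
  in_winter <- md >= "12-01" | md <= "01-31"
  keep <- ifelse(grp == "migratory", in_breeding, !in_winter)
  records[keep, , drop = FALSE]
}

#' Drop species with too few records
#'
#' Retains only species with strictly more than `minimum` records (the
#' sample-size screen for fitting a presence-only model); dropped species
#' are reported with a message.
#'
#' @param records Occurrence data.frame.
#' @param minimum Count threshold; species with `count <= minimum` are
#'   dropped. Default 25.
#' @return Filtered data.frame; attribute `dropped_species` lists exclusions.
#' @export
filter_min_records <- function(records, minimum = 25) {
  counts <- table(records$species)
  keep_sp <- names(counts)[counts > minimum]
  dropped <- setdiff(names(counts), keep_sp)
  if (length(dropped))
    message("filter_min_records: dropped ", length(dropped),
            " species with <= ", minimum, " records: ",
            paste(dropped, collapse = ", "))
  out <- records[records$species %in% keep_sp, , drop = FALSE]
  attr(out, "dropped_species") <- dropped
  out
}

#' Rasterize one species' records to presence cells
#'
#' Maps each record to its containing grid cell (half-open cell intervals:
#' a record exactly on an interior edge goes to the east/north neighbour).
#' Records outside the grid are dropped and counted. With `thin_to_cell`
#' (the default) duplicate hits in a cell collapse to a single presence
#' cell, the standard duplicate handling for grid-based presence-only
#' models.
#'
#' @param records Occurrence data.frame, all rows one species.
#' @param spec A [grid_spec()].
#' @param thin_to_cell Collapse multiple records per cell to one presence?
#' @return A `presence_set`: list with `species`, `cells` (sorted integer
#'   cell indices; with `thin_to_cell = FALSE` duplicates retained),
#'   `n_records` (records inside the grid), `n_outside`.
#' @export
rasterize_presences <- function(records, spec, thin_to_cell = TRUE) {
  sp <- unique(records$species)
  if (length(sp) > 1)
    stop("rasterize_presences: records contain more than one species")
  cells <- cell_at(spec, records$lon, records$lat)
  n_outside <- sum(is.na(cells))
  cells <- cells[!is.na(cells)]
  n_records <- length(cells)
  if (thin_to_cell) cells <- unique(cells)
  structure(list(species = if (length(sp)) sp else NA_character_,
                 cells = sort(cells), n_records = n_records,
                 n_outside = n_outside),
            class = "presence_set")
}

#' @export
print.presence_set <- function(x, ...) {
  cat(sprintf("presence_set: %s, %d cells from %d records (%d outside grid)\n",
              x$species, length(x$cells), x$n_records, x$n_outside))
  invisible(x)
}

#' Spatial-coverage statistic
#'
#' Fraction of `block`-degree blocks of the grid extent containing at least
#' one record — a measurable proxy for "records spread evenly across the
#' study area". Reported, not enforced, by the pipeline.
#'
#' @param records Occurrence data.frame (one or more species).
#' @param spec A [grid_spec()].
#' @param block Block edge in degrees (default 1).
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(records, spec, block = 1) {
  nbx <- ceiling((spec$lon_max - spec$lon_min) / block)
  nby <- ceiling((spec$lat_max - spec$lat_min) / block)
  inside <- records$lon >= spec$lon_min & records$lon < spec$lon_max &
    records$lat >= spec$lat_min & records$lat < spec$lat_max
  if (!any(inside)) return(0)
  bx <- floor((records$lon[inside] - spec$lon_min) / block)
  by <- floor((records$lat[inside] - spec$lat_min) / block)
  length(unique(bx * nby + by)) / (nbx * nby)
}

#' Per-species and per-group record totals
#'
#' Accepts either raw/cleaned occurrence records (tallied by species) or a
#' precomputed count table with columns `species` and `n`. Returns the
#' per-species counts joined with group labels plus per-group totals, the
#' layout used for record-accounting summaries.
#'
#' @param x Occurrence data.frame, or a data.frame with columns `species`
#'   and `n`.
#' @param groups Data.frame with columns `species`, `group`.
#' @return List with `species` (data.frame `species`, `group`, `n`) and
#'   `totals` (data.frame `group`, `n_species`, `n_records`).
#' @export
summarize_records <- function(x, groups) {
  stopifnot(all(c("species", "group") %in% names(groups)))
  if ("n" %in% names(x)) {
    counts <- data.frame(species = x$species, n = as.numeric(x$n),
                         stringsAsFactors = FALSE)
  } else {
    tab <- table(x$species)
    counts <- data.frame(species = names(tab), n = as.numeric(tab),
                         stringsAsFactors = FALSE)
  }
  if (nrow(counts) == 0) {
    return(list(
      species = data.frame(species = character(), group = character(),
                           n = numeric(), stringsAsFactors = FALSE),
      totals = data.frame(group = character(), n_species = integer(),
                          n_records = numeric(), stringsAsFactors = FALSE)))
  }
  counts$group <- groups$group[match(counts$species, groups$species)]
  if (anyNA(counts$group))
    stop("summarize_records: species without group assignment: ",
         paste(counts$species[is.na(counts$group)], collapse = ", "))
  counts <- counts[order(counts$group, counts$species),
                   c("species", "group", "n")]
  totals <- do.call(rbind, lapply(split(counts, counts$group), function(d)
    data.frame(group = d$group[1], n_species = nrow(d),
               n_records = sum(d$n), stringsAsFactors = FALSE)))
  rownames(counts) <- rownames(totals) <- NULL
  list(species = counts, totals = totals)
}
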