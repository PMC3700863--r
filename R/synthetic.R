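#' Spatially autocorrelated noise field
#'
#' Gaussian-kernel smoothing of white noise: a white-noise matrix is smoothed
#' separably along rows and columns with a normalized Gaussian kernel of the
#' given length scale, then rescaled to unit standard deviation across cells.
#' As `sigma` grows the field tends to a constant (every cell the kernel-
#' weighted mean of the whole grid).
#'
#' @param spec A [grid_spec()].
#' @param sigma Length scale in cells; `Inf` gives a constant field.
#' @return Matrix `n_rows` x `n_cols`, mean ~0, sd 1 (0 when constant).
#' @keywords internal
smooth_noise_field <- function(spec, sigma) {
  stopifnot(sigma > 0)
  z <- matrix(stats::rnorm(n_cells(spec)), spec$n_rows, spec$n_cols)
  kern <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    w <- exp(-d^2 / (2 * sigma^2))
    w / rowSums(w)
  }
  sm <- kern(spec$n_rows) %*% z %*% t(kern(spec$n_cols))
  s <- stats::sd(sm)
  if (is.finite(s) && s > 1e-12) (sm - mean(sm)) / s else sm * 0
}

#' Generate a synthetic monthly climate stack
#'
#' Emulates the structure of gridded monthly climatologies (12 layers each of
#' minimum temperature, maximum temperature and precipitation): a latitudinal
#' temperature gradient, a sinusoidal seasonal cycle peaking in July, a
#' winter-peaking precipitation cycle, and spatially autocorrelated noise
#' produced by Gaussian smoothing of white noise. The diurnal half-range is
#' strictly positive by construction, so `tmax > tmin` in every cell-month,
#' and precipitation is log-normal hence non-negative.
#'
#' @param spec A [grid_spec()].
#' @param seed Integer seed; the same seed reproduces the stack bit for bit.
#' @param smoothness Noise length scale in cells (> 0); `Inf` gives spatially
#'   constant noise.
#' @param base_temp Annual-mean temperature at the southern edge, deg C.
#' @param lat_gradient Change in mean temperature per degree of latitude
#'   northwards, deg C (negative = cooler north).
#' @param seasonal_amp Amplitude of the seasonal temperature cycle, deg C.
#' @param diurnal_range Mean diurnal (tmax - tmin) range, deg C.
#' @param temp_noise_sd Standard deviation of the temperature noise, deg C.
#' @param precip_mean Mean monthly precipitation, mm.
#' @param precip_season_amp Log-scale amplitude of the winter-wet cycle.
#' @param precip_noise_sd Log-scale sd of the precipitation noise.
#' @return A `climate_stack`: list with `spec` and three
#'   `n_rows x n_cols x 12` arrays `tmin`, `tmax`, `prec`.
#' @export
make_climate <- function(spec, seed, smoothness = 3,
                         base_temp = 16, lat_gradient = -0.8,
                         seasonal_amp = 10, diurnal_range = 10,
                         temp_noise_sd = 2, precip_mean = 55,
                         precip_season_amp = 0.5, precip_noise_sd = 0.45) {
  stopifnot(inherits(spec, "grid_spec"), smoothness > 0, diurnal_range > 0,
            precip_mean > 0)
  withr::with_seed(as.integer(seed), {
    lat <- matrix(spec$lat_max - (seq_len(spec$n_rows) - 0.5) * spec$cell_size,
                  spec$n_rows, spec$n_cols)
    shared_t <- smooth_noise_field(spec, smoothness)
    shared_p <- smooth_noise_field(spec, smoothness)
    range_f  <- smooth_noise_field(spec, smoothness)
    dims <- c(spec$n_rows, spec$n_cols, 12L)
    tmin <- tmax <- prec <- array(NA_real_, dims)
    half <- diurnal_range / 2 * exp(0.25 * range_f)
    for (m in 1:12) {
      own_t <- smooth_noise_field(spec, smoothness)
      own_p <- smooth_noise_field(spec, smoothness)
      tmid <- base_temp + lat_gradient * (lat - spec$lat_min) +
        seasonal_amp * cos(2 * pi * (m - 7) / 12) +
        temp_noise_sd * (0.75 * shared_t + 0.25 * own_t)
      tmin[, , m] <- tmid - half
      tmax[, , m] <- tmid + half
      prec[, , m] <- precip_mean *
        exp(precip_season_amp * cos(2 * pi * (m - 1) / 12) +
              precip_noise_sd * (0.75 * shared_p + 0.25 * own_p))
    }
    structure(list(spec = spec, tmin = tmin, tmax = tmax, prec = prec),
              class = "climate_stack")
  })
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("climate_stack: 36 monthly layers on %d x %d grid\n",
              x$spec$n_rows, x$spec$n_cols))
  invisible(x)
}

#' Apply a climate-scenario perturbation
#'
#' Stands in for future-scenario layers: shifts all temperatures by an
#' additive delta and scales precipitation by a factor, leaving the grid
#' untouched.
#'
#' @param base A `climate_stack` from [make_climate()] or read from disk.
#' @param delta_t Additive temperature change, deg C.
#' @param precip_factor Multiplicative precipitation change (> 0).
#' @return A `climate_stack` on the same grid.
#' @export
perturb_climate <- function(base, delta_t = 0, precip_factor = 1) {
  stopifnot(inherits(base, "climate_stack"), is.numeric(delta_t),
            precip_factor > 0)
  base$tmin <- base$tmin + delta_t
  base$tmax <- base$tmax + delta_t
  base$prec <- base$prec * precip_factor
  base
}

#' Ground-truth log-linear suitability model
#'
#' Defines a Gibbs suitability surface `exp(intercept + sum(w * z))` over
#' standardized bioclimatic variables, used to generate occurrences with a
#' known answer for parameter-recovery tests.
#'
#' @param weights Named numeric vector; names are bioclim layer names
#'   (`"BIO1"` ... `"BIO19"`), units per standardized variable unit.
#' @param intercept Dimensionless offset (immaterial after normalization).
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(weights, intercept = 0) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            all(nzchar(names(weights))), all(is.finite(weights)),
            is.finite(intercept))
  structure(list(weights = weights, intercept = intercept),
            class = "truth_model")
}

#' Evaluate a truth model on a bioclim stack
#'
#' Variables named in the model are standardized (mean 0, sd 1) over the
#' unmasked cells before the log-linear form is applied, so weights are
#' comparable across variables with different units.
#'
#' @param truth A [truth_model()].
#' @param bioclim A `bioclim_stack` from [derive_bioclim()].
#' @return Matrix of positive suitabilities; `NA` on masked cells.
#' @export
truth_suitability <- function(truth, bioclim) {
  stopifnot(inherits(truth, "truth_model"), inherits(bioclim, "bioclim_stack"))
  spec <- bioclim$spec
  eta <- matrix(truth$intercept, spec$n_rows, spec$n_cols)
  for (v in names(truth$weights)) {
    layer <- bioclim_layer(bioclim, v)
    mu <- mean(layer, na.rm = TRUE)
    sdv <- stats::sd(as.vector(layer), na.rm = TRUE)
    z <- if (is.finite(sdv) && sdv > 0) (layer - mu) / sdv else layer * 0
    eta <- eta + truth$weights[[v]] * z
  }
  exp(eta)
}

#' Sample occurrence records from a known suitability surface
#'
#' Cells are drawn (with replacement) with probability proportional to the
#' truth suitability, optionally multiplied by a Gaussian observer-bias
#' kernel around given cells — emulating casual records concentrated near
#' popular birding sites. Each record gets a coordinate jittered uniformly
#' within its cell, a date drawn uniformly from a seasonal window, and a
#' source flag.
#'
#' @param truth A [truth_model()].
#' @param bioclim A `bioclim_stack` on the analysis grid.
#' @param n Number of records (>= 0).
#' @param seed Integer seed.
#' @param species Species name written into the records.
#' @param bias_centers Optional integer vector of cell indices acting as
#'   observer hotspots.
#' @param bias_sigma Bias kernel length scale in cells.
#' @param window Character vector `c("mm-dd", "mm-dd")`: start and end of the
#'   sampling-date window (must not wrap the year end).
#' @param year Calendar year stamped on the dates.
#' @param source_probs Named probabilities for the source flag, over
#'   `casual`, `bbs`, `ringing`.
#' @return A data.frame with columns `species`, `lon`, `lat`, `date`,
#'   `source`.
#' @export
sample_occurrences <- function(truth, bioclim, n, seed,
                               species = "species_1",
                               bias_centers = NULL, bias_sigma = 2,
                               window = c("03-01", "08-31"), year = 2010,
                               source_probs = c(casual = 0.9, bbs = 0.05,
                                                ringing = 0.05)) {
  stopifnot(n >= 0, length(window) == 2)
  spec <- bioclim$spec
  suit <- truth_suitability(truth, bioclim)
  prob <- as.vector(t(suit))  # row-major cell order
  prob[!is.finite(prob)] <- 0
  if (!is.null(bias_centers)) {
    cc <- cell_centers(spec)
    bc <- cell_centers(spec, bias_centers)
    bias <- rep(0, n_cells(spec))
    for (k in seq_len(nrow(bc))) {
      d2 <- (cc$row - bc$row[k])^2 + (cc$col - bc$col[k])^2
      bias <- bias + exp(-d2 / (2 * bias_sigma^2))
    }
    prob <- prob * bias
  }
  if (sum(prob) <= 0) stop("sample_occurrences: suitability is zero everywhere")
  empty <- data.frame(species = character(), lon = numeric(), lat = numeric(),
                      date = as.Date(character()), source = character(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  withr::with_seed(as.integer(seed), {
    cells <- sample.int(n_cells(spec), n, replace = TRUE, prob = prob)
    cc <- cell_centers(spec, cells)
    lon <- spec$lon_min + (cc$col - 1 + stats::runif(n)) * spec$cell_size
    lat <- spec$lat_max - (cc$row - stats::runif(n)) * spec$cell_size
    d0 <- as.Date(sprintf("%d-%s", year, window[1]))
    d1 <- as.Date(sprintf("%d-%s", year, window[2]))
    if (d1 < d0) stop("sample_occurrences: date window must not wrap the year")
    date <- d0 + sample.int(as.integer(d1 - d0) + 1L, n, replace = TRUE) - 1L
    src <- sample(names(source_probs), n, replace = TRUE, prob = source_probs)
    data.frame(species = species, lon = lon, lat = lat, date = date,
               source = src, stringsAsFactors = FALSE)
  })
}

#' Write occurrence records as CSV
#'
#' @param records Data.frame with columns `species`, `lon`, `lat`, `date`,
#'   `source`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  need <- c("species", "lon", "lat", "date", "source")
  stopifnot(all(need %in% names(records)))
  out <- records[, need]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a climate stack as ESRI ASCII grids
#'
#' One file per layer, named `tmin_01.asc` ... `prec_12.asc`, in `dir`.
#'
#' @param climate A `climate_stack`.
#' @param dir Output directory (created if missing).
#' @return Character vector of the 36 file paths, invisibly.
#' @export
write_climate <- function(climate, dir) {
  stopifnot(inherits(climate, "climate_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (v in c("tmin", "tmax", "prec")) {
    for (m in 1:12) {
      p <- file.path(dir, sprintf("%s_%02d.asc", v, m))
      write_ascii_grid(climate[[v]][, , m], climate$spec, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read a climate stack from ESRI ASCII grids
#'
#' Expects the layout written by [write_climate()].
#'
#' @param dir Directory containing `tmin_01.asc` ... `prec_12.asc`.
#' @return A `climate_stack`.
#' @export
read_climate <- function(dir) {
  first <- read_ascii_grid(file.path(dir, "tmin_01.asc"))
  spec <- first$spec
  dims <- c(spec$n_rows, spec$n_cols, 12L)
  out <- list(spec = spec,
              tmin = array(NA_real_, dims), tmax = array(NA_real_, dims),
              prec = array(NA_real_, dims))
  for (v in c("tmin", "tmax", "prec")) {
    for (m in 1:12) {
      g <- read_ascii_grid(file.path(dir, sprintf("%s_%02d.asc", v, m)))
      if (!same_grid(g$spec, spec)) stop("read_climate: inconsistent grids")
      out[[v]][, , m] <- g$data
    }
  }
  structure(out, class = "climate_stack")
}
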