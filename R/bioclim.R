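#' Derive the 19 bioclimatic variables from monthly climate
#'
#' Computes the standard BIOCLIM summaries (WorldClim dialect) cellwise from
#' 12 months each of minimum temperature, maximum temperature and
#' precipitation. Monthly mean temperature is `(tmin + tmax) / 2`. Quarters
#' are every 3-consecutive-month window with December-January wraparound;
#' ties between equally wet/dry/warm/cold quarters go to the earliest
#' starting month. Seasonality uses the population standard deviation:
#' BIO4 = 100 * sd of monthly means, BIO15 = 100 * sd(precip) /
#' (1 + mean(precip)) (the +1 guards arid cells). Cells with any missing
#' month are `NA` in all 19 layers.
#'
#' Layers and units: BIO1 annual mean temperature (deg C); BIO2 mean diurnal
#' range; BIO3 isothermality 100*BIO2/BIO7; BIO4 temperature seasonality
#' (sd x 100); BIO5/BIO6 max/min temperature of warmest/coldest month;
#' BIO7 annual range BIO5-BIO6; BIO8/BIO9 mean temperature of wettest/driest
#' quarter; BIO10/BIO11 mean temperature of warmest/coldest quarter;
#' BIO12 annual precipitation (mm); BIO13/BIO14 wettest/driest month
#' precipitation; BIO15 precipitation seasonality (CV); BIO16-BIO19
#' precipitation of wettest/driest/warmest/coldest quarter.
#'
#' @param climate A `climate_stack` (see [make_climate()], [read_climate()]).
#' @return A `bioclim_stack`: list with `spec` and a
#'   `n_rows x n_cols x 19` array `layers` with dimnames `BIO1`...`BIO19`.
#' @export
derive_bioclim <- function(climate) {
  stopifnot(inherits(climate, "climate_stack"))
  spec <- climate$spec
  for (v in c("tmin", "tmax", "prec")) {
    d <- dim(climate[[v]])
    if (is.null(d) || length(d) != 3 || d[3] != 12)
      stop("derive_bioclim: ", v, " must have 12 monthly layers")
  }
  N <- n_cells(spec)
  # N x 12 matrices in row-major cell order
  tmn <- matrix(apply(climate$tmin, 3, as_cell_vector), N, 12)
  tmx <- matrix(apply(climate$tmax, 3, as_cell_vector), N, 12)
  pr  <- matrix(apply(climate$prec, 3, as_cell_vector), N, 12)
  tav <- (tmn + tmx) / 2

  valid <- stats::complete.cases(cbind(tmn, tmx, pr))
  # neutral fill so max.col and arithmetic stay defined; re-masked at the end
  fill <- function(m) { m[!valid, ] <- 0; m }
  tmn <- fill(tmn); tmx <- fill(tmx); pr <- fill(pr); tav <- fill(tav)

  row_max <- function(m) do.call(pmax, as.data.frame(m))
  row_min <- function(m) do.call(pmin, as.data.frame(m))
  pop_sd <- function(m) {
    mu <- rowMeans(m)
    sqrt(pmax(rowMeans(m^2) - mu^2, 0))
  }

  bio <- matrix(NA_real_, N, 19,
                dimnames = list(NULL, paste0("BIO", 1:19)))
  bio[, 1] <- rowMeans(tav)
  bio[, 2] <- rowMeans(tmx - tmn)
  bio[, 4] <- 100 * pop_sd(tav)
  bio[, 5] <- row_max(tmx)
  bio[, 6] <- row_min(tmn)
  bio[, 7] <- bio[, 5] - bio[, 6]
  bio[, 3] <- ifelse(bio[, 7] > 0, 100 * bio[, 2] / bio[, 7], NaN)
  bio[, 12] <- rowSums(pr)
  bio[, 13] <- row_max(pr)
  bio[, 14] <- row_min(pr)
  bio[, 15] <- 100 * pop_sd(pr) / (1 + rowMeans(pr))

  # quarter summaries: window q = months q, q+1, q+2 (mod 12)
  qtemp <- qprec <- matrix(0, N, 12)
  for (q in 1:12) {
    idx <- ((q - 1):(q + 1)) %% 12 + 1
    qtemp[, q] <- rowMeans(tav[, idx, drop = FALSE])
    qprec[, q] <- rowSums(pr[, idx, drop = FALSE])
  }
  i <- seq_len(N)
  wet  <- max.col(qprec,  ties.method = "first")
  dry  <- max.col(-qprec, ties.method = "first")
  warm <- max.col(qtemp,  ties.method = "first")
  cold <- max.col(-qtemp, ties.method = "first")
  bio[, 8]  <- qtemp[cbind(i, wet)]
  bio[, 9]  <- qtemp[cbind(i, dry)]
  bio[, 10] <- qtemp[cbind(i, warm)]
  bio[, 11] <- qtemp[cbind(i, cold)]
  bio[, 16] <- qprec[cbind(i, wet)]
  bio[, 17] <- qprec[cbind(i, dry)]
  bio[, 18] <- qprec[cbind(i, warm)]
  bio[, 19] <- qprec[cbind(i, cold)]

  bio[!valid, ] <- NA_real_

  layers <- array(NA_real_, c(spec$n_rows, spec$n_cols, 19),
                  dimnames = list(NULL, NULL, paste0("BIO", 1:19)))
  for (k in 1:19) layers[, , k] <- as_grid_matrix(bio[, k], spec)
  structure(list(spec = spec, layers = layers), class = "bioclim_stack")
}

#' @export
print.bioclim_stack <- function(x, ...) {
  cat(sprintf("bioclim_stack: 19 layers (BIO1..BIO19) on %d x %d grid, %d unmasked cells\n",
              x$spec$n_rows, x$spec$n_cols,
              sum(is.finite(x$layers[, , 1]))))
  invisible(x)
}

#' Extract one bioclim layer as a matrix
#' @param bioclim A `bioclim_stack`.
#' @param name Layer name, e.g. `"BIO12"`.
#' @return Matrix on the grid.
#' @export
bioclim_layer <- function(bioclim, name) {
  stopifnot(inherits(bioclim, "bioclim_stack"),
            name %in% dimnames(bioclim$layers)[[3]])
  bioclim$layers[, , name]
}

#' Bioclim values at cells, as a matrix
#'
#' @param bioclim A `bioclim_stack`.
#' @param cells Integer cell indices (row-major).
#' @param vars Layer names; default all 19.
#' @return `length(cells) x length(vars)` matrix.
#' @export
bioclim_values <- function(bioclim, cells, vars = NULL) {
  if (is.null(vars)) vars <- dimnames(bioclim$layers)[[3]]
  out <- sapply(vars, function(v) as_cell_vector(bioclim_layer(bioclim, v))[cells])
  matrix(out, nrow = length(cells), dimnames = list(NULL, vars))
}

#' Mask a stack to a bounding box
#'
#' Cells whose centres fall outside the box are set to `NA` in every layer;
#' the grid shape is preserved. Works on both `climate_stack` and
#' `bioclim_stack` objects.
#'
#' @param stack A `climate_stack` or `bioclim_stack`.
#' @param box Numeric vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return The stack with outside cells masked.
#' @export
mask_to_box <- function(stack, box) {
  stopifnot(length(box) == 4)
  spec <- stack$spec
  cc <- cell_centers(spec)
  inside <- cc$lon >= box[1] & cc$lon <= box[2] &
    cc$lat >= box[3] & cc$lat <= box[4]
  if (!any(inside)) stop("mask_to_box: box does not intersect the grid")
  mask <- as_grid_matrix(ifelse(inside, 1, NA_real_), spec)
  if (inherits(stack, "climate_stack")) {
    for (v in c("tmin", "tmax", "prec"))
      for (m in 1:12) stack[[v]][, , m] <- stack[[v]][, , m] * mask
  } else if (inherits(stack, "bioclim_stack")) {
    for (k in seq_len(dim(stack$layers)[3]))
      stack$layers[, , k] <- stack$layers[, , k] * mask
  } else stop("mask_to_box: unsupported stack type")
  stack
}

#' Unmasked cells of a bioclim stack
#'
#' @param bioclim A `bioclim_stack`.
#' @return Integer vector of row-major cell indices with finite values.
#' @export
unmasked_cells <- function(bioclim) {
  which(is.finite(as_cell_vector(bioclim_layer(bioclim, "BIO1"))))
}

#' Write a bioclim stack as ESRI ASCII grids
#'
#' One file per layer, `BIO1.asc` ... `BIO19.asc`.
#'
#' @param bioclim A `bioclim_stack`.
#' @param dir Output directory (created if missing).
#' @return File paths, invisibly.
#' @export
write_bioclim <- function(bioclim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- dimnames(bioclim$layers)[[3]]
  paths <- vapply(nm, function(v) {
    p <- file.path(dir, paste0(v, ".asc"))
    write_ascii_grid(bioclim$layers[, , v], bioclim$spec, p)
    p
  }, character(1))
  invisible(paths)
}
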