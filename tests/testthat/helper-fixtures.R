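# Shared fixtures: tiny grids and hand-constructed climate/bioclim stacks.

tiny_spec <- function(n_rows = 4, n_cols = 5, cell = 0.5,
                      lon_min = 30, lat_min = 38) {
  grid_spec(lon_min, lon_min + n_cols * cell,
            lat_min, lat_min + n_rows * cell, cell)
}

# climate stack with the same 12 monthly values in every cell
constant_climate <- function(spec, tmin, tmax, prec) {
  stopifnot(length(tmin) == 12, length(tmax) == 12, length(prec) == 12)
  arr <- function(v) {
    a <- array(NA_real_, c(spec$n_rows, spec$n_cols, 12))
    for (m in 1:12) a[, , m] <- v[m]
    a
  }
  structure(list(spec = spec, tmin = arr(tmin), tmax = arr(tmax),
                 prec = arr(prec)),
            class = "climate_stack")
}

# bioclim stack with layers taken from a named list of per-cell vectors
# (row-major); unspecified layers are zero
manual_bioclim <- function(spec, values) {
  layers <- array(0, c(spec$n_rows, spec$n_cols, 19),
                  dimnames = list(NULL, NULL, paste0("BIO", 1:19)))
  for (v in names(values))
    layers[, , v] <- matrix(values[[v]], spec$n_rows, spec$n_cols,
                            byrow = TRUE)
  structure(list(spec = spec, layers = layers), class = "bioclim_stack")
}

# binary map from explicit presence cells (row-major indices)
manual_binary <- function(spec, cells, species = "sp") {
  v <- rep(0, n_cells(spec))
  v[cells] <- 1
  binarize(matrix(v, spec$n_rows, spec$n_cols, byrow = TRUE), 0.5,
           species = species)
}

make_records <- function(species, lon, lat, date, source = "casual") {
  data.frame(species = species, lon = lon, lat = lat,
             date = as.Date(date), source = source, stringsAsFactors = FALSE)
}

# exhaustive pair-counting AUC oracle (ties 0.5)
auc_pairs <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}
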