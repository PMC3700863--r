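#' 10-percentile training-presence threshold
#'
#' The binarization cut-off below which the lowest 10% of training-presence
#' suitability values fall: with the values sorted ascending the threshold
#' is the value at index `floor(0.1 * m) + 1`, so at most `floor(0.1 * m)`
#' training presences sit strictly below it and at least 90% sit at or
#' above. Interpolation-free, hence exactly reproducible; ties stay at
#' presence.
#'
#' @param training_values Suitability values at training presences (>= 1).
#' @return The threshold value.
#' @export
ten_percentile_threshold <- function(training_values) {
  stopifnot(length(training_values) >= 1, all(is.finite(training_values)))
  v <- sort(training_values)
  v[floor(0.1 * length(v)) + 1L]
}

#' Binarize a suitability map
#'
#' Cells at or above the threshold become 1, below it 0; masked (`NA`)
#' cells are preserved. Using `>=` keeps the training presences that define
#' the threshold on the presence side.
#'
#' @param map Suitability matrix (see [logistic_output()]).
#' @param threshold Cut-off in `[0, 1]`.
#' @param species,period,scenario Optional metadata attached as attributes.
#' @return A `binary_map`: 0/1/`NA` matrix with attributes `threshold`,
#'   `species`, `period`, `scenario`.
#' @export
binarize <- function(map, threshold, species = NA_character_,
                     period = NA_character_, scenario = NA_character_) {
  stopifnot(is.matrix(map), threshold >= 0, threshold <= 1)
  out <- ifelse(is.na(map), NA_real_, as.numeric(map >= threshold))
  structure(out, threshold = threshold, species = species,
            period = period, scenario = scenario,
            class = c("binary_map", "matrix", "array"))
}

#' Cells predicted present in a binary map
#' @param map A `binary_map`.
#' @return Integer vector of row-major cell indices with value 1.
#' @export
presence_cells_of <- function(map) {
  which(as_cell_vector(unclass(map)) == 1)
}

#' Stack binary maps into a species-richness map
#'
#' Cellwise integer sum of per-species binary maps (one map per species, all
#' on one grid); `NA` cells stay `NA`.
#'
#' @param binaries List of `binary_map`s with distinct `species` attributes.
#' @return A `richness_map`: integer matrix with attribute `species`.
#' @export
stack_richness <- function(binaries) {
  stopifnot(length(binaries) >= 1)
  sp <- vapply(binaries, function(b) attr(b, "species"), character(1))
  if (anyDuplicated(sp[!is.na(sp)]))
    stop("stack_richness: duplicate species in the stack")
  d <- dim(binaries[[1]])
  for (b in binaries)
    if (!identical(dim(b), d)) stop("stack_richness: maps on different grids")
  out <- Reduce(`+`, lapply(binaries, function(b) {
    m <- unclass(b)
    attributes(m) <- list(dim = dim(m))
    m
  }))
  structure(out, species = sp, class = c("richness_map", "matrix", "array"))
}

#' Species richness change between periods
#'
#' Cellwise `future - current`; negative cells lose species, positive cells
#' gain them.
#'
#' @param current,future `richness_map`s on the same grid for the same
#'   species group.
#' @return Signed integer matrix.
#' @export
richness_change <- function(current, future) {
  if (!identical(dim(current), dim(future)))
    stop("richness_change: grid mismatch")
  out <- unclass(future) - unclass(current)
  attributes(out) <- list(dim = dim(out))
  out
}
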