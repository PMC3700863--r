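#' Pairwise Pearson correlation of bioclim layers
#'
#' Correlations are computed across unmasked cells, pairwise-complete on
#' `NA`s. A zero-variance layer has undefined correlations; those entries
#' are returned as `NA` and treated as "not correlated" downstream.
#'
#' @param bioclim A `bioclim_stack`.
#' @param vars Layer names; default all 19.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(bioclim, vars = NULL) {
  if (is.null(vars)) vars <- dimnames(bioclim$layers)[[3]]
  cells <- unmasked_cells(bioclim)
  if (length(cells) < 2)
    stop("pearson_matrix: need at least 2 unmasked cells")
  V <- bioclim_values(bioclim, cells, vars)
  r <- suppressWarnings(stats::cor(V, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' Default variable priority for collinearity screening
#'
#' Encodes the within-pair preference as an explicit ordered list: the eight
#' variables retained for the resident-species models, in their reported
#' importance order (BIO4, BIO1, BIO15, BIO12, BIO14, BIO8, BIO2, BIO3),
#' followed by the remaining layers in ascending number. A reproducible
#' stand-in for expert "biologically meaningful" choice.
#'
#' @return Character vector of the 19 layer names.
#' @export
default_bioclim_priority <- function() {
  head <- c("BIO4", "BIO1", "BIO15", "BIO12", "BIO14", "BIO8", "BIO2", "BIO3")
  c(head, setdiff(paste0("BIO", 1:19), head))
}

#' Greedy elimination of correlated variables
#'
#' Sweeps the candidates in priority order and accepts a variable iff its
#' absolute Pearson correlation with every already-accepted variable is
#' strictly below the threshold (so `|r|` exactly at the threshold counts as
#' highly correlated and eliminates). Deterministic given the priority
#' order; `NA` correlations (zero-variance layers) never block acceptance.
#'
#' @param r Correlation matrix with dimnames (see [pearson_matrix()]).
#' @param threshold `|r|` cutoff; default 0.75.
#' @param priority Ordered character vector covering all candidates;
#'   default [default_bioclim_priority()] restricted to `colnames(r)`.
#' @return A `variable_selection`: list with `retained` (ordered names),
#'   `threshold`, `priority`.
#' @export
eliminate_correlated <- function(r, threshold = 0.75, priority = NULL) {
  stopifnot(is.matrix(r), !is.null(colnames(r)))
  cand <- colnames(r)
  if (is.null(priority)) priority <- intersect(default_bioclim_priority(), cand)
  if (!all(cand %in% priority))
    stop("eliminate_correlated: priority must cover all candidates")
  priority <- intersect(priority, cand)
  retained <- character(0)
  for (v in priority) {
    rv <- abs(r[v, retained])
    if (!length(retained) || all(is.na(rv) | rv < threshold))
      retained <- c(retained, v)
  }
  structure(list(retained = retained, threshold = threshold,
                 priority = priority),
            class = "variable_selection")
}

#' @export
print.variable_selection <- function(x, ...) {
  cat("variable_selection:", paste(x$retained, collapse = ", "),
      sprintf("(|r| < %g)\n", x$threshold))
  invisible(x)
}

#' Warm-season substitution for migratory species
#'
#' Replaces annual-scale variables by their warm-quarter correlates: BIO1
#' (annual mean temperature) by BIO10 (mean temperature of warmest quarter)
#' and BIO14 (precipitation of driest month) by BIO18 (precipitation of
#' warmest quarter), which describe conditions during the season when summer
#' migrants are actually present. Order is preserved and no duplicates are
#' introduced if the replacement is already selected.
#'
#' @param selection A `variable_selection`.
#' @return The substituted `variable_selection`.
#' @export
migrant_substitution <- function(selection) {
  stopifnot(inherits(selection, "variable_selection"))
  sub <- c(BIO1 = "BIO10", BIO14 = "BIO18")
  out <- selection$retained
  for (from in names(sub)) {
    to <- sub[[from]]
    if (from %in% out) {
      if (to %in% out) out <- setdiff(out, from)
      else out[out == from] <- to
    }
  }
  selection$retained <- out
  selection
}

#' Write a correlation matrix as CSV
#' @param r Correlation matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(r, path) {
  utils::write.csv(as.data.frame(r), path, row.names = TRUE)
  invisible(path)
}

#' Write a variable selection as JSON
#' @param selection A `variable_selection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(unclass(selection), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
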