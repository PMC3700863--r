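#' Sample background cells
#'
#' Uniform sample without replacement from the unmasked cells, up to `n`
#' (all unmasked cells when fewer are available). Presence cells are
#' eligible: background represents the available environment, not absences.
#'
#' @param bioclim A `bioclim_stack`.
#' @param n Maximum number of background cells (default 10000).
#' @param seed Integer seed.
#' @return Sorted integer vector of cell indices.
#' @export
sample_background <- function(bioclim, n = 10000, seed = 1) {
  cells <- unmasked_cells(bioclim)
  if (length(cells) <= n) return(cells)
  withr::with_seed(as.integer(seed), sort(sample(cells, n)))
}

#' Build the model feature set
#'
#' For each selected variable: a linear and a quadratic feature, plus hinge
#' features `max(0, v - knot)` at `n_knots` knots placed at the background
#' quantiles (probabilities `0, 1/k, ..., (k-1)/k`). Every feature is
#' min-max scaled to `[0, 1]` over the background; the scaling parameters
#' are stored so projection onto other climate stacks reuses them, with
#' values outside the training range clamped to it (MaxEnt-style clamping).
#' Quadratic and hinge features that are constant on the background are
#' dropped with a message; a constant linear feature is kept as an all-zero
#' column so its weight simply stays 0.
#'
#' @param bioclim A `bioclim_stack` (the training stack).
#' @param selection A `variable_selection` or character vector of layer
#'   names.
#' @param background_cells Integer cell indices (>= 2) from
#'   [sample_background()].
#' @param hinge Include hinge features? (Disabled by the pipeline for small
#'   presence samples.)
#' @param quadratic Include quadratic features? (Linear-only sets are useful
#'   when the generating model is itself log-linear.)
#' @param n_knots Hinge knots per variable (default 10).
#' @return A `feature_set`: list with `vars`, `defs` (one row per feature:
#'   `name`, `var`, `type`, `knot`, `fmin`, `fmax`), `background_cells`,
#'   `F_bg` (background feature matrix), and the training `bioclim`.
#' @export
build_features <- function(bioclim, selection, background_cells,
                           hinge = TRUE, quadratic = TRUE, n_knots = 10) {
  vars <- if (inherits(selection, "variable_selection")) selection$retained
          else as.character(selection)
  stopifnot(length(vars) >= 1, length(background_cells) >= 2)
  V <- bioclim_values(bioclim, background_cells, vars)
  if (anyNA(V)) stop("build_features: background cells must be unmasked")
  defs <- list()
  for (v in vars) {
    x <- V[, v]
    defs[[length(defs) + 1L]] <-
      data.frame(name = paste0(v, ".lin"), var = v, type = "linear",
                 knot = NA_real_, stringsAsFactors = FALSE)
    if (quadratic)
      defs[[length(defs) + 1L]] <-
        data.frame(name = paste0(v, ".quad"), var = v, type = "quadratic",
                   knot = NA_real_, stringsAsFactors = FALSE)
    if (hinge) {
      knots <- unique(stats::quantile(
        x, probs = seq(0, 1, length.out = n_knots + 1)[seq_len(n_knots)],
        names = FALSE, type = 7))
      defs[[length(defs) + 1L]] <-
        data.frame(name = sprintf("%s.hinge%02d", v, seq_along(knots)),
                   var = v, type = "hinge", knot = knots,
                   stringsAsFactors = FALSE)
    }
  }
  defs <- do.call(rbind, defs)
  raw <- raw_features(defs, V)
  defs$fmin <- apply(raw, 2, min)
  defs$fmax <- apply(raw, 2, max)
  const <- defs$fmax - defs$fmin <= 0
  drop <- const & defs$type != "linear"
  if (any(drop))
    message("build_features: dropped ", sum(drop),
            " constant non-linear feature(s): ",
            paste(defs$name[drop], collapse = ", "))
  defs <- defs[!drop, , drop = FALSE]
  rownames(defs) <- NULL
  fs <- structure(list(vars = vars, defs = defs,
                       background_cells = background_cells,
                       bioclim = bioclim),
                  class = "feature_set")
  fs$F_bg <- feature_matrix(fs, bioclim, background_cells)
  fs
}

# raw (unscaled) feature columns for a variable-value matrix
raw_features <- function(defs, V) {
  out <- matrix(0, nrow(V), nrow(defs), dimnames = list(NULL, defs$name))
  for (j in seq_len(nrow(defs))) {
    x <- V[, defs$var[j]]
    out[, j] <- switch(defs$type[j],
                       linear = x,
                       quadratic = x^2,
                       hinge = pmax(0, x - defs$knot[j]))
  }
  out
}

#' Evaluate a feature set at grid cells
#'
#' Applies the stored feature definitions and background min-max scaling to
#' the given stack's values at `cells`; scaled values are clamped to
#' `[0, 1]` so projection never extrapolates beyond the training feature
#' range.
#'
#' @param fs A `feature_set`.
#' @param bioclim Stack to evaluate on (training stack or a projection
#'   stack on the same grid).
#' @param cells Integer cell indices.
#' @return `length(cells) x n_features` matrix in `[0, 1]`.
#' @export
feature_matrix <- function(fs, bioclim, cells) {
  V <- bioclim_values(bioclim, cells, fs$vars)
  raw <- raw_features(fs$defs, V)
  rng <- fs$defs$fmax - fs$defs$fmin
  sc <- sweep(raw, 2, fs$defs$fmin, "-")
  sc <- sweep(sc, 2, ifelse(rng > 0, rng, 1), "/")
  sc[, rng <= 0] <- 0
  pmin(pmax(sc, 0), 1)
}

#' Restrict a feature set to a subset of variables
#' @param fs A `feature_set`.
#' @param vars Variables to keep.
#' @return A `feature_set` over `vars`.
#' @export
subset_features <- function(fs, vars) {
  stopifnot(all(vars %in% fs$vars))
  keep <- fs$defs$var %in% vars
  fs$vars <- intersect(fs$vars, vars)
  fs$defs <- fs$defs[keep, , drop = FALSE]
  fs$F_bg <- fs$F_bg[, keep, drop = FALSE]
  fs
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit the maximum-entropy presence-only model
#'
#' Minimizes the L1-regularized negative log-likelihood of the Gibbs
#' distribution over background cells,
#' `-(1/m) sum_presence lambda.f(x) + log Z + sum_j beta * s_j * |lambda_j|`
#' with `Z = sum_background exp(lambda.f(x))` and per-feature scale
#' `s_j = sd(f_j over presences) / sqrt(m)` (MaxEnt's sample-size-adaptive
#' regularization). The objective is convex; it is minimized by proximal
#' gradient descent (soft-thresholding of the L1 term) with backtracking
#' line search, which makes the objective non-increasing across iterations.
#' Convergence is declared when the objective changes by less than `tol`.
#'
#' @param features A `feature_set` from [build_features()].
#' @param presence_cells Integer cell indices of (thinned) presences.
#' @param beta Regularization multiplier (default 1.0).
#' @param max_iter Iteration cap (default 1000).
#' @param tol Convergence threshold on the objective change (default 5e-5).
#' @return A `maxent_model`: list with `lambda` (named weights), `features`,
#'   `reg_scales`, `beta`, `logZ`, `entropy` (of the fitted background
#'   distribution), `presence_cells`, `n_iter`, `converged`, `objective`
#'   (final value) and `objective_path` (per-iteration values).
#' @export
fit_maxent <- function(features, presence_cells, beta = 1.0,
                       max_iter = 1000, tol = 5e-5) {
  stopifnot(inherits(features, "feature_set"), length(presence_cells) >= 1)
  Fb <- features$F_bg
  Fp <- feature_matrix(features, features$bioclim, presence_cells)
  if (anyNA(Fp)) stop("fit_maxent: presence cells must be unmasked")
  m <- nrow(Fp)
  p <- ncol(Fb)
  fbar <- colMeans(Fp)
  s <- sqrt(pmax(colMeans(Fp^2) - fbar^2, 0)) / sqrt(m)
  reg <- beta * s

  smooth_obj <- function(lam) {
    eta <- drop(Fb %*% lam)
    M <- max(eta)
    logZ <- M + log(sum(exp(eta - M)))
    list(value = -sum(fbar * lam) + logZ, eta = eta, logZ = logZ)
  }
  lam <- rep(0, p)
  so <- smooth_obj(lam)
  obj <- so$value + sum(reg * abs(lam))
  obj_path <- obj
  step <- 1
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    q <- exp(so$eta - so$logZ)
    grad <- -fbar + drop(crossprod(Fb, q))
    repeat {
      cand <- soft_threshold(lam - step * grad, step * reg)
      d <- cand - lam
      so_c <- smooth_obj(cand)
      if (so_c$value <= so$value + sum(grad * d) + sum(d^2) / (2 * step) ||
          step < 1e-12) break
      step <- step / 2
    }
    new_obj <- so_c$value + sum(reg * abs(cand))
    delta <- obj - new_obj
    lam <- cand
    so <- so_c
    obj <- new_obj
    obj_path <- c(obj_path, obj)
    step <- step * 1.25
    if (is.finite(delta) && abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fit_maxent: not converged in ", max_iter, " iterations")
  q <- exp(so$eta - so$logZ)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  names(lam) <- features$defs$name
  structure(list(lambda = lam, features = features, reg_scales = s,
                 beta = beta, logZ = so$logZ, entropy = H,
                 presence_cells = presence_cells,
                 n_iter = n_iter, converged = converged, objective = obj,
                 objective_path = obj_path),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "maxent_model: %d features over %s; %d presences, %d background\n",
    length(x$lambda), paste(x$features$vars, collapse = ", "),
    length(x$presence_cells), length(x$features$background_cells)))
  cat(sprintf("  beta = %g, entropy = %.4f, %d iterations%s\n", x$beta,
              x$entropy, x$n_iter,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Raw Gibbs probabilities over the background
#'
#' @param model A `maxent_model`.
#' @return Numeric vector summing to 1 over the background cells.
#' @export
raw_distribution <- function(model) {
  eta <- drop(model$features$F_bg %*% model$lambda)
  exp(eta - model$logZ)
}

#' Logistic suitability map
#'
#' Projects the fitted model onto a climate stack's unmasked cells and
#' applies the MaxEnt logistic transform `p = c q / (1 + c q)` with
#' `q(x) = exp(lambda.f(x)) / Z` and `c = exp(H)`, H the entropy of the
#' fitted background distribution. Under the uniform model this gives 0.5
#' everywhere.
#'
#' @param model A `maxent_model`.
#' @param bioclim Stack to project onto; default the training stack.
#' @return Matrix of suitabilities in `[0, 1]`; `NA` on masked cells.
#' @export
logistic_output <- function(model, bioclim = NULL) {
  if (is.null(bioclim)) bioclim <- model$features$bioclim
  spec <- bioclim$spec
  cells <- unmasked_cells(bioclim)
  p <- rep(NA_real_, n_cells(spec))
  if (length(cells)) {
    Fm <- feature_matrix(model$features, bioclim, cells)
    logq <- drop(Fm %*% model$lambda) - model$logZ
    p[cells] <- stats::plogis(model$entropy + logq)
  }
  as_grid_matrix(p, spec)
}

#' Logistic suitability at specific cells
#'
#' @param model A `maxent_model`.
#' @param cells Integer cell indices.
#' @param bioclim Stack to evaluate on; default the training stack.
#' @return Numeric vector of suitabilities.
#' @export
predict_cells <- function(model, cells, bioclim = NULL) {
  if (is.null(bioclim)) bioclim <- model$features$bioclim
  Fm <- feature_matrix(model$features, bioclim, cells)
  logq <- drop(Fm %*% model$lambda) - model$logZ
  stats::plogis(model$entropy + logq)
}

#' Random train/test split of presences
#'
#' `round(test_fraction * m)` presences are held out at random for testing;
#' the split is disjoint and exhaustive. With fewer than 4 presences the
#' test set is empty and a warning is raised.
#'
#' @param presence_cells Integer vector of presence cells.
#' @param test_fraction Held-out fraction (default 0.25).
#' @param seed Integer seed.
#' @return List with `train` and `test` integer vectors.
#' @export
split_train_test <- function(presence_cells, test_fraction = 0.25, seed = 1) {
  m <- length(presence_cells)
  if (m < 4) {
    warning("split_train_test: fewer than 4 presences; empty test set")
    return(list(train = presence_cells, test = integer(0)))
  }
  n_test <- round(test_fraction * m)
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(m, n_test)
    list(train = presence_cells[-idx], test = presence_cells[idx])
  })
}

#' Rank-based AUC
#'
#' Mann-Whitney form: the fraction of presence-background score pairs in
#' which the presence scores higher, ties counted 0.5 — computed via
#' midranks. 0.5 is random ranking, 1 a perfect ranker.
#'
#' @param pos Scores at presences.
#' @param neg Scores at background points.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pos, neg) {
  m <- length(pos)
  n <- length(neg)
  stopifnot(m > 0, n > 0)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Jackknife variable importance
#'
#' Refits the model with each variable excluded and with each variable
#' alone, reporting the training AUC of every refit, plus the percent
#' contribution of each variable in the full model (its share of
#' `sum_j |lambda_j * s_j|` over that variable's features).
#'
#' @param features A `feature_set` (>= 2 variables for the
#'   excluded-variable refits; with a single variable they are skipped).
#' @param presence_cells Training presence cells.
#' @param beta,max_iter,tol Passed to [fit_maxent()].
#' @return Data.frame with columns `variable`, `auc_without`, `auc_only`,
#'   `contribution_pct`, plus attribute `auc_full`.
#' @export
jackknife_importance <- function(features, presence_cells, beta = 1.0,
                                 max_iter = 1000, tol = 5e-5) {
  vars <- features$vars
  full <- fit_maxent(features, presence_cells, beta, max_iter, tol)
  train_auc <- function(model) {
    sc_p <- predict_cells(model, presence_cells)
    sc_b <- predict_cells(model, model$features$background_cells)
    auc(sc_p, sc_b)
  }
  auc_full <- train_auc(full)
  w <- abs(full$lambda * full$reg_scales)
  contrib <- vapply(vars, function(v)
    sum(w[full$features$defs$var == v]), numeric(1))
  contrib <- if (sum(contrib) > 0) 100 * contrib / sum(contrib)
             else rep(0, length(vars))
  res <- data.frame(variable = vars,
                    auc_without = NA_real_, auc_only = NA_real_,
                    contribution_pct = as.numeric(contrib),
                    stringsAsFactors = FALSE)
  for (k in seq_along(vars)) {
    if (length(vars) >= 2) {
      m_wo <- fit_maxent(subset_features(features, setdiff(vars, vars[k])),
                         presence_cells, beta, max_iter, tol)
      res$auc_without[k] <- train_auc(m_wo)
    }
    m_on <- fit_maxent(subset_features(features, vars[k]),
                       presence_cells, beta, max_iter, tol)
    res$auc_only[k] <- train_auc(m_on)
  }
  attr(res, "auc_full") <- auc_full
  res
}

#' Serialize a fitted model as JSON
#'
#' Stores feature definitions, scaling, weights, normalizer, entropy and
#' metadata (not the training stack itself).
#'
#' @param model A `maxent_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maxent_model <- function(model, path) {
  out <- list(lambda = as.list(model$lambda),
              defs = model$features$defs,
              vars = model$features$vars,
              beta = model$beta,
              reg_scales = as.numeric(model$reg_scales),
              logZ = model$logZ, entropy = model$entropy,
              n_presences = length(model$presence_cells),
              n_background = length(model$features$background_cells),
              n_iter = model$n_iter, converged = model$converged,
              objective = model$objective)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
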