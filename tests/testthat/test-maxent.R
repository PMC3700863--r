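# 1 x 3 grid with one variable whose scaled feature values are (0, 0.5, 1)
toy_3cell <- function() {
  spec <- tiny_spec(1, 3)
  bc <- manual_bioclim(spec, list(BIO1 = c(0, 5, 10)))
  fs <- build_features(bc, "BIO1", 1:3, hinge = FALSE, quadratic = FALSE)
  list(spec = spec, bc = bc, fs = fs)
}

test_that("features are min-max scaled over background with quantile hinge knots", {
  spec <- tiny_spec(2, 5, cell = 0.4)
  v <- c(3, 7, 1, 9, 5, 2, 8, 4, 6, 0)
  bc <- manual_bioclim(spec, list(BIO1 = v))
  fs <- build_features(bc, "BIO1", 1:10, hinge = FALSE, quadratic = FALSE)
  expect_equal(unname(fs$F_bg[, "BIO1.lin"]), (v - min(v)) / diff(range(v)))
  fs2 <- build_features(bc, "BIO1", 1:10, hinge = TRUE, n_knots = 10)
  knots <- fs2$defs$knot[fs2$defs$type == "hinge"]
  expect_equal(knots,
               unname(quantile(v, probs = seq(0, 0.9, by = 0.1), type = 7)))
  expect_true(all(fs2$F_bg >= 0 & fs2$F_bg <= 1))
})

test_that("projection clamps features to the training range", {
  spec <- tiny_spec(1, 4, cell = 0.4)
  bc <- manual_bioclim(spec, list(BIO1 = c(0, 1, 2, 3)))
  fs <- build_features(bc, "BIO1", 1:4, hinge = FALSE)
  hot <- manual_bioclim(spec, list(BIO1 = c(-5, 1, 2, 50)))
  Fm <- feature_matrix(fs, hot, 1:4)
  expect_true(all(Fm >= 0 & Fm <= 1))
  expect_equal(unname(Fm[, "BIO1.lin"]), c(0, 1 / 3, 2 / 3, 1))
})

test_that("a constant variable keeps weight zero and sheds its nonlinear features", {
  spec <- tiny_spec(1, 4, cell = 0.4)
  bc <- manual_bioclim(spec, list(BIO1 = c(0, 1, 2, 3), BIO2 = rep(4, 4)))
  expect_message(fs <- build_features(bc, c("BIO1", "BIO2"), 1:4,
                                      hinge = TRUE),
                 "constant non-linear")
  expect_false(any(fs$defs$var == "BIO2" & fs$defs$type != "linear"))
  m <- fit_maxent(fs, c(4, 4, 3), beta = 0.1)
  expect_equal(unname(m$lambda["BIO2.lin"]), 0)
})

test_that("matched presence and background feature means give the uniform distribution", {
  spec <- tiny_spec(3, 4)
  bc <- manual_bioclim(spec, list(BIO1 = seq_len(12), BIO12 = (1:12)^1.5))
  fs <- build_features(bc, c("BIO1", "BIO12"), 1:12, hinge = FALSE)
  m <- fit_maxent(fs, presence_cells = 1:12, beta = 0)
  q <- raw_distribution(m)
  expect_equal(q, rep(1 / 12, 12), tolerance = 1e-6)
  expect_true(all(abs(m$lambda) < 1e-8))
  expect_equal(m$entropy, log(12), tolerance = 1e-6)
  # uniform model: logistic output is exactly 0.5 everywhere
  p <- logistic_output(m)
  expect_equal(as.vector(p), rep(0.5, 12), tolerance = 1e-6)
})

test_that("the fitted weight matches a fine 1-D grid-search oracle on the 3-cell toy", {
  toy <- toy_3cell()
  m <- fit_maxent(toy$fs, presence_cells = c(2, 3, 3), beta = 0,
                  max_iter = 50000, tol = 1e-13)
  fbar <- 5 / 6
  grid <- seq(0, 10, by = 1e-4)
  obj <- -fbar * grid +
    log(1 + exp(0.5 * grid) + exp(grid))
  lam_star <- grid[which.min(obj)]
  expect_equal(unname(m$lambda[1]), lam_star, tolerance = 1e-3)
  # logistic values match the hand formula p = c q / (1 + c q), c = exp(H)
  q <- raw_distribution(m)
  H <- -sum(q * log(q))
  p_hand <- (exp(H) * q) / (1 + exp(H) * q)
  expect_equal(unname(predict_cells(m, 1:3)), unname(p_hand),
               tolerance = 1e-9)
})

test_that("with presences at the best cell the distribution concentrates there", {
  toy <- toy_3cell()
  m <- suppressWarnings(fit_maxent(toy$fs, presence_cells = c(3, 3, 3),
                                   beta = 0))
  q <- raw_distribution(m)
  expect_gt(q[3], 0.95)
  expect_equal(sum(q), 1, tolerance = 1e-10)
})

test_that("the raw distribution sums to one and the objective never increases", {
  spec <- tiny_spec(6, 7)
  bc <- derive_bioclim(make_climate(spec, seed = 14))
  occ <- sample_occurrences(truth_model(c(BIO1 = -1.5)), bc, 120, seed = 15)
  ps <- rasterize_presences(occ, spec)
  for (beta in c(0, 0.5, 1)) {
    fs <- build_features(bc, c("BIO1", "BIO12", "BIO4"),
                         unmasked_cells(bc))
    m <- fit_maxent(fs, ps$cells, beta = beta)
    expect_equal(sum(raw_distribution(m)), 1, tolerance = 1e-10)
    expect_true(all(diff(m$objective_path) <= 1e-12))
    expect_true(m$entropy >= 0 &&
                  m$entropy <= log(length(fs$background_cells)) + 1e-9)
  }
})

test_that("increasing the regularization multiplier never grows the weight mass", {
  spec <- tiny_spec(6, 7)
  bc <- derive_bioclim(make_climate(spec, seed = 16))
  occ <- sample_occurrences(truth_model(c(BIO12 = 1.2)), bc, 150, seed = 17)
  ps <- rasterize_presences(occ, spec)
  fs <- build_features(bc, c("BIO1", "BIO12"), unmasked_cells(bc))
  l1 <- vapply(c(0.1, 0.5, 1, 2, 5), function(b)
    sum(abs(fit_maxent(fs, ps$cells, beta = b, max_iter = 20000,
                       tol = 1e-8)$lambda)),
    numeric(1))
  expect_true(all(diff(l1) <= 1e-6))
})

test_that("linear-feature truth weights are recovered from synthetic occurrences", {
  spec <- tiny_spec(20, 20, cell = 0.2)
  bc <- derive_bioclim(make_climate(spec, seed = 18))
  truth <- truth_model(c(BIO1 = 1.2))
  occ <- sample_occurrences(truth, bc, 500, seed = 19)
  cells <- cell_at(spec, occ$lon, occ$lat)  # unthinned: keep the sample size
  fs <- build_features(bc, "BIO1", unmasked_cells(bc), hinge = FALSE,
                       quadratic = FALSE)
  m <- fit_maxent(fs, cells, beta = 0.01, tol = 1e-9)
  v <- bioclim_values(bc, unmasked_cells(bc), "BIO1")
  lam_std <- unname(m$lambda[1]) * sd(v) / diff(range(v))
  expect_lt(abs(lam_std - 1.2) / 1.2, 0.15)
})

test_that("train/test splitting is a seeded disjoint exhaustive partition", {
  cells <- sample.int(5000, 100)
  s <- split_train_test(cells, seed = 3)
  expect_equal(length(s$test), 25)
  expect_equal(length(s$train), 75)
  expect_setequal(c(s$train, s$test), cells)
  expect_length(intersect(s$train, s$test), 0)
  expect_identical(s, split_train_test(cells, seed = 3))
  expect_false(identical(s, split_train_test(cells, seed = 4)))
  expect_warning(s3 <- split_train_test(1:3), "fewer than 4")
  expect_equal(s3$train, 1:3)
  expect_length(s3$test, 0)
})

test_that("rank-based AUC matches exhaustive pair counting, with 0.5 for ties", {
  expect_equal(auc(c(0.8, 0.9), c(0.1, 0.2)), 1)
  expect_equal(auc(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  expect_equal(auc(rep(0.4, 5), rep(0.4, 7)), 0.5)
  set.seed(123)
  for (trial in 1:50) {
    pos <- sample(seq(0, 1, 0.1), sample(1:20, 1), replace = TRUE)
    neg <- sample(seq(0, 1, 0.1), sample(1:20, 1), replace = TRUE)
    expect_equal(auc(pos, neg), auc_pairs(pos, neg))
  }
})

test_that("jackknife importance is redundant-proof and its contributions sum to 100", {
  spec <- tiny_spec(6, 8)
  z <- sin(seq_len(n_cells(spec)) / 5)
  set.seed(44)
  noise <- rnorm(n_cells(spec))
  bc <- manual_bioclim(spec, list(BIO1 = z, BIO2 = z, BIO3 = noise))
  occ <- sample_occurrences(truth_model(c(BIO1 = 2)), bc, 200, seed = 45)
  cells <- cell_at(spec, occ$lon, occ$lat)
  bg <- seq_len(n_cells(spec))

  # duplicated variable: dropping one copy leaves the training AUC unchanged
  fs_dup <- build_features(bc, c("BIO1", "BIO2"), bg, hinge = FALSE)
  jk <- jackknife_importance(fs_dup, cells, beta = 0.5, tol = 1e-10)
  expect_equal(jk$auc_without[jk$variable == "BIO2"],
               attr(jk, "auc_full"), tolerance = 1e-6)
  expect_equal(sum(jk$contribution_pct), 100)

  # removing the signal variable hurts more than removing pure noise
  fs <- build_features(bc, c("BIO1", "BIO3"), bg, hinge = FALSE)
  jk2 <- jackknife_importance(fs, cells, beta = 0.5)
  expect_gte(jk2$auc_without[jk2$variable == "BIO3"],
             jk2$auc_without[jk2$variable == "BIO1"])
  expect_equal(sum(jk2$contribution_pct), 100)
  expect_gt(attr(jk2, "auc_full"), 0.5)  # beats the uniform model in training
})

test_that("model serialization writes the complete model description", {
  toy <- toy_3cell()
  m <- fit_maxent(toy$fs, c(2, 3, 3), beta = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent_model(m, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$lambda$BIO1.lin, unname(m$lambda[1]))
  expect_equal(back$entropy, m$entropy)
  expect_equal(back$n_presences, 3)
  expect_true(back$converged)
})
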