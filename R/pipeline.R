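# deterministic child seed from a master seed and a stage/species tag
child_seed <- function(master, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483646 + 1)
}

#' Demo pipeline configuration on synthetic data
#'
#' Builds a self-contained configuration: a 20 x 30 grid (0.3 deg cells over
#' 26-35 deg E, 36-42 deg N), synthetic climate, three species with known
#' truth models (a cool-adapted and a wet-adapted resident plus a
#' warm-season migrant; the cool-adapted range shifts north under warming),
#' and two scenario families of additive warming and precipitation scaling
#' for 2020/2050/2080 with magnitudes in line with mid-range GCM anomalies
#' for the region.
#'
#' @param seed Master seed.
#' @param n_per_species Records generated per species (default 200).
#' @return A config list consumable by [run_pipeline()].
#' @export
demo_config <- function(seed = 1, n_per_species = 200) {
  list(
    grid = list(lon_min = 26, lon_max = 35, lat_min = 36, lat_max = 42,
                cell_size = 0.3),
    box = c(26, 35, 36, 42),
    synthetic = list(
      smoothness = 3,
      species = list(
        resident_cool = list(group = "resident",
                             weights = list(BIO1 = -2.0),
                             window = c("02-01", "11-30")),
        resident_wet = list(group = "resident",
                            weights = list(BIO12 = 1.5),
                            window = c("02-01", "11-30")),
        migrant_warm = list(group = "migratory",
                            weights = list(BIO10 = 1.0, BIO18 = 0.8),
                            window = c("04-01", "08-31"))),
      n_per_species = n_per_species),
    scenarios = list(
      A2a = list(`2020` = list(delta_t = 1.0, precip_factor = 0.95),
                 `2050` = list(delta_t = 2.0, precip_factor = 0.90),
                 `2080` = list(delta_t = 3.5, precip_factor = 0.85)),
      B2a = list(`2020` = list(delta_t = 0.8, precip_factor = 0.97),
                 `2050` = list(delta_t = 1.5, precip_factor = 0.94),
                 `2080` = list(delta_t = 2.5, precip_factor = 0.90))),
    filters = list(min_records = 25),
    selection = list(threshold = 0.75),
    maxent = list(beta = 1.0, max_iter = 1000, tol = 5e-5,
                  n_background = 10000, test_fraction = 0.25,
                  hinge_min_presences = 15, n_knots = 10),
    seed = as.integer(seed))
}

#' Run the full modelling pipeline
#'
#' Sequences every stage: climate generation (or loading), bounding-box
#' masking, bioclim derivation for the current period and every scenario x
#' period, occurrence generation (or loading) and the record filters
#' (source, season, minimum count), correlation-based variable selection
#' with the migrant substitution, per-species maximum-entropy fitting with
#' train/test AUC, 10-percentile thresholding and binarization, per-group
#' richness and richness-change maps, per-species range-change records, and
#' same-species turnover. Every artifact is written under `out_dir` and
#' listed with an MD5 checksum in `manifest.json`; the run is deterministic
#' under the config's master seed.
#'
#' @param config Config list (see [demo_config()]) or path to a YAML file
#'   with the same structure.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly: list with `summary`, `selection`,
#'   `models` (per-species AUC/threshold table), `range_change`, `turnover`,
#'   `files`, `config`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  g <- config$grid
  spec <- grid_spec(g$lon_min, g$lon_max, g$lat_min, g$lat_max, g$cell_size)
  log <- list()

  # --- climate for every period/scenario -------------------------------
  if (!is.null(config$synthetic)) {
    current <- make_climate(spec, seed = child_seed(seed, "climate"),
                            smoothness = config$synthetic$smoothness)
  } else {
    current <- read_climate(config$paths$climate_current)
  }
  current <- mask_to_box(current, config$box)
  stacks <- list(current = derive_bioclim(current))
  for (sc in names(config$scenarios)) {
    for (per in names(config$scenarios[[sc]])) {
      d <- config$scenarios[[sc]][[per]]
      fut <- if (!is.null(config$synthetic)) {
        perturb_climate(current, d$delta_t, d$precip_factor)
      } else {
        mask_to_box(read_climate(config$paths$climate[[sc]][[per]]),
                    config$box)
      }
      stacks[[paste(sc, per, sep = "_")]] <- derive_bioclim(fut)
    }
  }

  # --- occurrences ------------------------------------------------------
  sp_cfg <- config$synthetic$species
  groups <- if (!is.null(sp_cfg)) {
    data.frame(species = names(sp_cfg),
               group = vapply(sp_cfg, `[[`, character(1), "group"),
               stringsAsFactors = FALSE)
  } else {
    utils::read.csv(config$paths$groups, stringsAsFactors = FALSE)
  }
  occ_path <- file.path(out_dir, "occurrences.csv")
  if (!is.null(sp_cfg)) {
    recs <- do.call(rbind, lapply(names(sp_cfg), function(sp) {
      cfg <- sp_cfg[[sp]]
      sample_occurrences(
        truth_model(unlist(cfg$weights)), stacks$current,
        n = config$synthetic$n_per_species,
        seed = child_seed(seed, paste0("occ_", sp)), species = sp,
        window = cfg$window)
    }))
    write_occurrences(recs, occ_path)
  } else {
    file.copy(config$paths$occurrences, occ_path, overwrite = TRUE)
  }
  records <- read_occurrences(occ_path)
  log$n_read <- nrow(records)
  records <- filter_sources(records)
  log$n_after_sources <- nrow(records)
  records <- suppressMessages(filter_season(records, groups))
  log$n_after_season <- nrow(records)
  records <- suppressMessages(
    filter_min_records(records, config$filters$min_records))
  log$n_after_min_records <- nrow(records)
  log$coverage_fraction <- coverage_fraction(records, spec)
  summary_tab <- summarize_records(records, groups)

  # --- variable selection on the current period ------------------------
  rmat <- pearson_matrix(stacks$current)
  sel_res <- eliminate_correlated(rmat, config$selection$threshold)
  sel_mig <- migrant_substitution(sel_res)
  write_correlation(rmat, file.path(out_dir, "correlation.csv"))
  write_selection(sel_res, file.path(out_dir, "selection_resident.json"))
  write_selection(sel_mig, file.path(out_dir, "selection_migratory.json"))

  # --- per-species models and projections ------------------------------
  mx <- config$maxent
  species <- summary_tab$species$species
  model_rows <- list()
  change_rows <- list()
  binaries <- list()  # binaries[[stack_name]][[species]]
  future_names <- setdiff(names(stacks), "current")
  for (sp in species) {
    grp <- groups$group[match(sp, groups$species)]
    sel <- if (identical(grp, "migratory")) sel_mig else sel_res
    ps <- rasterize_presences(records[records$species == sp, , drop = FALSE],
                              spec)
    split <- split_train_test(ps$cells, mx$test_fraction,
                              seed = child_seed(seed, paste0("split_", sp)))
    bg <- sample_background(stacks$current, mx$n_background,
                            seed = child_seed(seed, paste0("bg_", sp)))
    fs <- suppressMessages(build_features(
      stacks$current, sel, bg,
      hinge = length(split$train) >= mx$hinge_min_presences,
      n_knots = mx$n_knots))
    model <- fit_maxent(fs, split$train, beta = mx$beta,
                        max_iter = mx$max_iter, tol = mx$tol)
    write_maxent_model(model,
                       file.path(out_dir, paste0("model_", sp, ".json")))
    sc_bg <- predict_cells(model, bg)
    train_vals <- predict_cells(model, split$train)
    auc_train <- auc(train_vals, sc_bg)
    auc_test <- if (length(split$test))
      auc(predict_cells(model, split$test), sc_bg) else NA_real_
    thr <- ten_percentile_threshold(train_vals)
    model_rows[[sp]] <- data.frame(
      species = sp, group = grp, n_presence_cells = length(ps$cells),
      n_train = length(split$train), n_test = length(split$test),
      auc_train = auc_train, auc_test = auc_test, threshold = thr,
      converged = model$converged, stringsAsFactors = FALSE)
    for (nm in names(stacks)) {
      suit <- logistic_output(model, stacks[[nm]])
      bm <- binarize(suit, thr, species = sp, period = nm)
      binaries[[nm]][[sp]] <- bm
      write_ascii_grid(unclass(bm), spec,
                       file.path(out_dir,
                                 sprintf("binary_%s_%s.asc", sp, nm)))
    }
    for (nm in future_names) {
      sc_per <- strsplit(nm, "_")[[1]]
      change_rows[[paste(sp, nm)]] <- range_change(
        binaries$current[[sp]], binaries[[nm]][[sp]], spec,
        species = sp, scenario = sc_per[1], period = sc_per[2])
    }
  }
  model_tab <- do.call(rbind, model_rows)
  change_tab <- do.call(rbind, change_rows)
  rownames(model_tab) <- rownames(change_tab) <- NULL
  utils::write.csv(model_tab, file.path(out_dir, "models.csv"),
                   row.names = FALSE)
  utils::write.csv(change_tab, file.path(out_dir, "range_change.csv"),
                   row.names = FALSE)

  # --- richness and turnover per group and scenario --------------------
  turnover <- list()
  for (grp in unique(groups$group)) {
    grp_sp <- intersect(species, groups$species[groups$group == grp])
    if (!length(grp_sp)) next
    for (nm in names(stacks)) {
      rich <- stack_richness(binaries[[nm]][grp_sp])
      write_ascii_grid(unclass(rich), spec,
                       file.path(out_dir,
                                 sprintf("richness_%s_%s.asc", grp, nm)))
    }
    for (sc in names(config$scenarios)) {
      periods <- c("current", paste(sc, names(config$scenarios[[sc]]),
                                    sep = "_"))
      by_sp <- lapply(grp_sp, function(sp) {
        out <- binaries[periods]
        stats::setNames(lapply(out, `[[`, sp),
                        c("current", names(config$scenarios[[sc]])))
      })
      names(by_sp) <- grp_sp
      tv <- suppressMessages(turnover_same_species(by_sp))
      turnover[[paste(grp, sc, sep = "_")]] <- tv
      utils::write.csv(tv$species,
                       file.path(out_dir,
                                 sprintf("turnover_%s_%s.csv", grp, sc)),
                       row.names = FALSE)
    }
  }

  # --- manifest ---------------------------------------------------------
  jsonlite::write_json(log, file.path(out_dir, "filter_log.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(summary = summary_tab, selection = sel_res$retained,
                   selection_migratory = sel_mig$retained,
                   models = model_tab, range_change = change_tab,
                   turnover = turnover, filter_log = log,
                   files = checksums, seed = seed, config = config)
  jsonlite::write_json(
    list(files = checksums, seed = seed, filter_log = log),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Per-species record counts of the study reference tables
#'
#' The per-species presence-record counts and group labels distributed with
#' the package (columns `species`, `group`, `n`), usable as input to
#' [summarize_records()] for record accounting.
#'
#' @return Data.frame with columns `species`, `group`, `n`.
#' @export
species_counts_table <- function() {
  utils::read.csv(system.file("extdata", "species_counts.csv",
                              package = "sdmshift"),
                  stringsAsFactors = FALSE)
}
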