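#' Default run configuration
#'
#' All defaults are the published analysis conventions: 500 pseudo-absences
#' at the coarse level and 200 at the fine level, 10-fold cross-validation,
#' AUC consensus cutoff 0.7, sensitivity floor 0.9, target percentages 100
#' (smallest range) and 5 (largest), 1% priority envelopes, and 30000
#' Monte-Carlo permutations.
#'
#' @param seed Master seed; every stage seed is derived from it.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    schema_version = 1L,
    paths = list(records = "synthetic", predictors = "synthetic",
                 reserves = "synthetic"),
    synthetic = list(fine_rows = 72L, fine_cols = 72L, origin_lon = 10,
                     origin_lat = 0, fine_cell_size = 0.25, k = 4L,
                     n_species = 6L, n_predictors = 4L,
                     records_per_species = c(1L, 12L, 25L, 50L, 80L, 160L),
                     reserve_fraction = 0.12, coef_sd = 3),
    sdm = list(n_pseudo_absences_coarse = 500L, n_pseudo_absences_fine = 200L,
               folds = 10L, learners = c("logistic", "brt", "rf"),
               auc_cutoff = 0.7, sensitivity_floor = 0.9,
               min_records_for_model = 2L),
    priority = list(exact_limit = 20L, n_samples = 10000L),
    targets = list(pct_smallest = 100, pct_largest = 5),
    cross_scale = list(envelope_fraction = 0.01, n_perm = 30000L),
    seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys present in the file override the defaults of [default_config()].
#'
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- default_config(seed = if (!is.null(usr$seed)) usr$seed else 1L)
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_in(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  out <- merge_in(unclass(cfg), usr)
  class(out) <- "run_config"
  out
}

#' Validate a run configuration
#'
#' Checks value ranges, grid nesting and learner availability without
#' mutating anything; all problems are accumulated rather than thrown.
#'
#' @param config A `run_config`.
#' @return Character vector of error messages; `character(0)` when valid.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)
  cs <- config$cross_scale
  if (is.null(cs$envelope_fraction) || cs$envelope_fraction <= 0 || cs$envelope_fraction >= 1)
    push("envelope fraction must be in (0,1)")
  if (is.null(cs$n_perm) || cs$n_perm < 1) push("n_perm must be >= 1")
  sdm <- config$sdm
  if (is.null(sdm$auc_cutoff) || sdm$auc_cutoff < 0.5 || sdm$auc_cutoff > 1)
    push("auc_cutoff must be in [0.5, 1]")
  if (is.null(sdm$sensitivity_floor) || sdm$sensitivity_floor <= 0 || sdm$sensitivity_floor > 1)
    push("sensitivity_floor must be in (0, 1]")
  if (any(c(sdm$n_pseudo_absences_coarse, sdm$n_pseudo_absences_fine) < 1))
    push("pseudo-absence counts must be >= 1")
  if (is.null(sdm$folds) || sdm$folds < 2) push("folds must be >= 2")
  known <- c("logistic", "brt", "rf")
  bad <- setdiff(sdm$learners, known)
  if (length(bad)) push(paste0("unknown learners: ", paste(bad, collapse = ", ")))
  tg <- config$targets
  if (tg$pct_smallest <= 0 || tg$pct_smallest > 100 ||
      tg$pct_largest <= 0 || tg$pct_largest > 100 ||
      tg$pct_largest > tg$pct_smallest)
    push("target percentages must satisfy 0 < pct_largest <= pct_smallest <= 100")
  syn <- config$synthetic
  if (!is.null(syn)) {
    if (syn$k < 2 || syn$fine_rows %% syn$k != 0 || syn$fine_cols %% syn$k != 0)
      push("coarse cell not an integer multiple of fine: fine grid dimensions must be divisible by k >= 2")
    if (syn$reserve_fraction < 0 || syn$reserve_fraction > 0.5)
      push("reserve_fraction must be in [0, 0.5]")
  }
  pr <- config$priority
  if (pr$exact_limit < 1 || pr$exact_limit > 25) push("exact_limit must be in [1, 25]")
  if (pr$n_samples < 1000) push("n_samples must be >= 1000")
  errs
}

config_learners <- function(names) {
  all <- default_learners()
  all[names]
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# one analysis level: screened predictors -> per-species ranges -> priority
# maps -> gap report
run_level <- function(stack, records, reserves, reserve_area, config, level,
                      seed, log = message) {
  sdm <- config$sdm
  n_pa <- if (level == "coarse") sdm$n_pseudo_absences_coarse else sdm$n_pseudo_absences_fine
  learners <- config_learners(sdm$learners)
  spp <- sort(unique(records$species))
  spec <- stack$grid
  log(sprintf("[%s] screening predictors (VIF < 5)", level))
  stack <- vif_screen(stack)
  ranges <- list(); reports <- list()
  for (i in seq_along(spp)) {
    sp <- spp[i]
    xy <- as.matrix(records[records$species == sp, c("lon", "lat")])
    res <- build_species_range(stack, xy, n_pseudo_absences = n_pa,
                               learners = learners, folds = sdm$folds,
                               seed = derive_seed(seed, 1000L + i),
                               auc_cutoff = sdm$auc_cutoff,
                               sensitivity_floor = sdm$sensitivity_floor,
                               min_records_for_model = sdm$min_records_for_model)
    ranges[[sp]] <- res$range$layer
    reports[[sp]] <- data.frame(
      species = sp, level = level, n_records = nrow(xy),
      modelled = res$modelled,
      auc_logistic = if (res$modelled) res$ensemble$auc[["logistic"]] else NA,
      auc_brt = if (res$modelled) res$ensemble$auc[["brt"]] else NA,
      auc_rf = if (res$modelled) res$ensemble$auc[["rf"]] else NA,
      threshold = if (res$modelled) res$threshold$threshold else NA,
      criterion = if (res$modelled) res$threshold$criterion else "occupied cells",
      range_cells = sum(res$range$layer), d_bar = res$range$d_bar,
      stringsAsFactors = FALSE)
    log(sprintf("[%s] %s: %d records -> %d range cells%s", level, sp, nrow(xy),
                sum(res$range$layer),
                if (res$modelled) sprintf(" (mean AUC %.3f)",
                                          mean(reports[[sp]][1, c("auc_logistic", "auc_brt", "auc_rf")],
                                               na.rm = TRUE)) else " (record cells only)"))
  }
  model_report <- do.call(rbind, reports)
  rich <- richness(ranges)
  range_sets <- lapply(ranges, function(r) layer_which(r, r == 1L))
  targets <- set_targets(lengths(range_sets),
                         pct_smallest = config$targets$pct_smallest,
                         pct_largest = config$targets$pct_largest)
  cov <- reserve_coverage(spec, reserves)
  thr <- coverage_threshold(cov, spec$cell_size^2, reserve_area)
  prot <- protected_cells(cov, thr$threshold)
  gap <- gap_analysis(range_sets, prot, targets)
  log(sprintf("[%s] coverage threshold %.4f -> %d protected cells", level,
              thr$threshold, length(prot)))
  cons <- conservation_value(ranges, targets,
                             exact_limit = config$priority$exact_limit,
                             n_samples = config$priority$n_samples,
                             seed = derive_seed(seed, 2001L))
  comp <- complementarity(ranges, targets, prot,
                          exact_limit = config$priority$exact_limit,
                          n_samples = config$priority$n_samples,
                          seed = derive_seed(seed, 2002L))
  list(spec = spec, stack = stack, ranges = ranges, range_sets = range_sets,
       model_report = model_report, richness = rich, targets = targets,
       coverage = cov, coverage_threshold = thr, protected = prot,
       gap = gap, conservation_value = cons, complementarity = comp)
}

#' Run the full two-level prioritization pipeline
#'
#' Sequences predictor preparation, per-species ensemble modelling and range
#' construction, priority mapping, reserve gap analysis at both resolutions,
#' and the cross-scale congruence report. All randomness derives from the
#' master seed; two runs with the same config are identical.
#'
#' @param config A `run_config` (see [default_config()], [read_config()]).
#' @param out_dir Optional directory; when given, layers (ESRI ASCII), tables
#'   (CSV) and the manifest (JSON) are written there.
#' @param quiet Suppress per-stage log messages.
#' @return List with `levels` (`$coarse`, `$fine` stage outputs),
#'   `cross_scale` report, `world` (when synthetic) and `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL, quiet = FALSE) {
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))
  log <- if (quiet) function(...) invisible() else function(msg) message(msg)
  seed <- config$seed
  t0 <- Sys.time()

  stage <- "input"
  world <- NULL
  if (identical(config$paths$records, "synthetic")) {
    stage <- "synthetic_landscape"
    syn <- config$synthetic
    fine_spec <- grid_spec(syn$origin_lon, syn$origin_lat, syn$fine_cell_size,
                           syn$fine_rows, syn$fine_cols)
    world <- make_world(derive_seed(seed, 1L), fine_spec, k = syn$k,
                        n_species = syn$n_species, n_predictors = syn$n_predictors,
                        records_per_species = syn$records_per_species,
                        reserve_fraction = syn$reserve_fraction,
                        coef_sd = syn$coef_sd)
    fine_stack <- world$predictors
    records <- world$records
    reserves <- world$reserves
    reserve_area <- world$reserve_area
    coarse_spec <- world$coarse_spec
  } else {
    stage <- "predictor_prep"
    if (!dir.exists(config$paths$predictors))
      stop("stage predictor_prep: predictor directory not found: ", config$paths$predictors)
    asc <- list.files(config$paths$predictors, pattern = "\\.asc$", full.names = TRUE)
    if (!length(asc)) stop("stage predictor_prep: no .asc layers in ", config$paths$predictors)
    grids <- lapply(asc, read_ascii_grid)
    layers <- lapply(grids, `[[`, "values")
    names(layers) <- sub("\\.asc$", "", basename(asc))
    cat_name <- if ("landcover" %in% names(layers)) "landcover" else NULL
    fine_stack <- predictor_stack(grids[[1]]$spec, layers, categorical = cat_name)
    records <- read_records_csv(config$paths$records)
    reserves <- read_reserves_geojson(config$paths$reserves)
    reserve_area <- sum(vapply(reserves, polygon_area, numeric(1)))
    coarse_spec <- coarsen_spec(fine_stack$grid, config$synthetic$k)
  }

  run_stage <- function(name, expr) {
    t <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)), call. = FALSE))
    log(sprintf("stage %s done in %.1fs", name, as.numeric(Sys.time() - t, units = "secs")))
    res
  }

  coarse_stack <- run_stage("predictor_prep", aggregate_stack(fine_stack, coarse_spec))
  coarse <- run_stage("coarse_level",
                      run_level(coarse_stack, records, reserves, reserve_area,
                                config, "coarse", derive_seed(seed, 10L), log))
  fine <- run_stage("fine_level",
                    run_level(fine_stack, records, reserves, reserve_area,
                              config, "fine", derive_seed(seed, 20L), log))
  cross <- run_stage("cross_scale",
                     cross_scale_report(coarse, fine, config, derive_seed(seed, 30L)))

  manifest <- list(
    config_hash = hash_object(unclass(config)),
    master_seed = seed,
    stage_seeds = list(world = derive_seed(seed, 1L), coarse = derive_seed(seed, 10L),
                       fine = derive_seed(seed, 20L), cross = derive_seed(seed, 30L)),
    package_version = as.character(utils::packageVersion("prioritygrid")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    outputs = character(0))
  result <- list(levels = list(coarse = coarse, fine = fine),
                 cross_scale = cross, world = world, manifest = manifest)
  if (!is.null(out_dir)) result$manifest <- write_outputs(result, config, out_dir)
  result
}

cross_scale_report <- function(coarse, fine, config, seed) {
  n_perm <- config$cross_scale$n_perm
  frac <- config$cross_scale$envelope_fraction
  # per-species congruence: arcsine-transformed protection percentages,
  # species present at both levels
  common <- intersect(coarse$gap$species, fine$gap$species)
  gc <- coarse$gap[match(common, coarse$gap$species), ]
  gf <- fine$gap[match(common, fine$gap$species), ]
  species_tests <- list()
  for (v in c("pct_range_protected", "pct_target_met")) {
    x <- arcsine_pct(gc[[v]]); y <- arcsine_pct(gf[[v]])
    species_tests[[v]] <- if (length(common) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0)
      permutation_correlation(x, y, n_perm, derive_seed(seed, 40L)) else
        list(r_obs = NA_real_, p = NA_real_, n_perm = n_perm)
  }
  # per-cell congruence and envelope nestedness per index
  pm <- parent_map(fine$spec, coarse$spec)
  idx_layers <- list(richness = list(coarse$richness, fine$richness),
                     conservation_value = list(coarse$conservation_value, fine$conservation_value),
                     complementarity = list(coarse$complementarity, fine$complementarity))
  cell_tests <- list(); envelopes <- list()
  i <- 0L
  for (nm in names(idx_layers)) {
    i <- i + 1L
    pairs <- cross_scale_cell_pairs(idx_layers[[nm]][[1]], idx_layers[[nm]][[2]],
                                    fine$spec, coarse$spec, mode = "replicate")
    cell_tests[[nm]] <- if (nrow(pairs) >= 3 && stats::sd(pairs$coarse) > 0 && stats::sd(pairs$fine) > 0)
      permutation_correlation(pairs$fine, pairs$coarse, n_perm, derive_seed(seed, 50L + i)) else
        list(r_obs = NA_real_, p = NA_real_, n_perm = n_perm)
    env_c <- tryCatch(priority_envelope(idx_layers[[nm]][[1]], frac), error = function(e) NULL)
    env_f <- tryCatch(priority_envelope(idx_layers[[nm]][[2]], frac), error = function(e) NULL)
    envelopes[[nm]] <- list(
      coarse_fraction = if (is.null(env_c)) NA_real_ else env_c$realized_fraction,
      fine_fraction = if (is.null(env_f)) NA_real_ else env_f$realized_fraction,
      nestedness = if (is.null(env_c) || is.null(env_f) || !length(env_f$cells)) NA_real_ else
        nestedness(env_f$cells, env_c$cells, pm))
  }
  summary_df <- rbind(
    do.call(rbind, lapply(names(species_tests), function(v)
      data.frame(comparison = paste0("species_", v), r_obs = species_tests[[v]]$r_obs,
                 p = species_tests[[v]]$p, stringsAsFactors = FALSE))),
    do.call(rbind, lapply(names(cell_tests), function(v)
      data.frame(comparison = paste0("cells_", v), r_obs = cell_tests[[v]]$r_obs,
                 p = cell_tests[[v]]$p, stringsAsFactors = FALSE))))
  list(species_tests = species_tests, cell_tests = cell_tests,
       envelopes = envelopes, summary = summary_df, n_perm = n_perm)
}

write_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(path) { written <<- c(written, path); path }
  for (lv in c("coarse", "fine")) {
    L <- result$levels[[lv]]
    write_ascii_grid(L$richness, L$spec, put(file.path(out_dir, paste0(lv, "_richness.asc"))))
    write_ascii_grid(L$conservation_value, L$spec,
                     put(file.path(out_dir, paste0(lv, "_conservation_value.asc"))))
    write_ascii_grid(L$complementarity, L$spec,
                     put(file.path(out_dir, paste0(lv, "_complementarity.asc"))))
    write_gap_csv(L$gap, put(file.path(out_dir, paste0(lv, "_gap_report.csv"))))
    utils::write.csv(L$model_report, put(file.path(out_dir, paste0(lv, "_model_report.csv"))),
                     row.names = FALSE)
    if (!is.null(L$stack$drop_log))
      utils::write.csv(L$stack$drop_log, put(file.path(out_dir, paste0(lv, "_vif_drop_log.csv"))),
                       row.names = FALSE)
  }
  utils::write.csv(result$cross_scale$summary,
                   put(file.path(out_dir, "cross_scale_summary.csv")), row.names = FALSE)
  manifest <- result$manifest
  manifest$outputs <- stats::setNames(as.character(tools::md5sum(written)), basename(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
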