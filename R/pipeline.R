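#' Experiment configuration
#'
#' Bundles the cohort, the condition matrix (restoration x crop), the model
#' recipe and the evaluation protocol. The default condition matrix is the
#' full ten-condition design: raw, TV-l1 deblurred (sigma_b = 1, 2) and MMWF
#' denoised (window 3, 5), each with whole-volume and limbic-cropped inputs.
#'
#' @param cohort a [cohort_spec()].
#' @param conditions list of `list(restore = restoration_config, crop = flag)`.
#' @param model a [model_config()]; its `input_shape` is the network grid
#'   for whole-volume conditions.
#' @param crop_input_shape network grid for cropped conditions (in-plane
#'   extent kept, axial extent reduced to the slab proportion).
#' @param crop_regions,crop_margin arguments of [limbic_crop_box()].
#' @param eval list: `k` folds, `mode` (`"cv"` or `"split"`), `frac_train`,
#'   `seed`.
#' @param output_dir where reports are written.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(cohort = benchmark_cohort_spec(),
                              conditions = default_conditions(),
                              model = desk_model_config(),
                              crop_input_shape = c(32L, 32L, 8L),
                              crop_regions = c("hippocampus", "amygdala",
                                               "thalamus", "putamen"),
                              crop_margin = 1L,
                              eval = list(k = 3L, mode = "cv",
                                          frac_train = 0.7, seed = 1L),
                              output_dir = tempfile("limbicnet_run")) {
  stopifnot(length(conditions) >= 1)
  nms <- vapply(conditions, condition_name, "")
  if (anyDuplicated(nms)) stop("condition names must be unique")
  structure(list(cohort = cohort, conditions = conditions, model = model,
                 crop_input_shape = as.integer(crop_input_shape),
                 crop_regions = crop_regions,
                 crop_margin = as.integer(crop_margin),
                 eval = modifyList(list(k = 3L, mode = "cv", frac_train = 0.7,
                                        seed = 1L), eval),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' The ten-condition restoration-by-cropping design
#' @export
default_conditions <- function() {
  base <- list(
    restoration_config("none"),
    restoration_config("deblur", sigma_b = 1),
    restoration_config("deblur", sigma_b = 2),
    restoration_config("denoise", mmwf = mmwf_config(window = 3)),
    restoration_config("denoise", mmwf = mmwf_config(window = 5)))
  out <- list()
  for (crop in c(FALSE, TRUE))
    for (r in base) out[[length(out) + 1L]] <- list(restore = r, crop = crop)
  out
}

#' Desk-scale model configuration
#'
#' The reference architecture at reduced width and grid so that the full
#' condition matrix trains in minutes on one CPU: 32 x 32 x 20 whole-volume
#' input, 16/16/32 channels, otherwise the reference recipe (batch 4,
#' 20 epochs, Adam at 1e-4, cross-entropy).
#' @param seed model seed.
#' @export
desk_model_config <- function(seed = 1L) {
  model_config(input_shape = c(32L, 32L, 20L), base_channels = 16L,
               stage_channels = c(16L, 32L), seed = seed)
}

condition_name <- function(cond)
  paste0(cond$restore$name, if (isTRUE(cond$crop)) "_crop" else "_whole")

# Load, restore, (crop,) resample and normalise every cohort volume for one
# condition. Returns list(volumes = named list of arrays, box = crop_box or
# NULL).
prepare_condition <- function(manifest, atlas, cond, cfg) {
  box <- if (isTRUE(cond$crop))
    limbic_crop_box(atlas, cfg$crop_regions, cfg$crop_margin) else NULL
  target <- if (isTRUE(cond$crop)) cfg$crop_input_shape else cfg$model$input_shape
  vols <- lapply(seq_len(nrow(manifest)), function(i) {
    v <- read_volume(manifest$volume[i])
    v <- expand_slices(v, atlas$dims[3])
    v <- restore_volume(v, cond$restore)
    if (!is.null(box)) v <- crop_volume(v, box)$volume
    normalize_volume(resample_volume(v, target))
  })
  names(vols) <- manifest$id
  list(volumes = vols, box = box, input_shape = target)
}

run_condition <- function(manifest, atlas, cond, cfg, seed) {
  prep <- prepare_condition(manifest, atlas, cond, cfg)
  mcfg <- cfg$model
  mcfg$input_shape <- prep$input_shape
  mcfg$seed <- derive_seed(seed, 11L)
  labels <- stats::setNames(manifest$label, manifest$id)

  fold_models <- new.env(parent = emptyenv())
  fit <- function(train_ids, fold) {
    m <- build_model(mcfg)
    test_ids <- setdiff(manifest$id, train_ids)
    tr <- train_model(m, prep$volumes[train_ids], labels[train_ids],
                      prep$volumes[test_ids], labels[test_ids])
    attr(tr, "extras") <- list(train_loss = tr$train_loss,
                               test_loss = tr$test_loss)
    assign(as.character(fold), tr, envir = fold_models)
    tr
  }
  predict_fn <- function(tr, test_ids)
    predict(tr, prep$volumes[test_ids])$label

  if (identical(cfg$eval$mode, "split")) {
    # single stratified train/test split instead of k-fold CV
    sp <- split_train_test(manifest, cfg$eval$frac_train, seed = seed)
    fitted <- fit(sp$train, 1L)
    met <- classification_metrics(
      confusion_counts(predict_fn(fitted, sp$test), unname(labels[sp$test])))
    cv <- list(per_fold = data.frame(fold = 1L, t(met)), mean = met,
               sd = stats::setNames(rep(NA_real_, length(met)), names(met)),
               folds = stats::setNames(
                 ifelse(manifest$id %in% sp$test, 1L, 0L), manifest$id),
               extras = list(attr(fitted, "extras")))
    eval_folds <- 1L
  } else {
    cv <- cross_validate(manifest, cfg$eval$k, fit, predict_fn, seed = seed)
    eval_folds <- seq_len(cfg$eval$k)
  }

  # AD-class activation maps of held-out subjects under their fold's model
  maps <- list()
  fold <- cv$folds
  for (f in eval_folds) {
    tr <- get(as.character(f), envir = fold_models)
    for (id in manifest$id[fold[manifest$id] == f])
      maps[[id]] <- cam(tr, prep$volumes[[id]], class_index = 2L,
                        crop_box = prep$box)
  }
  avg_map <- average_maps(unname(maps))
  imp <- region_importance(avg_map, atlas)

  list(name = condition_name(cond), cv = cv, map = avg_map, importance = imp,
       box = prep$box)
}

#' Run the full experiment matrix
#'
#' Generates (or reuses) the cohort, then for every condition restores and
#' optionally crops the volumes, trains and evaluates the network by
#' stratified cross-validation, and derives the averaged AD activation map
#' with its region-importance summary. Writes a metrics CSV (condition by
#' metric mean/sd), per-condition loss-curve CSVs, region tables, NIfTI
#' maps and a JSON run manifest into `cfg$output_dir`. A failing condition
#' is logged and skipped; the others continue.
#'
#' @param cfg an [experiment_config()].
#' @param cohort_dir existing cohort directory; by default the cohort is
#'   generated under `cfg$output_dir/cohort`.
#' @return a report list: `metrics` data.frame, `conditions` (details),
#'   `manifest`.
#' @export
run_experiment <- function(cfg, cohort_dir = NULL) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- build_atlas(cfg$cohort$dims)
  if (is.null(cohort_dir)) {
    cohort_dir <- file.path(cfg$output_dir, "cohort")
    manifest <- generate_cohort(cfg$cohort, cohort_dir, atlas)
  } else {
    manifest <- read_manifest(cohort_dir)
  }

  results <- list()
  rows <- NULL
  for (cond in cfg$conditions) {
    nm <- condition_name(cond)
    res <- tryCatch(
      run_condition(manifest, atlas, cond, cfg, seed = cfg$eval$seed),
      error = function(e) {
        message(sprintf("condition '%s' failed: %s", nm, conditionMessage(e)))
        NULL
      })
    if (is.null(res)) next
    results[[nm]] <- res
    row <- data.frame(condition = nm)
    for (m in names(res$cv$mean)) {
      row[[paste0(m, "_mean")]] <- res$cv$mean[[m]]
      row[[paste0(m, "_sd")]] <- res$cv$sd[[m]]
    }
    row$non_brain_fraction <- res$importance$non_brain_fraction
    rows <- rbind(rows, row)

    write.csv(res$importance$table,
              file.path(cfg$output_dir, paste0("regions_", nm, ".csv")),
              row.names = FALSE)
    curves <- do.call(rbind, lapply(seq_along(res$cv$extras), function(f)
      data.frame(fold = f, epoch = seq_along(res$cv$extras[[f]]$train_loss),
                 train_loss = res$cv$extras[[f]]$train_loss,
                 test_loss = res$cv$extras[[f]]$test_loss)))
    write.csv(curves, file.path(cfg$output_dir, paste0("loss_", nm, ".csv")),
              row.names = FALSE)
    write_activation_map(res$map, atlas,
                         file.path(cfg$output_dir, paste0("cam_", nm, ".nii.gz")))
  }
  if (!is.null(rows))
    write.csv(rows, file.path(cfg$output_dir, "metrics.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$eval$seed, k = cfg$eval$k,
         n_subjects = nrow(manifest),
         conditions = vapply(cfg$conditions, condition_name, ""),
         package_version = as.character(utils::packageVersion("limbicnet"))),
    file.path(cfg$output_dir, "run_manifest.json"), auto_unbox = TRUE)
  list(metrics = rows, conditions = results, manifest = manifest)
}

#' Plain-text rendering of a metrics table (mean +/- sd)
#' @param metrics the `metrics` data.frame from [run_experiment()].
#' @export
render_metrics <- function(metrics) {
  stopifnot(is.data.frame(metrics))
  cols <- c("sensitivity", "specificity", "accuracy", "f1", "mcc")
  lines <- sprintf("%-22s %s", "Condition",
                   paste(sprintf("%-13s", cols), collapse = ""))
  for (i in seq_len(nrow(metrics))) {
    cells <- vapply(cols, function(m)
      sprintf("%.2f ± %.2f", metrics[[paste0(m, "_mean")]][i],
              metrics[[paste0(m, "_sd")]][i]), "")
    lines <- c(lines, sprintf("%-22s %s", metrics$condition[i],
                              paste(sprintf("%-13s", cells), collapse = "")))
  }
  paste(lines, collapse = "\n")
}

#' Validate and load an experiment configuration from YAML
#'
#' Parses a hierarchical YAML file and checks every invariant, returning
#' either the built [experiment_config()] or the exhaustive list of
#' violations.
#'
#' @param path YAML file.
#' @return list with `config` (or `NULL`) and `errors` (character vector).
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  co <- y$cohort %||% list()
  if (is.null(co$n_control) || co$n_control < 1) note("cohort.n_control must be a positive integer")
  if (is.null(co$n_ad) || co$n_ad < 1) note("cohort.n_ad must be a positive integer")
  eff <- unlist(co$effect %||% list(hippocampus = 0.25, middle_temporal = 0.25))
  if (any(eff < 0 | eff >= 1)) note("cohort.effect values must lie in [0, 1)")
  dims <- as.integer(co$dims %||% c(64, 64, 40))

  profs <- lapply(co$scanner %||% list(), function(s) {
    if (!is.null(s$blur_sigma) && s$blur_sigma < 0) note("scanner.blur_sigma must be >= 0")
    if (!is.null(s$noise_sd) && s$noise_sd < 0) note("scanner.noise_sd must be >= 0")
    if (!is.null(s$n_slices) && s$n_slices > dims[3]) note("scanner.n_slices exceeds the axial dimension")
    s
  })

  conds <- list()
  for (i in seq_along(y$conditions %||% list())) {
    c0 <- y$conditions[[i]]
    meth <- c0$restore %||% "none"
    if (!meth %in% c("none", "deblur", "denoise")) {
      note(sprintf("conditions[%d].restore '%s' invalid; allowed: none, deblur, denoise", i, meth))
      next
    }
    if (!is.null(c0$lambda) && c0$lambda <= 0) note(sprintf("conditions[%d].lambda must be > 0", i))
    if (!is.null(c0$sigma_b) && c0$sigma_b <= 0) note(sprintf("conditions[%d].sigma_b must be > 0", i))
    if (!is.null(c0$window) && (c0$window < 3 || c0$window %% 2 == 0))
      note(sprintf("conditions[%d].window must be odd and >= 3", i))
    if (length(errs)) next
    rc <- restoration_config(meth,
      sigma_b = c0$sigma_b %||% 2,
      tv = tv_deblur_config(lambda = c0$lambda %||% 0.01),
      mmwf = mmwf_config(window = c0$window %||% 5))
    conds[[length(conds) + 1L]] <- list(restore = rc, crop = isTRUE(c0$crop))
  }
  if (!length(y$conditions %||% list())) note("at least one condition is required")

  mo <- y$model %||% list()
  if (!is.null(mo$lr) && mo$lr < 0) note("model.lr must be >= 0")
  if (!is.null(mo$epochs) && mo$epochs < 1) note("model.epochs must be >= 1")

  ev <- y$eval %||% list()
  if (!is.null(ev$mode) && !ev$mode %in% c("cv", "split"))
    note("eval.mode must be 'cv' or 'split'")

  if (length(errs)) return(list(config = NULL, errors = errs))

  spec <- cohort_spec(
    n_control = co$n_control, n_ad = co$n_ad, effect_map = eff,
    scanner_profiles = if (length(profs))
      lapply(profs, function(s) scanner_profile(s$name %||% "scanner",
        s$blur_sigma %||% 0, s$noise_sd %||% 0, s$n_slices %||% dims[3]))
      else default_scanner_profiles(dims[3]),
    dims = dims, seed = co$seed %||% 1L,
    noise_model = co$noise_model %||% "gaussian")
  model <- model_config(
    input_shape = as.integer(mo$input_shape %||% c(32, 32, 20)),
    base_channels = mo$base_channels %||% 16L,
    stage_channels = as.integer(mo$stage_channels %||% c(16, 32)),
    lr = mo$lr %||% 1e-4, batch_size = mo$batch_size %||% 4L,
    epochs = mo$epochs %||% 20L, seed = mo$seed %||% 1L)
  cfg <- experiment_config(
    cohort = spec, conditions = conds, model = model,
    crop_input_shape = as.integer(y$crop_input_shape %||% c(32, 32, 8)),
    eval = list(k = ev$k %||% 3L, mode = ev$mode %||% "cv",
                frac_train = ev$frac_train %||% 0.7, seed = ev$seed %||% 1L),
    output_dir = y$output_dir %||% tempfile("limbicnet_run"))
  list(config = cfg, errors = character(0))
}
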