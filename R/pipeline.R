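#' Pipeline run configuration
#'
#' Centralizes every tunable of a full segment -> extract -> select/train ->
#' predict -> survival run. Can be read from / written to YAML so all
#' defaults live in one auditable place.
#'
#' @param input_dir directory holding, per cohort row, either
#'   `<image_id>.geojson` contours or a `<image_id>.png`/`.tif` image.
#' @param cohort_csv cohort table path (see [read_cohort()]).
#' @param out_dir output directory (created if needed).
#' @param catalog a [catalog_config()].
#' @param seg a [seg_params()].
#' @param mrmr_m number of features to select (default 5).
#' @param models candidate model types.
#' @param seed integer seed recorded in every output.
#' @return list of class `run_config`.
#' @export
run_config <- function(input_dir, cohort_csv, out_dir,
                       catalog = catalog_config(), seg = seg_params(),
                       mrmr_m = 5L, models = c("svm", "rf", "dac"),
                       seed = 1L) {
  structure(list(input_dir = input_dir, cohort_csv = cohort_csv,
                 out_dir = out_dir, catalog = catalog, seg = seg,
                 mrmr_m = as.integer(mrmr_m), models = models,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cat_args <- y$catalog %||% list()
  if (!is.null(cat_args$tensor)) cat_args$tensor <- as.list(cat_args$tensor)
  run_config(
    input_dir = y$input_dir, cohort_csv = y$cohort_csv, out_dir = y$out_dir,
    catalog = do.call(catalog_config, cat_args),
    seg = do.call(seg_params, y$seg %||% list()),
    mrmr_m = y$mrmr_m %||% 5L,
    models = y$models %||% c("svm", "rf", "dac"),
    seed = y$seed %||% 1L)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

load_gland_sets <- function(cfg, cohort) {
  lapply(cohort$image_id, function(id) {
    gj <- file.path(cfg$input_dir, paste0(id, ".geojson"))
    if (file.exists(gj)) return(read_contours(gj, image_id = id))
    for (ext in c(".png", ".tif", ".tiff")) {
      ip <- file.path(cfg$input_dir, paste0(id, ext))
      if (file.exists(ip)) return(segment_glands(read_image(ip), cfg$seg))
    }
    stop_domain("no contours or image found for image_id '%s' in %s",
                id, cfg$input_dir)
  })
}

#' Run the full recurrence-risk pipeline
#'
#' Stages: read cohort; load contours or segment images; extract the feature
#' catalog; discretize and select `mrmr_m` features by mRMR against the
#' recurrence label; train all candidate models with stratified five-fold CV
#' and lock the best; predict risk groups; evaluate against the recurrence
#' labels and run the survival analysis by predicted group. All outputs
#' (features.csv, model.json, risk.csv, report.json) carry the seed and a
#' config hash; a rerun with the same inputs and config reproduces them
#' bit-identically.
#'
#' @param cfg a [run_config()].
#' @return run manifest: list of output paths, their md5 hashes, the config
#'   hash, seed, and per-stage wall times. Also written as manifest.json.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  cohort <- stage("read_cohort", read_cohort(cfg$cohort_csv))
  timings["read_cohort"] <- tic() - t0

  t0 <- tic()
  gsets <- stage("load_glands", load_gland_sets(cfg, cohort))
  timings["load_glands"] <- tic() - t0

  t0 <- tic()
  feats <- stage("extract", extract_feature_table(gsets, cfg$catalog))
  features_csv <- file.path(cfg$out_dir, "features.csv")
  write.csv(feats, features_csv, row.names = FALSE)
  timings["extract"] <- tic() - t0

  t0 <- tic()
  X <- as.matrix(feats[, -1, drop = FALSE])
  y <- cohort$recurrence
  model <- stage("train", {
    # constant columns carry no information; excluded from selection
    keep <- apply(X, 2, function(v) sd(v) > 0)
    disc <- discretize(X[, keep, drop = FALSE])
    sel <- mrmr_select(disc$levels, y, cfg$mrmr_m)
    cands <- lapply(cfg$models, function(mt)
      crossval_train(X[, sel$selected, drop = FALSE], y, mt, seed = cfg$seed))
    m <- lock_down(cands)
    m$mrmr <- sel
    m
  })
  timings["train"] <- tic() - t0

  t0 <- tic()
  risk <- stage("predict", predict_risk(model, feats[, -1, drop = FALSE]))
  risk_csv <- file.path(cfg$out_dir, "risk.csv")
  write.csv(data.frame(patient_id = cohort$patient_id,
                       image_id = cohort$image_id, risk = risk),
            risk_csv, row.names = FALSE)
  timings["predict"] <- tic() - t0

  t0 <- tic()
  report <- stage("evaluate", {
    ev <- evaluate(model, feats, cohort)
    pos <- risk == "ECAHBC-positive"
    surv <- if (any(pos) && any(!pos)) {
      lr <- logrank_test(cohort$survival_time[pos], cohort$event[pos],
                         cohort$survival_time[!pos], cohort$event[!pos])
      cx <- cox_fit(data.frame(ecahbc = as.integer(pos)),
                    cohort$survival_time, cohort$event, mode = "univariate")
      list(logrank = lr, cox = as.list(cx[1, ]))
    } else NULL
    list(evaluation = ev, survival = surv)
  })
  timings["evaluate"] <- tic() - t0

  # the config hash covers the scientific configuration, not where the
  # outputs land, so reruns into a different directory hash identically
  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                               auto_unbox = TRUE, digits = 10, force = TRUE)
  config_path <- file.path(cfg$out_dir, "config.json")
  writeLines(cfg_json, config_path)
  config_hash <- unname(tools::md5sum(config_path))

  model_json <- file.path(cfg$out_dir, "model.json")
  jsonlite::write_json(serialize_model(model, config_hash), model_json,
                       auto_unbox = TRUE, digits = 10)
  report_json <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(list(seed = cfg$seed, config_hash = config_hash,
                            evaluation = report$evaluation[
                              setdiff(names(report$evaluation), "model")],
                            survival = report$survival),
                       report_json, auto_unbox = TRUE, digits = 10,
                       force = TRUE)
  outputs <- c(features = features_csv, model = model_json, risk = risk_csv,
               report = report_json, config = config_path)
  manifest <- list(seed = cfg$seed, config_hash = config_hash,
                   outputs = as.list(outputs),
                   hashes = as.list(tools::md5sum(outputs)),
                   stage_seconds = as.list(round(timings, 3)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  manifest$model <- model
  invisible(manifest)
}

serialize_model <- function(model, config_hash = NULL) {
  out <- list(model_type = model$model_type,
              selected_features = model$selected_features,
              cv_accuracy_per_fold = model$cv_metrics,
              cv_accuracy_mean = mean(model$cv_metrics),
              locked = model$locked, seed = model$seed,
              scaler = model$scaler, config_hash = config_hash)
  if (model$model_type == "svm") {
    w <- t(model$fit$coefs) %*% model$fit$SV
    out$svm <- list(weights = as.numeric(w), rho = model$fit$rho)
  }
  if (!is.null(model$mrmr)) out$mrmr_scores <- model$mrmr$scores
  out
}

#' Evaluate a locked classifier against recurrence labels
#'
#' @param model a locked `fitted_classifier`.
#' @param features feature table from [extract_feature_table()] (or any
#'   table with the selected feature columns), rows aligned to `cohort`.
#' @param cohort a `cohort_table` with recurrence labels.
#' @return list: `metrics` ([confusion_metrics()]), `counts` (2x2),
#'   `recurrence_rate_ratio` (predicted-positive vs predicted-negative
#'   recurrence rate; NA when a group is empty).
#' @export
evaluate <- function(model, features, cohort) {
  fdf <- as.data.frame(features)
  if ("image_id" %in% names(fdf)) fdf <- fdf[, -match("image_id", names(fdf)),
                                             drop = FALSE]
  pred <- predict_risk(model, fdf)
  truth <- cohort$recurrence
  cm <- confusion_metrics(pred, truth)
  pos <- pred == "ECAHBC-positive"
  rr <- if (any(pos) && any(!pos) && mean(truth[!pos]) > 0)
    mean(truth[pos]) / mean(truth[!pos]) else NA_real_
  list(metrics = cm,
       counts = matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2, 2,
                       dimnames = list(pred = c("positive", "negative"),
                                       truth = c("recurrence", "none"))),
       recurrence_rate_ratio = rr)
}

#' Write a synthetic dataset to disk
#'
#' Renders images, truth label masks, GeoJSON contours, and the linked
#' cohort CSV for `n_patients` synthetic cores — the on-disk form consumed
#' by [run_pipeline()].
#'
#' @param n_patients number of cores/patients.
#' @param kappa vector (recycled) of per-patient orientation concentrations.
#' @param out_dir output directory.
#' @param shape_noise boundary perturbation level.
#' @param n_glands glands per core.
#' @param field_size field side, pixels.
#' @param seed base seed; patient i uses seed + i.
#' @param render write rendered PNGs (TRUE) or contours only.
#' @param outcome a [synth_outcome_config()] (n_patients/seed overridden).
#' @return path of the cohort CSV, invisibly.
#' @export
write_synth_dataset <- function(n_patients, kappa, out_dir,
                                shape_noise = 0.08, n_glands = 30L,
                                field_size = 256L, seed = 1L, render = TRUE,
                                outcome = synth_outcome_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kappa <- rep_len(kappa, n_patients)
  cfgs <- lapply(seq_len(n_patients), function(i)
    synth_config(n_glands = n_glands, field_size = field_size,
                 kappa = kappa[i], shape_noise = shape_noise,
                 seed = seed + i))
  outcome$n_patients <- as.integer(n_patients)
  outcome$seed <- as.integer(seed)
  cohort <- simulate_cohort(cfgs, outcome)
  for (i in seq_len(n_patients)) {
    gs <- sample_layout(cfgs[[i]])
    write_contours(gs, file.path(out_dir, paste0(cohort$image_id[i], ".geojson")))
    if (render) {
      img <- render_image(gs, field_size = field_size, seed = cfgs[[i]]$seed)
      write_image(img, file.path(out_dir, paste0(cohort$image_id[i], ".png")))
      write_label_mask(gs, c(field_size, field_size),
                       file.path(out_dir, paste0(cohort$image_id[i], "_mask.tif")))
    }
  }
  cohort_csv <- file.path(out_dir, "cohort.csv")
  write.csv(cohort, cohort_csv, row.names = FALSE)
  invisible(cohort_csv)
}
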