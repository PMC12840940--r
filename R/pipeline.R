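#' Configuration for the end-to-end fusion experiment
#'
#' Collects every knob of the simulate - calibrate - preprocess - select -
#' extract - fuse - train - evaluate pipeline. Defaults follow the study
#' design the package models: 7:3 train/test split, 5-fold cross-validation
#' with shuffle seed 42 and at most 25 latent variables, SG+SNV
#' preprocessing, CARS wavelength selection, per-feature OLS fusion weights.
#'
#' @param n_samples Fruits to simulate (ignored when `paths` is given).
#' @param seed Global seed, fanned out to named substreams per stage.
#' @param chain Preprocessing chain specification (see [fit_preprocess()]).
#' @param sg_window,sg_order Savitzky-Golay settings.
#' @param selection `"cars"`, `"spa"`, `"uve"` or `"none"`.
#' @param selection_args Named list of extra arguments for the selector.
#' @param fusion_mode `"per_feature"` or `"per_block"`.
#' @param split_ratio Training fraction (default 0.7).
#' @param cv_folds,cv_seed,max_latent Latent-variable selection settings.
#' @param fwd,acq,ssc_params,image_params Generator settings (see
#'   [simulate_dataset()]).
#' @param paths Optional named list (`spectra`, `dark`, `white`, `ssc`,
#'   `images`) of on-disk inputs; when given, nothing is simulated.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_samples = 120, seed = 1, chain = "SG+SNV",
                            sg_window = 11, sg_order = 2,
                            selection = c("cars", "spa", "uve", "none"),
                            selection_args = list(),
                            fusion_mode = c("per_feature", "per_block"),
                            split_ratio = 0.7, cv_folds = 5, cv_seed = 42,
                            max_latent = 25,
                            fwd = spectral_forward_model(),
                            acq = acquisition_params(),
                            ssc_params = list(), image_params = list(),
                            paths = NULL) {
  selection <- match.arg(selection)
  fusion_mode <- match.arg(fusion_mode)
  if (split_ratio <= 0 || split_ratio >= 1) {
    abort("`split_ratio` must be in (0, 1)", class = "plumfuse_parameter_error")
  }
  if (!is.numeric(seed) || seed != round(seed)) {
    abort("`seed` must be an integer", class = "plumfuse_parameter_error")
  }
  if (!is.null(paths)) {
    need <- c("spectra", "dark", "white", "ssc", "images")
    missing <- setdiff(need, names(paths))
    if (length(missing)) {
      abort(paste0("`paths` must name: ", paste(missing, collapse = ", ")),
            class = "plumfuse_parameter_error")
    }
    gone <- !vapply(paths[need], file.exists, TRUE)
    if (any(gone)) {
      abort(paste0("input path does not exist: ", unlist(paths[need])[gone][1]),
            class = "plumfuse_io_error")
    }
  }
  structure(
    list(n_samples = n_samples, seed = seed, chain = chain,
         sg_window = sg_window, sg_order = sg_order, selection = selection,
         selection_args = selection_args, fusion_mode = fusion_mode,
         split_ratio = split_ratio, cv_folds = cv_folds, cv_seed = cv_seed,
         max_latent = max_latent, fwd = fwd, acq = acq,
         ssc_params = ssc_params, image_params = image_params, paths = paths),
    class = "pipeline_config"
  )
}

#' Run the full multi-source fusion experiment
#'
#' Executes every stage on one shared train/test split and returns the three
#' model evaluations (spectral-only, image-only, fused). All stateful fits —
#' the preprocessing chain, wavelength selection, standardizers, fusion
#' weights, and latent-variable counts — are functions of the training
#' partition only; the test partition is touched once, for the final metrics.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, the summary
#'   (CSV + plain text), per-sample predictions, feature tables, selection
#'   results, fitted-model JSON and a manifest are written there.
#' @return A tibble with one row per model (`spectral`, `image`, `fused`) and
#'   columns `r2_train`, `rmse_train`, `r2_test`, `rmse_test`, `rpd`,
#'   `n_latent`, `n_features`. Attributes: `predictions` (per-sample tibble),
#'   `models` (fitted objects), `selection` (the `selection_result`),
#'   `split`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(n_samples = 40, seed = 1)
#' run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "plumfuse_pipeline_error", parent = e)
    })
  }

  data <- stage("data", pipeline_data(config))
  ssc <- data$ssc

  split <- stage("split",
                 train_test_split(ssc$sample_id, config$split_ratio, config$seed))
  y <- stats::setNames(ssc$ssc_brix, ssc$sample_id)
  y_tr <- y[split$train]; y_te <- y[split$test]

  refl <- stage("calibrate",
                calibrate_reflectance(data$spectra, data$dark, data$white))
  refl_tr <- refl[match(split$train, refl$sample_id), ]
  refl_te <- refl[match(split$test, refl$sample_id), ]

  pp <- stage("preprocess",
              fit_preprocess(refl_tr, config$chain, config$sg_window, config$sg_order))
  sp_tr <- spectra_matrix(pp$spectra)
  sp_te <- spectra_matrix(stage("preprocess", apply_preprocess(pp, refl_te)))

  sel <- stage("select", switch(config$selection,
    cars = do.call(cars_select, c(list(x = pp$spectra, y = y_tr,
                                       seed = config$seed), config$selection_args)),
    spa = do.call(spa_select, c(list(x = pp$spectra, y = y_tr,
                                     seed = config$seed), config$selection_args)),
    uve = do.call(uve_select, c(list(x = pp$spectra, y = y_tr,
                                     seed = config$seed), config$selection_args)),
    none = new_selection_result("NONE", seq_len(ncol(sp_tr)),
                                spectra_wavelengths(pp$spectra), NULL,
                                config$seed)))
  xs_tr <- sp_tr[, sel$selected, drop = FALSE]
  xs_te <- sp_te[, sel$selected, drop = FALSE]

  feats <- stage("features", {
    ft <- extract_features_table(data$images)
    ft[match(ssc$sample_id, ft$sample_id), ]
  })
  fm <- as_feature_matrix(feats)
  rownames(fm) <- feats$sample_id
  fv_tr <- fm[match(split$train, feats$sample_id), , drop = FALSE]
  fv_te <- fm[match(split$test, feats$sample_id), , drop = FALSE]

  fit_block <- function(x_tr, x_te, label) {
    cv <- select_n_latent(x_tr, y_tr, config$max_latent, config$cv_folds,
                          config$cv_seed)
    fit <- plsr_fit(x_tr, y_tr, n_latent = cv$n_latent)
    list(fit = fit, cv = cv,
         pred_tr = predict(fit, x_tr), pred_te = predict(fit, x_te),
         label = label)
  }

  spec_model <- stage("train_spectral", fit_block(xs_tr, xs_te, "spectral"))

  vis_std <- stage("train_image", zscore_fit(fv_tr))
  zv_tr <- zscore_apply(vis_std, fv_tr)
  zv_te <- zscore_apply(vis_std, fv_te)
  vis_model <- stage("train_image", fit_block(zv_tr, zv_te, "image"))

  fused_model <- stage("train_fused", {
    spec_std <- zscore_fit(xs_tr)
    zs_tr <- zscore_apply(spec_std, xs_tr)
    zs_te <- zscore_apply(spec_std, xs_te)
    fw <- learn_fusion_weights(zs_tr, zv_tr, y_tr, config$fusion_mode)
    out <- fit_block(fuse(zs_tr, zv_tr, fw), fuse(zs_te, zv_te, fw), "fused")
    out$fusion <- fw
    out$spec_std <- spec_std
    out
  })

  models <- list(spectral = spec_model, image = vis_model, fused = fused_model)
  summary <- purrr::map(models, function(m) {
    tr <- evaluate_predictions(y_tr, m$pred_tr, "train")
    te <- evaluate_predictions(y_te, m$pred_te, "test")
    tibble(model = m$label, r2_train = tr$r2, rmse_train = tr$rmse,
           r2_test = te$r2, rmse_test = te$rmse, rpd = te$rpd,
           n_latent = m$fit$n_latent,
           n_features = length(m$fit$coefficients))
  }) |> purrr::list_rbind()

  predictions <- purrr::map(models, function(m) {
    tibble(sample_id = c(split$train, split$test), model = m$label,
           partition = rep(c("train", "test"),
                           c(length(split$train), length(split$test))),
           y_true = c(y_tr, y_te), y_pred = c(m$pred_tr, m$pred_te))
  }) |> purrr::list_rbind()

  if (!is.null(out_dir)) {
    stage("report", write_run_artifacts(out_dir, config, summary, predictions,
                                        feats, sel, models, vis_std))
  }

  attr(summary, "predictions") <- predictions
  attr(summary, "models") <- models
  attr(summary, "selection") <- sel
  attr(summary, "split") <- split
  attr(summary, "visual_standardizer") <- vis_std
  class(summary) <- c("plum_run", class(summary))
  summary
}

pipeline_data <- function(config) {
  if (!is.null(config$paths)) {
    p <- config$paths
    list(ssc = read_ssc_csv(p$ssc),
         spectra = read_spectra_csv(p$spectra),
         dark = read_reference_csv(p$dark),
         white = read_reference_csv(p$white),
         images = p$images)
  } else {
    ssc_args <- modifyList(
      list(mu = 13.00, sigma = 1.25, lower = 10.2, upper = 15.3),
      config$ssc_params)
    ssc <- sample_ssc(config$n_samples, mu = ssc_args$mu,
                      sigma = ssc_args$sigma, lower = ssc_args$lower,
                      upper = ssc_args$upper,
                      seed = substream_seed(config$seed, "ssc"))
    raw <- simulate_spectra(ssc, config$fwd, config$acq, seed = config$seed)
    images <- do.call(simulate_images,
                      c(list(ssc = ssc, seed = config$seed),
                        config$image_params))
    list(ssc = ssc, spectra = raw$spectra, dark = raw$dark,
         white = raw$white, images = images)
  }
}

write_run_artifacts <- function(out_dir, config, summary, predictions, feats,
                                sel, models, vis_std) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(as_tibble(summary), file.path(out_dir, "summary.csv"))
  readr::write_csv(predictions, file.path(out_dir, "predictions.csv"))
  write_features_csv(feats, file.path(out_dir, "visual_features.csv"))
  write_selection_csv(sel, file.path(out_dir, "selection.csv"))
  save_model(models, vis_std, config, file.path(out_dir, "models.json"))

  lines <- c("Multi-source SSC prediction summary",
             "",
             sprintf("%-10s %8s %8s %8s %8s %6s", "model", "R2c", "RMSEC",
                     "R2v", "RMSEV", "RPD"),
             sprintf("%-10s %8.4f %8.4f %8.4f %8.4f %6.2f", summary$model,
                     summary$r2_train, summary$rmse_train, summary$r2_test,
                     summary$rmse_test, summary$rpd))
  writeLines(lines, file.path(out_dir, "summary.txt"))

  write_manifest(
    list(seed = config$seed, n_samples = config$n_samples,
         chain = config$chain, selection = config$selection,
         fusion_mode = config$fusion_mode, split_ratio = config$split_ratio,
         cv_folds = config$cv_folds, cv_seed = config$cv_seed,
         max_latent = config$max_latent,
         R2c_fused = summary$r2_train[summary$model == "fused"],
         R2v_fused = summary$r2_test[summary$model == "fused"],
         RMSEV_fused = summary$rmse_test[summary$model == "fused"],
         RPD_fused = summary$rpd[summary$model == "fused"]),
    file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' Serialize and restore fitted pipeline models as JSON
#'
#' Stores the three fitted PLSR models, the visual standardizer, fusion
#' weights and configuration scalars in a documented JSON text format with a
#' `format_version` field.
#'
#' @param models,vis_std,config Internal objects from [run_pipeline()].
#' @param path JSON file path.
#' @return `load_model()` returns the nested list with `plsr_model` /
#'   `standardizer` / `fusion_spec` classes restored.
#' @export
save_model <- function(models, vis_std, config, path) {
  strip <- function(m) {
    f <- m$fit
    list(n_latent = f$n_latent, coefficients = f$coefficients,
         intercept = f$intercept, x_center = f$x_center,
         x_scale = f$x_scale, y_center = f$y_center,
         x_weights = f$x_weights, x_loadings = f$x_loadings,
         y_loadings = f$y_loadings)
  }
  payload <- list(
    format_version = 1,
    config = list(chain = config$chain, selection = config$selection,
                  fusion_mode = config$fusion_mode, seed = config$seed),
    visual_standardizer = list(center = vis_std$center, scale = vis_std$scale),
    fusion = list(spectral_weights = models$fused$fusion$spectral_weights,
                  visual_weights = models$fused$fusion$visual_weights,
                  mode = models$fused$fusion$mode),
    models = purrr::map(models, strip)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$models <- purrr::map(payload$models, function(m) {
    m$x_weights <- as.matrix(m$x_weights)
    m$x_loadings <- as.matrix(m$x_loadings)
    m$feature_names <- NULL
    m$n_obs <- NA_integer_
    class(m) <- "plsr_model"
    m
  })
  class(payload$visual_standardizer) <- "standardizer"
  payload
}
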