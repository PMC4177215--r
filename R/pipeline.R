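#' Configuration for an end-to-end encoding-model run
#'
#' Bundles every stage parameter of [run_pipeline()]. Two input modes exist:
#' the default simulation mode draws stimuli and responses from
#' [synthetic_study()]; file mode (set `images_train`, `images_test`,
#' `responses_train`, `responses_test`) reads PNG stimulus directories and
#' response CSVs produced elsewhere.
#'
#' @param mode `"vbem"` (stimulus encoding model), `"avbem"` (analogical
#'   model using source-region patterns as input channels), or `"combined"`
#'   (fit both, average the predictions).
#' @param seed Integer seed driving simulation and estimation.
#' @param sim Named list of overrides for [synthetic_study()] parameters.
#' @param control A [train_control()]; its seed is replaced by `seed`.
#' @param combine_weight Weight on the stimulus model in `"combined"` mode.
#' @param out_dir Optional directory: when set, models, predictions, the
#'   identification result, and a run log are written there.
#' @param images_train,images_test Optional PNG directories (file mode).
#' @param responses_train,responses_test Optional response CSVs aligned with
#'   the image stacks (file mode).
#' @param source_train,source_test Optional source-region response CSVs
#'   (file mode, `"avbem"`/`"combined"`).
#' @param roi Optional ROI JSON path, or a named list, for per-ROI scoring.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("vbem", "avbem", "combined"), seed = 1,
                            sim = list(), control = train_control(),
                            combine_weight = 0.5, out_dir = NULL,
                            images_train = NULL, images_test = NULL,
                            responses_train = NULL, responses_test = NULL,
                            source_train = NULL, source_test = NULL,
                            roi = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(control, "train_control"))
  file_mode <- !is.null(responses_train)
  if (file_mode) {
    paths <- c(images_train, images_test, responses_train, responses_test,
               source_train, source_test,
               if (is.character(roi)) roi)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop(sprintf("input file(s) not found: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  structure(list(mode = mode, seed = as.integer(seed), sim = sim,
                 control = control, combine_weight = combine_weight,
                 out_dir = out_dir, images_train = images_train,
                 images_test = images_test,
                 responses_train = responses_train,
                 responses_test = responses_test,
                 source_train = source_train, source_test = source_test,
                 roi = roi, file_mode = file_mode),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may contain any [pipeline_config()] argument; entries under
#' `control:` are passed to [train_control()] and entries under `sim:` to
#' [synthetic_study()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  ctl <- do.call(train_control, y$control %||% list())
  y$control <- ctl
  do.call(pipeline_config, y)
}

#' Run the full encoding-identification pipeline
#'
#' Executes featurization, model fitting, prediction, optional prediction
#' combination, and correlation-matrix identification for one configuration,
#' and (when `out_dir` is set) persists every stage artifact together with a
#' reproducibility log (seed, configuration hash, per-stage wall time).
#' Rerunning with the same configuration reproduces all results bit-exactly.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress?
#' @return A list of class `pipeline_result`: the `identification_result`
#'   (and per-ROI results when ROI labels are available), predictions per
#'   fitted model, the fitted models, and the run log.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_all <- proc.time()[3]
  log <- list(seed = config$seed, mode = config$mode,
              package_version = as.character(utils::packageVersion("voxelenc")),
              r_version = R.version.string, stages = list())
  tick <- function(stage, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
    log$stages[[stage]] <<- round(proc.time()[3] - t0, 3)
    if (verbose) message(sprintf("stage %-12s %7.2fs", stage,
                                 log$stages[[stage]]))
    out
  }
  ctl <- config$control
  ctl$seed <- config$seed

  if (!config$file_mode) {
    sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
    study <- tick("simulate", do.call(synthetic_study, sim_args))
    X_tr <- unclass(study$features_train); X_te <- unclass(study$features_test)
    Y_tr <- study$erc$train; Y_te <- study$erc$test
    S_tr <- study$loc$train; S_te <- study$loc$test
    roi_labels <- split(names(study$erc$ground_truth$roi),
                        study$erc$ground_truth$roi)
  } else {
    study <- NULL
    pyr_args <- config$sim
    imgs_tr <- tick("load_images", read_images_png(config$images_train))
    imgs_te <- read_images_png(config$images_test)
    pyr <- do.call(gabor_pyramid,
                   c(list(image_size = dim(imgs_tr)[1]),
                     pyr_args[intersect(names(pyr_args),
                                        names(formals(gabor_pyramid)))]))
    X_tr <- tick("featurize", unclass(gabor_features(imgs_tr, pyr)))
    X_te <- unclass(gabor_features(imgs_te, pyr))
    Y_tr <- read_matrix_csv(config$responses_train)
    Y_te <- read_matrix_csv(config$responses_test)
    # file-mode correspondence is by order: lexicographic image order is the
    # stimulus order of the response rows
    if (nrow(X_tr) != nrow(Y_tr) || nrow(X_te) != nrow(Y_te))
      stop("image and response stimulus counts differ", call. = FALSE)
    rownames(X_tr) <- rownames(Y_tr)
    rownames(X_te) <- rownames(Y_te)
    S_tr <- if (!is.null(config$source_train))
      read_matrix_csv(config$source_train)
    S_te <- if (!is.null(config$source_test))
      read_matrix_csv(config$source_test)
    roi_labels <- if (is.character(config$roi)) read_roi_json(config$roi)
                  else config$roi
  }
  if (config$mode %in% c("avbem", "combined") && is.null(S_tr))
    stop("mode requires source-region responses", call. = FALSE)

  models <- list(); preds <- list()
  if (config$mode %in% c("vbem", "combined")) {
    models$vbem <- tick("fit_vbem",
                        fit_encoding(X_tr, Y_tr, ctl, verbose = verbose))
    preds$vbem <- tick("predict_vbem", predict(models$vbem, X_te))
  }
  if (config$mode %in% c("avbem", "combined")) {
    models$avbem <- tick("fit_avbem",
                         fit_encoding(S_tr, Y_tr, ctl, verbose = verbose))
    preds$avbem <- tick("predict_avbem", predict(models$avbem, S_te))
  }
  final_pred <- if (config$mode == "combined") {
    tick("combine", combine_predictions(preds$vbem, preds$avbem,
                                        weight_a = config$combine_weight))
  } else preds[[config$mode]]

  idr <- tick("identify",
              identify_patterns(pattern_correlation(final_pred, Y_te)))
  roi_results <- if (!is.null(roi_labels) && length(roi_labels))
    tick("identify_roi", identify_by_roi(final_pred, Y_te, roi_labels))

  log$total_seconds <- round(proc.time()[3] - t_all, 3)
  result <- structure(list(identification = idr, roi_results = roi_results,
                           predictions = preds, final_prediction = final_pred,
                           models = models, study = study, config = config,
                           log = log),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result)
  result
}

# Persist every stage artifact plus a run log stamped with the configuration
# hash (md5 of the serialized configuration JSON) and the seed.
write_pipeline_artifacts <- function(result) {
  config <- result$config
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- file.path(config$out_dir, "config.json")
  cfg <- config
  cfg$control <- unclass(cfg$control)
  jsonlite::write_json(Filter(Negate(is.null), unclass(cfg)), cfg_json,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (nm in names(result$models))
    save_encoding_model(result$models[[nm]],
                        file.path(config$out_dir, paste0("model_", nm)))
  for (nm in names(result$predictions))
    write_matrix_csv(result$predictions[[nm]],
                     file.path(config$out_dir, paste0("pred_", nm, ".csv")))
  write_matrix_csv(result$final_prediction,
                   file.path(config$out_dir, "pred_final.csv"))
  write_identification_json(result$identification,
                            file.path(config$out_dir, "identification.json"),
                            file.path(config$out_dir, "corr_matrix.csv"))
  if (!is.null(result$roi_results))
    write_identification_json(result$roi_results,
                              file.path(config$out_dir,
                                        "identification_roi.json"))
  log <- result$log
  log$config_md5 <- unname(tools::md5sum(cfg_json))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Encoding pipeline run (mode %s, seed %d)\n",
              x$config$mode, x$config$seed))
  print(x$identification)
  if (!is.null(x$roi_results)) {
    for (roi in names(x$roi_results)) {
      r <- x$roi_results[[roi]]
      cat(sprintf("  %-4s %s\n", roi,
                  if (is.na(r$accuracy)) "undefined (needs >= 2 voxels)"
                  else sprintf("%d/%d correct (%.1f%%)", r$n_correct, r$P,
                               100 * r$accuracy)))
    }
  }
  cat(sprintf("  total wall time: %.1fs\n", x$log$total_seconds))
  invisible(x)
}
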