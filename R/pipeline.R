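# End-to-end pipeline orchestration.
#
# simulate -> [magnify] -> ROI extraction -> estimator (feature-image CNN or
# meta-learning model) -> PPG/BPM -> metrics. One run seed fans out to every
# stochastic stage through derive_seed(), so a full run is reproducible.

#' Pipeline configuration
#'
#' Nested stage configurations plus a single run seed. Round-trips through
#' JSON losslessly via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param scene a [scene_config()] (used when simulating the input)
#' @param extractor an [extractor_config()]
#' @param magnify `NULL` (off, the default) or a [magnify_config()]
#' @param model `"evm"` or `"meta"`
#' @param adapt_steps transductive adaptation steps for the meta model
#' @param seed run seed
#' @param out_dir optional output directory for predictions and reports
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(scene = scene_config(), extractor = extractor_config(),
                            magnify = NULL, model = c("evm", "meta"),
                            adapt_steps = 0L, seed = 1L, out_dir = NULL) {
  model <- match.arg(model)
  structure(list(scene = scene, extractor = extractor, magnify = magnify,
                 model = model, adapt_steps = as.integer(adapt_steps),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#' @param config a [pipeline_config()]
#' @param path JSON file
#' @return `path` (write) or the restored `pipeline_config` (read)
#' @export
write_pipeline_config <- function(config, path) {
  drop_null <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[!vapply(x, is.null, TRUE)]
    lapply(x, drop_null)
  }
  jsonlite::write_json(drop_null(unclass(config)), path, auto_unbox = TRUE,
                       digits = NA)
  path
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- do.call(scene_config, as.list(raw$scene))
  ex <- do.call(extractor_config, as.list(raw$extractor))
  mg <- if (!is.null(raw$magnify)) do.call(magnify_config, as.list(raw$magnify))
  pipeline_config(scene = sc, extractor = ex, magnify = mg,
                  model = raw$model, adapt_steps = raw$adapt_steps,
                  seed = raw$seed, out_dir = raw$out_dir)
}

#' Run the full pipeline on a synthetic scene
#'
#' Generates (or accepts) a clip, extracts stabilized ROIs, runs the selected
#' estimator, converts to BPM and — when ground truth is present — computes
#' the metrics report. An untrained model may be supplied to smoke-test the
#' chain; pass a trained `evm_fit` / `meta_fit` for real predictions.
#'
#' @param input a [scene_config()] or a `synthetic_clip`
#' @param config a [pipeline_config()]
#' @param fit optional trained `evm_fit` or `meta_fit` (default: a freshly
#'   initialized, untrained model of the configured kind)
#' @return list with `predictions`, `bpm` (summary BPM), `metrics` (or `NULL`
#'   when undefined), `log` (extractor track log)
#' @export
run_pipeline <- function(input, config = pipeline_config(), fit = NULL) {
  clip <- if (inherits(input, "synthetic_clip")) input else {
    sc <- input
    sc$seed <- derive_seed(config$seed, "scene")
    generate_clip(sc)
  }
  frames <- clip$frames
  if (clip$fps != 30) {
    frames <- resample_fps(frames, clip$fps, 30)
  }
  if (!is.null(config$magnify))
    frames <- magnify_stream(frames, 30, config$magnify)
  lms <- clip$landmarks
  if (clip$fps != 30) lms <- resample_fps(lms, clip$fps, 30)
  ext <- process_video(frames, lms, config$extractor, keep_frames = TRUE)
  gt_bpm <- clip$heart_rate
  if (config$model == "evm") {
    model <- fit %||% build_evm_network(
      evm_config(seed = derive_seed(config$seed, "evm")))
    # each ROI yields its own feature images; predictions are averaged
    preds <- lapply(c("left_eye", "right_eye", "lower_face"), function(rn)
      predict_evm(model, ext$crops[[rn]], fps = 30))
    if (inherits(preds[[1]], "ppg_trace")) {
      avg <- Reduce(`+`, lapply(preds, `[[`, "samples")) / length(preds)
      predictions <- ppg_trace(avg, preds[[1]]$fs)
      bpm_series <- ppg_to_bpm(predictions)
      bpm <- summarize_bpm(bpm_series)
    } else {
      bpm_series <- preds[[1]]
      bpm_series$bpm <- Reduce(`+`, lapply(preds, `[[`, "bpm")) / length(preds)
      bpm <- stats::median(bpm_series$bpm)
      predictions <- bpm_series
    }
  } else {
    model <- fit %||% build_meta_network(
      channels = if (config$extractor$grayscale) 1L else 3L,
      seed = derive_seed(config$seed, "meta"))
    composed <- lapply(seq_along(ext$crops$left_eye), function(i)
      compose_frame(ext$crops$left_eye[[i]], ext$crops$right_eye[[i]],
                    ext$crops$lower_face[[i]],
                    grayscale = config$extractor$grayscale))
    seqs <- make_sequences(composed, clip$ppg$samples)
    if (!length(seqs)) stop_cfg("meta pipeline needs at least 60 frames")
    res <- adapt_and_predict(model, seqs, k = config$adapt_steps)
    predictions <- res$ppg
    bpm_series <- res$bpm
    bpm <- if (!is.null(bpm_series)) summarize_bpm(bpm_series) else NA_real_
  }
  metrics <- NULL
  if (!is.null(bpm_series) && is.data.frame(bpm_series)) {
    ok <- bpm_series$valid %||% rep(TRUE, nrow(bpm_series))
    if (sum(ok) >= 2 && stats::sd(bpm_series$bpm[ok]) > 0)
      metrics <- tryCatch(
        compute_metrics(bpm_series$bpm[ok], rep(gt_bpm, sum(ok))),
        error = function(e) NULL)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_config(config, file.path(config$out_dir, "config.json"))
    if (is.data.frame(bpm_series))
      utils::write.csv(bpm_series, file.path(config$out_dir, "bpm.csv"),
                       row.names = FALSE)
    if (!is.null(metrics))
      jsonlite::write_json(as.list(metrics),
                           file.path(config$out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  list(predictions = predictions, bpm = bpm, bpm_series = bpm_series,
       metrics = metrics, log = ext$log)
}
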