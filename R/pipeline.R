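#' Acquisition frequency of a line-scanned ultrasound probe
#'
#' Each beamline requires one transmit/receive round trip, so a frame of
#' `l` lines at depth `d` metres limits the frame rate to
#' `f = c / (2 d l)` Hz. Acquiring half or a quarter of the lines doubles
#' or quadruples the achievable frame rate, which is what beamline
#' super-resolution trades on.
#'
#' @param c Speed of sound in m/s (soft tissue: 1540).
#' @param d Imaging depth in metres.
#' @param l Number of acquired beamlines per frame.
#' @return Frame rate in Hz.
#' @export
acquisition_frequency <- function(c = 1540, d, l) {
  if (any(c(c, d, l) <= 0)) stop("all arguments must be positive")
  c / (2 * d * l)
}

#' Super-resolve one low-resolution image
#'
#' The two-stage reconstruction: cubic-convolution up-sampling restores
#' the full line grid, then the trained network refines the interpolated
#' image. The intermediate up-sampled image is returned alongside the
#' prediction for side-by-side evaluation.
#'
#' @param lowres Low-resolution `us_image` (acquired lines only).
#' @param model A trained `wdsr_model`.
#' @param scheme The [sampling_scheme()] describing the decimation.
#' @return List with `prediction` and `upsampled` (both `us_image` with
#'   `scheme$factor * n_lines(lowres)` lines).
#' @export
superresolve_image <- function(lowres, model, scheme) {
  upsampled <- upsample_beamlines(lowres, scheme)
  prediction <- predict(model, upsampled)
  list(prediction = prediction, upsampled = upsampled)
}

#' Super-resolve a video frame by frame
#'
#' Applies [superresolve_image()] independently to each frame (the model
#' is stateless across frames; there is no temporal coupling).
#'
#' @param frames List of low-resolution `us_image` frames sharing one
#'   shape.
#' @param model A trained `wdsr_model`.
#' @param scheme The [sampling_scheme()] describing the decimation.
#' @return List with `predictions` and `upsampled`, each a list of
#'   `us_image` frames in input order.
#' @export
superresolve_video <- function(frames, model, scheme) {
  if (length(frames) == 0) stop("empty frame sequence")
  dims <- vapply(frames, function(f) dim(pixel_matrix(f)), integer(2))
  if (any(dims != dims[, 1])) stop("all frames must share one shape")
  out <- lapply(frames, superresolve_image, model = model, scheme = scheme)
  list(predictions = lapply(out, `[[`, "prediction"),
       upsampled = lapply(out, `[[`, "upsampled"))
}

#' Experiment configuration
#'
#' Bundles every knob of a desk-scale end-to-end run: phantom data-set
#' sizes and dimensions, the up-sampling factor, network width and
#' training schedule, and output options. One configuration corresponds to
#' one trained network (one district x one factor).
#'
#' @param up_factor Up-sampling factor, 2 or 4.
#' @param n_train,n_val,n_test Split sizes; the splits are disjoint by
#'   construction (different sub-seeds).
#' @param lines,depth Phantom dimensions.
#' @param n_feats,expansion,n_blocks Network width parameters; defaults
#'   are the desk-scale reduced width (`n_feats = 8`).
#' @param epochs,batch_size,lr_init Training schedule.
#' @param seed Master seed for data generation, initialisation, shuffling.
#' @param district District tag stamped on generated images and reports.
#' @param denoise_hook Optional `function(us_image) -> us_image` applied
#'   to every image before pairing (a pluggable pre-processing slot, e.g.
#'   for an external denoiser); `NULL` leaves the raw pathway untouched.
#' @param out_dir Optional directory for reports and figures.
#' @param write_figures Also write box-plot and error-histogram PNGs
#'   (requires `out_dir`).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(up_factor = 2L, n_train = 150L, n_val = 25L,
                              n_test = 25L, lines = 64L, depth = 64L,
                              n_feats = 8L, expansion = 6L, n_blocks = 8L,
                              epochs = 30L, batch_size = 16L, lr_init = 1e-3,
                              seed = 1L, district = "phantom",
                              denoise_hook = NULL, out_dir = NULL,
                              write_figures = FALSE) {
  stopifnot(up_factor %in% c(2L, 4L), n_train >= 1, n_test >= 1)
  if (!is.null(denoise_hook)) stopifnot(is.function(denoise_hook))
  structure(list(up_factor = as.integer(up_factor),
                 n_train = as.integer(n_train), n_val = as.integer(n_val),
                 n_test = as.integer(n_test), lines = as.integer(lines),
                 depth = as.integer(depth), n_feats = as.integer(n_feats),
                 expansion = as.integer(expansion),
                 n_blocks = as.integer(n_blocks),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr_init = lr_init,
                 seed = as.integer(seed), district = district,
                 denoise_hook = denoise_hook, out_dir = out_dir,
                 write_figures = isTRUE(write_figures)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Scalar fields of the file override the defaults of
#' [experiment_config()].
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: ", ext)
  )
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(experiment_config, vals)
}

# Per-image evaluation record of one reconstruction against its target.
eval_record <- function(target, recon) {
  hist <- error_histogram(target, recon)
  data.frame(psnr = us_psnr(target, recon), ssim = us_ssim(target, recon),
             mae = us_mae(target, recon),
             first_bin_count = attr(hist, "first_bin"),
             max_abs_error = error_image(target, recon)$max)
}

#' Run a full desk-scale super-resolution experiment
#'
#' End-to-end protocol: generate a phantom data set, split it into
#' disjoint train/validation/test sets, build training pairs by beamline
#' decimation and cubic up-sampling, train the refinement network, and
#' evaluate both the network prediction and the cubic-convolution input
#' against the targets on the test split (PSNR, SSIM, MAE, first-bin
#' count, maximum absolute error, and the maximum |input - prediction|
#' alteration). Cohort statistics are Tukey box-plot summaries. The whole
#' run is deterministic for a fixed seed.
#'
#' @param cfg An [experiment_config()].
#' @return An object of class `sr_experiment` with elements `per_image`
#'   (data frame: one row per test image and method), `cohort` (named
#'   summaries), `history` (training history), `model`, and `cfg`. If
#'   `cfg$out_dir` is set, per-image CSV, cohort JSON, history CSV and a
#'   run manifest are written there.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  n_total <- cfg$n_train + cfg$n_val + cfg$n_test
  images <- generate_dataset(n_total, seed = cfg$seed, lines = cfg$lines,
                             depth = cfg$depth)
  images <- lapply(images, function(im) {
    im$district <- cfg$district
    if (!is.null(cfg$denoise_hook)) im <- cfg$denoise_hook(im)
    im
  })
  splits <- list(train = images[seq_len(cfg$n_train)],
                 val = images[cfg$n_train + seq_len(cfg$n_val)],
                 test = images[cfg$n_train + cfg$n_val + seq_len(cfg$n_test)])
  scheme <- sampling_scheme(cfg$up_factor)
  pairs <- lapply(splits, function(set) {
    lapply(set, make_training_pair, scheme = scheme)
  })
  mean_shift <- mean(vapply(pairs$train,
                            function(p) mean(pixel_matrix(p$input)),
                            numeric(1)))
  net_cfg <- network_config(cfg$up_factor, n_feats = cfg$n_feats,
                            expansion = cfg$expansion,
                            n_blocks = cfg$n_blocks)
  model <- with_seed(cfg$seed, build_network(net_cfg, mean_shift = mean_shift))
  fit <- train_network(
    model, pairs$train,
    train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                 lr_init = cfg$lr_init, seed = cfg$seed),
    loss_config(cfg$up_factor),
    validation = pairs$val
  )
  per_image <- do.call(rbind, lapply(seq_along(pairs$test), function(i) {
    p <- pairs$test[[i]]
    pred <- predict(fit$model, p$input)
    rec_p <- eval_record(p$target, pred)
    rec_i <- eval_record(p$target, p$input)
    alter <- error_image(p$input, pred)$max
    rbind(cbind(image = i, method = "prediction", rec_p,
                max_input_pred_diff = alter),
          cbind(image = i, method = "input", rec_i,
                max_input_pred_diff = alter))
  }))
  cohort <- list()
  for (m in c("psnr", "ssim", "mae", "first_bin_count")) {
    for (meth in c("prediction", "input")) {
      vals <- per_image[per_image$method == meth, m]
      cohort[[paste(m, meth, sep = "_")]] <- cohort_summary(vals)
    }
  }
  out <- structure(list(per_image = per_image, cohort = cohort,
                        history = fit$history, model = fit$model, cfg = cfg),
                   class = "sr_experiment")
  if (!is.null(cfg$out_dir)) write_experiment(out)
  out
}

# Write the report files (and optional figures) of a finished experiment.
write_experiment <- function(exp) {
  cfg <- exp$cfg
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_metrics_report(exp$per_image, exp$cohort, cfg$out_dir)
  write.csv(exp$history, file.path(cfg$out_dir, "training_history.csv"),
            row.names = FALSE)
  manifest <- list(report_version = "1.0", district = cfg$district,
                   up_factor = cfg$up_factor,
                   splits = list(train = cfg$n_train, val = cfg$n_val,
                                 test = cfg$n_test),
                   image_size = list(lines = cfg$lines, depth = cfg$depth),
                   epochs = cfg$epochs, seed = cfg$seed,
                   parameter_count = model_parameter_count(exp$model),
                   denoised = !is.null(cfg$denoise_hook))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  save_model(exp$model, file.path(cfg$out_dir, "model.rds"))
  if (cfg$write_figures) write_experiment_figures(exp)
  invisible(cfg$out_dir)
}

write_experiment_figures <- function(exp) {
  cfg <- exp$cfg
  pi <- exp$per_image
  grDevices::png(file.path(cfg$out_dir, "psnr_boxplot.png"), 600, 500)
  graphics::boxplot(psnr ~ method, data = pi, range = 1.5,
                    col = c("indianred", "steelblue"),
                    main = sprintf("PSNR, %dX, %d test images",
                                   cfg$up_factor, cfg$n_test),
                    ylab = "PSNR [dB]")
  grDevices::dev.off()
  grDevices::png(file.path(cfg$out_dir, "error_histogram.png"), 600, 500)
  pred_err <- pi[pi$method == "prediction", "first_bin_count"]
  in_err <- pi[pi$method == "input", "first_bin_count"]
  graphics::boxplot(list(input = in_err, prediction = pred_err),
                    col = c("indianred", "steelblue"),
                    main = "Pixels with error < 5 (first bin)",
                    ylab = "pixel count")
  grDevices::dev.off()
  invisible(NULL)
}

#' @export
print.sr_experiment <- function(x, ...) {
  ch <- x$cohort
  cat(sprintf("<sr_experiment> %dX, %d test images\n", x$cfg$up_factor,
              x$cfg$n_test))
  cat(sprintf("  median PSNR: input %.2f dB -> prediction %.2f dB\n",
              ch$psnr_input$median, ch$psnr_prediction$median))
  cat(sprintf("  median SSIM: input %.4f -> prediction %.4f\n",
              ch$ssim_input$median, ch$ssim_prediction$median))
  cat(sprintf("  median MAE:  input %.3f -> prediction %.3f (grey levels)\n",
              ch$mae_input$median, ch$mae_prediction$median))
  invisible(x)
}
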