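# End-to-end orchestration: configuration, file IO and the full
# simulate -> render -> segment -> measure -> statistic -> gate pipeline.

#' Write an intensity or label matrix as a 16-bit grayscale TIFF
#'
#' @param x Integer matrix with values in `[0, 2^bit_depth - 1]`.
#' @param path Output path.
#' @param bit_depth Bit depth used for scaling (default 16).
#' @export
write_image_tiff <- function(x, path, bit_depth = 16) {
  top <- 2^bit_depth - 1
  if (any(x < 0) || any(x > top))
    stop("values out of range for ", bit_depth, "-bit TIFF")
  tiff::writeTIFF(x / top, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a TIFF written by [write_image_tiff()] back to an integer matrix
#'
#' @param path TIFF path.
#' @param bit_depth Bit depth used when writing (default 16).
#' @return Integer matrix.
#' @export
read_image_tiff <- function(path, bit_depth = 16) {
  m <- round(tiff::readTIFF(path) * (2^bit_depth - 1))
  storage.mode(m) <- "integer"
  m
}

#' Default pipeline configuration
#'
#' A nested list with one block per pipeline stage, serialisable to YAML
#' with [write_config()]. The defaults describe the reference experiment:
#' 10,000 cells with a 0.44 labelled fraction, a 300-cell rendered field,
#' 0.2% formaldehyde post-fixation immediately after antibody incubation,
#' and flow-style acquisition of one event per cell.
#'
#' @param seed Global integer seed recorded in the config.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    population = list(n_cells = 10000L, frac_replicating = 0.44,
                      mu_signal_R = 2000, mu_signal_nonR = 100,
                      cv_R = 0.3, cv_nonR = 0.1),
    cell_cycle = list(frac_g1 = 0.45, frac_s = 0.44, frac_g2m = 0.11,
                      dna_g1 = 100, dna_cv = 0.05),
    imaging = list(width = 1024L, height = 1024L, radius_min = 8,
                   radius_max = 14, min_center_spacing = 2,
                   gaussian_noise_sd = 10, poisson_noise = FALSE,
                   bit_depth = 16L, dapi_gain = 1000, n_rendered = 300L),
    segmentation = list(threshold_method = "otsu", min_area = 50,
                        max_area = 5000, split_touching = TRUE,
                        smoothing_sigma = 2),
    kinetics = list(antibody = "Bu20a", k_off = log(5) / 5),
    wash = list(t_wash = 0, stabilised = TRUE, formaldehyde_conc = 0.2),
    flow = list(noise_cv = 0.05),
    analysis = list(f = 0.44),
    gating = list(signal_threshold_mode = "otsu_log", k_sigma = 3,
                  g1_g2m_boundary = 1.5)
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config Configuration list (see [default_config()]).
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  config <- yaml::read_yaml(path)
  defaults <- default_config()
  for (block in names(defaults)) {
    if (is.null(config[[block]])) config[[block]] <- defaults[[block]]
    else if (is.list(defaults[[block]]))
      config[[block]] <- utils::modifyList(defaults[[block]], config[[block]])
  }
  config
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

# Write a CSV with a provenance comment line (config hash + seed) above the
# header; read back with utils::read.csv(..., comment.char = "#").
write_csv_prov <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# replicyte run: config %s seed %s", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Executes simulate -> render -> segment -> measure -> R/non-R statistic ->
#' flow simulation -> cell-cycle gating, writing every intermediate plus a
#' JSON manifest with file hashes and a summary (estimated labelled
#' fraction, R/non-R ratio on both the truth table and the image-derived
#' measurements, phase fractions). Deterministic for a fixed config and
#' seed. The R/non-R statistic is computed both on the full truth table
#' (exact group counts at the configured population size) and on the
#' per-nucleus measurements recovered from the rendered field.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `config$seed` when given.
#' @param plot If `TRUE` (default), the gating report also renders the
#'   bivariate PNG plot.
#' @return Invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         seed = NULL, plot = TRUE) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)

  pop <- config$population
  pop_par <- population_params(n_cells = pop$n_cells,
                               frac_replicating = pop$frac_replicating,
                               mu_signal_R = pop$mu_signal_R,
                               mu_signal_nonR = pop$mu_signal_nonR,
                               cv_R = pop$cv_R, cv_nonR = pop$cv_nonR,
                               seed = seed)
  cyc <- config$cell_cycle
  cyc_par <- cell_cycle_params(frac_g1 = cyc$frac_g1, frac_s = cyc$frac_s,
                               frac_g2m = cyc$frac_g2m, dna_g1 = cyc$dna_g1,
                               dna_cv = cyc$dna_cv)
  truth <- run_stage("simulate", generate_population(pop_par, cyc_par))

  kin <- antibody_kinetics(name = config$kinetics$antibody,
                           k_off = config$kinetics$k_off)
  wash <- config$wash
  truth <- run_stage("wash", apply_wash_dissociation(
    truth, kin, t_wash = wash$t_wash, stabilised = isTRUE(wash$stabilised),
    formaldehyde_conc = wash$formaldehyde_conc))

  im <- config$imaging
  img_par <- imaging_params(width = im$width, height = im$height,
                            radius_range = c(im$radius_min, im$radius_max),
                            min_center_spacing = im$min_center_spacing,
                            gaussian_noise_sd = im$gaussian_noise_sd,
                            poisson_noise = im$poisson_noise,
                            bit_depth = im$bit_depth,
                            dapi_gain = im$dapi_gain, seed = seed + 1L)
  n_render <- min(im$n_rendered, nrow(truth))
  field <- withr::with_seed(seed + 2L,
                            truth[sample.int(nrow(truth), n_render), ])
  rendered <- run_stage("render", render_images(field, img_par))

  seg <- config$segmentation
  seg_par <- segmentation_params(threshold_method = seg$threshold_method,
                                 min_area = seg$min_area,
                                 max_area = seg$max_area,
                                 split_touching = seg$split_touching,
                                 smoothing_sigma = seg$smoothing_sigma)
  labels_pred <- run_stage("segment",
                           segment_nuclei(rendered$dapi, seg_par))
  meas <- run_stage("measure",
                    measure_nuclei(labels_pred, rendered$signal,
                                   rendered$dapi))

  f <- config$analysis$f
  fhat <- run_stage("rnonr", estimate_f(truth$true_signal))
  rn_truth <- run_stage("rnonr", r_nonr_ratio(truth$true_signal, f = f))
  rn_image <- run_stage("rnonr", r_nonr_ratio(meas$signal_mean, f = f))

  events <- run_stage("flow",
                      generate_flow_events(truth,
                                           noise_cv = config$flow$noise_cv,
                                           seed = seed + 3L))
  gp <- config$gating
  gate_par <- gating_params(signal_threshold_mode = gp$signal_threshold_mode,
                            k_sigma = gp$k_sigma,
                            g1_g2m_boundary = gp$g1_g2m_boundary)
  gating <- run_stage("gate", gate_phases(events, gate_par))

  # --- outputs -------------------------------------------------------------
  paths <- c(truth = "truth.csv", events = "events.csv",
             measurements = "measurements.csv", gating = "gating.csv",
             dapi = "dapi.tif", signal = "signal.tif", labels = "labels.tif",
             labels_pred = "labels_pred.tif", config = "config.yaml",
             summary = "summary.json")
  fp <- function(k) file.path(out_dir, paths[[k]])
  write_csv_prov(truth, fp("truth"), hash, seed)
  write_csv_prov(events, fp("events"), hash, seed)
  write_csv_prov(meas, fp("measurements"), hash, seed)
  write_csv_prov(gating$events, fp("gating"), hash, seed)
  write_image_tiff(rendered$dapi, fp("dapi"), im$bit_depth)
  write_image_tiff(rendered$signal, fp("signal"), im$bit_depth)
  write_image_tiff(rendered$labels, fp("labels"), im$bit_depth)
  write_image_tiff(labels_pred, fp("labels_pred"), im$bit_depth)
  write_config(config, fp("config"))

  summary <- list(
    seed = seed, config_hash = hash,
    n_cells = nrow(truth), n_rendered = n_render,
    n_segmented = max(labels_pred),
    f_estimate = list(f_hat = fhat$f_hat, separation = fhat$separation,
                      reliable = fhat$reliable),
    rnonr_truth = unclass(rn_truth),
    rnonr_image = unclass(rn_image),
    gating = list(fractions = as.list(gating$fractions),
                  g1_peak = gating$g1_peak,
                  signal_threshold = gating$signal_threshold))
  jsonlite::write_json(summary, fp("summary"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  report_files <- run_stage("report", {
    rep <- if (plot) cycle_report(gating, out_dir) else NULL
    if (plot) basename(c(rep$summary_csv, rep$plot)) else character()
  })

  hashed <- vapply(unname(paths), function(p)
    unname(tools::md5sum(file.path(out_dir, p))), character(1))
  manifest <- list(package = "replicyte",
                   version = as.character(utils::packageVersion("replicyte")),
                   seed = seed, config_hash = hash,
                   files = data.frame(path = unname(paths), md5 = hashed),
                   extra_files = report_files,
                   summary = summary)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
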