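# End-to-end pipeline: a declarative config drives simulation and the
# analysis stages, with one run seed fanned out deterministically to
# per-stage seeds, JSON/CSV reports, and a log. Reports contain no
# timestamps, so identical configs give identical report files.

pipeline_stages <- c("simulate", "deconvolve", "kinetics", "spots",
                     "ifquant")

#' Default pipeline configuration
#'
#' Mirrors the synthetic-data defaults: a 98.1% monomer mixture of 5000
#' spots for deconvolution, a two-phase recruitment trace sampled every
#' 0.5 min over [-2, 15] min, a short TIRF movie at 25 spots per 100 µm²,
#' and a 20-cell immunofluorescence field.
#'
#' @param seed Run seed. Default 1.
#' @param stages Stages to execute, a subset of `simulate`, `deconvolve`,
#'   `kinetics`, `spots`, `ifquant`.
#' @return A nested config list.
#' @export
default_config <- function(seed = 1, stages = pipeline_stages) {
  list(
    seed = seed,
    stages = stages,
    simulate = list(
      n_calib = 5000, n_expt = 5000,
      fractions = c(0.981, 0.019, 0),
      monomer = list(log_mean = log(1000), log_sd = 0.4),
      mixture_mode = "scale",
      kinetics = list(F_max = 1, n_syn = 2, tau_syn = 1 / 1.09,
                      n_deg = 2, tau_deg = 1 / 0.13, F0 = 0),
      trace = list(t_min = -2, t_max = 15, dt = 0.5, noise_sd = 0.05),
      movie = list(n_frames = 3, spot_density = 25),
      iffield = list(n_cells = 20, frac_transfected = 0.3)),
    deconvolve = list(max_order = 3, mode = "scale", n_bins = 50),
    kinetics = list(n_boot = 0),
    spots = list(min_snr = 5),
    ifquant = list(min_area = 10))
}

#' Validate a pipeline configuration
#'
#' Checks seeds, stage names, ranges and the simplex constraint. Never
#' throws for content problems; violations are returned as character
#' messages (an empty vector means the config is valid).
#'
#' @param config Config list (see [default_config()]).
#' @return Character vector of violations; `character(0)` if valid.
#' @export
validate_config <- function(config) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  if (is.null(config$seed) || !is.numeric(config$seed))
    add("seed: missing or non-numeric")
  bad <- setdiff(config$stages, pipeline_stages)
  if (length(bad))
    add(sprintf("stages: unknown stage(s) %s", paste(bad, collapse = ", ")))
  sim <- config$simulate
  if (!is.null(sim$fractions)) {
    if (any(sim$fractions < 0))
      add("simulate$fractions: negative weight")
    if (abs(sum(sim$fractions) - 1) > 1e-9)
      add(sprintf("simulate$fractions: sum %.6f != 1", sum(sim$fractions)))
  }
  if (!is.null(sim$monomer$log_sd) && sim$monomer$log_sd <= 0)
    add("simulate$monomer$log_sd: must be > 0")
  if (!is.null(sim$trace$dt) && sim$trace$dt <= 0)
    add("simulate$trace$dt: must be > 0")
  if (!is.null(sim$movie$spot_density) && sim$movie$spot_density < 0)
    add("simulate$movie$spot_density: must be >= 0")
  if (!is.null(config$deconvolve$max_order) &&
      config$deconvolve$max_order < 1)
    add("deconvolve$max_order: must be >= 1")
  if (!is.null(config$spots$pixel_size) && config$spots$pixel_size <= 0)
    add("spots$pixel_size: must be > 0")
  v
}

# Polynomial rolling hash of the JSON-serialized config; fingerprints a
# run without external digest dependencies.
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

write_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the configured pipeline
#'
#' Executes the requested stages in order simulate, deconvolve, kinetics,
#' spots, ifquant, writing each stage's inputs/outputs and a JSON report
#' into `out_dir`. Every report carries the config hash; a log file
#' records package version, per-stage seeds and timings. A stage failure
#' raises an error naming the stage; outputs of completed stages are kept.
#'
#' @param config Config list (see [default_config()]); validated first.
#' @param out_dir Run directory (created if needed).
#' @return Invisibly, a named list of stage reports.
#' @export
run_pipeline <- function(config, out_dir) {
  viol <- validate_config(config)
  if (length(viol))
    stop_arg("invalid config:\n  %s", paste(viol, collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  cat(sprintf("run %s | smolsensor %s | started %s\n", hash,
              as.character(utils::packageVersion("smolsensor")),
              format(Sys.time())), file = log_path)
  write_report(config, file.path(out_dir, "config.json"))
  reports <- list()
  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    seed <- derive_seed(config$seed, match(name, pipeline_stages))
    t0 <- proc.time()[["elapsed"]]
    rep <- tryCatch(fun(seed),
                    error = function(e)
                      stop_arg("stage '%s' failed: %s", name,
                               conditionMessage(e)))
    logline("stage %s: seed %d, %.2f s", name, seed,
            proc.time()[["elapsed"]] - t0)
    rep$stage <- name
    rep$config_hash <- hash
    rep$seed <- seed
    write_report(rep, file.path(out_dir, paste0(name, ".json")))
    reports[[name]] <<- rep
  }
  sim <- config$simulate
  run_stage("simulate", function(seed) {
    model <- monomer_model(sim$monomer$log_mean, sim$monomer$log_sd)
    calib <- gen_monomer_intensities(sim$n_calib, model,
                                     seed = derive_seed(seed, 1))
    mix <- gen_multimer_mixture(sim$n_expt, sim$fractions, model,
                                mode = sim$mixture_mode,
                                seed = derive_seed(seed, 2))
    utils::write.csv(data.frame(intensity = calib),
                     file.path(out_dir, "calibration.csv"),
                     row.names = FALSE)
    utils::write.csv(mix, file.path(out_dir, "experiment.csv"),
                     row.names = FALSE)
    kp <- do.call(kinetic_params, sim$kinetics)
    tgrid <- seq(sim$trace$t_min, sim$trace$t_max, by = sim$trace$dt)
    tc <- gen_timecourse(kp, tgrid, noise_sd = sim$trace$noise_sd,
                         seed = derive_seed(seed, 3))
    write_timecourse(tc, file.path(out_dir, "trace.csv"))
    spec <- scene_spec(spot_density = sim$movie$spot_density)
    movie <- gen_tirf_movie(spec, n_frames = sim$movie$n_frames,
                            model = model, seed = derive_seed(seed, 4))
    write_image_tiff(movie$frames, file.path(out_dir, "movie.tif"),
                     max_value = 65535)
    utils::write.csv(movie$truth, file.path(out_dir, "movie_truth.csv"),
                     row.names = FALSE)
    field <- gen_if_field(sim$iffield$n_cells,
                          frac_transfected = sim$iffield$frac_transfected,
                          seed = derive_seed(seed, 5))
    for (nm in names(field$channels))
      write_image_tiff(field$channels[[nm]],
                       file.path(out_dir, paste0("if_", nm, ".tif")),
                       max_value = 4095)
    utils::write.csv(field$truth, file.path(out_dir, "if_truth.csv"),
                     row.names = FALSE)
    list(n_calib = sim$n_calib, n_expt = sim$n_expt,
         fractions = sim$fractions,
         files = c("calibration.csv", "experiment.csv", "trace.csv",
                   "movie.tif", "movie_truth.csv",
                   paste0("if_", names(field$channels), ".tif"),
                   "if_truth.csv"))
  })
  run_stage("deconvolve", function(seed) {
    dc <- config$deconvolve
    calib <- utils::read.csv(file.path(out_dir, "calibration.csv"))$intensity
    expt <- utils::read.csv(file.path(out_dir, "experiment.csv"))$intensity
    rho1 <- build_histogram(calib, n_bins = dc$n_bins)
    basis <- derive_basis(rho1, M = dc$max_order, mode = dc$mode)
    eh <- build_histogram(expt, n_bins = dc$n_bins * dc$max_order,
                          range = range(basis$bin_edges))
    fit <- fit_mixture(eh, basis, seed = seed)
    utils::write.csv(
      data.frame(bin_lo = basis$bin_edges[-length(basis$bin_edges)],
                 bin_hi = basis$bin_edges[-1], observed = eh$counts),
      file.path(out_dir, "deconvolution_histogram.csv"), row.names = FALSE)
    list(fractions = fit$fractions, monomer_percent = 100 * fit$fractions[1],
         chi2_red = fit$chi2_red, dof = fit$dof, mode = dc$mode,
         M = dc$max_order)
  })
  run_stage("kinetics", function(seed) {
    tc <- read_timecourse(file.path(out_dir, "trace.csv"))
    fit <- fit_timecourse(tc, seed = seed)
    if (!fit$converged) stop("kinetic fit did not converge")
    rep <- list(params = unclass(fit$params), k_syn = fit$rates$k_syn,
                k_deg = fit$rates$k_deg, rss = fit$rss)
    nb <- config$kinetics$n_boot
    if (!is.null(nb) && nb >= 100) {
      ci <- bootstrap_ci(tc, n_boot = nb, seed = seed, fit = fit)
      rep$ci <- cbind(parameter = rownames(ci), as.data.frame(ci))
    }
    rep
  })
  run_stage("spots", function(seed) {
    movie <- read_image_tiff(file.path(out_dir, "movie.tif"),
                             max_value = 65535)
    spec <- scene_spec(spot_density = sim$movie$spot_density)
    tab <- detect_spots(movie, pixel_size = spec$pixel_size,
                        min_snr = config$spots$min_snr,
                        psf_sigma = spec$psf_sigma)
    write_spot_table(tab, file.path(out_dir, "spots.csv"))
    dens <- spot_density(tab, roi_area = prod(spec$fov_size),
                         per_frame = TRUE)
    utils::write.csv(dens, file.path(out_dir, "density.csv"),
                     row.names = FALSE)
    list(n_spots = nrow(tab), mean_density = mean(dens$density))
  })
  run_stage("ifquant", function(seed) {
    px <- 0.5
    ch <- list(dapi = read_image_tiff(file.path(out_dir, "if_dapi.tif"),
                                      max_value = 4095),
               cellmask = read_image_tiff(
                 file.path(out_dir, "if_cellmask.tif"), max_value = 4095),
               reporter = read_image_tiff(
                 file.path(out_dir, "if_reporter.tif"), max_value = 4095),
               stain = read_image_tiff(file.path(out_dir, "if_stain.tif"),
                                       max_value = 4095))
    res <- if_quantify(list(channels = ch, pixel_size = px),
                       min_area = config$ifquant$min_area)
    utils::write.csv(res$rois, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    list(n_cells = nrow(res$rois), cutoff = res$gating$cutoff,
         n_positive = res$gating$n_positive)
  })
  logline("done")
  invisible(reports)
}

#' Read / write a config as YAML
#'
#' @param path YAML file path.
#' @param config Config list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
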