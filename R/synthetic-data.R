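# Synthetic-data generators: intensity samples, TIRF frames and movies,
# recruitment time courses and immunofluorescence fields, all with ground
# truth and explicit seeds.

#' Lognormal monomer intensity model
#'
#' Describes the integrated spot intensity of a single fluorophore as a
#' lognormal distribution, the mono-modal shape observed for calibration
#' constructs imaged at single-molecule levels. Intensities are in camera
#' ADU after background subtraction.
#'
#' @param log_mean Location of the log-intensity (dimensionless); the
#'   distribution median is `exp(log_mean)`. Default `log(1000)` ADU, a
#'   plausible sCMOS/EMCCD scale.
#' @param log_sd Scale of the log-intensity; must be positive. Default 0.4.
#' @return An object of class `monomer_model`.
#' @examples
#' m <- monomer_model()
#' x <- gen_monomer_intensities(1000, m, seed = 1)
#' @export
monomer_model <- function(log_mean = log(1000), log_sd = 0.4) {
  check_scalar(log_mean, "log_mean")
  check_scalar(log_sd, "log_sd", positive = TRUE)
  structure(list(log_mean = log_mean, log_sd = log_sd),
            class = "monomer_model")
}

#' @export
print.monomer_model <- function(x, ...) {
  cat(sprintf("Lognormal monomer model: median %.1f ADU, log-sd %.3f\n",
              exp(x$log_mean), x$log_sd))
  invisible(x)
}

#' Draw monomer spot intensities
#'
#' @param n Number of samples (>= 0).
#' @param model A [monomer_model()].
#' @param seed Optional integer seed; identical seeds give identical samples.
#' @return Numeric vector of `n` strictly positive intensities (ADU).
#' @export
gen_monomer_intensities <- function(n, model = monomer_model(), seed = NULL) {
  check_scalar(n, "n", nonneg = TRUE, integerish = TRUE)
  stopifnot(inherits(model, "monomer_model"))
  with_seed(seed, stats::rlnorm(n, model$log_mean, model$log_sd))
}

#' Draw a labeled multimer intensity mixture
#'
#' Samples spot intensities from a mixture of c-mers (c = 1..M, where M is
#' the length of `fractions`). In `convolve` mode a c-mer intensity is the
#' sum of c independent monomer draws (independent emitters); in `scale`
#' mode it is c times a single monomer draw (axis-scaled monomer
#' distribution).
#'
#' @param n Number of spots.
#' @param fractions Mixture weights over c = 1..M; non-negative, summing
#'   to 1 within 1e-9.
#' @param model A [monomer_model()].
#' @param mode `"convolve"` (default) or `"scale"`.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `order` (true c) and `intensity` (ADU).
#' @export
gen_multimer_mixture <- function(n, fractions, model = monomer_model(),
                                 mode = c("convolve", "scale"), seed = NULL) {
  check_scalar(n, "n", nonneg = TRUE, integerish = TRUE)
  check_fractions(fractions)
  mode <- match.arg(mode)
  stopifnot(inherits(model, "monomer_model"))
  M <- length(fractions)
  with_seed(seed, {
    ord <- sample.int(M, n, replace = TRUE, prob = fractions)
    x <- numeric(n)
    for (c in seq_len(M)) {
      idx <- which(ord == c)
      if (!length(idx)) next
      if (mode == "convolve") {
        draws <- stats::rlnorm(length(idx) * c, model$log_mean, model$log_sd)
        x[idx] <- rowSums(matrix(draws, ncol = c))
      } else {
        x[idx] <- c * stats::rlnorm(length(idx), model$log_mean, model$log_sd)
      }
    }
    data.frame(order = ord, intensity = x)
  })
}

#' Imaging scene description
#'
#' Geometry, camera and noise parameters used to render synthetic TIRF
#' frames. The camera model is Poisson shot noise on (background + signal)
#' photons plus additive Gaussian read noise.
#'
#' @param fov_size Field of view, µm; scalar (square) or length-2 (x, y).
#' @param pixel_size Pixel pitch, µm. Default 0.087 (6.5 µm camera pixels
#'   behind 150x magnification with 2x binning).
#' @param psf_sigma Gaussian PSF standard deviation, µm. Default 0.085,
#'   the Gaussian approximation of a 1.45 NA objective's green-channel
#'   PSF. Must be at least `pixel_size/4` so spots are resolvable.
#' @param background Uniform background level, ADU.
#' @param read_noise_sd Gaussian read noise, ADU.
#' @param photon_scale Conversion gain, ADU per photon.
#' @param spot_density Default spot density, count per 100 µm².
#' @param bleach_prob_per_frame Per-frame probability that a spot bleaches.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(fov_size = c(10, 10), pixel_size = 0.087,
                       psf_sigma = 0.085, background = 100,
                       read_noise_sd = 2, photon_scale = 1,
                       spot_density = 25, bleach_prob_per_frame = 0) {
  if (length(fov_size) == 1L) fov_size <- rep(fov_size, 2L)
  stopifnot(length(fov_size) == 2L, all(fov_size > 0))
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(psf_sigma, "psf_sigma", positive = TRUE)
  if (psf_sigma < pixel_size / 4)
    stop_arg("psf_sigma must be >= pixel_size/4 for a resolvable PSF")
  check_scalar(background, "background", positive = TRUE)
  check_scalar(read_noise_sd, "read_noise_sd", nonneg = TRUE)
  check_scalar(photon_scale, "photon_scale", positive = TRUE)
  check_scalar(spot_density, "spot_density", nonneg = TRUE)
  check_scalar(bleach_prob_per_frame, "bleach_prob_per_frame", nonneg = TRUE)
  if (bleach_prob_per_frame > 1)
    stop_arg("bleach_prob_per_frame must be a probability")
  structure(list(fov_size = fov_size, pixel_size = pixel_size,
                 psf_sigma = psf_sigma, background = background,
                 read_noise_sd = read_noise_sd, photon_scale = photon_scale,
                 spot_density = spot_density,
                 bleach_prob_per_frame = bleach_prob_per_frame),
            class = "scene_spec")
}

#' Place ground-truth spots in a field of view
#'
#' Positions are uniform over the FOV (optionally inset by a margin);
#' intensities are drawn from the monomer model, or a multimer mixture when
#' `fractions` is given.
#'
#' @param spec A [scene_spec()]; `spec$spot_density` sets the expected count
#'   unless `n` is given.
#' @param n Exact number of spots; default derives it from the density.
#' @param model A [monomer_model()].
#' @param fractions Optional mixture weights (see [gen_multimer_mixture()]).
#' @param margin Inset from the FOV edge, µm.
#' @param seed Optional integer seed.
#' @return A data.frame (`x`, `y` in µm, `order`, `intensity` in ADU).
#' @export
gen_spot_field <- function(spec = scene_spec(), n = NULL,
                           model = monomer_model(), fractions = 1,
                           margin = 0, seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  area <- prod(spec$fov_size)
  if (is.null(n)) n <- round(spec$spot_density * area / 100)
  check_scalar(n, "n", nonneg = TRUE, integerish = TRUE)
  with_seed(seed, {
    mix <- gen_multimer_mixture(n, fractions, model)
    data.frame(
      x = stats::runif(n, margin, spec$fov_size[1] - margin),
      y = stats::runif(n, margin, spec$fov_size[2] - margin),
      order = mix$order, intensity = mix$intensity)
  })
}

#' Render one TIRF frame
#'
#' Draws each ground-truth spot as an integrated 2D Gaussian of total signal
#' equal to its true intensity, on a uniform background, then applies the
#' camera noise model (unless `noise = FALSE`). The expectation of the
#' background-subtracted image integral equals the summed true intensities
#' up to PSF truncation at the FOV edge.
#'
#' @param truth Data.frame with columns `x`, `y` (µm, inside the FOV) and
#'   `intensity` (ADU).
#' @param spec A [scene_spec()].
#' @param noise Apply shot + read noise? Default TRUE.
#' @param seed Optional integer seed (noise only).
#' @return Numeric matrix (rows = y, cols = x), ADU.
#' @export
render_tirf_frame <- function(truth, spec = scene_spec(), noise = TRUE,
                              seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(truth) || nrow(truth) == 0L)
    truth <- data.frame(x = numeric(), y = numeric(), intensity = numeric())
  if (nrow(truth) > 0 &&
      (any(truth$x < 0 | truth$x > spec$fov_size[1]) ||
       any(truth$y < 0 | truth$y > spec$fov_size[2])))
    stop_arg("spot positions must lie inside the field of view")
  nx <- max(1L, round(spec$fov_size[1] / spec$pixel_size))
  ny <- max(1L, round(spec$fov_size[2] / spec$pixel_size))
  img <- matrix(spec$background, nrow = ny, ncol = nx)
  s_px <- spec$psf_sigma / spec$pixel_size
  half <- ceiling(5 * s_px)
  for (i in seq_len(nrow(truth))) {
    # pixel-center coordinates: pixel j covers [(j-1)*px, j*px)
    cx <- truth$x[i] / spec$pixel_size + 0.5
    cy <- truth$y[i] / spec$pixel_size + 0.5
    jx <- max(1L, floor(cx - half)):min(nx, ceiling(cx + half))
    jy <- max(1L, floor(cy - half)):min(ny, ceiling(cy + half))
    if (!length(jx) || !length(jy)) next
    gx <- exp(-((jx - cx)^2) / (2 * s_px^2))
    gy <- exp(-((jy - cy)^2) / (2 * s_px^2))
    amp <- truth$intensity[i] / (2 * pi * s_px^2)
    img[jy, jx] <- img[jy, jx] + amp * outer(gy, gx)
  }
  if (noise) {
    img <- with_seed(seed, {
      photons <- stats::rpois(length(img), pmax(img, 0) / spec$photon_scale)
      matrix(photons * spec$photon_scale +
               stats::rnorm(length(img), 0, spec$read_noise_sd),
             nrow = ny, ncol = nx)
    })
  }
  img
}

#' Render a TIRF movie with photobleaching
#'
#' Spots are placed once and rendered in every frame until they bleach;
#' bleaching is a per-frame Bernoulli event with probability
#' `spec$bleach_prob_per_frame`. No new spots arrive.
#'
#' @param spec A [scene_spec()].
#' @param n_frames Number of frames.
#' @inheritParams gen_spot_field
#' @return List with `frames` (ny x nx x n_frames array) and `truth`
#'   (per-spot data.frame with `bleach_frame`, the last frame the spot is
#'   visible; `Inf` if it survives).
#' @export
gen_tirf_movie <- function(spec = scene_spec(), n_frames = 10, n = NULL,
                           model = monomer_model(), fractions = 1,
                           seed = NULL) {
  check_scalar(n_frames, "n_frames", positive = TRUE, integerish = TRUE)
  with_seed(seed, {
    truth <- gen_spot_field(spec, n = n, model = model, fractions = fractions,
                            margin = 3 * spec$psf_sigma)
    nspot <- nrow(truth)
    surv <- if (spec$bleach_prob_per_frame > 0 && nspot > 0)
      stats::rgeom(nspot, spec$bleach_prob_per_frame) + 1 else rep(Inf, nspot)
    truth$bleach_frame <- surv
    nx <- max(1L, round(spec$fov_size[1] / spec$pixel_size))
    ny <- max(1L, round(spec$fov_size[2] / spec$pixel_size))
    frames <- array(0, dim = c(ny, nx, n_frames))
    for (f in seq_len(n_frames))
      frames[, , f] <- render_tirf_frame(truth[truth$bleach_frame >= f, ,
                                               drop = FALSE], spec)
    list(frames = frames, truth = truth)
  })
}

#' Simulate a recruitment time course
#'
#' Evaluates the two-phase cooperative model (see [model_eval()]) on a time
#' grid and adds i.i.d. Gaussian noise expressed as a fraction of `F_max`.
#'
#' @param params A [kinetic_params()].
#' @param t_grid Strictly increasing times, minutes (stimulus at t = 0).
#' @param noise_sd Noise standard deviation as a fraction of `F_max`; >= 0.
#' @param seed Optional integer seed.
#' @return A [time_course()] data.frame (`t`, `F`).
#' @export
gen_timecourse <- function(params, t_grid, noise_sd = 0, seed = NULL) {
  if (any(diff(t_grid) <= 0))
    stop_arg("t_grid must be strictly increasing")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  f <- model_eval(params, t_grid)
  if (noise_sd > 0)
    f <- f + with_seed(seed,
                       stats::rnorm(length(t_grid), 0, noise_sd * params$F_max))
  time_course(t_grid, f)
}

#' Simulate a multichannel immunofluorescence field
#'
#' Cells are concentric disks: a bright nucleus (DAPI channel) inside a
#' larger cell body (cell-mask channel). Nuclei are placed without overlap
#' by rejection sampling. Per-cell reporter means are drawn from a Gaussian
#' untransfected population; a `frac_transfected` subset gets
#' `transfected_offset` added. The stain channel mirrors the reporter with
#' its own per-cell means. Mild Gaussian camera noise is added to every
#' channel. Morphological realism is deliberately absent: only segmentation
#' and gating logic are exercised.
#'
#' @param n_cells Number of cells (>= 0).
#' @param fov_px Field size in pixels (square).
#' @param pixel_size Pixel size, µm.
#' @param nucleus_radius,cell_radius Disk radii, µm.
#' @param untransfected_mean,untransfected_sd Gaussian per-cell reporter
#'   population (ADU, 12-bit convention).
#' @param transfected_offset Added reporter mean for transfected cells, ADU.
#' @param frac_transfected Fraction of transfected cells.
#' @param stain_mean,stain_sd Per-cell stain population (ADU).
#' @param background Channel background, ADU.
#' @param noise_sd Pixel noise, ADU.
#' @param seed Optional integer seed.
#' @return List with `channels` (named list of matrices: `dapi`, `cellmask`,
#'   `reporter`, `stain`), `truth` (per-cell data.frame: `cell`, `x`, `y`
#'   in µm, `reporter_mean`, `stain_mean`, `transfected`) and `pixel_size`.
#' @export
gen_if_field <- function(n_cells, fov_px = 400, pixel_size = 0.5,
                         nucleus_radius = 3.5, cell_radius = 7,
                         untransfected_mean = 50, untransfected_sd = 15,
                         transfected_offset = 300, frac_transfected = 0,
                         stain_mean = 200, stain_sd = 40,
                         background = 10, noise_sd = 2, seed = NULL) {
  check_scalar(n_cells, "n_cells", nonneg = TRUE, integerish = TRUE)
  check_scalar(fov_px, "fov_px", positive = TRUE, integerish = TRUE)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  with_seed(seed, {
    r_cell_px <- cell_radius / pixel_size
    margin <- r_cell_px + 2
    lo <- margin; hi <- fov_px - margin
    if (n_cells > 0 && hi <= lo)
      stop_arg("field of view too small for the requested cells")
    xs <- ys <- numeric(0)
    min_d2 <- (2 * nucleus_radius / pixel_size + 2)^2
    tries <- 0L
    while (length(xs) < n_cells) {
      if ((tries <- tries + 1L) > 2000L * max(n_cells, 1L))
        stop_arg("could not place %d non-overlapping cells in the field",
                 n_cells)
      px <- stats::runif(1, lo, hi); py <- stats::runif(1, lo, hi)
      if (!length(xs) || min((xs - px)^2 + (ys - py)^2) > min_d2) {
        xs <- c(xs, px); ys <- c(ys, py)
      }
    }
    transfected <- stats::runif(n_cells) < frac_transfected
    rep_mean <- stats::rnorm(n_cells, untransfected_mean, untransfected_sd) +
      ifelse(transfected, transfected_offset, 0)
    st_mean <- stats::rnorm(n_cells, stain_mean, stain_sd)
    blank <- matrix(background, fov_px, fov_px)
    ch <- list(dapi = blank, cellmask = blank, reporter = blank, stain = blank)
    col_idx <- matrix(rep(seq_len(fov_px), each = fov_px), fov_px)
    row_idx <- matrix(rep(seq_len(fov_px), times = fov_px), fov_px)
    r_nuc_px <- nucleus_radius / pixel_size
    for (i in seq_len(n_cells)) {
      d2 <- (row_idx - ys[i])^2 + (col_idx - xs[i])^2
      nuc <- d2 <= r_nuc_px^2
      body <- d2 <= r_cell_px^2
      ch$dapi[nuc] <- ch$dapi[nuc] + 500
      ch$cellmask[body] <- pmax(ch$cellmask[body], background + 300)
      ch$reporter[body] <- pmax(ch$reporter[body], background + rep_mean[i])
      ch$stain[body] <- pmax(ch$stain[body], background + st_mean[i])
    }
    if (noise_sd > 0)
      ch <- lapply(ch, function(m)
        m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m)))
    truth <- data.frame(cell = seq_len(n_cells),
                        x = xs * pixel_size, y = ys * pixel_size,
                        reporter_mean = rep_mean, stain_mean = st_mean,
                        transfected = transfected)
    list(channels = ch, truth = truth, pixel_size = pixel_size)
  })
}
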