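# Diffraction-limited spot detection, intensity extraction and molecule
# densities per 100 um^2 in TIRF image series. Pipeline: difference-of-
# Gaussians pre-filter, 8-connected local maxima above a robust noise
# threshold, duplicate suppression, then per-candidate 2D Gaussian
# least-squares refinement for sub-pixel coordinates and integrated
# intensity.

dog_filter <- function(image, sigma_px) {
  s1 <- max(sigma_px, 0.5)
  g1 <- EBImage::gblur(image, sigma = s1)
  g2 <- EBImage::gblur(image, sigma = 1.6 * s1)
  g1 - g2
}

local_maxima_8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  ok <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ok <- ok & (m >= pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  ok
}

# Least-squares fit of A*exp(-((x-x0)^2+(y-y0)^2)/(2 s^2)) + b on a window.
# Window of +-2.5 sigma: wide enough for the core, narrow enough that a
# neighbouring spot's tail rarely enters the fit in dense fields.
fit_gaussian_2d <- function(image, row0, col0, sigma_px, half = NULL) {
  if (is.null(half)) half <- ceiling(2.5 * sigma_px)
  nr <- nrow(image); nc <- ncol(image)
  rows <- max(1L, row0 - half):min(nr, row0 + half)
  cols <- max(1L, col0 - half):min(nc, col0 + half)
  z <- image[rows, cols]
  b0 <- min(z)
  a0 <- image[row0, col0] - b0
  par0 <- c(A = a0, r = row0, c = col0, ls = log(sigma_px), b = b0)
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  obj <- function(p) {
    s2 <- 2 * exp(2 * p[4])
    mu <- p[1] * exp(-((rr - p[2])^2 + (cc - p[3])^2) / s2) + p[5]
    sum((z - mu)^2)
  }
  opt <- tryCatch(
    stats::optim(par0, obj, method = "L-BFGS-B",
                 lower = c(0, row0 - half, col0 - half,
                           log(sigma_px) - 1.5, -Inf),
                 upper = c(Inf, row0 + half, col0 + half,
                           log(sigma_px) + 1.5, Inf)),
    error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  p <- opt$par
  sig <- exp(p[4])
  list(row = p[2], col = p[3], amplitude = p[1], sigma_px = sig,
       intensity = p[1] * 2 * pi * sig^2, background = p[5])
}

#' Detect diffraction-limited spots
#'
#' @param image 2D numeric matrix (one frame) or 3D array (stack, third
#'   dimension = frame), ADU.
#' @param pixel_size Pixel size, µm.
#' @param min_snr Detection threshold in units of the robust noise level of
#'   the band-pass response. Default 5.
#' @param psf_sigma Expected PSF standard deviation, µm. Default 0.085.
#' @return A `spot_table` data.frame: `frame` (0-based), `x`, `y` (µm,
#'   sub-pixel), `intensity` (integrated, ADU above local background),
#'   `sigma_fit` (µm).
#' @export
detect_spots <- function(image, pixel_size, min_snr = 5, psf_sigma = 0.085) {
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(min_snr, "min_snr", positive = TRUE)
  if (is.matrix(image)) {
    frames <- list(image)
  } else if (is.array(image) && length(dim(image)) == 3L) {
    frames <- lapply(seq_len(dim(image)[3]), function(f) image[, , f])
  } else stop_arg("'image' must be a 2D matrix or a 3D stack")
  sigma_px <- psf_sigma / pixel_size
  out <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    m <- frames[[f]]
    dog <- dog_filter(m, sigma_px)
    noise <- stats::mad(dog)
    thr <- stats::median(dog) + min_snr * noise
    cand <- which(local_maxima_8(dog) & dog > thr, arr.ind = TRUE)
    if (nrow(cand) == 0L) { out[[f]] <- NULL; next }
    spots <- list()
    for (i in seq_len(nrow(cand))) {
      g <- fit_gaussian_2d(m, cand[i, 1], cand[i, 2], sigma_px)
      if (is.null(g) || g$amplitude <= 0) next
      spots[[length(spots) + 1L]] <- data.frame(
        frame = f - 1L,
        x = (g$col - 0.5) * pixel_size,
        y = (g$row - 0.5) * pixel_size,
        intensity = g$intensity,
        sigma_fit = g$sigma_px * pixel_size)
    }
    if (!length(spots)) { out[[f]] <- NULL; next }
    tab <- do.call(rbind, spots)
    # merge duplicates closer than 2*psf_sigma, keeping the brighter
    if (nrow(tab) > 1L) {
      ord <- order(-tab$intensity)
      tab <- tab[ord, , drop = FALSE]
      keep <- rep(TRUE, nrow(tab))
      for (i in seq_len(nrow(tab))[-1]) {
        prev <- which(keep[seq_len(i - 1L)])
        d2 <- (tab$x[prev] - tab$x[i])^2 + (tab$y[prev] - tab$y[i])^2
        if (any(d2 < (2 * psf_sigma)^2)) keep[i] <- FALSE
      }
      tab <- tab[keep, , drop = FALSE]
    }
    out[[f]] <- tab
  }
  out <- out[!vapply(out, is.null, logical(1))]
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(), x = numeric(), y = numeric(),
               intensity = numeric(), sigma_fit = numeric())
  rownames(tab) <- NULL
  class(tab) <- c("spot_table", "data.frame")
  tab
}

#' Molecule density per 100 µm²
#'
#' @param table A spot table (needs a `frame` column for `per_frame`).
#' @param roi_area ROI area, µm²; > 0.
#' @param per_frame If TRUE, one density per frame; otherwise the pooled
#'   density `nrow(table) / roi_area * 100`.
#' @return For `per_frame`, a data.frame (`frame`, `count`, `density`);
#'   otherwise a single density (count per 100 µm²).
#' @export
spot_density <- function(table, roi_area, per_frame = FALSE) {
  check_scalar(roi_area, "roi_area", positive = TRUE)
  if (!per_frame) return(nrow(table) / roi_area * 100)
  if (nrow(table) == 0L)
    return(data.frame(frame = integer(), count = integer(),
                      density = numeric()))
  frames <- seq(0L, max(table$frame))
  counts <- vapply(frames, function(f) sum(table$frame == f), integer(1))
  data.frame(frame = frames, count = counts,
             density = counts / roi_area * 100)
}

#' Centered rolling average of a uniformly sampled trace
#'
#' Edge windows shrink symmetrically; the series length is preserved. With
#' a window of one sample interval the series is returned unchanged.
#'
#' @param tc A [time_course()] (uniform sampling).
#' @param window Window width in the units of `tc$t`; at least one sample
#'   interval.
#' @return A smoothed [time_course()].
#' @export
rolling_mean <- function(tc, window) {
  tc <- as_time_course(tc)
  dt <- diff(tc$t)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop_arg("rolling_mean requires uniform sampling")
  check_scalar(window, "window", positive = TRUE)
  if (window < dt[1] * (1 - 1e-9))
    stop_arg("window must be at least one sample interval")
  k <- max(1L, round(window / dt[1]))
  h1 <- (k - 1L) %/% 2L
  h2 <- k - 1L - h1
  n <- nrow(tc)
  cs <- c(0, cumsum(tc$F))
  lo <- pmax(seq_len(n) - h1, 1L)
  hi <- pmin(seq_len(n) + h2, n)
  time_course(tc$t, (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Normalize a trace to its pre-stimulus baseline (F/F0)
#'
#' @param tc A [time_course()].
#' @param baseline_window Indices defining the baseline; default all
#'   pre-stimulus points (t < 0).
#' @return A [time_course()] divided by the baseline mean F0.
#' @export
normalize_to_baseline <- function(tc, baseline_window = NULL) {
  tc <- as_time_course(tc)
  if (is.null(baseline_window)) baseline_window <- which(tc$t < 0)
  if (!length(baseline_window))
    stop_arg("baseline window is empty (no pre-stimulus points?)")
  F0 <- mean(tc$F[baseline_window])
  if (F0 <= 0)
    stop_arg("baseline F0 must be positive; subtract background first")
  time_course(tc$t, tc$F / F0)
}

#' Subtract the modal background level
#'
#' Estimates the background as the mode of the value histogram at 1-ADU
#' bin width (the most common pixel value, i.e. the camera level outside
#' cells) and subtracts it.
#'
#' @param x Numeric vector, matrix or `time_course` with >= 100 values.
#' @param clip Clip negative results at 0? Default FALSE.
#' @return Same shape as `x`, background-subtracted; the estimated mode is
#'   attached as attribute `mode` (not for time_course input).
#' @export
subtract_modal_background <- function(x, clip = FALSE) {
  if (inherits(x, "time_course")) {
    v <- x$F
    res <- subtract_modal_background(v, clip = clip)
    return(time_course(x$t, as.numeric(res)))
  }
  v <- as.numeric(x)
  if (length(v) < 100)
    stop_arg("modal background estimation needs at least 100 values")
  b <- floor(min(v)):(ceiling(max(v)) + 1L)
  idx <- findInterval(v, b, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(b) - 1L)
  mode_est <- mean(v[idx == which.max(counts)])
  out <- x - mode_est
  if (clip) out[out < 0] <- 0
  attr(out, "mode") <- mode_est
  out
}
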