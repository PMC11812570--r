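# Single-cell immunofluorescence quantification: Huang fuzzy thresholding,
# nucleus-seeded watershed/Voronoi segmentation, ROI filtering and
# transfection-positive intensity gating.

#' Huang fuzzy-entropy threshold
#'
#' Picks the threshold minimizing the Huang-Wang measure of fuzziness over
#' a 256-bin histogram of the image: for each candidate threshold the
#' below/above classes get means mu0/mu1, each gray level a membership
#' `1 / (1 + |g - mu_class| / C)` (C = occupied gray-level range), and the
#' fuzziness is the histogram-weighted Shannon entropy of the memberships.
#' All candidates are scanned exhaustively.
#'
#' @param image Numeric matrix or vector with at least two distinct values.
#' @param n_bins Histogram bins. Default 256.
#' @return Threshold on the intensity scale of `image` (upper edge of the
#'   last below-class bin); foreground is `image > threshold`.
#' @export
huang_threshold <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) <= 0)
    stop_arg("image must contain at least two distinct values")
  check_scalar(n_bins, "n_bins", positive = TRUE, integerish = TRUE)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > n_bins] <- n_bins
  h <- tabulate(idx, nbins = n_bins)
  g <- seq_len(n_bins)                        # gray level = bin index
  first <- min(which(h > 0)); last <- max(which(h > 0))
  C <- last - first
  if (C == 0) stop_arg("image must contain at least two distinct values")
  W <- cumsum(h); S <- cumsum(h * g)
  ent <- function(mu) {
    # Shannon fuzzy entropy; memberships lie in (0.5, 1], entropy 0 at 1
    x <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -x * log(x) - (1 - x) * log(1 - x)
  }
  best_t <- first; best_E <- Inf
  for (t in first:(last - 1L)) {
    mu0 <- S[t] / W[t]
    mu1 <- (S[n_bins] - S[t]) / (W[n_bins] - W[t])
    mem <- c(1 / (1 + abs(g[first:t] - mu0) / C),
             1 / (1 + abs(g[(t + 1L):last] - mu1) / C))
    E <- sum(h[first:last] * ent(mem))
    if (E < best_E) { best_E <- E; best_t <- t }
  }
  edges[best_t + 1L]
}

#' Segment cells from nuclei and a cell-body channel
#'
#' Nuclei are Huang-thresholded from the DAPI channel and bunched nuclei
#' split by a watershed on the Euclidean distance transform. The cell-body
#' channel is Huang-thresholded to a cytoplasm mask, which is partitioned
#' among the nuclei by label propagation (the Voronoi-style boundary lines
#' of nearest-nucleus geodesics), giving one ROI per retained nucleus.
#'
#' @param dapi,cellbody Registered equal-size numeric matrices.
#' @param pixel_size Pixel size, µm.
#' @param channels Optional named list of additional registered channels;
#'   per-ROI mean intensities are reported for each.
#' @param watershed_tolerance Minimum distance-map depth separating two
#'   nuclei (pixels). Default 2.
#' @param min_nucleus_px Discard nucleus fragments smaller than this many
#'   pixels. Default 20.
#' @return List with `rois` (data.frame: `label`, `area_um2`,
#'   `touches_border`, `mean_<channel>` columns) and `labels` (ROI label
#'   matrix). Zero nuclei give zero ROIs with a warning.
#' @export
segment_cells <- function(dapi, cellbody, pixel_size, channels = list(),
                          watershed_tolerance = 2, min_nucleus_px = 20) {
  stopifnot(is.matrix(dapi), is.matrix(cellbody),
            all(dim(dapi) == dim(cellbody)))
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  thr <- tryCatch(huang_threshold(dapi), error = function(e) NULL)
  nuc_mask <- if (is.null(thr)) matrix(FALSE, nrow(dapi), ncol(dapi))
              else dapi > thr
  # reject a threshold that merely splits background noise: nuclei must
  # stand out from the background by more than 4 background-SDs
  if (any(nuc_mask) && !all(nuc_mask)) {
    bg <- dapi[!nuc_mask]
    if (mean(dapi[nuc_mask]) - mean(bg) < 4 * stats::sd(bg))
      nuc_mask[] <- FALSE
  }
  empty <- function() {
    cols <- list(label = integer(), area_um2 = numeric(),
                 touches_border = logical())
    for (nm in names(channels)) cols[[paste0("mean_", nm)]] <- numeric()
    list(rois = as.data.frame(cols), labels = matrix(0L, nrow(dapi),
                                                     ncol(dapi)))
  }
  if (!any(nuc_mask)) {
    warning("no nuclei found", call. = FALSE)
    return(empty())
  }
  dm <- EBImage::distmap(EBImage::Image(nuc_mask * 1))
  nuclei <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  nuclei <- EBImage::imageData(nuclei)
  # drop speckle fragments
  sizes <- tabulate(nuclei[nuclei > 0])
  drop <- which(sizes < min_nucleus_px)
  if (length(drop)) nuclei[nuclei %in% drop] <- 0L
  if (!any(nuclei > 0)) {
    warning("no nuclei found", call. = FALSE)
    return(empty())
  }
  # relabel 1..K
  old <- sort(unique(nuclei[nuclei > 0]))
  relab <- integer(max(old)); relab[old] <- seq_along(old)
  nuclei[nuclei > 0] <- relab[nuclei[nuclei > 0]]
  cell_mask <- (cellbody > huang_threshold(cellbody)) | nuc_mask
  terr <- EBImage::propagate(EBImage::Image(cellbody),
                             seeds = EBImage::Image(nuclei),
                             mask = EBImage::Image(cell_mask))
  terr <- EBImage::imageData(terr)
  labs <- sort(unique(terr[terr > 0]))
  nr <- nrow(terr); nc <- ncol(terr)
  border <- unique(c(terr[1, ], terr[nr, ], terr[, 1], terr[, nc]))
  rois <- data.frame(
    label = as.integer(labs),
    area_um2 = vapply(labs, function(l) sum(terr == l), numeric(1)) *
      pixel_size^2,
    touches_border = labs %in% border)
  for (nm in names(channels))
    rois[[paste0("mean_", nm)]] <- vapply(
      labs, function(l) mean(channels[[nm]][terr == l]), numeric(1))
  list(rois = rois, labels = terr)
}

#' Filter cell ROIs on area and border contact
#'
#' @param rois ROI data.frame from [segment_cells()].
#' @param min_area Keep ROIs strictly larger than this, µm². Default 10.
#' @param exclude_border Drop ROIs touching the image periphery. Default
#'   TRUE.
#' @return Filtered data.frame.
#' @export
filter_rois <- function(rois, min_area = 10, exclude_border = TRUE) {
  keep <- rois$area_um2 > min_area
  if (exclude_border) keep <- keep & !rois$touches_border
  rois[keep, , drop = FALSE]
}

#' Gate transfection-positive cells on reporter intensity
#'
#' The positivity cutoff is the mean plus `n_sd` standard deviations of a
#' non-transfected control population; cells with reporter mean strictly
#' above the cutoff are positive. A manual cutoff may be supplied instead.
#'
#' @param reporter_means Per-cell reporter intensities, ADU.
#' @param control_means Per-cell intensities of at least 10 non-transfected
#'   control cells (ignored when `cutoff` is given).
#' @param n_sd Standard-deviation multiplier. Default 3.
#' @param cutoff Optional manual cutoff, ADU.
#' @return An object of class `gating_result`: `cutoff`, `control_mean`,
#'   `control_sd`, `positive` (logical per cell), `n_positive`,
#'   `fraction_positive`.
#' @export
gate_positive <- function(reporter_means, control_means = NULL, n_sd = 3,
                          cutoff = NULL) {
  if (is.null(cutoff)) {
    if (is.null(control_means) || length(control_means) < 10)
      stop_arg("at least 10 control cells are required to set a cutoff")
    cm <- mean(control_means); cs <- stats::sd(control_means)
    cutoff <- cm + n_sd * cs
  } else {
    check_scalar(cutoff, "cutoff")
    cm <- if (!is.null(control_means)) mean(control_means) else NA_real_
    cs <- if (!is.null(control_means)) stats::sd(control_means) else NA_real_
  }
  pos <- reporter_means > cutoff
  structure(list(cutoff = cutoff, control_mean = cm, control_sd = cs,
                 positive = pos, n_positive = sum(pos),
                 fraction_positive = mean(pos)),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf(
    "Gating: cutoff %.2f ADU (control %.2f +/- %.2f); %d/%d positive (%.2f%%)\n",
    x$cutoff, x$control_mean, x$control_sd, x$n_positive,
    length(x$positive), 100 * x$fraction_positive))
  invisible(x)
}

#' Subtract antibody-staining background
#'
#' Subtracts the mean intensity of a no-primary-antibody control from
#' per-cell staining values. Results may be negative; nothing is clipped.
#'
#' @param values Per-cell staining intensities, ADU.
#' @param control_mean Mean of the no-primary control, ADU; >= 0.
#' @return `values - control_mean`.
#' @export
subtract_staining_background <- function(values, control_mean) {
  check_scalar(control_mean, "control_mean", nonneg = TRUE)
  values - control_mean
}

#' Quantify a multichannel immunofluorescence field
#'
#' Convenience wrapper: segments cells from the `dapi` and `cellmask`
#' channels, measures per-ROI means for all channels, filters on area and
#' border contact, and gates positives on the reporter channel.
#'
#' @param field List with `channels` (named list incl. `dapi`, `cellmask`,
#'   `reporter`) and `pixel_size`, as produced by [gen_if_field()].
#' @param min_area ROI area filter, µm². Default 10.
#' @param cutoff Manual gating cutoff; default derives mean + 3 sd from
#'   the control population given in `control_means`.
#' @param control_means Control-cell reporter intensities for the
#'   automatic cutoff; defaults to the field's own below-median cells
#'   (only sensible for mostly-untransfected fields) — pass explicit
#'   controls for real use.
#' @return List with `rois` (filtered, incl. `positive` flag) and `gating`.
#' @export
if_quantify <- function(field, min_area = 10, cutoff = NULL,
                        control_means = NULL) {
  ch <- field$channels
  seg <- segment_cells(ch$dapi, ch$cellmask, field$pixel_size,
                       channels = ch[setdiff(names(ch),
                                             c("dapi", "cellmask"))])
  rois <- filter_rois(seg$rois, min_area = min_area, exclude_border = TRUE)
  if (is.null(cutoff) && is.null(control_means))
    control_means <- rois$mean_reporter[
      rois$mean_reporter <= stats::median(rois$mean_reporter)]
  gating <- gate_positive(rois$mean_reporter, control_means,
                          cutoff = cutoff)
  rois$positive <- gating$positive
  list(rois = rois, gating = gating, labels = seg$labels)
}
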