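# File formats: ThunderSTORM-compatible localization CSV, time-series CSV
# and 16-bit TIFF stacks.

#' Write a spot table as localization CSV
#'
#' Columns follow the ThunderSTORM export convention (`frame`, `x [nm]`,
#' `y [nm]`, `intensity [photon]`, `sigma [nm]`), with native µm/ADU
#' columns (`x_um`, `y_um`, `intensity_adu`, `sigma_um`) alongside.
#'
#' @param table Spot table from [detect_spots()] (or any data.frame with
#'   `frame`, `x`, `y`, `intensity`, `sigma_fit`).
#' @param path Output CSV path.
#' @param photon_scale ADU per photon used for the photon column. Default 1.
#' @export
write_spot_table <- function(table, path, photon_scale = 1) {
  out <- data.frame(
    frame = table$frame,
    check.names = FALSE)
  out[["x [nm]"]] <- table$x * 1000
  out[["y [nm]"]] <- table$y * 1000
  out[["intensity [photon]"]] <- table$intensity / photon_scale
  out[["sigma [nm]"]] <- table$sigma_fit * 1000
  out$x_um <- table$x
  out$y_um <- table$y
  out$intensity_adu <- table$intensity
  out$sigma_um <- table$sigma_fit
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a localization CSV
#'
#' Accepts both the native columns written by [write_spot_table()] and
#' plain ThunderSTORM exports (nm/photon units, converted back to µm/ADU).
#'
#' @param path CSV path.
#' @param photon_scale ADU per photon for unit back-conversion. Default 1.
#' @return A `spot_table` data.frame (`frame`, `x`, `y`, `intensity`,
#'   `sigma_fit`).
#' @export
read_spot_table <- function(path, photon_scale = 1) {
  d <- utils::read.csv(path, check.names = FALSE)
  tab <- if ("x_um" %in% names(d)) {
    data.frame(frame = d$frame, x = d$x_um, y = d$y_um,
               intensity = d$intensity_adu, sigma_fit = d$sigma_um)
  } else {
    data.frame(frame = d$frame,
               x = d[["x [nm]"]] / 1000, y = d[["y [nm]"]] / 1000,
               intensity = d[["intensity [photon]"]] * photon_scale,
               sigma_fit = if ("sigma [nm]" %in% names(d))
                 d[["sigma [nm]"]] / 1000 else NA_real_)
  }
  class(tab) <- c("spot_table", "data.frame")
  tab
}

#' Write / read a time course as CSV
#'
#' Two-column CSV (`time_min`, `F`).
#'
#' @param tc A [time_course()].
#' @param path CSV path.
#' @export
write_timecourse <- function(tc, path) {
  tc <- as_time_course(tc)
  utils::write.csv(data.frame(time_min = tc$t, F = tc$F), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  d <- utils::read.csv(path)
  time_course(d$time_min, d$F)
}

#' Write an image or stack as 16-bit TIFF
#'
#' Values are stored as 16-bit unsigned integers; the scale is chosen from
#' the data maximum (or `max_value`) and is recorded nowhere, so round
#' trips preserve relative, not absolute, intensities.
#'
#' @param image Matrix or 3D array (third dimension = frame), ADU.
#' @param path Output TIFF path (multi-page for stacks).
#' @param max_value Full-scale value; default the data maximum.
#' @export
write_image_tiff <- function(image, path, max_value = NULL) {
  if (is.null(max_value)) max_value <- max(image)
  if (max_value <= 0) max_value <- 1
  norm <- function(m) pmin(pmax(m / max_value, 0), 1)
  if (is.matrix(image)) {
    tiff::writeTIFF(norm(image), path, bits.per.sample = 16L)
  } else {
    pages <- lapply(seq_len(dim(image)[3]), function(f) norm(image[, , f]))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a TIFF written by [write_image_tiff()]
#'
#' @param path TIFF path.
#' @param max_value Full-scale value used at write time. Default 1 (raw
#'   [0, 1] values).
#' @return Matrix (single page) or 3D array (stack).
#' @export
read_image_tiff <- function(path, max_value = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * max_value
  })
  if (length(pages) == 1L) return(pages[[1]])
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}
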