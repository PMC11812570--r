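# Copy-number and optical-crowding arithmetic linking measured spot
# densities to per-cell molecule counts, ploidy-corrected totals, proteome
# fractions and the density ceiling set by the diffraction limit. All
# operations are pure; the rounding conventions (nearest integer percent,
# 2 significant figures for areas, 1 for crowding densities) reproduce the
# approximate figures quoted in this field deterministically, with raw
# values always returned alongside.

#' Cell geometry and proteome context
#'
#' @param surface_area Plasma-membrane footprint, µm²; > 0. Default 1500
#'   (adherent HEK293 cell).
#' @param ploidy Copies of the tagged allele's chromosome; >= 1. Default 3
#'   (HEK293 cells are pseudotriploid).
#' @param total_copies Total per-cell copy number of the protein; > 0.
#'   Default 23000 (proteomic estimate for AKT1 in HEK293).
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(surface_area = 1500, ploidy = 3,
                          total_copies = 23000) {
  check_scalar(surface_area, "surface_area", positive = TRUE)
  check_scalar(ploidy, "ploidy", positive = TRUE, integerish = TRUE)
  check_scalar(total_copies, "total_copies", positive = TRUE)
  structure(list(surface_area = surface_area, ploidy = ploidy,
                 total_copies = total_copies), class = "cell_geometry")
}

#' Molecules per cell from a membrane density
#'
#' @param density Spot density, count per 100 µm²; >= 0.
#' @param geometry A [cell_geometry()] (or a bare surface area in µm²).
#' @return `density / 100 * surface_area`, molecules per cell.
#' @export
cell_count_from_density <- function(density, geometry = cell_geometry()) {
  check_scalar(density, "density", nonneg = TRUE)
  area <- if (inherits(geometry, "cell_geometry")) geometry$surface_area
          else check_scalar(geometry, "geometry", positive = TRUE)
  density / 100 * area
}

#' Scale a per-allele count by ploidy
#'
#' A single edited allele reports only its own share of expression; the
#' minimal whole-cell estimate multiplies by the number of alleles.
#'
#' @param count Molecules attributed to one allele; >= 0.
#' @param ploidy Allele copies; >= 1.
#' @return `count * ploidy`.
#' @export
ploidy_scale <- function(count, ploidy) {
  check_scalar(count, "count", nonneg = TRUE)
  check_scalar(ploidy, "ploidy", positive = TRUE, integerish = TRUE)
  count * ploidy
}

#' Membrane copies as a fraction of the whole-cell pool
#'
#' @param count Membrane-localized molecules; >= 0.
#' @param total_copies Whole-cell copy number; > 0.
#' @return List with `percent` (raw `100 * count / total_copies`) and
#'   `percent_rounded` (nearest integer).
#' @export
proteome_fraction <- function(count, total_copies) {
  check_scalar(count, "count", nonneg = TRUE)
  check_scalar(total_copies, "total_copies", positive = TRUE)
  pct <- 100 * count / total_copies
  list(percent = pct, percent_rounded = round(pct))
}

#' Airy disc footprint of a point emitter
#'
#' @param diameter_nm Airy disc diameter, nm; > 0.
#' @return List with `area_um2` (raw `pi * (d/2)^2` in µm²) and
#'   `area_um2_2sf` (2 significant figures).
#' @export
airy_area <- function(diameter_nm) {
  check_scalar(diameter_nm, "diameter_nm", positive = TRUE)
  a <- pi * (diameter_nm / 2000)^2
  list(area_um2 = a, area_um2_2sf = signif(a, 2))
}

#' Density at which single emitters merge into continuous fluorescence
#'
#' The crowding (convolution) threshold is one molecule per Airy disc,
#' expressed per 100 µm².
#'
#' @param airy_area_um2 Airy disc area, µm²; > 0.
#' @return List with `density_per_100um2` (raw `100 / area`) and
#'   `density_1sf` (1 significant figure).
#' @export
crowding_density <- function(airy_area_um2) {
  check_scalar(airy_area_um2, "airy_area_um2", positive = TRUE)
  d <- 100 / airy_area_um2
  list(density_per_100um2 = d, density_1sf = signif(d, 1))
}

#' Full copy-number report
#'
#' Chains the copy-number arithmetic for a measured density: molecules per
#' cell, ploidy-scaled total, proteome fraction, and the optical crowding
#' ceiling for a given Airy disc diameter.
#'
#' @param density Measured density, count per 100 µm².
#' @param geometry A [cell_geometry()].
#' @param airy_diameter_nm Airy disc diameter, nm. Default 210.
#' @return Named list of raw and rounded quantities.
#' @export
copy_number_report <- function(density, geometry = cell_geometry(),
                               airy_diameter_nm = 210) {
  stopifnot(inherits(geometry, "cell_geometry"))
  per_allele <- cell_count_from_density(density, geometry)
  total <- ploidy_scale(per_allele, geometry$ploidy)
  frac <- proteome_fraction(total, geometry$total_copies)
  airy <- airy_area(airy_diameter_nm)
  crowd <- crowding_density(airy$area_um2)
  list(density_per_100um2 = density,
       molecules_per_allele = per_allele,
       molecules_ploidy_scaled = total,
       proteome_percent = frac$percent,
       proteome_percent_rounded = frac$percent_rounded,
       airy_area_um2 = airy$area_um2,
       airy_area_um2_2sf = airy$area_um2_2sf,
       crowding_density_per_100um2 = crowd$density_per_100um2,
       crowding_density_1sf = crowd$density_1sf)
}
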