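#' Default integration and fit windows
#'
#' The reciprocal-spacing windows used by the standard analysis, all in nm^-1:
#' axial fit windows for the M3 (0.066-0.072) and M6 (0.135-0.142) meridional
#' reflections; the mixed myosin/actin first layer line region (axial
#' 0.017-0.033, radial integration band 0.0638-0.0826); the equator
#' (meridional half-width 0.0036, fit region 0.02-0.065); and the ultra-low
#' angle sarcomere region (half-width 0.00304, fit region 0.0033-0.0083,
#' intensity analysis band 0.0052-0.0072). The meridional projection
#' half-width is 0.01522.
#'
#' @return A named list of numeric windows (length-2 vectors) and half-widths
#'   (scalars). Override individual entries by passing a modified copy to the
#'   analysis functions that take a `windows` argument.
#' @export
xrd_windows <- function() {
  list(
    m3_axial            = c(0.066, 0.072),
    m6_axial            = c(0.135, 0.142),
    layerline_axial     = c(0.017, 0.033),
    layerline_radial    = c(0.0638, 0.0826),
    equator_halfwidth   = 0.0036,
    equator_fit         = c(0.02, 0.065),
    sarcomere_halfwidth = 0.00304,
    sarcomere_fit       = c(0.0033, 0.0083),
    sarcomere_band      = c(0.0052, 0.0072),
    meridian_halfwidth  = 0.01522
  )
}

#' Detector point-spread function width in reciprocal space
#'
#' Converts the combined beam/detector point-spread sigma given on the
#' detector face to reciprocal spacing: `sigma_R = sigma_det / (lambda * L)`.
#' With the defaults (190 um sigma, 0.1 nm wavelength, 8.26 m camera length)
#' this is ~2.3e-4 nm^-1.
#'
#' @param sigma_det_um point-spread sigma on the detector, micrometres.
#' @param wavelength_nm X-ray wavelength, nm.
#' @param camera_m sample-to-detector distance, metres.
#' @return Sigma in nm^-1.
#' @export
psf_sigma_reciprocal <- function(sigma_det_um = 190, wavelength_nm = 0.1,
                                 camera_m = 8.26) {
  (sigma_det_um * 1e-6) / (wavelength_nm * 1e-9 * camera_m) * 1e-9
}
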