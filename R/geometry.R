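#' Pixelated detector geometry
#'
#' Describes a row of identical rectangular crystal pixels separated by thin
#' inert reflector gaps.  Coordinates: the gamma beam enters at z = 0, the
#' photodetector face is at z = `length_z`; crystal 1 occupies
#' x in \[0, `pixel_pitch_x`\], each further crystal is offset by
#' `pixel_pitch_x + reflector_gap` in +x; y spans \[0, `pixel_pitch_y`\].
#' All lengths in mm.  The default is the dual-pixel 2.5 x 2.8 x 15 mm module.
#'
#' @param pixel_pitch_x,pixel_pitch_y transverse pixel dimensions, mm.
#' @param length_z crystal length along the beam, mm.
#' @param n_pixels_x number of pixels along x.
#' @param reflector_gap inert gap between adjacent pixels, mm.
#' @return an object of class `detector_geometry`.
#' @export
detector_geometry <- function(pixel_pitch_x = 2.5, pixel_pitch_y = 2.8,
                              length_z = 15, n_pixels_x = 2,
                              reflector_gap = 0.07) {
  if (pixel_pitch_x <= 0) stop("detector_geometry: pixel_pitch_x must be > 0")
  if (pixel_pitch_y <= 0) stop("detector_geometry: pixel_pitch_y must be > 0")
  if (length_z <= 0) stop("detector_geometry: length_z must be > 0")
  if (n_pixels_x < 1) stop("detector_geometry: n_pixels_x must be >= 1")
  if (reflector_gap < 0) stop("detector_geometry: reflector_gap must be >= 0")
  structure(list(pixel_pitch_x = as.numeric(pixel_pitch_x),
                 pixel_pitch_y = as.numeric(pixel_pitch_y),
                 length_z = as.numeric(length_z),
                 n_pixels_x = as.integer(n_pixels_x),
                 reflector_gap = as.numeric(reflector_gap)),
            class = "detector_geometry")
}

# Low x-edge of each crystal
crystal_x_lo <- function(geom) {
  (seq_len(geom$n_pixels_x) - 1) * (geom$pixel_pitch_x + geom$reflector_gap)
}

# Full transverse extent of the module along x (crystals + gaps)
module_x_extent <- function(geom) {
  geom$n_pixels_x * geom$pixel_pitch_x +
    (geom$n_pixels_x - 1) * geom$reflector_gap
}

#' Locate a point in the detector
#'
#' @param geom a [detector_geometry()].
#' @param x,y,z coordinates in mm (vectorised).
#' @return integer vector: crystal index (1-based) if inside a crystal,
#'   `0` inside a reflector gap, `-1` outside the module bounding box.
#' @export
crystal_at <- function(geom, x, y, z) {
  xmax <- module_x_extent(geom)
  inside <- x >= 0 & x <= xmax &
    y >= 0 & y <= geom$pixel_pitch_y &
    z >= 0 & z <= geom$length_z
  period <- geom$pixel_pitch_x + geom$reflector_gap
  cell <- pmin(floor(x / period), geom$n_pixels_x - 1)
  off <- x - cell * period
  id <- ifelse(off <= geom$pixel_pitch_x, cell + 1L, 0L)
  out <- ifelse(inside, id, -1L)
  as.integer(out)
}

#' Collimated beam source
#'
#' A 511 keV pencil/collimated beam entering the front face (z = 0) of the
#' module along +z, aimed at the centre of one pixel.  The entry point is
#' jittered uniformly over a square collimator aperture of side `beam_width`.
#'
#' @param energy initial photon energy, keV.
#' @param beam_width collimator aperture side, mm; must not exceed the pixel
#'   pitch.
#' @param crystal index of the irradiated pixel.
#' @return an object of class `beam_source`.
#' @export
beam_source <- function(energy = 511, beam_width = 0.5, crystal = 1L) {
  if (energy <= 0) stop("beam_source: energy must be > 0")
  if (beam_width < 0) stop("beam_source: beam_width must be >= 0")
  structure(list(energy = as.numeric(energy),
                 beam_width = as.numeric(beam_width),
                 crystal = as.integer(crystal)),
            class = "beam_source")
}

# Entry points (n x 2 matrix of x, y) for a source on a geometry
source_entry_points <- function(source, geom, n) {
  if (source$crystal > geom$n_pixels_x)
    stop("beam_source: irradiated crystal index exceeds n_pixels_x")
  if (source$beam_width > min(geom$pixel_pitch_x, geom$pixel_pitch_y))
    stop("beam_source: beam_width exceeds the pixel pitch")
  cx <- crystal_x_lo(geom)[source$crystal] + geom$pixel_pitch_x / 2
  cy <- geom$pixel_pitch_y / 2
  w <- source$beam_width
  cbind(x = cx + stats::runif(n, -w / 2, w / 2),
        y = cy + stats::runif(n, -w / 2, w / 2))
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf("<detector_geometry> %d pixel(s) of %.2f x %.2f x %.1f mm, gap %.2f mm\n",
              x$n_pixels_x, x$pixel_pitch_x, x$pixel_pitch_y, x$length_z,
              x$reflector_gap))
  invisible(x)
}
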