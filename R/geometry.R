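#' Display geometry for a saccadic-choice setup
#'
#' Describes the screen and stimulus layout used both by the gaze
#' simulator and by the saccade detector: an 800x600 px display viewed
#' at 50 cm, with the two stimulus images centred 8.6 degrees of visual
#' angle left and right of fixation and subtending 14x14 degrees.
#'
#' The physical monitor size (and hence the pixels-per-degree factor)
#' is a free parameter of the setup; the default of 25 px/deg places
#' the outer image edge (8.6 + 7 = 15.6 deg) at 390 px from the screen
#' centre, just inside the 400 px half-width of the display.
#'
#' @param screen integer vector (width, height) in px.
#' @param px_per_deg pixels per degree of visual angle.
#' @param eccentricity_deg eccentricity of each image centre, degrees.
#' @param image_size_deg width/height of the (square) images, degrees.
#' @param viewing_distance_cm viewing distance, cm (metadata only).
#' @return A list of class `"display_geometry"`.
#' @examples
#' geom <- display_geometry()
#' deg_to_px(8.6, geom)
#' @export
display_geometry <- function(screen = c(800, 600),
                             px_per_deg = 25,
                             eccentricity_deg = 8.6,
                             image_size_deg = 14,
                             viewing_distance_cm = 50) {
  stopifnot(length(screen) == 2, all(screen > 0), px_per_deg > 0,
            eccentricity_deg > 0, image_size_deg > 0)
  outer_edge <- (eccentricity_deg + image_size_deg / 2) * px_per_deg
  if (outer_edge > screen[1] / 2)
    stop("geometry inconsistent: outer image edge (", outer_edge,
         " px) falls outside the screen half-width (", screen[1] / 2, " px)")
  structure(list(screen = as.numeric(screen),
                 px_per_deg = px_per_deg,
                 eccentricity_deg = eccentricity_deg,
                 image_size_deg = image_size_deg,
                 viewing_distance_cm = viewing_distance_cm,
                 center = as.numeric(screen) / 2),
            class = "display_geometry")
}

#' Convert degrees of visual angle to pixels
#' @param deg degrees of visual angle.
#' @param geometry a [display_geometry()].
#' @return Distance in px.
#' @export
deg_to_px <- function(deg, geometry = display_geometry()) {
  deg * geometry$px_per_deg
}

#' Convert pixels to degrees of visual angle
#' @param px distance in px.
#' @inheritParams deg_to_px
#' @return Degrees of visual angle.
#' @export
px_to_deg <- function(px, geometry = display_geometry()) {
  px / geometry$px_per_deg
}
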