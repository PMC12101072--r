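#' Maximum analysed spatial frequency from camera geometry
#'
#' The analysis uses frequencies up to one tenth of the crop side in pixels,
#' so for a full sensor of `sensor_width_px` pixels spanning `fov_mm`
#' millimetres the highest analysed physical frequency is
#' `sensor_width_px / fov_mm / 10` cycles/mm. With the standard macro setup
#' (1392 px across a 5.7 mm field of view) this is 24.4 cycles/mm.
#'
#' @param sensor_width_px sensor width in pixels (default 1392).
#' @param fov_mm horizontal field of view in mm (default 5.7).
#' @param divisor analysis divisor (default 10, the anti-aliasing rule).
#' @return cycles/mm.
#' @export
max_analyzed_frequency <- function(sensor_width_px = 1392, fov_mm = 5.7,
                                   divisor = 10) {
  if (sensor_width_px <= 0 || fov_mm <= 0 || divisor <= 0)
    stop("all acuity parameters must be positive")
  sensor_width_px / fov_mm / divisor
}

#' Spatial resolution limit of the viewer's eye
#'
#' Highest spatial frequency (cycles/mm on the pattern) a viewer with
#' inter-receptor angle `inter_receptor_deg` can resolve at distance
#' `distance_mm`, assuming sharp focus: `1 / (4 d tan(angle / 2))`. For a
#' salticid principal eye with a 0.04 degree inter-receptor angle viewing at
#' the typical 27 mm courtship distance this is 26.5 cycles/mm.
#'
#' @param distance_mm viewing distance in mm.
#' @param inter_receptor_deg inter-receptor angle in degrees (default 0.04).
#' @return cycles/mm.
#' @export
spatial_resolution_limit <- function(distance_mm, inter_receptor_deg = 0.04) {
  if (distance_mm <= 0 || inter_receptor_deg <= 0)
    stop("all acuity parameters must be positive")
  1 / (4 * distance_mm * tan(inter_receptor_deg * pi / 180 / 2))
}
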