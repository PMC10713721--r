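# Closed-form optics and sensor-bandwidth arithmetic for the array
# microscope: Abbe resolution, magnification/FOV/pixel-size relations, raw
# and reduced sensor bit rates, and FPGA frame-buffer sizing.

#' Optical specification of one lens channel
#'
#' @param wavelength Illumination wavelength in nm.
#' @param numerical_aperture Numerical aperture, in (0, 1].
#' @param magnification Optical magnification, > 0.
#' @return An `optics_spec` list.
#' @examples
#' optics_spec(550, 0.3, 4.7)
#' @export
optics_spec <- function(wavelength, numerical_aperture, magnification) {
  check_positive(wavelength, "wavelength")
  if (!is.numeric(numerical_aperture) || numerical_aperture <= 0 ||
      numerical_aperture > 1)
    stop_invalid("`numerical_aperture` must be in (0, 1]")
  check_positive(magnification, "magnification")
  structure(list(wavelength = wavelength,
                 numerical_aperture = numerical_aperture,
                 magnification = magnification),
            class = "optics_spec")
}

#' Image-sensor specification
#'
#' Defaults describe a WXGA CMOS imager: 1280 x 800 pixels on a
#' 3888 x 2430 micrometre active area, 30 bits RGB per pixel at 30 fps,
#' 16 sensors in the array.
#'
#' @param width_px,height_px Pixel counts.
#' @param active_width_um,active_height_um Active sensor area in micrometres.
#' @param bits_per_pixel Bits generated per pixel.
#' @param fps Frame rate in frames/s.
#' @param n_sensors Number of sensors in the array.
#' @return A `sensor_spec` list.
#' @export
sensor_spec <- function(width_px = 1280, height_px = 800,
                        active_width_um = 3888, active_height_um = 2430,
                        bits_per_pixel = 30, fps = 30, n_sensors = 16) {
  for (nm in c("width_px", "height_px", "active_width_um",
               "active_height_um", "bits_per_pixel", "fps", "n_sensors"))
    check_positive(get(nm), nm)
  pitch_x <- active_width_um / width_px
  pitch_y <- active_height_um / height_px
  if (abs(pitch_x - pitch_y) / pitch_x > 0.01)
    stop_invalid("pixel pitch differs by more than 1%% between axes (%.4f vs %.4f um)",
                 pitch_x, pitch_y)
  structure(list(width_px = width_px, height_px = height_px,
                 active_width_um = active_width_um,
                 active_height_um = active_height_um,
                 bits_per_pixel = bits_per_pixel, fps = fps,
                 n_sensors = n_sensors),
            class = "sensor_spec")
}

#' Abbe lateral resolution
#'
#' Diffraction-limited lateral resolution d = lambda / (2 NA). An NA 0.3
#' lens at 550 nm resolves 917 nm; an NA 0.4 lens resolves 688 nm.
#'
#' @param wavelength Wavelength in nm.
#' @param na Numerical aperture in (0, 1].
#' @return List with `resolution_nm` (rounded to integer nm, half-up) and
#'   `resolution_nm_exact` (unrounded).
#' @examples
#' abbe_resolution(550, 0.3)$resolution_nm # 917
#' @export
abbe_resolution <- function(wavelength, na) {
  check_positive(wavelength, "wavelength")
  if (!is.numeric(na) || length(na) != 1L || is.na(na) || na <= 0 || na > 1)
    stop_invalid("`na` must be in (0, 1]")
  exact <- wavelength / (2 * na)
  list(resolution_nm = floor(exact + 0.5), resolution_nm_exact = exact)
}

#' Field of view from sensor size and magnification
#'
#' @param sensor A [sensor_spec()].
#' @param magnification Optical magnification, > 0.
#' @return List with `width_um` and `height_um`.
#' @export
field_of_view <- function(sensor, magnification) {
  check_positive(magnification, "magnification")
  structure(list(width_um = sensor$active_width_um / magnification,
                 height_um = sensor$active_height_um / magnification),
            class = "field_of_view")
}

#' Pixel size in the sample plane
#'
#' @param fov A field of view (list with `width_um`) or a width in um.
#' @param width_px Number of pixels across the width.
#' @return Pixel size in micrometres per pixel.
#' @examples
#' pixel_size(list(width_um = 825.8), 1280) # ~0.645
#' @export
pixel_size <- function(fov, width_px) {
  check_positive(width_px, "width_px")
  width_um <- if (is.list(fov)) fov$width_um else fov
  check_positive(width_um, "fov width")
  width_um / width_px
}

#' Raw sensor-array data rate
#'
#' Aggregate bit rate of the sensor array in binary gigabits per second
#' (bits/s divided by 2^30). The full-resolution 16-sensor array
#' (1280 x 800, 30 bits, 30 fps) produces 13.73 Gbit/s; the reduced
#' 8-bit grayscale 720p stream produces 3.30 Gbit/s.
#'
#' @param sensor A [sensor_spec()].
#' @return Data rate in binary Gbit/s, rounded to two decimals; the exact
#'   value is attached as attribute `"exact"`.
#' @examples
#' raw_data_rate(sensor_spec()) # 13.73
#' @export
raw_data_rate <- function(sensor) {
  bits <- sensor$width_px * sensor$height_px * sensor$bits_per_pixel *
    sensor$fps * sensor$n_sensors
  exact <- bits / 2^30
  structure(round(exact, 2), exact = exact)
}

#' FPGA frame-buffer requirement
#'
#' Intermediate image storage for ping-pong buffering: two frame memories
#' per channel in triggered mode, plus a third sharpest-frame memory in
#' free-running autofocus mode.
#'
#' @param width_px,height_px Frame dimensions in pixels.
#' @param bytes_per_px Bytes per pixel (1 for 8-bit grayscale).
#' @param n_channels Number of imaging channels.
#' @param n_buffers Frame memories per channel (2 ping-pong, 3 free-running).
#' @return List with `bytes` and `mib` (bytes / 2^20).
#' @examples
#' buffer_requirement(1280, 720, 1, 16, 2)$mib # 28.125
#' @export
buffer_requirement <- function(width_px, height_px, bytes_per_px = 1,
                               n_channels = 16, n_buffers = 2) {
  for (nm in c("width_px", "height_px", "bytes_per_px", "n_channels",
               "n_buffers"))
    check_positive(get(nm), nm)
  bytes <- width_px * height_px * bytes_per_px * n_channels * n_buffers
  list(bytes = bytes, mib = bytes / 2^20)
}

#' Full instrument budget table
#'
#' Convenience summary combining resolution, field of view, pixel size,
#' raw and reduced data rates, and buffer sizes for one instrument
#' configuration.
#'
#' @param optics An [optics_spec()].
#' @param sensor Full-resolution [sensor_spec()].
#' @param reduced_sensor Reduced-stream [sensor_spec()] (default 1280 x 720,
#'   8-bit grayscale).
#' @return A data.frame of named quantities with values and units.
#' @export
budget_table <- function(optics = optics_spec(550, 0.3, 4.708),
                         sensor = sensor_spec(),
                         reduced_sensor = sensor_spec(
                           width_px = 1280, height_px = 720,
                           active_width_um = 3888,
                           active_height_um = 3888 * 720 / 1280,
                           bits_per_pixel = 8)) {
  res <- abbe_resolution(optics$wavelength, optics$numerical_aperture)
  fov <- field_of_view(sensor, optics$magnification)
  px <- pixel_size(fov, sensor$width_px)
  buf2 <- buffer_requirement(reduced_sensor$width_px,
                             reduced_sensor$height_px, 1,
                             sensor$n_sensors, 2)
  buf3 <- buffer_requirement(reduced_sensor$width_px,
                             reduced_sensor$height_px, 1,
                             sensor$n_sensors, 3)
  data.frame(
    quantity = c("resolution", "fov_width", "fov_height", "pixel_size",
                 "raw_rate", "reduced_rate", "buffer_triggered",
                 "buffer_free_running"),
    value = c(res$resolution_nm, fov$width_um, fov$height_um, px,
              as.numeric(raw_data_rate(sensor)),
              as.numeric(raw_data_rate(reduced_sensor)),
              buf2$mib, buf3$mib),
    unit = c("nm", "um", "um", "um/px", "Gbit/s", "Gbit/s", "MiB", "MiB"),
    stringsAsFactors = FALSE
  )
}
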