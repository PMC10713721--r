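# Shared file I/O: multi-page TIFF stacks and masks, track tables,
# plate layouts, YAML configuration and JSON run manifests.

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval Metadata attached to the stack.
#' @return An `image_stack` (frames as matrices; no masks).
#' @export
read_stack <- function(path, pixel_size = 0.645, frame_interval = 8) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1] # collapse any channel axis
    f
  })
  structure(list(frames = frames, masks = NULL,
                 frame_index = seq_along(frames),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 z_offset = 0),
            class = "image_stack")
}

#' Write an image stack (or mask list) as multi-page TIFF
#'
#' Frames are rescaled to \[0, 1\] jointly so relative intensities across
#' frames survive the round trip up to the common affine rescaling.
#'
#' @param stack An `image_stack` or list of matrices.
#' @param path Output path.
#' @param bits_per_sample TIFF bit depth (16 keeps mask labels and
#'   intensity resolution).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = 16) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(frames, function(f) (f - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Write / read a track table CSV
#'
#' Columns track_id, frame, x_um, y_um (and any extras such as area_px)
#' round-trip losslessly.
#'
#' @param tracks Track table data.frame.
#' @param path CSV path.
#' @return `path` (write) or the track table (read).
#' @export
write_tracks <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a plate-layout CSV
#'
#' @param layout Layout data.frame (well, round, label, role, ...).
#' @param path CSV path.
#' @return `path` (write) or the layout (read).
#' @export
write_layout <- function(layout, path) {
  write.csv(layout, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a YAML configuration file
#'
#' @param path YAML path.
#' @return Named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' Write a JSON run manifest
#'
#' Structured record of all parameters of a run, for reproducibility.
#'
#' @param params Named list of parameters.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
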