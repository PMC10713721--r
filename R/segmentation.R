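# Baseline segmentation: automatic threshold + distance-map watershed to
# split touching cells + connected-component labeling with an area
# filter. Pluggable: any externally produced label masks (e.g. from a
# learned segmenter) can be fed to the tracker instead.

#' Segment one frame into a label mask
#'
#' Otsu bimodal threshold on the intensity image, then an
#' intensity-guided watershed inside the foreground (on a lightly
#' smoothed copy of the image) to separate touching cells — bright-blob
#' cells keep distinct intensity peaks well after their outlines merge,
#' so this splits contacts that a plain distance-map watershed misses.
#' Components outside `[min_area, max_area]` pixels are removed and
#' labels renumbered 1..k. A constant image yields an empty mask.
#'
#' @param frame Numeric intensity matrix (rows = y, cols = x).
#' @param min_area,max_area Component area bounds in pixels.
#' @param smooth_sigma Gaussian smoothing (px) applied before the
#'   watershed, suppressing noise-born spurious peaks.
#' @param split_tolerance Watershed tolerance on the \[0, 1\]-normalized
#'   intensity scale; peaks shallower than this merge into one object.
#' @return Integer label matrix (0 = background).
#' @export
segment_baseline <- function(frame, min_area = 20, max_area = 5000,
                             smooth_sigma = 1, split_tolerance = 0.02) {
  if (!is.matrix(frame) || length(frame) == 0L)
    stop_invalid("`frame` must be a non-empty numeric matrix")
  rng <- range(frame)
  if (diff(rng) == 0) return(matrix(0L, nrow(frame), ncol(frame)))
  norm <- (frame - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm))
  bw <- norm > th
  if (!any(bw)) return(matrix(0L, nrow(frame), ncol(frame)))
  sm <- if (smooth_sigma > 0)
    as.matrix(EBImage::gblur(norm, sigma = smooth_sigma)) else norm
  lbl <- EBImage::imageData(EBImage::watershed(EBImage::Image(sm * bw),
                                               tolerance = split_tolerance,
                                               ext = 1))
  relabel_filtered(lbl, min_area, max_area)
}

# drop components outside the area band and renumber labels 1..k
relabel_filtered <- function(lbl, min_area, max_area) {
  lbl <- matrix(as.integer(lbl), nrow(lbl), ncol(lbl))
  if (max(lbl) == 0L) return(lbl)
  areas <- tabulate(lbl[lbl > 0L])
  keep <- which(areas >= min_area & areas <= max_area)
  map <- integer(length(areas))
  map[keep] <- seq_along(keep)
  out <- lbl
  out[lbl > 0L] <- map[lbl[lbl > 0L]]
  out
}

#' Convert a label mask to centroid detections
#'
#' One detection per label: centroid at the mean pixel-center coordinate
#' converted to micrometres (origin top-left, x rightward, y downward),
#' area in pixels.
#'
#' @param mask Integer label matrix.
#' @param frame Frame index stored with the detections.
#' @param pixel_size Pixel size in um/px.
#' @return data.frame with columns frame, label, x_um, y_um, area_px.
#' @export
mask_to_detections <- function(mask, frame = 1L, pixel_size = 0.645) {
  check_positive(pixel_size, "pixel_size")
  labs <- mask[mask > 0L]
  if (length(labs) == 0L)
    return(data.frame(frame = integer(0), label = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_px = numeric(0)))
  idx <- which(mask > 0L)
  row <- (idx - 1L) %% nrow(mask) + 1L
  col <- (idx - 1L) %/% nrow(mask) + 1L
  area <- tabulate(labs)
  ids <- which(area > 0L)
  f <- factor(labs, levels = ids) # keep numeric label order
  cx <- tapply((col - 0.5) * pixel_size, f, mean)
  cy <- tapply((row - 0.5) * pixel_size, f, mean)
  data.frame(frame = as.integer(frame), label = ids,
             x_um = as.numeric(cx), y_um = as.numeric(cy),
             area_px = as.numeric(area[ids]))
}

#' Segment a whole stack into per-frame detections
#'
#' @param stack An `image_stack` (see [render_stack()]) or list of frame
#'   matrices.
#' @param pixel_size Pixel size in um/px (taken from the stack if present).
#' @param min_area,max_area Area band passed to [segment_baseline()].
#' @param masks Optional list of precomputed label masks (external
#'   segmenter plug-in); when given, segmentation is skipped.
#' @return data.frame of detections over all frames.
#' @export
detect_stack <- function(stack, pixel_size = NULL, min_area = 20,
                         max_area = 5000, masks = NULL) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  if (is.null(pixel_size))
    pixel_size <- if (inherits(stack, "image_stack")) stack$pixel_size
                  else stop_invalid("`pixel_size` required")
  if (is.null(masks))
    masks <- lapply(frames, segment_baseline, min_area = min_area,
                    max_area = max_area)
  dets <- lapply(seq_along(masks), function(i)
    mask_to_detections(masks[[i]], frame = i, pixel_size = pixel_size))
  do.call(rbind, dets)
}
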