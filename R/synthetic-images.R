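# Rendering of synthetic time-lapse stacks: cells as radially symmetric
# bright blobs on a noisy background, with optional uniform defocus blur
# proportional to |z - z_focus|. Ground-truth label masks are noise-free
# discs with overlaps resolved by nearest-center assignment.

#' Scene parameters for stack rendering
#'
#' Defaults match one array-lens field of view: 825.8 x 512 um at
#' 0.645 um/pixel, ~10 um diameter cells.
#'
#' @param fov_um Field of view c(width, height) in um.
#' @param pixel_size Pixel size in um/px; `fov_um / pixel_size` must be
#'   integer within 2%.
#' @param cell_radius Cell radius in um.
#' @param cell_intensity Peak intensity added by one cell.
#' @param background Background intensity.
#' @param noise_sd SD of additive Gaussian pixel noise (>= 0).
#' @param defocus_blur_per_um Blur sigma in px per um of defocus.
#' @return A `scene_params` list with derived frame dimensions
#'   `nx`, `ny` in pixels.
#' @export
scene_params <- function(fov_um = c(825.8, 512), pixel_size = 0.645,
                         cell_radius = 5, cell_intensity = 0.6,
                         background = 0.1, noise_sd = 0.02,
                         defocus_blur_per_um = 0.8) {
  check_positive(pixel_size, "pixel_size")
  check_positive(cell_radius, "cell_radius")
  check_nonneg(noise_sd, "noise_sd")
  check_nonneg(defocus_blur_per_um, "defocus_blur_per_um")
  nx <- fov_um[1] / pixel_size
  ny <- fov_um[2] / pixel_size
  if (abs(nx - round(nx)) > 0.02 * nx || abs(ny - round(ny)) > 0.02 * ny)
    stop_invalid("fov_um / pixel_size must give near-integer frame dimensions")
  structure(list(fov_um = fov_um, pixel_size = pixel_size,
                 cell_radius = cell_radius, cell_intensity = cell_intensity,
                 background = background, noise_sd = noise_sd,
                 defocus_blur_per_um = defocus_blur_per_um,
                 nx = as.integer(round(nx)), ny = as.integer(round(ny))),
            class = "scene_params")
}

# render one frame: image matrix (ny x nx) + integer label mask.
# Gaussian intensity blobs (sigma = radius/2); mask = disc of cell_radius,
# overlap resolved by nearest center.
render_frame <- function(xs, ys, ids, scene) {
  nx <- scene$nx; ny <- scene$ny; px <- scene$pixel_size
  img <- matrix(scene$background, ny, nx)
  mask <- matrix(0L, ny, nx)
  bestd <- matrix(Inf, ny, nx)
  r_px <- scene$cell_radius / px
  sig <- r_px / 2
  w <- ceiling(r_px + 3 * sig)
  for (k in seq_along(xs)) {
    cx <- xs[k] / px + 0.5 # pixel-center coordinates: pixel j covers (j-1, j]
    cy <- ys[k] / px + 0.5
    jx <- max(1, floor(cx - w)):min(nx, ceiling(cx + w))
    jy <- max(1, floor(cy - w)):min(ny, ceiling(cy + w))
    if (length(jx) == 0L || length(jy) == 0L) next
    ddx <- jx - cx
    ddy <- jy - cy
    d2 <- outer(ddy^2, ddx^2, "+")
    img[jy, jx] <- img[jy, jx] +
      scene$cell_intensity * exp(-d2 / (2 * sig^2))
    inside <- d2 <= r_px^2
    closer <- inside & (d2 < bestd[jy, jx])
    if (any(closer)) {
      sub <- mask[jy, jx]; sub[closer] <- ids[k]; mask[jy, jx] <- sub
      subd <- bestd[jy, jx]; subd[closer] <- d2[closer]; bestd[jy, jx] <- subd
    }
  }
  list(image = img, mask = mask)
}

#' Render a time-lapse image stack from ground-truth tracks
#'
#' Each cell becomes a radially symmetric bright blob at its track
#' position; Gaussian pixel noise is added and, for out-of-focus scenes, a
#' uniform Gaussian blur of sigma = `defocus_blur_per_um * |z_offset|` px.
#' Label masks are noise-free discs (overlaps assigned to the nearest
#' center) so every rendered cell keeps exactly one ground-truth label.
#'
#' @param truth A `prw_truth` from [simulate_prw_tracks()], or a track
#'   data.frame with columns track_id, frame, x_um, y_um.
#' @param scene A [scene_params()].
#' @param z_offset Defocus in um (0 = in focus).
#' @param seed Integer seed for the pixel noise.
#' @return List of class `image_stack`: `frames` (list of matrices),
#'   `masks` (list of integer matrices), `pixel_size`, `frame_interval`.
#' @export
render_stack <- function(truth, scene = scene_params(), z_offset = 0,
                         seed = 1) {
  tracks <- if (inherits(truth, "prw_truth")) truth$tracks else truth
  frame_interval <- if (inherits(truth, "prw_truth"))
    truth$params$frame_interval else NA_real_
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  frames_idx <- if (nrow(tracks) > 0) sort(unique(tracks$frame)) else integer(0)
  sigma_blur <- scene$defocus_blur_per_um * abs(z_offset)
  frames <- vector("list", length(frames_idx))
  masks <- vector("list", length(frames_idx))
  for (i in seq_along(frames_idx)) {
    sel <- tracks$frame == frames_idx[i]
    fr <- render_frame(tracks$x_um[sel], tracks$y_um[sel],
                       tracks$track_id[sel], scene)
    img <- fr$image
    if (sigma_blur > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = sigma_blur))
    if (scene$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, scene$noise_sd),
                          nrow(img), ncol(img))
    frames[[i]] <- img
    masks[[i]] <- fr$mask
  }
  if (length(frames_idx) == 0L) {
    fr <- render_frame(numeric(0), numeric(0), integer(0), scene)
    img <- fr$image
    if (scene$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, scene$noise_sd),
                          nrow(img), ncol(img))
    frames <- list(img)
    masks <- list(fr$mask)
    frames_idx <- 1L
  }
  structure(list(frames = frames, masks = masks, frame_index = frames_idx,
                 pixel_size = scene$pixel_size,
                 frame_interval = frame_interval,
                 z_offset = z_offset),
            class = "image_stack")
}

#' Simulate a defocus z-stack
#'
#' One rendered frame per z position, blurred in proportion to the
#' distance from the true focal plane; fixture for autofocus testing.
#'
#' @param scene A [scene_params()].
#' @param z_positions Vector of >= 2 z positions (um).
#' @param z_focus True focal plane (um).
#' @param n_cells Number of static cells in the scene.
#' @param seed Integer seed (cell placement and noise).
#' @return List of class `defocus_stack`: `frames`, `z_positions`,
#'   `z_focus`.
#' @export
simulate_defocus_stack <- function(scene = scene_params(),
                                   z_positions, z_focus = 0,
                                   n_cells = 30, seed = 1) {
  if (length(z_positions) < 2) stop_invalid("need >= 2 z positions")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  xs <- runif(n_cells, 0, scene$fov_um[1])
  ys <- runif(n_cells, 0, scene$fov_um[2])
  base <- render_frame(xs, ys, seq_len(max(n_cells, 1L)), scene)$image
  frames <- lapply(z_positions, function(z) {
    sig <- scene$defocus_blur_per_um * abs(z - z_focus)
    img <- if (sig > 0) as.matrix(EBImage::gblur(base, sigma = sig)) else base
    if (scene$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, scene$noise_sd),
                          nrow(img), ncol(img))
    img
  })
  structure(list(frames = frames, z_positions = z_positions,
                 z_focus = z_focus),
            class = "defocus_stack")
}
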