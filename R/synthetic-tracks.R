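# Persistent-random-walk (PRW) track generator: the ground-truthed
# stand-in for fMLP-stimulated neutrophil movies. Cells carry a stable
# individual speed (drawn once), a heading that decorrelates via per-step
# turning noise, and reflective boundaries at the field edges.

#' Persistent-random-walk parameters
#'
#' Defaults emulate fMLP-stimulated human neutrophils recorded at one
#' frame per 8 s for one hour (450 frames): stable per-cell speeds around
#' 15 um/min, gradually decorrelating headings, and a fraction of inactive
#' cells that only jitter in place.
#'
#' @param mean_speed Mean per-cell path speed, um/min.
#' @param speed_sd SD of the per-cell speed distribution (truncated normal
#'   at 0), um/min.
#' @param turn_sd SD of the per-step heading change, radians.
#' @param frame_interval Frame interval in s.
#' @param n_frames Number of frames (>= 2).
#' @param active_fraction Fraction of cells that move at all, in \[0, 1\].
#' @param jitter_sd Positional jitter SD of inactive cells, um per frame.
#' @return A `prw_params` list.
#' @export
prw_params <- function(mean_speed = 15, speed_sd = 5, turn_sd = 0.6,
                       frame_interval = 8, n_frames = 450,
                       active_fraction = 0.7, jitter_sd = 0.2) {
  check_nonneg(mean_speed, "mean_speed")
  check_nonneg(speed_sd, "speed_sd")
  check_nonneg(turn_sd, "turn_sd")
  check_positive(frame_interval, "frame_interval")
  if (n_frames < 2) stop_invalid("n_frames must be >= 2")
  if (active_fraction < 0 || active_fraction > 1)
    stop_invalid("active_fraction must be in [0, 1]")
  check_nonneg(jitter_sd, "jitter_sd")
  structure(list(mean_speed = mean_speed, speed_sd = speed_sd,
                 turn_sd = turn_sd, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 active_fraction = active_fraction, jitter_sd = jitter_sd),
            class = "prw_params")
}

# normal truncated at 0 by rejection (exact, vectorized)
rtruncnorm0 <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(max(mean, 0), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0]
  }
  x
}

# reflect coordinates into [0, L]
reflect_into <- function(x, L) {
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

#' Simulate persistent-random-walk cell tracks
#'
#' Active cells draw a stable speed s_i ~ Normal(mean_speed, speed_sd)
#' truncated at 0 and step s_i * dt per frame while their heading performs
#' a Gaussian random walk with SD `turn_sd` per step; inactive cells
#' jitter around their position with zero mean speed. Tracks reflect off
#' the field-of-view edges. Identical (params, n_cells, seed) give
#' identical output.
#'
#' @param params A [prw_params()].
#' @param n_cells Number of cells (>= 0).
#' @param seed Integer RNG seed.
#' @param fov_um Field of view c(width, height) in um.
#' @return List of class `prw_truth` with `tracks` (data.frame: track_id,
#'   frame, x_um, y_um), `cells` (track_id, active, speed_um_min) and the
#'   generating parameters.
#' @export
simulate_prw_tracks <- function(params = prw_params(), n_cells, seed = 1,
                                fov_um = c(825.8, 512)) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 0)
    stop_invalid("`n_cells` must be a single non-negative count")
  n_cells <- as.integer(n_cells)
  nf <- params$n_frames
  dt_min <- params$frame_interval / 60
  W <- fov_um[1]; H <- fov_um[2]

  if (n_cells == 0L) {
    return(structure(list(
      tracks = data.frame(track_id = integer(0), frame = integer(0),
                          x_um = numeric(0), y_um = numeric(0)),
      cells = data.frame(track_id = integer(0), active = logical(0),
                         speed_um_min = numeric(0)),
      params = params, fov_um = fov_um, seed = seed),
      class = "prw_truth"))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  active <- runif(n_cells) < params$active_fraction
  speeds <- numeric(n_cells)
  speeds[active] <- rtruncnorm0(sum(active), params$mean_speed,
                                params$speed_sd)

  x0 <- runif(n_cells, 0, W)
  y0 <- runif(n_cells, 0, H)
  theta0 <- runif(n_cells, 0, 2 * pi)

  # headings: cumulative Gaussian turns per cell (matrix cells x steps)
  nsteps <- nf - 1L
  row_cumsum <- function(m) if (ncol(m) == 1L) m else t(apply(m, 1, cumsum))
  turns <- matrix(rnorm(n_cells * nsteps, 0, params$turn_sd),
                  n_cells, nsteps)
  theta <- theta0 + row_cumsum(turns)
  step_len <- speeds * dt_min # um per frame
  dx <- step_len * cos(theta)
  dy <- step_len * sin(theta)
  # inactive cells: zero-mean jitter instead of directed steps
  if (any(!active) && params$jitter_sd > 0) {
    ji <- which(!active)
    dx[ji, ] <- rnorm(length(ji) * nsteps, 0, params$jitter_sd)
    dy[ji, ] <- rnorm(length(ji) * nsteps, 0, params$jitter_sd)
  }
  X <- cbind(x0, x0 + row_cumsum(dx))
  Y <- cbind(y0, y0 + row_cumsum(dy))
  X <- reflect_into(X, W)
  Y <- reflect_into(Y, H)

  tracks <- data.frame(
    track_id = rep(seq_len(n_cells), each = nf),
    frame = rep(seq_len(nf), times = n_cells),
    x_um = as.vector(t(X)),
    y_um = as.vector(t(Y)))
  cells <- data.frame(track_id = seq_len(n_cells), active = active,
                      speed_um_min = speeds)
  structure(list(tracks = tracks, cells = cells, params = params,
                 fov_um = fov_um, seed = seed),
            class = "prw_truth")
}

# preserve caller RNG state around seeded generators
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
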