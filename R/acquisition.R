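# Acquisition control-loop simulator: image sharpness scoring, sharpest-
# frame selection under the two autofocus modes, per-well focus-position
# maps, and XYZ stage cycle scheduling against the 8 s frame interval.

#' Stage specification
#'
#' Kinematic parameters of the motorized XYZ platform. Defaults follow the
#' instrument: XY linear stages at 10 mm/s, Z lifting stage at 20 mm/s with
#' 0.2 um step resolution, 4.5 mm well pitch (384-well plate) and a ~40 ms
#' per-position rest in triggered autofocus.
#'
#' @param xy_speed,z_speed Positioning speeds in mm/s.
#' @param z_step_resolution Z step resolution in um.
#' @param well_pitch Center-to-center well spacing in mm (9.0 for 96-well,
#'   4.5 for 384-well plates).
#' @param focus_dwell Per-position rest time in triggered mode, ms.
#' @return A `stage_spec` list.
#' @export
stage_spec <- function(xy_speed = 10, z_speed = 20, z_step_resolution = 0.2,
                       well_pitch = 4.5, focus_dwell = 40) {
  check_positive(xy_speed, "xy_speed")
  check_positive(z_speed, "z_speed")
  check_positive(z_step_resolution, "z_step_resolution")
  if (!well_pitch %in% c(4.5, 9.0))
    warning("well_pitch is not a standard 96-well (9.0) or 384-well (4.5) pitch")
  check_nonneg(focus_dwell, "focus_dwell")
  structure(list(xy_speed = xy_speed, z_speed = z_speed,
                 z_step_resolution = z_step_resolution,
                 well_pitch = well_pitch, focus_dwell = focus_dwell),
            class = "stage_spec")
}

#' Focus sweep specification
#'
#' One periodic up-and-down pass of the lens array through the focus range,
#' during which only the sharpest frame per channel is retained
#' (~1.5 s per sweep).
#'
#' @param z_min,z_max Sweep range in um (z_min < z_max).
#' @param n_positions Number of discrete focus positions (>= 2).
#' @param sweep_duration Nominal sweep time in s.
#' @return A `focus_sweep` list.
#' @export
focus_sweep <- function(z_min = -10, z_max = 10, n_positions = 11,
                        sweep_duration = 1.5) {
  if (!(z_min < z_max)) stop_invalid("z_min must be < z_max")
  if (n_positions < 2) stop_invalid("n_positions must be >= 2")
  check_positive(sweep_duration, "sweep_duration")
  structure(list(z_min = z_min, z_max = z_max, n_positions = n_positions,
                 sweep_duration = sweep_duration),
            class = "focus_sweep")
}

#' Tenengrad image sharpness score
#'
#' Mean squared gradient magnitude from 3x3 Sobel derivative kernels.
#' Zero for a constant image and invariant to adding a constant offset;
#' decreases monotonically under Gaussian blur, which makes it a focus
#' indicator: the in-focus plane of a z-stack maximizes the score.
#'
#' @param frame Numeric matrix of pixel intensities (rows = y, cols = x).
#' @return Non-negative scalar score.
#' @export
sharpness_score <- function(frame) {
  if (!is.matrix(frame) || length(frame) == 0L)
    stop_invalid("`frame` must be a non-empty numeric matrix")
  if (nrow(frame) < 3 || ncol(frame) < 3) return(0)
  # direct 3x3 convolution via shifted submatrices (no boundary padding)
  nr <- nrow(frame); nc <- ncol(frame)
  s <- function(dy, dx) frame[(2 + dy):(nr - 1 + dy), (2 + dx):(nc - 1 + dx)]
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) -
        (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) -
        (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  mean(gx^2 + gy^2)
}

#' Select the stored frame of a focusing sequence
#'
#' Models the FPGA frame selection. In `"triggered"` mode (focus-position
#' map-based) the last complete frame in the ping-pong memory at trigger
#' time is transferred. In `"free_running"` mode the frame with the highest
#' sharpness over the whole sweep is kept in a third memory block; ties go
#' to the earliest frame.
#'
#' @param frames List of frame matrices in completion order, or a numeric
#'   vector of precomputed sharpness scores.
#' @param completion_times Completion time (s) of each frame.
#' @param mode `"free_running"` or `"triggered"`.
#' @param trigger_time Trigger time in s (triggered mode).
#' @return List with `index`, `score` and `completion_time` of the chosen
#'   frame.
#' @export
select_sharpest <- function(frames, completion_times,
                            mode = c("free_running", "triggered"),
                            trigger_time = NULL) {
  mode <- match.arg(mode)
  n <- length(frames)
  if (n == 0L) stop_invalid("no frames supplied")
  if (length(completion_times) != n)
    stop_invalid("`completion_times` must match `frames` in length")
  scores <- if (is.numeric(frames)) as.numeric(frames)
            else vapply(frames, sharpness_score, numeric(1))
  if (mode == "triggered") {
    if (is.null(trigger_time))
      stop_invalid("triggered mode requires `trigger_time`")
    done <- which(completion_times <= trigger_time)
    if (length(done) == 0L)
      stop_invalid("no frame completed at or before the trigger time")
    idx <- done[which.max(completion_times[done])]
  } else {
    idx <- which.max(scores) # which.max returns the earliest maximum
  }
  list(index = idx, score = scores[idx],
       completion_time = completion_times[idx])
}

#' Build a per-well focus-position map
#'
#' Calibrates the focal plane for each well/lens from a defocus z-stack:
#' z* is the plane maximizing the sharpness score. Performed once at the
#' start of a measurement, the map then drives the triggered autofocus.
#'
#' @param defocus_stacks Named list; each element a list with `frames`
#'   (list of matrices) and `z_positions` (um, same length).
#' @return Named numeric vector of z* per well (um).
#' @export
build_focus_map <- function(defocus_stacks) {
  if (length(defocus_stacks) == 0L) stop_invalid("no stacks supplied")
  vapply(defocus_stacks, function(st) {
    z <- st$z_positions
    if (length(st$frames) < 2 || length(z) != length(st$frames))
      stop_invalid("each stack needs >= 2 planes with matching z_positions")
    sc <- vapply(st$frames, sharpness_score, numeric(1))
    if (diff(range(sc)) < .Machine$double.eps * max(1, max(abs(sc)))) {
      warning("flat sharpness profile; choosing midpoint plane")
      return(z[ceiling(length(z) / 2)])
    }
    z[which.max(sc)]
  }, numeric(1))
}

#' Stage travel time at constant velocity
#'
#' @param distance Travel distance in mm (>= 0).
#' @param speed Stage speed in mm/s (> 0).
#' @return Time in s. A 4.5 mm well-pitch move at 10 mm/s takes 0.45 s,
#'   inside the < 500 ms budget.
#' @export
move_time <- function(distance, speed) {
  check_nonneg(distance, "distance")
  check_positive(speed, "speed")
  distance / speed
}

#' Simulate one acquisition cycle
#'
#' Builds the event timeline of one frame-interval cycle. In 384-well mode
#' the 16-lens array visits 4 positions (one 4.5 mm move + focus sweep +
#' exposure each), covering 64 wells per 8 s interval; in 96-well mode the
#' array images its 16 wells in a single position block. The configuration
#' is feasible iff the total cycle time fits in the frame interval.
#'
#' @param plate `"384"` or `"96"`.
#' @param stage A [stage_spec()].
#' @param sweep A [focus_sweep()].
#' @param exposure Exposure (illumination) time in s, default 1/30.
#' @param frame_interval Frame-to-frame interval in s, default 8.
#' @param mode Autofocus mode; in `"triggered"` mode the per-position dwell
#'   extends the sweep when `n_positions * focus_dwell` exceeds the nominal
#'   sweep duration.
#' @return List with `timeline` (data.frame of events: kind, start,
#'   duration, position), `block_durations`, `total_time`, `feasible` and
#'   `violated` (name of the violated budget, or `NA`).
#' @export
simulate_cycle <- function(plate = c("384", "96"), stage = stage_spec(),
                           sweep = focus_sweep(), exposure = 1 / 30,
                           frame_interval = 8,
                           mode = c("triggered", "free_running")) {
  plate <- match.arg(as.character(plate), c("384", "96"))
  mode <- match.arg(mode)
  check_positive(frame_interval, "frame_interval")
  check_nonneg(exposure, "exposure")
  n_blocks <- if (plate == "384") 4L else 1L
  move_mm <- if (plate == "384") stage$well_pitch else 0
  sweep_s <- sweep$sweep_duration
  if (mode == "triggered")
    sweep_s <- max(sweep_s, sweep$n_positions * stage$focus_dwell / 1000)

  events <- list()
  t <- 0
  for (b in seq_len(n_blocks)) {
    pos <- sprintf("position_%d", b)
    if (move_mm > 0) {
      mt <- move_time(move_mm, stage$xy_speed)
      events[[length(events) + 1L]] <-
        data.frame(kind = "move_xy", start = t, duration = mt,
                   position = pos, stringsAsFactors = FALSE)
      t <- t + mt
    }
    events[[length(events) + 1L]] <-
      data.frame(kind = "focus_sweep", start = t, duration = sweep_s,
                 position = pos, stringsAsFactors = FALSE)
    t <- t + sweep_s
    events[[length(events) + 1L]] <-
      data.frame(kind = "expose", start = t, duration = exposure,
                 position = pos, stringsAsFactors = FALSE)
    t <- t + exposure
  }
  timeline <- do.call(rbind, events)
  blocks <- tapply(timeline$duration, timeline$position, sum)
  blocks <- as.numeric(blocks[unique(timeline$position)])
  total <- sum(timeline$duration)
  feasible <- total <= frame_interval
  list(timeline = timeline,
       block_durations = blocks,
       total_time = total,
       feasible = feasible,
       violated = if (feasible) NA_character_ else "frame_interval")
}
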