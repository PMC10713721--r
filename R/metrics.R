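# Per-track and per-well motility statistics: path length, net
# displacement, mean speed, confinement ratio, and the migrating-cell
# criterion (net displacement of at least one cell diameter).

#' Per-track motility metrics
#'
#' `path_length` sums consecutive-step Euclidean distances,
#' `duration = (n_frames - 1) * frame_interval / 60` minutes,
#' `mean_speed = path_length / duration` um/min, and
#' `confinement_ratio = net_displacement / path_length` (1 for straight
#' paths, near 0 for confined wandering; 0 for a stationary track).
#' A track is called migrating when its lifetime net displacement is at
#' least `migration_displacement_min` (default 10 um, about one cell
#' diameter), separating translocation from in-place jitter.
#'
#' @param track data.frame of one track ordered by frame (columns x_um,
#'   y_um), length >= 2.
#' @param frame_interval Frame interval in s.
#' @param migration_displacement_min Migration criterion in um.
#' @return One-row data.frame: path_length, net_displacement, duration,
#'   mean_speed, confinement_ratio, migrating.
#' @export
track_metrics <- function(track, frame_interval = 8,
                          migration_displacement_min = 10) {
  if (nrow(track) < 2)
    stop_invalid("track metrics need at least 2 points")
  dx <- diff(track$x_um); dy <- diff(track$y_um)
  path <- sum(sqrt(dx^2 + dy^2))
  net <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
              (track$y_um[nrow(track)] - track$y_um[1])^2)
  dur <- (nrow(track) - 1) * frame_interval / 60
  data.frame(path_length = path, net_displacement = net, duration = dur,
             mean_speed = path / dur,
             confinement_ratio = if (path > 0) net / path else 0,
             migrating = net >= migration_displacement_min)
}

#' Metrics for every track in a track table
#'
#' @param tracks Track table (columns track_id, frame, x_um, y_um).
#' @param frame_interval Frame interval in s.
#' @param migration_displacement_min Migration criterion in um.
#' @return data.frame with one row per track (track_id + metrics);
#'   single-point tracks are dropped.
#' @export
tracks_metrics <- function(tracks, frame_interval = 8,
                           migration_displacement_min = 10) {
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  parts <- split(tracks, tracks$track_id)
  parts <- parts[vapply(parts, nrow, integer(1)) >= 2]
  if (length(parts) == 0L)
    return(cbind(data.frame(track_id = integer(0)),
                 track_metrics(data.frame(x_um = c(0, 1),
                                          y_um = c(0, 0)))[0, ]))
  out <- do.call(rbind, lapply(parts, track_metrics,
                               frame_interval = frame_interval,
                               migration_displacement_min =
                                 migration_displacement_min))
  out <- cbind(data.frame(track_id = as.integer(names(parts))), out)
  rownames(out) <- NULL
  out
}

#' Per-well summary
#'
#' Mean speed is the unweighted mean over track mean speeds (long tracks
#' are not over-weighted), `n_migrating` counts tracks passing the
#' migration criterion.
#'
#' @param metrics data.frame from [tracks_metrics()].
#' @param well Well id.
#' @param condition Condition/compound label.
#' @return One-row data.frame: well, condition, n_tracks, mean_speed,
#'   n_migrating, evaluable. An empty well is flagged `evaluable = FALSE`
#'   with `NA` speed and is excluded from normalization.
#' @export
well_summary <- function(metrics, well = "", condition = "") {
  n <- nrow(metrics)
  data.frame(well = well, condition = condition, n_tracks = n,
             mean_speed = if (n > 0) mean(metrics$mean_speed) else NA_real_,
             n_migrating = if (n > 0) sum(metrics$migrating) else 0L,
             evaluable = n > 0,
             stringsAsFactors = FALSE)
}
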