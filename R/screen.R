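# Screen analytics: per-round normalization to the stimulated (fMLP)
# control, hit calling at the screen's thresholds, compound
# classification, round planning, polar-plot coordinates, validation
# rate.

#' Hit-calling thresholds
#'
#' Relative-speed and relative-activity cuts of the screen: a strong
#' inhibitor reduces speed by more than 40% (relative speed < 0.6), a
#' moderate inhibitor by 20-40%, an enhancer increases speed by more than
#' 20% (> 1.2), and an activity hit reduces the number of migrating cells
#' by more than 20% (< 0.8). The "unaffected" band for class sorting is
#' \[0.8, 1.2\], symmetric with the 20% cuts. All thresholds are strict on
#' the hit side (exactly 0.6 is moderate, not strong).
#'
#' @param strong_speed,moderate_speed,enhancer_speed,activity_cut
#'   Threshold values on the relative scale.
#' @param unaffected_band Two-element band treated as "not affected".
#' @return A `hit_thresholds` list.
#' @export
hit_thresholds <- function(strong_speed = 0.6, moderate_speed = 0.8,
                           enhancer_speed = 1.2, activity_cut = 0.8,
                           unaffected_band = c(0.8, 1.2)) {
  if (!(0 < strong_speed && strong_speed < 1 && 1 < enhancer_speed))
    stop_invalid("need 0 < strong_speed < 1 < enhancer_speed")
  structure(list(strong_speed = strong_speed,
                 moderate_speed = moderate_speed,
                 enhancer_speed = enhancer_speed,
                 activity_cut = activity_cut,
                 unaffected_band = unaffected_band),
            class = "hit_thresholds")
}

#' Normalize well summaries to the per-round stimulated control
#'
#' Each well's mean speed and migrating-cell count are divided by the
#' same quantities in that round's designated normalization control
#' (role `"control_norm"`, the fMLP or fMLP/DMSO well), whose own
#' relative values are exactly 1. Non-evaluable wells propagate as `NA`.
#'
#' @param summaries data.frame of [well_summary()] rows joined with
#'   layout columns `round`, `role` (and optionally `compound`).
#' @return data.frame of screen rows: well, condition, round, compound,
#'   relative_speed, relative_activity plus the absolute summaries.
#' @export
normalize_to_control <- function(summaries) {
  need <- c("round", "role", "mean_speed", "n_migrating")
  if (!all(need %in% names(summaries)))
    stop_invalid("summaries must carry columns: %s",
                 paste(need, collapse = ", "))
  out <- summaries
  out$relative_speed <- NA_real_
  out$relative_activity <- NA_real_
  for (r in unique(out$round)) {
    in_r <- out$round == r
    ctrl <- which(in_r & out$role == "control_norm")
    if (length(ctrl) != 1L)
      stop_invalid("round %s needs exactly one normalization control", r)
    cs <- out$mean_speed[ctrl]
    ca <- out$n_migrating[ctrl]
    if (!isTRUE(out$evaluable[ctrl]) || is.na(cs) || cs <= 0 || ca <= 0)
      stop_invalid("round %s: normalization control is missing or zero-valued", r)
    ok <- in_r & (if ("evaluable" %in% names(out)) out$evaluable else TRUE)
    out$relative_speed[ok] <- out$mean_speed[ok] / cs
    out$relative_activity[ok] <- out$n_migrating[ok] / ca
    out$relative_speed[ctrl] <- 1
    out$relative_activity[ctrl] <- 1
  }
  out
}

#' Call hits on normalized screen rows
#'
#' Flags are independent: `strong_inhibitor` (relative speed < 0.6),
#' `moderate_inhibitor` (0.6 <= relative speed < 0.8), `enhancer`
#' (relative speed > 1.2) and `activity_hit` (relative activity < 0.8).
#' Rows with missing relative values are skipped with a warning.
#'
#' @param rows data.frame with `relative_speed` and `relative_activity`.
#' @param thresholds A [hit_thresholds()].
#' @return `rows` with logical flag columns added.
#' @export
call_hits <- function(rows, thresholds = hit_thresholds()) {
  th <- thresholds
  miss <- is.na(rows$relative_speed) | is.na(rows$relative_activity)
  if (any(miss))
    warning(sprintf("%d rows with missing relative values skipped",
                    sum(miss)))
  rs <- rows$relative_speed
  ra <- rows$relative_activity
  rows$strong_inhibitor <- !miss & rs < th$strong_speed
  rows$moderate_inhibitor <- !miss & rs >= th$strong_speed &
    rs < th$moderate_speed
  rows$enhancer <- !miss & rs > th$enhancer_speed
  rows$activity_hit <- !miss & ra < th$activity_cut
  rows
}

#' Sort compounds into inhibitor classes
#'
#' Class 1: speed strongly or moderately reduced while activity stays in
#' the unaffected band. Class 2: activity reduced while speed stays in
#' the band. Class 3: both reduced. Everything else: `"none"`.
#'
#' @param rows Output of [call_hits()].
#' @param thresholds A [hit_thresholds()].
#' @return `rows` with a `class` column (`"1"`, `"2"`, `"3"` or
#'   `"none"`).
#' @export
classify_compound <- function(rows, thresholds = hit_thresholds()) {
  th <- thresholds
  rs <- rows$relative_speed
  ra <- rows$relative_activity
  speed_red <- !is.na(rs) & rs < th$moderate_speed
  act_red <- !is.na(ra) & ra < th$activity_cut
  speed_ok <- !is.na(rs) & rs >= th$unaffected_band[1] &
    rs <= th$unaffected_band[2]
  act_ok <- !is.na(ra) & ra >= th$unaffected_band[1] &
    ra <= th$unaffected_band[2]
  cls <- rep("none", nrow(rows))
  cls[speed_red & act_ok] <- "1"
  cls[act_red & speed_ok] <- "2"
  cls[speed_red & act_red] <- "3"
  rows$class <- cls
  rows
}

#' Polar-plot coordinates
#'
#' Translates every track so its first point sits at the common origin
#' and reports ring radii at 100 um intervals out to the maximum radial
#' extent, as used to display migration paths of all cells of an
#' experiment around one center.
#'
#' @param tracks Track table (track_id, frame, x_um, y_um).
#' @param ring_spacing Ring spacing in um (default 100).
#' @return List with `paths` (track table with origin-centered `x_um`,
#'   `y_um` and `r_um`), `rings` (radii vector) and `max_extent`.
#' @export
polar_transform <- function(tracks, ring_spacing = 100) {
  if (nrow(tracks) == 0L) stop_invalid("no tracks supplied")
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  first <- !duplicated(tracks$track_id)
  x0 <- tracks$x_um[first][match(tracks$track_id,
                                 tracks$track_id[first])]
  y0 <- tracks$y_um[first][match(tracks$track_id,
                                 tracks$track_id[first])]
  out <- tracks
  out$x_um <- tracks$x_um - x0
  out$y_um <- tracks$y_um - y0
  out$r_um <- sqrt(out$x_um^2 + out$y_um^2)
  max_extent <- max(out$r_um)
  rings <- if (max_extent >= ring_spacing)
    seq(ring_spacing, max_extent, by = ring_spacing) else numeric(0)
  list(paths = out, rings = rings, max_extent = max_extent)
}

#' Plan screen rounds
#'
#' With `compounds_per_round` compound wells plus the control wells per
#' round, `ceiling(n_compounds / compounds_per_round)` rounds are needed;
#' 1000 compounds at 61 per round take 17 rounds (last round 24
#' compounds).
#'
#' @param n_compounds Number of compounds.
#' @param compounds_per_round Compound wells per round.
#' @param controls_per_round Control wells per round.
#' @return List with `n_rounds` and `rounds` (list of per-round compound
#'   index vectors), plus `controls_per_round`.
#' @export
plan_screen <- function(n_compounds, compounds_per_round = 61,
                        controls_per_round = 3) {
  check_positive(n_compounds, "n_compounds")
  check_positive(compounds_per_round, "compounds_per_round")
  check_positive(controls_per_round, "controls_per_round")
  n_rounds <- ceiling(n_compounds / compounds_per_round)
  rounds <- lapply(seq_len(n_rounds), function(r) {
    lo <- (r - 1) * compounds_per_round + 1
    seq(lo, min(r * compounds_per_round, n_compounds))
  })
  list(n_rounds = as.integer(n_rounds), rounds = rounds,
       controls_per_round = as.integer(controls_per_round))
}

#' Hit validation rate
#'
#' @param n_validated Hits confirmed in the validation rounds.
#' @param n_hits Hits called in the primary screen (> 0).
#' @return Percentage (one decimal); 12 of 17 gives 70.6.
#' @export
validation_rate <- function(n_validated, n_hits) {
  check_positive(n_hits, "n_hits")
  check_nonneg(n_validated, "n_validated")
  if (n_validated > n_hits)
    stop_invalid("n_validated cannot exceed n_hits")
  round(100 * n_validated / n_hits, 1)
}

#' Run the analysis pipeline over a simulated screen
#'
#' For every well of a [simulate_screen()] layout: regenerate the well's
#' ground-truth tracks, compute track metrics and the well summary, then
#' normalize per round and call hits. Streaming (one well in memory at a
#' time), so full-size screens are tractable.
#'
#' @param sim A `screen_sim`.
#' @param n_frames,cells_per_well Optional per-well problem-size
#'   overrides passed to [simulate_well_tracks()].
#' @param thresholds A [hit_thresholds()].
#' @return Screen table: one row per well with relative values, hit
#'   flags and class.
#' @export
screen_pipeline <- function(sim, n_frames = NULL, cells_per_well = NULL,
                            thresholds = hit_thresholds()) {
  fi <- sim$params$baseline$frame_interval
  sums <- lapply(seq_len(nrow(sim$layout)), function(i) {
    row <- sim$layout[i, ]
    truth <- simulate_well_tracks(sim, row$well, n_frames = n_frames,
                                  cells_per_well = cells_per_well)
    mets <- tracks_metrics(truth$tracks, frame_interval = fi)
    ws <- well_summary(mets, well = row$well, condition = row$label)
    cbind(ws, row[, c("round", "role", "compound")])
  })
  summaries <- do.call(rbind, sums)
  rows <- normalize_to_control(summaries)
  classify_compound(call_hits(rows, thresholds), thresholds)
}
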