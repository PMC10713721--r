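# Whole-screen simulator: rounds of 64 wells (61 compounds + 3 controls),
# per-compound speed/activity effects applied as multipliers on the
# stimulated-control motility parameters, with planted hits and full
# ground truth for end-to-end pipeline validation.

#' Screen simulation parameters
#'
#' Defaults reproduce the screen layout: 64-well rounds of 61 compounds
#' plus three controls (stimulated fMLP normalization control, vehicle
#' DMSO or fMLP/DMSO, and unstimulated PBS), 2000 cells per well, one
#' frame per 8 s for an hour. Compound effects are multiplicative on the
#' stimulated baseline: `speed_multiplier` scales mean track speed and
#' `activity_multiplier` scales the fraction of actively migrating cells.
#'
#' @param n_compounds Number of compounds to screen.
#' @param compounds_per_round Compound wells per round (default 61).
#' @param wells_per_round Total wells per round (default 64);
#'   `compounds_per_round + length(controls)` must equal it.
#' @param controls Ordered control labels; the first is the per-round
#'   normalization control.
#' @param speed_multiplier,activity_multiplier Numeric vectors of length
#'   `n_compounds` (recycled if length 1).
#' @param cells_per_well Cells seeded per well.
#' @param baseline A [prw_params()] for the stimulated (fMLP) condition.
#' @param unstim A [prw_params()] for the unstimulated (PBS/DMSO)
#'   condition.
#' @param seed Integer master seed; per-well seeds are derived from it.
#' @return A `screen_sim_params` list.
#' @export
screen_sim_params <- function(n_compounds = 1000,
                              compounds_per_round = 61,
                              wells_per_round = 64,
                              controls = c("fMLP", "DMSO", "PBS"),
                              speed_multiplier = 1,
                              activity_multiplier = 1,
                              cells_per_well = 2000,
                              baseline = prw_params(),
                              unstim = prw_params(mean_speed = 4,
                                                  speed_sd = 2,
                                                  active_fraction = 0.15),
                              seed = 1) {
  check_positive(n_compounds, "n_compounds")
  if (compounds_per_round >= wells_per_round)
    stop_invalid("compounds_per_round must leave room for controls")
  if (compounds_per_round + length(controls) != wells_per_round)
    stop_invalid("compounds_per_round + number of controls must equal wells_per_round")
  sm <- rep_len(speed_multiplier, n_compounds)
  am <- rep_len(activity_multiplier, n_compounds)
  if (any(sm <= 0) || any(am <= 0))
    stop_invalid("effect multipliers must be > 0")
  structure(list(n_compounds = as.integer(n_compounds),
                 compounds_per_round = as.integer(compounds_per_round),
                 wells_per_round = as.integer(wells_per_round),
                 controls = controls,
                 speed_multiplier = sm, activity_multiplier = am,
                 cells_per_well = as.integer(cells_per_well),
                 baseline = baseline, unstim = unstim,
                 seed = as.integer(seed)),
            class = "screen_sim_params")
}

#' Simulate a compound screen
#'
#' Lays out `ceiling(n_compounds / compounds_per_round)` rounds; each
#' round holds its compounds plus the control wells. Control wells get the
#' baseline condition parameters (stimulated for the normalization
#' control, unstimulated for PBS/DMSO); compound wells get the stimulated
#' baseline scaled by the compound's multipliers. Ground-truth relative
#' speed and activity per compound equal the multipliers by construction.
#'
#' Tracks are not stored for every well (a full screen is > 1000 wells);
#' each well's tracks are regenerated deterministically on demand with
#' [simulate_well_tracks()] from the per-well seed in the layout.
#'
#' @param params A [screen_sim_params()].
#' @return List of class `screen_sim`: `layout` (data.frame: round, well,
#'   label, role, seed, mean_speed, active_fraction), `truth` (compound,
#'   true_relative_speed, true_relative_activity) and `params`.
#' @export
simulate_screen <- function(params = screen_sim_params()) {
  p <- params
  n_rounds <- ceiling(p$n_compounds / p$compounds_per_round)
  rows <- list()
  cid <- 0L
  for (r in seq_len(n_rounds)) {
    labels <- p$controls
    roles <- c("control_norm", rep("control", length(p$controls) - 1L))
    n_cmp <- min(p$compounds_per_round, p$n_compounds - cid)
    cmp_ids <- cid + seq_len(n_cmp)
    labels <- c(labels, sprintf("C%04d", cmp_ids))
    roles <- c(roles, rep("compound", n_cmp))
    stim <- c(rep(TRUE, 1L),
              grepl("fMLP", p$controls[-1]),
              rep(TRUE, n_cmp))
    sm <- c(rep(1, length(p$controls)), p$speed_multiplier[cmp_ids])
    am <- c(rep(1, length(p$controls)), p$activity_multiplier[cmp_ids])
    base_speed <- ifelse(stim, p$baseline$mean_speed, p$unstim$mean_speed)
    base_sd <- ifelse(stim, p$baseline$speed_sd, p$unstim$speed_sd)
    base_act <- ifelse(stim, p$baseline$active_fraction,
                       p$unstim$active_fraction)
    nw <- length(labels)
    rows[[r]] <- data.frame(
      round = r,
      well = sprintf("R%02dW%02d", r, seq_len(nw)),
      label = labels, role = roles,
      compound = c(rep(NA_character_, length(p$controls)),
                   sprintf("C%04d", cmp_ids)),
      mean_speed = base_speed * sm,
      speed_sd = base_sd * sm,
      active_fraction = pmin(1, base_act * am),
      seed = (p$seed + (r - 1L) * p$wells_per_round + seq_len(nw)) %%
        .Machine$integer.max,
      stringsAsFactors = FALSE)
    cid <- cid + n_cmp
  }
  layout <- do.call(rbind, rows)
  truth <- data.frame(
    compound = sprintf("C%04d", seq_len(p$n_compounds)),
    true_relative_speed = p$speed_multiplier,
    true_relative_activity = pmin(1, p$baseline$active_fraction *
                                    p$activity_multiplier) /
      p$baseline$active_fraction,
    stringsAsFactors = FALSE)
  structure(list(layout = layout, truth = truth, params = p,
                 n_rounds = n_rounds),
            class = "screen_sim")
}

#' Regenerate the ground-truth tracks of one screen well
#'
#' Deterministic given the screen layout row: the well's PRW parameters
#' and per-well seed fully define its tracks.
#'
#' @param sim A `screen_sim` from [simulate_screen()].
#' @param well Well id (value of `layout$well`).
#' @param n_frames,cells_per_well Optional overrides of the per-well
#'   problem size (defaults from the screen parameters).
#' @return A `prw_truth` (see [simulate_prw_tracks()]).
#' @export
simulate_well_tracks <- function(sim, well, n_frames = NULL,
                                 cells_per_well = NULL) {
  row <- sim$layout[sim$layout$well == well, , drop = FALSE]
  if (nrow(row) != 1L) stop_invalid("unknown well `%s`", well)
  base <- sim$params$baseline
  pp <- prw_params(mean_speed = row$mean_speed, speed_sd = row$speed_sd,
                   turn_sd = base$turn_sd,
                   frame_interval = base$frame_interval,
                   n_frames = if (is.null(n_frames)) base$n_frames
                              else n_frames,
                   active_fraction = row$active_fraction,
                   jitter_sd = base$jitter_sd)
  n <- if (is.null(cells_per_well)) sim$params$cells_per_well
       else cells_per_well
  simulate_prw_tracks(pp, n_cells = n, seed = row$seed)
}
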