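# Earth Mover's Distance single-cell tracking. Each frame's detections
# form a weighted point set (weight proportional to segmented area,
# total mass 1); the discrete transportation problem between consecutive
# frames is solved exactly by min-cost flow, with links longer than the
# displacement gate forbidden. Optimal flows are turned into one-to-one
# frame links by a majority-mass rule, and links are chained into tracks
# with the 8-frame minimum-length filter.

#' Tracker parameters
#'
#' @param gate Maximum per-frame displacement in um (default 20 um per
#'   8 s frame = 150 um/min, several-fold above fast neutrophil speeds).
#' @param flow_threshold Fraction of `min(w_i, w_j)` that must flow
#'   between two detections to declare them linked, in (0, 1].
#' @param min_track_frames Minimum reported track length in frames
#'   (default 8, i.e. at least one minute at 8 s/frame).
#' @param min_area,max_area Detection area band in pixels.
#' @return A `tracker_params` list.
#' @export
tracker_params <- function(gate = 20, flow_threshold = 0.5,
                           min_track_frames = 8, min_area = 20,
                           max_area = 5000) {
  check_positive(gate, "gate")
  if (flow_threshold <= 0 || flow_threshold > 1)
    stop_invalid("flow_threshold must be in (0, 1]")
  if (min_track_frames < 2) stop_invalid("min_track_frames must be >= 2")
  structure(list(gate = gate, flow_threshold = flow_threshold,
                 min_track_frames = as.integer(min_track_frames),
                 min_area = min_area, max_area = max_area),
            class = "tracker_params")
}

#' EMD matching between two frames of detections
#'
#' Detections are weighted by area (normalized to total mass 1 per
#' frame). The transportation problem minimizing total flow x distance is
#' solved exactly; pairs farther apart than `gate` are forbidden, and a
#' dummy sink/source absorbs unmatched mass at cost `gate / 2` per side,
#' so a real link is cheaper than appearance + disappearance exactly when
#' its distance is below the gate. A pair (i, j) is declared matched iff
#' its optimal flow is at least `flow_threshold * min(w_i, w_j)`; the
#' majority-mass rule plus greedy flow ordering keeps links one-to-one.
#'
#' @param dets_t,dets_t1 Detection data.frames (columns label, x_um,
#'   y_um, area_px) for consecutive frames.
#' @param params A [tracker_params()].
#' @return List of class `emd_assignment`: `matched` (data.frame label_t,
#'   label_t1, flow, mass_frac, distance), `unmatched_t` (disappearances),
#'   `unmatched_t1` (appearances), `cost` (total transport cost over real
#'   links), `matched_mass`.
#' @export
emd_match <- function(dets_t, dets_t1, params = tracker_params()) {
  empty <- function(un_t, un_t1) {
    structure(list(
      matched = data.frame(label_t = integer(0), label_t1 = integer(0),
                           flow = numeric(0), mass_frac = numeric(0),
                           distance = numeric(0)),
      unmatched_t = un_t, unmatched_t1 = un_t1,
      cost = 0, matched_mass = 0), class = "emd_assignment")
  }
  n <- nrow(dets_t); m <- nrow(dets_t1)
  if (n == 0L || m == 0L)
    return(empty(if (n) dets_t$label else integer(0),
                 if (m) dets_t1$label else integer(0)))

  w <- dets_t$area_px / sum(dets_t$area_px)
  v <- dets_t1$area_px / sum(dets_t1$area_px)
  d <- sqrt(outer(dets_t$x_um, dets_t1$x_um, "-")^2 +
            outer(dets_t$y_um, dets_t1$y_um, "-")^2)
  allowed <- which(d <= params$gate, arr.ind = TRUE)
  # order arcs by (label_t, label_t1): deterministic solver tie-breaks
  allowed <- allowed[order(allowed[, 1], allowed[, 2]), , drop = FALSE]

  # dummy source n+1 / dummy sink m+1 absorb unmatched mass at gate/2
  pen <- params$gate / 2
  arc_from <- c(allowed[, 1], seq_len(n), rep(n + 1L, m), n + 1L)
  arc_to <- c(allowed[, 2], rep(m + 1L, n), seq_len(m), m + 1L)
  arc_cost <- c(d[allowed], rep(pen, n), rep(pen, m), 0)
  supply <- c(w, 1)
  demand <- c(v, 1)
  flow <- .mcf_transport(supply, demand, arc_from, arc_to, arc_cost)

  nr <- nrow(allowed)
  real <- seq_len(nr)
  cand <- data.frame(i = allowed[, 1], j = allowed[, 2],
                     flow = flow[real], distance = d[allowed])
  cand$minw <- pmin(w[cand$i], v[cand$j])
  cand <- cand[cand$flow >= params$flow_threshold * cand$minw - 1e-12, ,
               drop = FALSE]
  # greedy one-to-one by descending flow, ties by (label_t, label_t1)
  cand <- cand[order(-cand$flow, cand$i, cand$j), , drop = FALSE]
  used_i <- logical(n); used_j <- logical(m); keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_i[cand$i[k]] && !used_j[cand$j[k]]) {
      keep[k] <- TRUE
      used_i[cand$i[k]] <- TRUE
      used_j[cand$j[k]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$i), , drop = FALSE]

  matched <- data.frame(label_t = dets_t$label[cand$i],
                        label_t1 = dets_t1$label[cand$j],
                        flow = cand$flow,
                        mass_frac = cand$flow / cand$minw,
                        distance = cand$distance)
  structure(list(
    matched = matched,
    unmatched_t = dets_t$label[!used_i],
    unmatched_t1 = dets_t1$label[!used_j],
    cost = sum(flow[real] * d[allowed]),
    matched_mass = sum(cand$flow)), class = "emd_assignment")
}

#' Link frame-pair assignments into tracks
#'
#' Matched chains are concatenated; an unmatched detection in the later
#' frame starts a new track and a disappearance terminates one (no gap
#' closing). Only tracks spanning at least `min_track_frames` consecutive
#' frames are reported.
#'
#' @param detections Detection data.frame over all frames (columns frame,
#'   label, x_um, y_um, area_px).
#' @param assignments List of `emd_assignment`s for consecutive frame
#'   pairs (element p links frame p to frame p + 1).
#' @param params A [tracker_params()].
#' @return data.frame with columns track_id, frame, label, x_um, y_um,
#'   area_px; every reported detection belongs to exactly one track.
#' @export
link_tracks <- function(detections, assignments,
                        params = tracker_params()) {
  frames <- sort(unique(detections$frame))
  if (length(assignments) != length(frames) - 1L)
    stop_invalid("need one assignment per consecutive frame pair (%d pairs for %d frames)",
                 length(frames) - 1L, length(frames))
  # track id per (frame, label)
  det_key <- paste(detections$frame, detections$label)
  track_of <- setNames(rep(NA_integer_, nrow(detections)), det_key)
  next_id <- 0L
  first <- detections$frame == frames[1]
  for (lab in detections$label[first]) {
    next_id <- next_id + 1L
    track_of[paste(frames[1], lab)] <- next_id
  }
  for (p in seq_along(assignments)) {
    a <- assignments[[p]]
    f_t <- frames[p]; f_t1 <- frames[p + 1L]
    if (nrow(a$matched) > 0)
      track_of[paste(f_t1, a$matched$label_t1)] <-
        track_of[paste(f_t, a$matched$label_t)]
    for (lab in a$unmatched_t1) {
      next_id <- next_id + 1L
      track_of[paste(f_t1, lab)] <- next_id
    }
  }
  out <- detections
  out$track_id <- as.integer(track_of[det_key])
  out <- out[!is.na(out$track_id), , drop = FALSE]
  len <- table(out$track_id)
  keep <- as.integer(names(len)[len >= params$min_track_frames])
  out <- out[out$track_id %in% keep, , drop = FALSE]
  out <- out[order(out$track_id, out$frame),
             c("track_id", "frame", "label", "x_um", "y_um", "area_px")]
  rownames(out) <- NULL
  out
}

#' Track a whole movie
#'
#' Segmentation (unless masks are supplied), per-frame detections, EMD
#' matching of consecutive frames, and track linking with the minimum
#' track-length filter.
#'
#' @param stack An `image_stack` or list of frame matrices.
#' @param params A [tracker_params()].
#' @param pixel_size Pixel size in um/px (taken from the stack if absent).
#' @param masks Optional precomputed label masks (external segmenter).
#' @return List of class `emd_tracking`: `tracks` (reported track table),
#'   `detections`, `assignments`, `params`.
#' @export
track_movie <- function(stack, params = tracker_params(),
                        pixel_size = NULL, masks = NULL) {
  detections <- detect_stack(stack, pixel_size = pixel_size,
                             min_area = params$min_area,
                             max_area = params$max_area, masks = masks)
  frames <- sort(unique(detections$frame))
  assignments <- vector("list", max(0L, length(frames) - 1L))
  for (p in seq_along(assignments)) {
    assignments[[p]] <- emd_match(
      detections[detections$frame == frames[p], , drop = FALSE],
      detections[detections$frame == frames[p + 1L], , drop = FALSE],
      params)
  }
  tracks <- link_tracks(detections, assignments, params)
  structure(list(tracks = tracks, detections = detections,
                 assignments = assignments, params = params),
            class = "emd_tracking")
}
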