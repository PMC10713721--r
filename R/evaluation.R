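# Tracker evaluation against ground truth by the frame-pair
# error-counting scheme: links are judged on the basis of the former
# frame's detections, and the correctness statistic is
# (created - erroneous) / (created + untracked).

#' Match criterion for predicted-to-true cell correspondence
#'
#' @param max_centroid_distance Maximum centroid distance (um) for a
#'   detection to correspond to a true cell; default 5 um, well under one
#'   cell diameter.
#' @return A `match_criterion` list.
#' @export
match_criterion <- function(max_centroid_distance = 5) {
  check_positive(max_centroid_distance, "max_centroid_distance")
  structure(list(max_centroid_distance = max_centroid_distance),
            class = "match_criterion")
}

# greedy nearest one-to-one correspondence within a distance cut;
# returns integer vector: for each row of a, the matched row of b (NA if none)
greedy_correspond <- function(ax, ay, bx, by, max_dist) {
  na <- length(ax); nb <- length(bx)
  out <- rep(NA_integer_, na)
  if (na == 0L || nb == 0L) return(out)
  d <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
  cand <- which(d <= max_dist, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(out)
  ord <- order(d[cand])
  used_b <- logical(nb)
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (is.na(out[i]) && !used_b[j]) {
      out[i] <- j
      used_b[j] <- TRUE
    }
  }
  out
}

#' Evaluate tracking on sampled frame pairs
#'
#' Automated analogue of manual frame-pair inspection, judged on the
#' basis of the former frame's detections: each former-frame detection is
#' put in one-to-one correspondence with a true cell (nearest centroid
#' within the criterion distance; detections with no correspondence are
#' former-frame segmentation errors and are excluded). A predicted link
#' is correct when its later endpoint lies within the criterion distance
#' of the followed true cell's position in the later frame, erroneous
#' otherwise. True cells correctly detected in the former frame but
#' carrying no predicted link count as untracked; when no detection at
#' all exists near the lost cell's later position the miss is attributed
#' to false-negative segmentation. Counts are summed over the sample.
#'
#' @param tracking An `emd_tracking` from [track_movie()] (needs
#'   `detections` and `assignments`).
#' @param truth Ground-truth track table (columns track_id, frame, x_um,
#'   y_um), e.g. `prw_truth$tracks`.
#' @param criterion A [match_criterion()].
#' @param pairs Former-frame indices of the sampled consecutive pairs;
#'   default all pairs.
#' @return List of class `eval_counts`: n_tracks_created, n_erroneous,
#'   n_untracked, n_fn_segmentation, plus n_true_former and
#'   n_detected_former for the detection statistic.
#' @export
evaluate_frame_pairs <- function(tracking, truth,
                                 criterion = match_criterion(),
                                 pairs = NULL) {
  dets <- tracking$detections
  frames <- sort(unique(dets$frame))
  if (is.null(pairs)) pairs <- head(frames, -1L)
  if (length(pairs) == 0L) stop_invalid("empty frame-pair sample")
  md <- criterion$max_centroid_distance

  created <- err <- untracked <- fn_seg <- 0L
  n_true_former <- n_det_former <- 0L
  for (p in pairs) {
    ip <- match(p, frames)
    if (is.na(ip) || ip == length(frames))
      stop_invalid("frame %s is not a former frame of a consecutive pair", p)
    a <- tracking$assignments[[ip]]
    d_t <- dets[dets$frame == frames[ip], , drop = FALSE]
    d_t1 <- dets[dets$frame == frames[ip + 1L], , drop = FALSE]
    g_t <- truth[truth$frame == frames[ip], , drop = FALSE]
    g_t1 <- truth[truth$frame == frames[ip + 1L], , drop = FALSE]

    # one-to-one correspondence former detections -> true cells
    m_t <- greedy_correspond(d_t$x_um, d_t$y_um, g_t$x_um, g_t$y_um, md)
    true_t <- ifelse(is.na(m_t), NA_integer_, g_t$track_id[m_t])

    n_true_former <- n_true_former + nrow(g_t)
    n_det_former <- n_det_former + sum(!is.na(m_t))

    links <- a$matched
    if (nrow(links) > 0) {
      ti <- true_t[match(links$label_t, d_t$label)]
      # errors in the segmentation of the former frame are not
      # considered: links from a detection with no true correspondence
      # are excluded from the counts
      valid <- !is.na(ti)
      created <- created + sum(valid)
      pos <- g_t1[match(ti, g_t1$track_id), , drop = FALSE]
      ex <- d_t1$x_um[match(links$label_t1, d_t1$label)] - pos$x_um
      ey <- d_t1$y_um[match(links$label_t1, d_t1$label)] - pos$y_um
      follows <- !is.na(ex) & sqrt(ex^2 + ey^2) <= md
      err <- err + sum(valid & !follows)
    }
    # true cells correctly detected in the former frame but not linked
    linked_labels <- if (nrow(links) > 0) links$label_t else integer(0)
    det_ok <- !is.na(true_t)
    unl <- det_ok & !(d_t$label %in% linked_labels)
    untracked <- untracked + sum(unl)
    # attributed to false-negative segmentation when no detection exists
    # near the lost cell's later position
    if (any(unl)) {
      ids <- true_t[unl]
      p1 <- g_t1[match(ids, g_t1$track_id), , drop = FALSE]
      for (k in seq_along(ids)) {
        if (is.na(p1$x_um[k])) { fn_seg <- fn_seg + 1L; next }
        dd <- sqrt((d_t1$x_um - p1$x_um[k])^2 + (d_t1$y_um - p1$y_um[k])^2)
        if (!any(dd <= md)) fn_seg <- fn_seg + 1L
      }
    }
  }
  structure(list(n_tracks_created = created, n_erroneous = err,
                 n_untracked = untracked, n_fn_segmentation = fn_seg,
                 n_true_former = n_true_former,
                 n_detected_former = n_det_former),
            class = "eval_counts")
}

#' Correctness statistics from evaluation counts
#'
#' `track_correct_pct = 100 * (created - erroneous) / (created +
#' untracked)`, reported to two decimals: the printed counts 2207 created
#' / 7 erroneous / 43 untracked give 97.78. When the counts carry the
#' former-frame detection totals, `detection_correct_pct` is the fraction
#' of true cells with a corresponding detection.
#'
#' @param counts An `eval_counts` (or list with n_tracks_created,
#'   n_erroneous, n_untracked).
#' @return List with `track_correct_pct` and, when available,
#'   `detection_correct_pct`.
#' @export
correctness_stats <- function(counts) {
  denom <- counts$n_tracks_created + counts$n_untracked
  if (is.null(denom) || denom <= 0)
    stop_invalid("n_tracks_created + n_untracked must be > 0")
  out <- list(track_correct_pct = round(
    100 * (counts$n_tracks_created - counts$n_erroneous) / denom, 2))
  if (!is.null(counts$n_true_former) && counts$n_true_former > 0)
    out$detection_correct_pct <- round(
      100 * counts$n_detected_former / counts$n_true_former, 2)
  out
}
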