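test_that("identical detection sets match to identity at zero cost", {
  d <- data.frame(label = 1:3, x_um = c(0, 30, 60), y_um = c(0, 10, 0),
                  area_px = c(10, 20, 30))
  a <- emd_match(d, d)
  expect_equal(a$matched$label_t, 1:3)
  expect_equal(a$matched$label_t1, 1:3)
  expect_equal(a$cost, 0)
  expect_equal(a$matched_mass, 1)
  expect_length(a$unmatched_t, 0)
  expect_length(a$unmatched_t1, 0)
})

test_that("three displaced cells match the brute-force optimum", {
  set.seed(31)
  p1 <- data.frame(label = 1:3, x_um = c(5, 25, 45), y_um = c(5, 20, 8),
                   area_px = c(8, 15, 30)) # unequal areas
  p2 <- p1
  p2$x_um <- p1$x_um + rnorm(3, 0, 3)
  p2$y_um <- p1$y_um + rnorm(3, 0, 3)
  bf <- brute_force_matching(p1$x_um, p1$y_um, p2$x_um, p2$y_um)
  a <- emd_match(p1, p2, tracker_params(gate = 100))
  got <- a$matched$label_t1[order(a$matched$label_t)]
  expect_equal(as.integer(got), bf$perm)
})

test_that("EMD matching equals exhaustive min-cost matching on small instances", {
  # equal counts, equal areas, all pairs within gate: the optimal
  # transport plan is a permutation and must agree with enumeration
  for (s in 1:60) {
    set.seed(s)
    n <- sample(2:6, 1)
    p1 <- random_detections(n)
    p2 <- random_detections(n)
    bf <- brute_force_matching(p1$x_um, p1$y_um, p2$x_um, p2$y_um)
    a <- emd_match(p1, p2, tracker_params(gate = 1000))
    got <- a$matched$label_t1[order(a$matched$label_t)]
    expect_equal(as.integer(got), bf$perm,
                 label = sprintf("seed %d matching", s))
    expect_equal(a$cost, bf$cost / n, tolerance = 1e-9,
                 label = sprintf("seed %d cost", s))
  }
})

test_that("EMD matching agrees with the Hungarian assignment oracle", {
  skip_if_not_installed("clue")
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- sample(3:8, 1)
    p1 <- random_detections(n)
    p2 <- random_detections(n)
    d <- sqrt(outer(p1$x_um, p2$x_um, "-")^2 +
              outer(p1$y_um, p2$y_um, "-")^2)
    hung <- as.integer(clue::solve_LSAP(d))
    a <- emd_match(p1, p2, tracker_params(gate = 1000))
    got <- a$matched$label_t1[order(a$matched$label_t)]
    expect_equal(as.integer(got), hung)
  }
})

test_that("cells beyond the gate are reported as disappearance/appearance", {
  p1 <- data.frame(label = 1:2, x_um = c(10, 200), y_um = c(10, 10),
                   area_px = c(10, 10))
  p2 <- data.frame(label = 1:2, x_um = c(12, 400), y_um = c(10, 10),
                   area_px = c(10, 10))
  a <- emd_match(p1, p2, tracker_params(gate = 20))
  expect_equal(nrow(a$matched), 1L)
  expect_equal(a$matched$label_t, 1L)
  expect_equal(a$unmatched_t, 2L)
  expect_equal(a$unmatched_t1, 2L)
})

test_that("empty frames produce all-unmatched assignments without error", {
  d <- data.frame(label = 1:2, x_um = c(1, 2), y_um = c(1, 2),
                  area_px = c(5, 5))
  e <- d[0, ]
  a1 <- emd_match(d, e)
  expect_equal(nrow(a1$matched), 0L)
  expect_equal(a1$unmatched_t, 1:2)
  a2 <- emd_match(e, d)
  expect_equal(a2$unmatched_t1, 1:2)
})

test_that("transported mass is conserved and bounded", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    p1 <- random_detections(n, area = sample(5:30, 1))
    p2 <- random_detections(m, area = sample(5:30, 1))
    a <- emd_match(p1, p2, tracker_params(gate = 25))
    expect_lte(a$matched_mass, 1 + 1e-9)
    expect_gte(a$matched_mass, 0)
  }
  # equal counts/areas, nothing gated out: all mass matched
  p1 <- random_detections(4, box = 10)
  p2 <- random_detections(4, box = 10)
  a <- emd_match(p1, p2, tracker_params(gate = 1000))
  expect_equal(a$matched_mass, 1, tolerance = 1e-9)
})

test_that("matching is deterministic", {
  set.seed(55)
  p1 <- random_detections(6)
  p2 <- random_detections(6)
  a1 <- emd_match(p1, p2)
  a2 <- emd_match(p1, p2)
  expect_identical(a1$matched, a2$matched)
})

test_that("linking chains matches into tracks and applies the length filter", {
  # one cell drifting right for 10 frames, another visible only 7 frames
  n <- 10
  det <- do.call(rbind, lapply(1:n, function(f) {
    d <- data.frame(frame = f, label = 1L, x_um = 2 * f, y_um = 5,
                    area_px = 10)
    if (f <= 7)
      d <- rbind(d, data.frame(frame = f, label = 2L, x_um = 2 * f,
                               y_um = 50, area_px = 10))
    d
  }))
  frames <- 1:n
  asg <- lapply(1:(n - 1), function(p)
    emd_match(det[det$frame == p, ], det[det$frame == p + 1, ],
              tracker_params(gate = 20)))
  tracks <- link_tracks(det, asg, tracker_params(min_track_frames = 8))
  expect_equal(length(unique(tracks$track_id)), 1L) # 7-frame chain filtered
  expect_equal(nrow(tracks), 10L)
  expect_equal(sort(tracks$frame), 1:10)
  # every reported detection belongs to exactly one track
  expect_false(any(duplicated(tracks[, c("frame", "label")])))
})

test_that("crossing cells keep their identities when separated beyond the gate", {
  # two cells pass each other on parallel lanes 30 um apart
  n <- 12
  det <- do.call(rbind, lapply(1:n, function(f) rbind(
    data.frame(frame = f, label = 1L, x_um = 5 * f, y_um = 10, area_px = 10),
    data.frame(frame = f, label = 2L, x_um = 60 - 5 * f, y_um = 40,
               area_px = 10))))
  asg <- lapply(1:(n - 1), function(p)
    emd_match(det[det$frame == p, ], det[det$frame == p + 1, ],
              tracker_params(gate = 20)))
  tracks <- link_tracks(det, asg, tracker_params())
  t1 <- tracks[tracks$track_id == tracks$track_id[1], ]
  expect_true(all(t1$y_um == t1$y_um[1])) # no lane switching
  expect_equal(length(unique(tracks$track_id)), 2L)
})

test_that("a never-lost cell yields a single full-length track", {
  fx <- small_movie_fixture()
  tr <- track_movie(fx$stack, tracker_params(min_track_frames = 8))
  lens <- table(tr$tracks$track_id)
  expect_true(all(lens >= 8))
  expect_gte(sum(lens == 12), 28) # most of the 40 cells tracked end-to-end
})
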