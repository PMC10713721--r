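test_that("track metrics follow the path/displacement arithmetic", {
  # straight track, 10 um per 8 s step
  tr <- data.frame(x_um = seq(0, 50, by = 10), y_um = 0)
  m <- track_metrics(tr, frame_interval = 8)
  expect_equal(m$mean_speed, 75)
  expect_equal(m$confinement_ratio, 1)
  expect_true(m$migrating)

  # stationary track
  st <- data.frame(x_um = rep(3, 5), y_um = rep(4, 5))
  ms <- track_metrics(st)
  expect_equal(ms$mean_speed, 0)
  expect_equal(ms$confinement_ratio, 0)
  expect_false(ms$migrating)

  # closed square path of side 20 um over 4 steps
  sq <- data.frame(x_um = c(0, 20, 20, 0, 0), y_um = c(0, 0, 20, 20, 0))
  mq <- track_metrics(sq)
  expect_equal(mq$path_length, 80)
  expect_equal(mq$net_displacement, 0)
  expect_equal(mq$confinement_ratio, 0)

  expect_error(track_metrics(data.frame(x_um = 1, y_um = 1)), "2 points")
})

test_that("confinement ratio stays within [0, 1] on random walks", {
  set.seed(13)
  truth <- simulate_prw_tracks(prw_params(n_frames = 25), n_cells = 100,
                               seed = 13)
  mets <- tracks_metrics(truth$tracks)
  expect_true(all(mets$confinement_ratio >= 0 &
                  mets$confinement_ratio <= 1 + 1e-12))
})

test_that("well summaries average tracks and count migrating cells", {
  mets <- data.frame(mean_speed = c(10, 10, 10, 10),
                     migrating = c(TRUE, TRUE, FALSE, FALSE))
  ws <- well_summary(mets, well = "A1", condition = "fMLP")
  expect_equal(ws$mean_speed, 10)
  expect_equal(ws$n_migrating, 2L)
  expect_equal(ws$n_tracks, 4L)
  empty <- well_summary(mets[0, ], well = "A2")
  expect_false(empty$evaluable)
  expect_true(is.na(empty$mean_speed))
})

test_that("activity recovery matches the generator's active fraction", {
  truth <- simulate_prw_tracks(prw_params(n_frames = 50,
                                          active_fraction = 0.6),
                               n_cells = 400, seed = 17)
  mets <- tracks_metrics(truth$tracks)
  frac <- sum(mets$migrating) / nrow(mets)
  expect_lt(abs(frac - 0.6), 0.1)
})

test_that("normalization sets the control to 1 and scales the round", {
  s <- data.frame(well = c("w1", "w2", "w3"),
                  condition = c("fMLP", "A", "B"), n_tracks = c(10, 10, 10),
                  mean_speed = c(12, 6, 18), n_migrating = c(8, 4, 8),
                  evaluable = TRUE, round = 1,
                  role = c("control_norm", "compound", "compound"))
  rows <- normalize_to_control(s)
  expect_equal(rows$relative_speed, c(1, 0.5, 1.5))
  expect_equal(rows$relative_activity, c(1, 0.5, 1))
  # scale invariance: multiplying all speeds by c leaves ratios unchanged
  s2 <- s
  s2$mean_speed <- s$mean_speed * 7.3
  expect_equal(normalize_to_control(s2)$relative_speed, rows$relative_speed)
  # missing control errors with the round named
  s3 <- s
  s3$role <- "compound"
  expect_error(normalize_to_control(s3), "round 1")
})

test_that("non-evaluable wells propagate as missing relative values", {
  s <- data.frame(well = c("w1", "w2"), condition = c("fMLP", "A"),
                  n_tracks = c(10, 0), mean_speed = c(12, NA),
                  n_migrating = c(8, 0), evaluable = c(TRUE, FALSE),
                  round = 1, role = c("control_norm", "compound"))
  rows <- normalize_to_control(s)
  expect_true(is.na(rows$relative_speed[2]))
  expect_warning(call_hits(rows), "skipped")
})

test_that("hit flags follow the strict threshold conventions", {
  rows <- data.frame(relative_speed = c(0.55, 0.60, 0.79, 0.80, 1.20,
                                        1.25, 1.00),
                     relative_activity = c(1, 1, 1, 1, 1, 1, 0.75))
  out <- call_hits(rows)
  expect_equal(out$strong_inhibitor,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$moderate_inhibitor,
               c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$enhancer,
               c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$activity_hit,
               c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  # flags partition: never both strong and moderate; never enhancer + inhibitor
  expect_false(any(out$strong_inhibitor & out$moderate_inhibitor))
  expect_false(any(out$enhancer & (out$strong_inhibitor |
                                   out$moderate_inhibitor)))
})

test_that("compound classes separate speed, activity and joint effects", {
  rows <- data.frame(relative_speed = c(0.50, 0.95, 0.50, 1.0),
                     relative_activity = c(0.95, 0.50, 0.50, 1.0))
  out <- classify_compound(call_hits(rows))
  expect_equal(out$class, c("1", "2", "3", "none"))
})

test_that("polar transform centers tracks and emits 100-um rings", {
  tr <- data.frame(track_id = c(1, 1, 1, 2, 2),
                   frame = c(1, 2, 3, 1, 2),
                   x_um = c(5, 105, 255, 50, 50), y_um = c(5, 5, 5, 9, 9))
  pol <- polar_transform(tr)
  firsts <- pol$paths[!duplicated(pol$paths$track_id), ]
  expect_true(all(firsts$x_um == 0 & firsts$y_um == 0))
  expect_equal(pol$rings, c(100, 200)) # straight 250 um track crosses both
  expect_equal(pol$max_extent, 250)
  # brute-force max radial extent over all points
  expect_equal(pol$max_extent, max(pol$paths$r_um))
})

test_that("screen planning reproduces the 17-round layout", {
  ps <- plan_screen(1000, 61, 3)
  expect_equal(ps$n_rounds, 17L)
  expect_length(ps$rounds[[17]], 24L)
  expect_equal(plan_screen(61)$n_rounds, 1L)
  expect_equal(plan_screen(62)$n_rounds, 2L)
  expect_error(plan_screen(0), "n_compounds")
})

test_that("validation rate reproduces the reported percentage", {
  expect_equal(validation_rate(12, 17), 70.6)
  expect_equal(validation_rate(17, 17), 100.0)
  expect_equal(validation_rate(0, 17), 0.0)
  expect_error(validation_rate(5, 0), "n_hits")
  expect_error(validation_rate(18, 17), "exceed")
})

test_that("a planted inhibitor is recovered through the full well pipeline", {
  sm <- c(0.5, rep(1, 4))
  sim <- simulate_screen(screen_sim_params(
    n_compounds = 5, compounds_per_round = 5, wells_per_round = 8,
    speed_multiplier = sm, seed = 23))
  tab <- screen_pipeline(sim, n_frames = 40, cells_per_well = 150)
  hit <- tab[!is.na(tab$compound) & tab$compound == "C0001", ]
  expect_lt(abs(hit$relative_speed - 0.5), 0.07)
  expect_true(hit$strong_inhibitor)
  ctrl <- tab[tab$role == "control_norm", ]
  expect_equal(ctrl$relative_speed, 1)
})
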