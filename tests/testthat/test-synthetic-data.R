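test_that("PRW generator is deterministic and respects the field bounds", {
  p <- prw_params(n_frames = 30)
  a <- simulate_prw_tracks(p, n_cells = 50, seed = 11)
  b <- simulate_prw_tracks(p, n_cells = 50, seed = 11)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$cells, b$cells)
  c2 <- simulate_prw_tracks(p, n_cells = 50, seed = 12)
  expect_false(identical(a$tracks, c2$tracks))
  expect_true(all(a$tracks$x_um >= 0 & a$tracks$x_um <= 825.8))
  expect_true(all(a$tracks$y_um >= 0 & a$tracks$y_um <= 512))
  expect_error(simulate_prw_tracks(p, n_cells = -1), "n_cells")
})

test_that("deterministic limit gives straight tracks at the nominal speed", {
  p <- prw_params(mean_speed = 12, speed_sd = 0, turn_sd = 0,
                  frame_interval = 8, n_frames = 10, active_fraction = 1)
  tr <- simulate_prw_tracks(p, n_cells = 5, seed = 3,
                            fov_um = c(1e5, 1e5)) # huge field: no reflection
  mets <- tracks_metrics(tr$tracks, frame_interval = 8,
                         migration_displacement_min = 1)
  expect_equal(mets$mean_speed, rep(12, 5), tolerance = 1e-10)
  expect_equal(mets$confinement_ratio, rep(1, 5), tolerance = 1e-10)
})

test_that("path-based speed over many cells recovers the generator mean", {
  p <- prw_params(n_frames = 40, active_fraction = 1)
  tr <- simulate_prw_tracks(p, n_cells = 500, seed = 21)
  mets <- tracks_metrics(tr$tracks, frame_interval = 8)
  # per-cell path speed equals the drawn speed exactly; the Monte-Carlo
  # check is on the truncated-normal sample mean
  se <- p$speed_sd / sqrt(500)
  expect_lt(abs(mean(mets$mean_speed) - p$mean_speed), 2.5 * se + 0.05)
})

test_that("rendered blobs sit within a pixel of the true positions", {
  fx <- small_movie_fixture()
  stack <- fx$stack
  truth <- fx$truth
  f1 <- stack$masks[[1]]
  dets <- mask_to_detections(f1, frame = 1, pixel_size = stack$pixel_size)
  g1 <- truth$tracks[truth$tracks$frame == 1, ]
  # isolated cells only: overlap resolution legitimately shifts the mask
  # centroid of touching cells
  dd <- as.matrix(dist(g1[, c("x_um", "y_um")]))
  diag(dd) <- Inf
  r <- fx$scene$cell_radius
  interior <- g1$x_um > 2 * r & g1$x_um < fx$scene$fov_um[1] - 2 * r &
    g1$y_um > 2 * r & g1$y_um < fx$scene$fov_um[2] - 2 * r
  iso <- which(apply(dd, 1, min) > 3 * r & interior)
  expect_gt(length(iso), 5)
  for (k in iso) {
    d <- sqrt((dets$x_um - g1$x_um[k])^2 + (dets$y_um - g1$y_um[k])^2)
    expect_lt(min(d), fx$scene$pixel_size * 1.5)
  }
})

test_that("mask labels map one-to-one onto ground-truth track ids", {
  fx <- small_movie_fixture()
  for (i in c(1, 6, 12)) {
    m <- fx$stack$masks[[i]]
    labs <- setdiff(unique(as.vector(m)), 0L)
    g <- fx$truth$tracks[fx$truth$tracks$frame == i, ]
    expect_true(all(labs %in% g$track_id))
  }
})

test_that("an empty scene renders pure background with empty masks", {
  scene <- scene_params(fov_um = c(64.5, 64.5))
  p <- prw_params(n_frames = 2)
  empty <- simulate_prw_tracks(p, n_cells = 0, seed = 1)
  st <- render_stack(empty, scene = scene, seed = 1)
  expect_true(all(st$masks[[1]] == 0L))
  expect_equal(mean(st$frames[[1]]), scene$background, tolerance = 0.01)
})

test_that("defocus stacks put the sharpness argmax at the focal plane", {
  scene <- scene_params(fov_um = c(103.2, 103.2))
  zs <- seq(-8, 8, by = 2)
  st0 <- simulate_defocus_stack(scene, zs, z_focus = 0, n_cells = 12,
                                seed = 9)
  s0 <- vapply(st0$frames, sharpness_score, numeric(1))
  expect_equal(zs[which.max(s0)], 0)
  # shifting the focal plane shifts the argmax accordingly
  st4 <- simulate_defocus_stack(scene, zs, z_focus = 4, n_cells = 12,
                                seed = 9)
  s4 <- vapply(st4$frames, sharpness_score, numeric(1))
  expect_equal(zs[which.max(s4)], 4)
  # all planes at focus: identical up to noise
  stf <- simulate_defocus_stack(scene_params(fov_um = c(103.2, 103.2),
                                             noise_sd = 0),
                                c(2, 2, 2), z_focus = 2, n_cells = 12,
                                seed = 9)
  expect_equal(stf$frames[[1]], stf$frames[[3]])
})

test_that("screen layout follows the 61 + 3 round structure", {
  sim <- simulate_screen(screen_sim_params(n_compounds = 1000, seed = 2))
  expect_equal(sim$n_rounds, 17L)
  per_round <- table(sim$layout$round)
  expect_true(all(per_round[1:16] == 64))
  expect_equal(as.integer(per_round[17]), 24 + 3) # 24 leftover compounds
  # every round has exactly one normalization control
  norm <- tapply(sim$layout$role == "control_norm", sim$layout$round, sum)
  expect_true(all(norm == 1))
  expect_error(screen_sim_params(compounds_per_round = 64,
                                 wells_per_round = 64),
               "controls")
})

test_that("effect multipliers define the ground-truth relative read-outs", {
  sm <- c(0.5, 1, 1)
  sim <- simulate_screen(screen_sim_params(n_compounds = 3,
                                           compounds_per_round = 3,
                                           wells_per_round = 6,
                                           speed_multiplier = sm, seed = 4))
  expect_equal(sim$truth$true_relative_speed, sm)
  expect_equal(sim$truth$true_relative_activity, rep(1, 3))
  # well-level parameters carry the planted effect
  w <- sim$layout[!is.na(sim$layout$compound) & sim$layout$compound == "C0001", ]
  expect_equal(w$mean_speed, 0.5 * prw_params()$mean_speed)
})

test_that("regenerated well tracks are reproducible from the layout seed", {
  sim <- simulate_screen(screen_sim_params(n_compounds = 2,
                                           compounds_per_round = 2,
                                           wells_per_round = 5, seed = 8))
  w <- sim$layout$well[1]
  t1 <- simulate_well_tracks(sim, w, n_frames = 10, cells_per_well = 20)
  t2 <- simulate_well_tracks(sim, w, n_frames = 10, cells_per_well = 20)
  expect_identical(t1$tracks, t2$tracks)
})
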