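# Shared expensive fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# full imaging pipeline on one in-focus synthetic movie: 300 cells,
# 60 frames (8 min of recording), default scene and tracker
pipeline_fixture <- function() {
  cached_fixture("pipeline", function() {
    truth <- simulate_prw_tracks(prw_params(n_frames = 60),
                                 n_cells = 300, seed = 7)
    stack <- render_stack(truth, seed = 7)
    tracking <- track_movie(stack)
    list(truth = truth, stack = stack, tracking = tracking)
  })
}

# small rendered movie for cheap unit tests: 40 cells, 12 frames on a
# quarter-size field
small_movie_fixture <- function() {
  cached_fixture("small_movie", function() {
    scene <- scene_params(fov_um = c(206.4, 129))
    truth <- simulate_prw_tracks(prw_params(n_frames = 12),
                                 n_cells = 40, seed = 5,
                                 fov_um = scene$fov_um)
    stack <- render_stack(truth, scene = scene, seed = 5)
    list(truth = truth, stack = stack, scene = scene)
  })
}
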