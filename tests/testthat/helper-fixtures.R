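# Shared fixtures, built once per test run and cached (rendering the
# training path is the expensive part).
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Arena oriented with the training shape's left edge at azimuth 0 and the
# feeder 30 degrees to its right (the rectangle training regime).
default_arena <- function() arena_config(feeder_azimuth = 30)

# The 30 training panoramas along the feeder path for the 160 x 38 rectangle.
train_panos_160 <- function() fixture("train_panos_160", function() {
  arena <- default_arena()
  lapply(training_path_poses(arena, 30), function(po)
    render_panorama(shape_library()$rect_160x38, po, arena))
})

train_views_160 <- function(overlap = 0) {
  fixture(paste0("train_views_160_", overlap), function()
    lapply(train_panos_160(), process_view, overlap = overlap))
}

centre_pano <- function(shape_name) {
  fixture(paste0("pano_", shape_name), function()
    render_panorama(shape_library()[[shape_name]], agent_pose(heading = 0),
                    default_arena()))
}

# A default-parameter connectome (25,000 KCs/hemisphere), built once.
default_connectome <- function() {
  fixture("conn_default", function() build_connectome(mb_params(seed = 1)))
}

# Small network for fast unit tests.
small_params <- function(...) {
  args <- list(...)
  defaults <- list(n_kc = 2000L, seed = 99L)
  do.call(mb_params, utils::modifyList(defaults, args))
}
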