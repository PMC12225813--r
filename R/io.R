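## Import/export: panoramas as CSV/PNG, experiment definitions as YAML,
## signal tables as CSV.

#' Export a panorama or processed view
#'
#' `write_panorama_csv()` writes the raw matrix (no headers);
#' `write_panorama_png()` writes an 8-bit greyscale PNG. Pixel value 1
#' means black in the model, so PNG intensities are written as `1 - value`.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_panorama_csv <- function(img, path) {
  stopifnot(is.matrix(img))
  utils::write.table(img, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_panorama_csv
#' @export
write_panorama_png <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0), all(img <= 1))
  png::writePNG(1 - img, path)
  invisible(path)
}

#' Read a panorama matrix back from CSV
#'
#' @param path CSV file written by [write_panorama_csv()].
#' @return numeric matrix.
#' @export
read_panorama_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write rotational signals as CSV
#'
#' One row per direction with columns direction, left, right, sum, diff
#' (and, for ensembles, the per-signal mean and sd).
#'
#' @param signals a [signal_set()] or [ensemble_signals()] object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_signals_csv <- function(signals, path) {
  df <- if (inherits(signals, "rotational_signals")) {
    data.frame(direction = signals$direction, left = signals$left,
               right = signals$right, sum = signals$sum, diff = signals$diff)
  } else if (inherits(signals, "ensemble_signals")) {
    data.frame(direction = signals$direction,
               left_mean = signals$mean$left, left_sd = signals$sd$left,
               right_mean = signals$mean$right, right_sd = signals$sd$right,
               sum_mean = signals$mean$sum, sum_sd = signals$sd$sum,
               diff_mean = signals$mean$diff, diff_sd = signals$sd$diff)
  } else stop("unsupported signals object")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise a connectome to a plain-text bundle
#'
#' Writes a directory holding `params.yaml` (network parameters and edge
#' count), one edge table per hemisphere (`edges_L.csv` / `edges_R.csv`
#' with columns kc, vpn, weight) and `kc_state.csv` (per-KC output weights
#' and training fire counts). Weights are written with 17 significant
#' digits so the round trip is exact.
#'
#' @param conn an [build_connectome()] result.
#' @param path directory to create/write.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(conn, path) {
  stopifnot(inherits(conn, "mb_connectome"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  p <- conn$params
  yaml::write_yaml(list(n_kc = p$n_kc, k_mean = p$k_mean, p_fire = p$p_fire,
                        crossover = p$crossover, overlap = p$overlap,
                        alpha = p$alpha, weight_init = p$weight_init,
                        n_vpn = p$n_vpn, seed = p$seed,
                        n_edges = conn$n_edges),
                   file.path(path, "params.yaml"))
  for (h in c("L", "R")) {
    W <- methods::as(conn$W[[h]], "TsparseMatrix")
    df <- data.frame(kc = W@i + 1L, vpn = W@j + 1L,
                     weight = sprintf("%.17g", W@x))
    utils::write.csv(df, file.path(path, paste0("edges_", h, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  st <- data.frame(w_out_L = sprintf("%.17g", conn$w_out$L),
                   w_out_R = sprintf("%.17g", conn$w_out$R),
                   n_tot_L = conn$n_tot$L, n_tot_R = conn$n_tot$R)
  utils::write.csv(st, file.path(path, "kc_state.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "params.yaml"))
  params <- mb_params(n_kc = meta$n_kc, k_mean = meta$k_mean,
                      p_fire = meta$p_fire, crossover = meta$crossover,
                      overlap = meta$overlap, alpha = meta$alpha,
                      weight_init = meta$weight_init, n_vpn = meta$n_vpn,
                      seed = meta$seed)
  W <- lapply(c(L = "L", R = "R"), function(h) {
    df <- utils::read.csv(file.path(path, paste0("edges_", h, ".csv")))
    Matrix::sparseMatrix(i = df$kc, j = df$vpn, x = as.numeric(df$weight),
                         dims = c(meta$n_kc, meta$n_vpn))
  })
  st <- utils::read.csv(file.path(path, "kc_state.csv"))
  structure(list(W = W,
                 w_out = list(L = as.numeric(st$w_out_L),
                              R = as.numeric(st$w_out_R)),
                 n_tot = list(L = as.integer(st$n_tot_L),
                              R = as.integer(st$n_tot_R)),
                 n_edges = meta$n_edges, params = params),
            class = "mb_connectome")
}

shape_from_config <- function(x, name = NULL) {
  comps <- if (is.list(x) && !is.null(x$components)) x$components else x
  # a single polygon may be given directly as a list of [az, elev] pairs
  if (is.list(comps) && length(comps) && is.numeric(comps[[1]]) &&
      length(comps[[1]]) == 2)
    comps <- list(comps)
  mats <- lapply(comps, function(poly)
    do.call(rbind, lapply(poly, function(v) as.numeric(v))))
  shape_spec(mats, name = name)
}

#' Read an experiment definition from YAML
#'
#' The file holds an `arena` block (`radius`, `feeder_distance`), a
#' `shapes` block (named polygons as lists of `[azimuth, elevation]` vertex
#' pairs in degrees; composites as a `components` list), and an
#' `experiment` block (`train`, `tests`, `feeder_azimuth`, `n_train`,
#' optional `true_modes`). Shape names may also refer to entries of
#' [shape_library()]. See `system.file("extdata", "experiments.yaml",
#' package = "mbnav")` for a worked file.
#'
#' @param path YAML file path.
#' @param experiment name of the experiment block to load when the file
#'   defines several (under `experiments:`); `NULL` takes the single
#'   `experiment:` block.
#' @return a [nav_experiment()].
#' @export
read_experiment_config <- function(path, experiment = NULL) {
  cfg <- yaml::read_yaml(path)
  lib <- shape_library()
  shapes <- lib
  if (!is.null(cfg$shapes))
    for (nm in names(cfg$shapes))
      shapes[[nm]] <- shape_from_config(cfg$shapes[[nm]], name = nm)
  exp_cfg <- if (!is.null(experiment)) cfg$experiments[[experiment]]
             else cfg$experiment %||% cfg$experiments[[1L]]
  if (is.null(exp_cfg)) stop("no experiment block found in ", path)
  get_shape <- function(nm) {
    if (is.null(shapes[[nm]])) stop("unknown shape '", nm, "'")
    shapes[[nm]]
  }
  arena_cfg <- cfg$arena %||% list()
  arena <- arena_config(
    radius = arena_cfg$radius %||% 1.5,
    feeder_distance = arena_cfg$feeder_distance %||% 0.6,
    feeder_azimuth = exp_cfg$feeder_azimuth %||% 0)
  tests <- lapply(exp_cfg$tests, get_shape)
  names(tests) <- unlist(exp_cfg$tests)
  nav_experiment(train = get_shape(exp_cfg$train), tests = tests,
                 feeder_azimuth = exp_cfg$feeder_azimuth %||% 0,
                 n_train = exp_cfg$n_train %||% 30, arena = arena,
                 true_modes = if (!is.null(exp_cfg$true_modes))
                   unlist(exp_cfg$true_modes),
                 name = experiment %||% exp_cfg$name)
}
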