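## Rotational novelty signals and the image-difference-function baseline.

#' Construct a rotational signal set from left/right novelties
#'
#' @param left,right numeric vectors of length 360, novelty per integer
#'   facing direction 0..359 (degrees right of the shape's left edge).
#' @return object of class `rotational_signals` with elements `direction`,
#'   `left`, `right`, `sum`, `diff` and scalars `s_min`, `s_max`,
#'   `abs_diff_max`.
#' @export
signal_set <- function(left, right) {
  stopifnot(length(left) == 360L, length(right) == 360L,
            all(is.finite(left)), all(is.finite(right)))
  s <- left + right
  d <- left - right
  structure(list(direction = 0:359, left = left, right = right,
                 sum = s, diff = d,
                 s_min = min(s), s_max = max(s), abs_diff_max = max(abs(d))),
            class = "rotational_signals")
}

#' @export
print.rotational_signals <- function(x, ...) {
  cat(sprintf(paste0("rotational signals over 360 directions: ",
                     "S in [%.4f, %.4f], |diff| max %.4g\n"),
              x$s_min, x$s_max, x$abs_diff_max))
  invisible(x)
}

#' Rotational novelty scan of a test shape
#'
#' Renders the test shape from a position (by default the arena centre, the
#' single test view), then forward-passes the view at each of the 360
#' integer facing directions through the network, yielding left novelty,
#' right novelty, their sum S and difference. Directions are measured from
#' the test shape's left edge (placed at world azimuth 0).
#'
#' @param conn a (trained or untrained) [build_connectome()] result.
#' @param test_shape a [shape_spec()].
#' @param arena an [arena_config()].
#' @param position test position (x, y) in metres.
#' @return a [signal_set()] object.
#' @export
rotational_signals <- function(conn, test_shape, arena = arena_config(),
                               position = c(0, 0)) {
  pano <- render_panorama(test_shape,
                          agent_pose(position[1], position[2], heading = 0),
                          arena)
  V <- direction_views(pano, conn$params$overlap)
  nov <- novelty_batch(conn, V)
  signal_set(nov[1, ], nov[2, ])
}

#' Ensemble of rotational signals over seeded model instances
#'
#' Builds, trains and tests `n_models` independently seeded model instances
#' on the same geometry, and returns per-direction means and standard
#' deviations of the four rotational signals. Training views (along the
#' feeder path) and test views are rendered once and shared across models.
#'
#' @param params an [mb_params()]; model i uses seed `params$seed + i - 1`.
#' @param train_shape,test_shape [shape_spec()] objects; `test_shape` may be
#'   a (named) list of shapes, in which case a list of ensembles sharing the
#'   same trained models is returned.
#' @param n_models number of model instances.
#' @param arena an [arena_config()] (its feeder fields define the path).
#' @param n_train number of training views.
#' @return object of class `ensemble_signals` (or named list of them): per
#'   direction `mean` and `sd` for `left`, `right`, `sum`, `diff`, plus
#'   `n_models`.
#' @export
ensemble_signals <- function(params, train_shape, test_shape, n_models = 50,
                             arena = arena_config(), n_train = 30) {
  stopifnot(n_models >= 1)
  single <- inherits(test_shape, "shape_spec")
  tests <- if (single) list(test = test_shape) else test_shape
  poses <- training_path_poses(arena, n_train)
  TV <- vapply(poses, function(po)
    as_vpn_vector(process_view(render_panorama(train_shape, po, arena),
                               params$overlap)),
    numeric(params$n_vpn))
  Vs <- lapply(tests, function(sh)
    direction_views(render_panorama(sh, agent_pose(heading = 0), arena),
                    params$overlap))
  base_seed <- params$seed %||% 1L
  acc <- lapply(Vs, function(.) list(L = matrix(0, 360, n_models),
                                     R = matrix(0, 360, n_models)))
  for (i in seq_len(n_models)) {
    pi <- params
    pi$seed <- base_seed + i - 1L
    conn <- train_network(build_connectome(pi), TV)
    for (t in seq_along(Vs)) {
      nov <- novelty_batch(conn, Vs[[t]])
      acc[[t]]$L[, i] <- nov[1, ]
      acc[[t]]$R[, i] <- nov[2, ]
    }
  }
  out <- lapply(acc, function(a) {
    S <- a$L + a$R
    D <- a$L - a$R
    structure(list(direction = 0:359,
                   mean = list(left = rowMeans(a$L), right = rowMeans(a$R),
                               sum = rowMeans(S), diff = rowMeans(D)),
                   sd = list(left = apply(a$L, 1, sd),
                             right = apply(a$R, 1, sd),
                             sum = apply(S, 1, sd),
                             diff = apply(D, 1, sd)),
                   n_models = n_models),
              class = "ensemble_signals")
  })
  if (single) out[[1]] else out
}

#' @export
print.ensemble_signals <- function(x, ...) {
  cat(sprintf("ensemble of %d models: mean diff range [%.4g, %.4g]\n",
              x$n_models, min(x$mean$diff), max(x$mean$diff)))
  invisible(x)
}

#' Mean signals of an ensemble as a signal set
#'
#' @param ens an [ensemble_signals()] result.
#' @return a [signal_set()] built from the ensemble means.
#' @export
mean_signal_set <- function(ens) signal_set(ens$mean$left, ens$mean$right)

#' Zero crossings of a rotational signal
#'
#' All directions where the sign of the (circular) length-360 signal flips,
#' located to sub-degree precision by linear interpolation between adjacent
#' integer directions; exact zeros are reported at their index. The wrap
#' between directions 359 and 0 is included.
#'
#' @param signal numeric vector of length 360.
#' @return sorted numeric vector of crossing directions in `[0, 360)`.
#' @export
find_zero_crossings <- function(signal) {
  x <- as.numeric(signal)
  stopifnot(length(x) == 360L, all(is.finite(x)))
  if (all(x == 0)) stop("signal is identically zero; crossings are degenerate")
  out <- numeric(0)
  for (d0 in 0:359) {
    s1 <- x[d0 + 1L]
    s2 <- x[(d0 + 1L) %% 360L + 1L]
    if (s1 == 0) {
      out <- c(out, d0)
    } else if (s2 != 0 && sign(s1) != sign(s2)) {
      out <- c(out, d0 + s1 / (s1 - s2))
    }
  }
  sort(unique(out))
}

## Group sorted integer degrees (0..359) into circularly contiguous runs.
circular_runs <- function(deg) {
  if (!length(deg)) return(list())
  deg <- sort(unique(as.integer(deg)))
  breaks <- which(diff(deg) > 1L)
  runs <- if (length(breaks))
    split(deg, rep(seq_len(length(breaks) + 1L),
                   times = diff(c(0L, breaks, length(deg)))))
  else list(deg)
  # merge wrap-around (… 359 | 0 …)
  if (length(runs) > 1L) {
    first <- runs[[1L]]
    last <- runs[[length(runs)]]
    if (first[1] == 0L && last[length(last)] == 359L) {
      runs[[1L]] <- c(last, first)
      runs[[length(runs)]] <- NULL
    }
  }
  unname(runs)
}

#' Rotational image difference function
#'
#' The classic snapshot-matching baseline: for each facing direction d, the
#' IDF is the minimum over stored training views of the root-mean-square
#' pixel difference between the processed test view at d and the stored
#' view. For test shapes smaller than the training shape the IDF flattens
#' over a wide angular interval, leaving the goal direction under-determined
#' — which is why the bilateral novelty difference is needed. The "minimal
#' set" collects all directions within `eps_frac` of the IDF's dynamic range
#' above its minimum, reported as circular interval(s).
#'
#' @param train_views list of processed views (or an n_vpn x n matrix) —
#'   the stored snapshots.
#' @param test_shape a [shape_spec()].
#' @param arena an [arena_config()].
#' @param overlap visual-field overlap at which views are processed.
#' @param eps_frac flatness tolerance as a fraction of the IDF range.
#' @return list with `direction` (0:359), `idf`, `minimal_set` (integer
#'   degrees) and `intervals` (list of contiguous runs).
#' @export
rotational_idf <- function(train_views, test_shape, arena = arena_config(),
                           overlap = 0, eps_frac = 0.01) {
  TV <- if (is.list(train_views))
    vapply(train_views, as_vpn_vector, numeric(1800L))
  else as.matrix(train_views)
  stopifnot(ncol(TV) >= 1L)
  V <- direction_views(render_panorama(test_shape, agent_pose(heading = 0),
                                       arena), overlap)
  cross <- crossprod(V, TV)                       # 360 x n_train
  d2 <- outer(colSums(V^2), colSums(TV^2), "+") - 2 * cross
  idf <- sqrt(pmax(apply(d2, 1, min), 0) / nrow(V))
  eps <- eps_frac * diff(range(idf))
  minimal <- which(idf <= min(idf) + eps) - 1L
  list(direction = 0:359, idf = idf, minimal_set = minimal,
       intervals = circular_runs(minimal))
}
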