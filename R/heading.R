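## Heading-distribution generation: rejection sampler, pooling, KDE modes,
## and distance-between-modes performance scoring.

#' Sampler configuration
#'
#' @param beta exponential decay of the acceptance probability; larger beta
#'   concentrates samples near the novelty-sum minimum and the
#'   novelty-difference zero. beta = 0 samples uniformly.
#' @param n_saccade accepted saccade endpoints per run.
#' @param hist_range display/binning range in degrees.
#' @param bin_width histogram bin width in degrees.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(beta = 4, n_saccade = 100,
                           hist_range = c(-70, 200), bin_width = 5,
                           seed = NULL) {
  stopifnot(beta >= 0, n_saccade >= 1, length(hist_range) == 2L,
            hist_range[2] > hist_range[1], bin_width > 0)
  structure(list(beta = beta, n_saccade = as.integer(n_saccade),
                 hist_range = hist_range, bin_width = bin_width, seed = seed),
            class = "sampler_config")
}

#' Acceptance probability of a tentative direction
#'
#' A direction with novelty sum S and novelty difference delta is accepted
#' with probability
#' `exp(-beta |S - S_min| / (S_max - S_min)) * exp(-beta |delta| / |delta|_max)`,
#' favouring directions where the overall memory match is good (low S) and
#' the left/right match quality is balanced (delta near 0). If the sum
#' signal is flat (`S_max = S_min`) or the difference is identically zero,
#' the corresponding factor is 1.
#'
#' @param S novelty sum value(s).
#' @param delta novelty difference value(s).
#' @param stats list (or [signal_set()]) with `s_min`, `s_max`,
#'   `abs_diff_max`.
#' @param beta decay parameter.
#' @return probability in (0, 1], vectorised over `S`/`delta`.
#' @export
acceptance_probability <- function(S, delta, stats, beta = 4) {
  f_s <- if (stats$s_max > stats$s_min)
    exp(-beta * abs(S - stats$s_min) / (stats$s_max - stats$s_min))
  else rep(1, length(S))
  f_d <- if (stats$abs_diff_max > 0)
    exp(-beta * abs(delta) / stats$abs_diff_max)
  else rep(1, length(delta))
  f_s * f_d
}

#' Sample saccade endpoints from rotational signals
#'
#' Rejection sampler: tentative directions are drawn continuously uniformly
#' on `[-180, 180)`, the signals are looked up at the nearest integer
#' degree, and the draw is accepted with [acceptance_probability()], until
#' `n_saccade` endpoints are accepted. Accepted angles are reported in the
#' 360-degree window centred on the midpoint of `hist_range` (so the
#' default range `[-70, 200]` lies inside it).
#'
#' @param signals a [signal_set()] (or [ensemble_signals()] means via
#'   [mean_signal_set()]).
#' @param cfg a [sampler_config()].
#' @return numeric vector of `n_saccade` accepted angles in degrees.
#' @export
sample_headings <- function(signals, cfg = sampler_config()) {
  stopifnot(inherits(signals, "rotational_signals"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_saccade
  out <- numeric(0)
  while (length(out) < n) {
    u <- runif(max(4L * n, 256L), -180, 180)
    d <- (round(u) %% 360) + 1L
    p <- acceptance_probability(signals$sum[d], signals$diff[d],
                                signals, cfg$beta)
    out <- c(out, u[runif(length(u)) < p])
  }
  out <- out[seq_len(n)]
  lo <- mean(cfg$hist_range) - 180
  ((out - lo) %% 360) + lo
}

#' Pooling configuration for the parameter grid
#'
#' The aggregate model behaviour is reported by pooling saccades over a grid
#' of crossover and overlap values (the parameters that can shift
#' zero-crossings), with alpha, K and p fixed at their defaults. For each
#' crossover value `n_repeat` models are initialised, and each model is
#' trained in turn at every overlap value, so the default grid gives
#' 5 x 50 x 6 = 1500 trained/tested runs and, at 100 saccades each, 150,000
#' pooled samples.
#'
#' @param crossover_grid,overlap_grid parameter grids.
#' @param n_repeat model initialisations per crossover value.
#' @param n_kc,k_mean,p_fire,alpha network parameters held fixed.
#' @param seed base seed for model construction.
#' @return object of class `pooling_config`.
#' @export
pooling_config <- function(crossover_grid = c(0, 0.1, 0.2, 0.3, 0.4),
                           overlap_grid = c(0, 8, 16, 24, 32, 40),
                           n_repeat = 50, n_kc = 25000L, k_mean = 8,
                           p_fire = 0.05, alpha = 0.95, seed = 1L) {
  stopifnot(length(crossover_grid) >= 1, length(overlap_grid) >= 1,
            n_repeat >= 1)
  structure(list(crossover_grid = crossover_grid,
                 overlap_grid = overlap_grid, n_repeat = as.integer(n_repeat),
                 n_kc = as.integer(n_kc), k_mean = k_mean, p_fire = p_fire,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pooling_config")
}

#' Pool heading distributions over the parameter grid
#'
#' Runs the full train/test/sample pipeline for one experiment and one test
#' shape over every (crossover, overlap) pair: for each crossover value,
#' `n_repeat` seeded connectomes are built, each is trained along the
#' feeder path at every overlap value, rotational signals are read from the
#' centre-of-arena test view, and `n_saccade` endpoints are sampled per run.
#' Per-run provenance (crossover, overlap, model) is retained so per-pair
#' subsets can be extracted for heatmaps.
#'
#' @param experiment a [nav_experiment()].
#' @param test_shape which test to use: a name/index into
#'   `experiment$tests`, or a [shape_spec()].
#' @param pool a [pooling_config()].
#' @param sampler a [sampler_config()] (its seed, default the pool seed,
#'   derives per-run sampling seeds).
#' @return object of class `pooled_headings`: `samples` (data.frame with
#'   columns crossover, overlap, model, angle), plus the configurations.
#' @export
pool_distributions <- function(experiment, test_shape = 1L,
                               pool = pooling_config(),
                               sampler = sampler_config()) {
  stopifnot(inherits(experiment, "nav_experiment"))
  if (!inherits(test_shape, "shape_spec"))
    test_shape <- experiment$tests[[test_shape]]
  arena <- experiment$arena
  poses <- training_path_poses(arena, experiment$n_train)
  train_panos <- lapply(poses, function(po)
    render_panorama(experiment$train, po, arena))
  test_pano <- render_panorama(test_shape, agent_pose(heading = 0), arena)
  n_ov <- length(pool$overlap_grid)
  TVs <- lapply(pool$overlap_grid, function(ov)
    vapply(train_panos, function(p) as_vpn_vector(process_view(p, ov)),
           numeric(1800L)))
  Vs <- lapply(pool$overlap_grid, function(ov) direction_views(test_pano, ov))
  samp_seed <- sampler$seed %||% pool$seed
  rows <- vector("list", length(pool$crossover_grid) * pool$n_repeat * n_ov)
  ri <- 0L
  for (ci in seq_along(pool$crossover_grid)) {
    for (m in seq_len(pool$n_repeat)) {
      run <- (ci - 1L) * pool$n_repeat + (m - 1L)
      params <- mb_params(n_kc = pool$n_kc, k_mean = pool$k_mean,
                          p_fire = pool$p_fire,
                          crossover = pool$crossover_grid[ci],
                          alpha = pool$alpha, seed = pool$seed + run)
      conn0 <- build_connectome(params)
      for (oi in seq_len(n_ov)) {
        conn0$params$overlap <- pool$overlap_grid[oi]
        conn <- train_network(conn0, TVs[[oi]])
        nov <- novelty_batch(conn, Vs[[oi]])
        sig <- signal_set(nov[1, ], nov[2, ])
        scfg <- sampler
        scfg$seed <- samp_seed + run * n_ov + oi
        ang <- sample_headings(sig, scfg)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(crossover = pool$crossover_grid[ci],
                                 overlap = pool$overlap_grid[oi],
                                 model = m, angle = ang)
      }
    }
  }
  structure(list(samples = do.call(rbind, rows), pool = pool,
                 sampler = sampler,
                 test = test_shape$name %||% "test"),
            class = "pooled_headings")
}

#' @export
print.pooled_headings <- function(x, ...) {
  cat(sprintf("pooled headings for '%s': %d samples over %d parameter pairs\n",
              x$test, nrow(x$samples),
              length(x$pool$crossover_grid) * length(x$pool$overlap_grid)))
  invisible(x)
}

#' Kernel-density modes of a heading distribution
#'
#' Gaussian KDE (bandwidth h, the kernel standard deviation) on the linear
#' angle axis, evaluated at `step`-degree intervals over `range`. A grid
#' point is a mode if the density strictly increases for 5 consecutive
#' degrees before it and strictly decreases for 5 after, which suppresses
#' duplicate optima from small-sample ripple.
#'
#' @param samples numeric vector of heading angles, degrees.
#' @param h KDE bandwidth in degrees.
#' @param range evaluation range.
#' @param step evaluation step in degrees.
#' @return list with `x`, `y` (the KDE curve) and `modes` (degrees).
#' @export
kde_modes <- function(samples, h = 5, range = c(-70, 200), step = 1) {
  stopifnot(length(samples) >= 1, all(is.finite(samples)))
  ngrid <- round(diff(range) / step) + 1L
  den <- density(samples, bw = h, from = range[1], to = range[2], n = ngrid)
  y <- den$y
  run <- 5L
  is_mode <- vapply((run + 1L):(ngrid - run), function(i) {
    all(diff(y[(i - run):i]) > 0) && all(diff(y[i:(i + run)]) < 0)
  }, TRUE)
  list(x = den$x, y = y,
       modes = den$x[(run + 1L):(ngrid - run)][is_mode])
}

#' Distance between modes
#'
#' Minimum absolute angular distance between the modes of a simulated
#' distribution and the reference (true) mode.
#'
#' @param modes numeric vector of simulated mode directions, degrees.
#' @param true_mode reference mode direction, degrees.
#' @return DBM in degrees.
#' @export
dbm <- function(modes, true_mode) {
  stopifnot(length(modes) >= 1, length(true_mode) == 1L)
  min(abs(modes - true_mode))
}

#' Performance over a set of experiments
#'
#' For each experiment the DBM is averaged over `n_iter` fresh Monte-Carlo
#' realisations of the distribution (the rotational signals stay fixed;
#' only the saccade sampling is repeated), and the MAE is the mean DBM over
#' experiments. Reference modes must be supplied by the user (for the
#' original behavioural data they are not part of this package).
#'
#' @param experiments list whose elements are either a function
#'   `function(seed)` returning a sample vector, or a fixed numeric sample
#'   vector (then used unchanged in every iteration).
#' @param true_modes numeric vector, one reference mode per experiment.
#' @param n_iter repetitions to average over.
#' @param h KDE bandwidth for mode extraction.
#' @param base_seed seed from which per-iteration seeds are derived.
#' @return list with `dbm` (per experiment), `mae`, and the `n_iter x N`
#'   matrix of per-iteration DBMs.
#' @export
distribution_performance <- function(experiments, true_modes, n_iter = 10,
                                     h = 5, base_seed = 1L) {
  N <- length(experiments)
  stopifnot(N >= 1, length(true_modes) == N, n_iter >= 1)
  D <- matrix(NA_real_, n_iter, N)
  for (j in seq_len(n_iter)) {
    for (i in seq_len(N)) {
      e <- experiments[[i]]
      smp <- if (is.function(e)) e(base_seed + (j - 1L) * N + i) else e
      modes <- kde_modes(smp, h = h)$modes
      if (!length(modes)) stop("no modes found for experiment ", i)
      D[j, i] <- dbm(modes, true_modes[i])
    }
  }
  per <- colMeans(D)
  list(dbm = per, mae = mean(per), per_iter = D)
}
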