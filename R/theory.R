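## Numerical verification of the analytical chain: FPM alignment <=> equal
## bilateral covering fractions <=> equal conditional KC firing
## probabilities <=> balanced left/right novelties.

#' FPM-alignment / covering-fraction identity
#'
#' For a test shape nested inside a training shape, split by the visual
#' midline into train-left area X, train-right area W, test-left area Y and
#' test-right area Z: the two views are aligned at the same FPM exactly when
#' X/W = Y/Z, which rearranges into equal covering fractions
#' `gamma_L = Y/X = Z/W = gamma_R` — the proportion of the trained pattern
#' covered by the test pattern is the same in both hemispheres.
#'
#' @param X,W train-left and train-right areas (> 0).
#' @param Y,Z test-left and test-right areas (>= 0, nested: Y <= X, Z <= W).
#' @param tol alignment tolerance.
#' @return list with `gamma_l`, `gamma_r` and logical `aligned`.
#' @export
fpm_balance_identity <- function(X, W, Y, Z, tol = 1e-12) {
  stopifnot(X > 0, W > 0, Y >= 0, Z >= 0)
  gl <- Y / X
  gr <- Z / W
  # X/W = Y/Z and Y/X = Z/W share the cross product X*Z - W*Y
  cross_gap <- abs(X * Z - W * Y)
  scale <- max(abs(X * Z), abs(W * Y), 1)
  list(gamma_l = gl, gamma_r = gr, aligned = cross_gap <= tol * scale)
}

#' Closed-form expected novelty after a single training exposure
#'
#' With constant weight initialisation and training on exactly one view,
#' every KC that fired has its output weight depreciated once, so the
#' novelty of any test view is a linear function of the firing-set
#' intersection I between train and test:
#' `novelty = 1 - I (1 - alpha) / (p n_kc)` — intercept A = 1 and slope
#' B = (1 - alpha)/(p n_kc) of the general linear law
#' `E[novelty] = A - B E[|KC_test intersect KC_train|]`.
#'
#' @param alpha depreciation factor.
#' @param p KC firing proportion.
#' @param n_kc KCs per hemisphere.
#' @param intersection firing-set intersection size I, in
#'   `[0, round(p n_kc)]`.
#' @return expected novelty.
#' @export
closed_form_novelty <- function(alpha, p, n_kc, intersection) {
  k <- round(p * n_kc)
  stopifnot(alpha > 0, alpha <= 1, all(intersection >= 0),
            all(intersection <= k))
  1 - intersection * (1 - alpha) / (p * n_kc)
}

#' Nested bar patterns in vPN space
#'
#' Constructs train/test vPN activity patterns with exactly controlled
#' covering fractions, bypassing arena rendering: in each hemisphere the
#' train pattern activates a leading block of vPNs and the test pattern a
#' nested sub-block whose size is the covering fraction gamma times the
#' train block.
#'
#' @param n_vpn total vPN count (even; halves are the hemifields).
#' @param gamma_l,gamma_r covering fractions in `[0, 1]`.
#' @param train_frac_l,train_frac_r fraction of each hemifield activated by
#'   the train pattern.
#' @return list with binary vectors `train`, `test` and the block sizes
#'   `X`, `W`, `Y`, `Z`.
#' @export
nested_bar_patterns <- function(n_vpn, gamma_l, gamma_r,
                                train_frac_l = 0.5, train_frac_r = 0.5) {
  stopifnot(n_vpn %% 2 == 0, gamma_l >= 0, gamma_l <= 1,
            gamma_r >= 0, gamma_r <= 1)
  half <- n_vpn %/% 2L
  X <- round(train_frac_l * half)
  W <- round(train_frac_r * half)
  Y <- round(gamma_l * X)
  Z <- round(gamma_r * W)
  train <- numeric(n_vpn)
  test <- numeric(n_vpn)
  train[seq_len(X)] <- 1
  train[half + seq_len(W)] <- 1
  if (Y > 0) test[seq_len(Y)] <- 1
  if (Z > 0) test[half + seq_len(Z)] <- 1
  list(train = train, test = test, X = X, W = W, Y = Y, Z = Z)
}

#' Monte-Carlo conditional KC firing probabilities
#'
#' Estimates, over independently seeded connectomes, the probability that a
#' Kenyon cell fires on the test pattern given that it fired on the train
#' pattern, per hemisphere. Because a KC's connections into the train
#' firing vPN set are homogeneously distributed, each such connection lands
#' in the nested test set with probability equal to the covering fraction
#' gamma, so equal left/right gammas balance the conditional probabilities
#' — and with them the novelties. Random vPN->KC weights are recommended
#' for this oracle so that binary bar patterns do not produce massive input
#' ties.
#'
#' @param params an [mb_params()] for a small network (the theory setting
#'   uses `crossover = 0`, `overlap = 0`).
#' @param train_pattern,test_pattern vPN activity vectors (length
#'   `params$n_vpn`), e.g. from [nested_bar_patterns()].
#' @param n_nets number of seeded connectomes.
#' @return list per hemisphere (`L`, `R`): estimate `p`, binomial standard
#'   error `se`, and conditioning event count `n`.
#' @export
conditional_probability_mc <- function(params, train_pattern, test_pattern,
                                       n_nets = 200) {
  stopifnot(inherits(params, "mb_params"),
            length(train_pattern) == params$n_vpn,
            length(test_pattern) == params$n_vpn, n_nets >= 1)
  base_seed <- params$seed %||% 1L
  events <- c(L = 0, R = 0)
  succ <- c(L = 0, R = 0)
  for (i in seq_len(n_nets)) {
    pi <- params
    pi$seed <- base_seed + i - 1L
    conn <- build_connectome(pi)
    for (h in c("L", "R")) {
      f_tr <- apl_select(as.numeric(conn$W[[h]] %*% train_pattern),
                         params$p_fire)
      f_te <- apl_select(as.numeric(conn$W[[h]] %*% test_pattern),
                         params$p_fire)
      events[h] <- events[h] + length(f_tr)
      succ[h] <- succ[h] + length(intersect(f_tr, f_te))
    }
  }
  if (any(events < 10))
    stop("fewer than 10 conditioning events; enlarge the network or n_nets")
  out <- lapply(c(L = "L", R = "R"), function(h) {
    p <- succ[[h]] / events[[h]]
    list(p = p, se = sqrt(p * (1 - p) / events[[h]]), n = events[[h]])
  })
  out
}
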