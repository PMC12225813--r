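#' Network parameters
#'
#' Parameters of the bilateral Mushroom-Body model. Defaults are the model's
#' standard operating point: 25,000 Kenyon cells (KCs) per hemisphere, a mean
#' of K = 8 visual projection neuron (vPN) inputs per KC, APL-enforced firing
#' proportion p = 0.05, ipsilateral connection bias 1 - crossover = 0.8, no
#' visual-field overlap, and learning rate alpha = 0.95.
#'
#' @param n_kc Kenyon cells per hemisphere.
#' @param k_mean mean number of vPN inputs per KC.
#' @param p_fire proportion of KCs allowed to fire per hemisphere (0, 1].
#' @param crossover probability that a vPN->KC connection targets the
#'   contralateral Mushroom Body, in `[0, 1]`.
#' @param overlap frontal visual-field overlap in degrees.
#' @param alpha anti-Hebbian depreciation factor in (0, 1]; each time a KC
#'   fires during training its output weight is multiplied by alpha.
#' @param weight_init `"constant"` (vPN->KC weights 1/K, KC->MBON weights
#'   1/(p n_kc)), `"random_pn"` (vPN->KC uniform on `[0, 2/K]`),
#'   `"random_out"` (KC->MBON uniform on `[0, 2/(p n_kc)]`) or
#'   `"random_both"`. Random ranges keep the mean weights equal to the
#'   constant values.
#' @param n_vpn total number of vPNs (left + right fields).
#' @param seed integer seed for connectome construction; `NULL` leaves the
#'   RNG state untouched.
#' @return an object of class `mb_params`.
#' @export
mb_params <- function(n_kc = 25000L, k_mean = 8, p_fire = 0.05,
                      crossover = 0.2, overlap = 0, alpha = 0.95,
                      weight_init = c("constant", "random_pn", "random_out",
                                      "random_both"),
                      n_vpn = 1800L, seed = NULL) {
  weight_init <- match.arg(weight_init)
  stopifnot(n_kc >= 1, k_mean > 0, p_fire > 0, p_fire <= 1,
            crossover >= 0, crossover <= 1, alpha > 0, alpha <= 1,
            overlap >= 0, overlap < 180, n_vpn >= 2, n_vpn %% 2 == 0)
  structure(list(n_kc = as.integer(n_kc), k_mean = k_mean, p_fire = p_fire,
                 crossover = crossover, overlap = overlap, alpha = alpha,
                 weight_init = weight_init, n_vpn = as.integer(n_vpn),
                 seed = seed),
            class = "mb_params")
}

#' Build the bilateral connectome
#'
#' Random sparse vPN->KC connectivity with an ipsilateral bias. Each vPN
#' emits `round(2 K n_kc / n_vpn)` connections (so KCs receive K inputs on
#' average across the 2 n_kc cells); each connection targets the ipsilateral
#' Mushroom Body with probability `1 - crossover` and the contralateral one
#' with probability `crossover`, with the KC index uniform within the chosen
#' hemisphere. Connections are sampled with replacement; coincident
#' (vPN, KC) pairs merge additively. RNG consumption order (from `seed`):
#' crossover draws, then KC targets, then vPN->KC weights, then left and
#' right KC->MBON weights — so connectomes are reproducible and identical
#' across alpha/p scans at a fixed seed.
#'
#' @param params an [mb_params()].
#' @return an object of class `mb_connectome`: sparse per-hemisphere weight
#'   matrices `W$L`, `W$R` (n_kc x n_vpn), KC->MBON weight vectors
#'   `w_out$L/R`, per-KC training fire counts `n_tot$L/R`, and `params`.
#' @export
build_connectome <- function(params = mb_params()) {
  stopifnot(inherits(params, "mb_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n_vpn <- params$n_vpn
  n_kc <- params$n_kc
  n_out <- as.integer(round(2 * params$k_mean * n_kc / n_vpn))
  if (n_out < 1) stop("per-vPN connection count rounds to zero; increase k_mean or n_kc")
  n_edges <- n_vpn * n_out
  vpn <- rep(seq_len(n_vpn), each = n_out)
  vpn_left <- vpn <= n_vpn %/% 2L
  cross <- runif(n_edges) < params$crossover
  tgt_left <- xor(vpn_left, cross)
  kc <- sample.int(n_kc, n_edges, replace = TRUE)
  w <- if (params$weight_init %in% c("random_pn", "random_both"))
    runif(n_edges, 0, 2 / params$k_mean)
  else
    rep(1 / params$k_mean, n_edges)
  W <- list(
    L = Matrix::sparseMatrix(i = kc[tgt_left], j = vpn[tgt_left],
                             x = w[tgt_left], dims = c(n_kc, n_vpn)),
    R = Matrix::sparseMatrix(i = kc[!tgt_left], j = vpn[!tgt_left],
                             x = w[!tgt_left], dims = c(n_kc, n_vpn)))
  w0 <- 1 / (params$p_fire * n_kc)
  rand_out <- params$weight_init %in% c("random_out", "random_both")
  w_out <- list(
    L = if (rand_out) runif(n_kc, 0, 2 * w0) else rep(w0, n_kc),
    R = if (rand_out) runif(n_kc, 0, 2 * w0) else rep(w0, n_kc))
  structure(list(W = W, w_out = w_out,
                 n_tot = list(L = integer(n_kc), R = integer(n_kc)),
                 n_edges = n_edges, params = params),
            class = "mb_connectome")
}

#' @export
print.mb_connectome <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("bilateral MB connectome: %d KCs/hemisphere, %d vPNs, ",
                     "%d connections (mean in-degree %.2f)\n"),
              p$n_kc, p$n_vpn, x$n_edges, x$n_edges / (2 * p$n_kc)))
  cat(sprintf("  crossover %.2f, overlap %g deg, alpha %.2f, p %.3f, init %s\n",
              p$crossover, p$overlap, p$alpha, p$p_fire, p$weight_init))
  cat(sprintf("  training exposures so far: %d\n", sum(x$n_tot$L) + sum(x$n_tot$R)))
  invisible(x)
}

## Indices of the top-k entries of x, ties at the threshold broken by
## ascending index, entries equal to zero excluded.
top_k_positive <- function(x, k) {
  n <- length(x)
  if (k <= 0) return(integer(0))
  if (k >= n) {
    fire <- seq_len(n)
  } else {
    thr <- sort(x, partial = n - k + 1)[n - k + 1]
    above <- which(x > thr)
    m <- k - length(above)
    fire <- if (m > 0) sort(c(above, which(x == thr)[seq_len(m)])) else sort(above)
  }
  fire[x[fire] > 0]
}

#' APL-gated Kenyon-cell selection
#'
#' The anterior paired lateral neuron normalises Mushroom-Body activity:
#' within one hemisphere only the `round(p_fire * n_kc)` KCs with the
#' strongest summed input fire (binary output 1). Ties at the threshold are
#' broken by ascending KC index; cells with zero input never fire, so blank
#' scenes silence the hemisphere.
#'
#' @param kc_input numeric vector of summed KC inputs for one hemisphere.
#' @param p_fire firing proportion.
#' @return sorted integer indices of the firing KCs.
#' @export
apl_select <- function(kc_input, p_fire) {
  stopifnot(all(is.finite(kc_input)), all(kc_input >= 0),
            p_fire > 0, p_fire <= 1)
  top_k_positive(kc_input, round(p_fire * length(kc_input)))
}

## Trained KC->MBON weights: initial x alpha^n_tot.
trained_weights <- function(conn, hemi) {
  conn$w_out[[hemi]] * conn$params$alpha^conn$n_tot[[hemi]]
}

check_view_overlap <- function(conn, view) {
  ov <- attr(view, "overlap")
  if (!is.null(ov) && ov != conn$params$overlap)
    stop(sprintf("view processed at overlap %g but connectome uses %g",
                 ov, conn$params$overlap))
}

as_vpn_matrix <- function(conn, views) {
  if (is.list(views)) {
    for (v in views) check_view_overlap(conn, v)
    views <- vapply(views, function(v)
      if (is.matrix(v) && nrow(v) == 20L) as_vpn_vector(v) else as.numeric(v),
      numeric(conn$params$n_vpn))
  } else if (is.matrix(views) && nrow(views) == 20L && ncol(views) == 90L) {
    check_view_overlap(conn, views)
    views <- matrix(as_vpn_vector(views), ncol = 1)
  } else {
    views <- as.matrix(views)
  }
  stopifnot(nrow(views) == conn$params$n_vpn)
  views
}

#' Train the network along a sequence of views
#'
#' Anti-Hebbian learning on the KC->MBON synapses only: for each view in
#' order, KC inputs are computed as weighted sums of vPN activities, the APL
#' selects the firing set, and the fire count `n_tot` of each firing KC is
#' incremented. The trained output weight of a KC is its initial weight
#' times `alpha^n_tot`; vPN->KC weights are untouched. Returns a new
#' connectome (the input is not modified).
#'
#' @param conn an [build_connectome()] result.
#' @param views a list of processed views (20 x 90, see [process_view()]),
#'   a single processed view, or an n_vpn x n matrix of vPN activity columns.
#'   Views must be processed at the connectome's overlap.
#' @return the trained `mb_connectome`.
#' @export
train_network <- function(conn, views) {
  stopifnot(inherits(conn, "mb_connectome"))
  V <- as_vpn_matrix(conn, views)
  p <- conn$params$p_fire
  for (h in c("L", "R")) {
    IN <- .kc_input_cpp(conn$W[[h]], V)
    for (j in seq_len(ncol(V))) {
      fire <- apl_select(IN[, j], p)
      conn$n_tot[[h]][fire] <- conn$n_tot[[h]][fire] + 1L
    }
  }
  conn
}

#' Left and right novelty of a view
#'
#' Forward pass without learning: KC inputs, APL selection, then each MBON
#' sums the (depreciated) output weights of its hemisphere's firing KCs.
#' Low output means familiar. An untrained constant-initialisation network
#' returns exactly 1 per hemisphere for any view that drives a full firing
#' set.
#'
#' @inheritParams train_network
#' @param view a processed view (20 x 90) or vPN activity vector.
#' @return named numeric vector `c(left = , right = )`.
#' @export
mbon_novelty <- function(conn, view) {
  nov <- novelty_batch(conn, as_vpn_matrix(conn, view))
  c(left = nov[1, 1], right = nov[2, 1])
}

## Batched forward pass: V is n_vpn x m; returns 2 x m matrix (left, right).
## The sparse input summation and APL readout run in compiled code with the
## same semantics as apl_select().
novelty_batch <- function(conn, V) {
  k <- round(conn$params$p_fire * conn$params$n_kc)
  out <- matrix(0, 2L, ncol(V))
  for (hi in 1:2) {
    h <- c("L", "R")[hi]
    IN <- .kc_input_cpp(conn$W[[h]], V)
    out[hi, ] <- .apl_novelty_cols_cpp(IN, trained_weights(conn, h), k)
  }
  out
}

#' Firing Kenyon-cell sets for a view
#'
#' @inheritParams mbon_novelty
#' @return list with sorted firing KC indices `L` and `R`.
#' @export
kc_firing_sets <- function(conn, view) {
  V <- as_vpn_matrix(conn, view)
  p <- conn$params$p_fire
  list(L = apl_select(.kc_input_cpp(conn$W$L, V)[, 1], p),
       R = apl_select(.kc_input_cpp(conn$W$R, V)[, 1], p))
}
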