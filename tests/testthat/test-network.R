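test_that("connectome edge counts follow the out-degree rule", {
  conn <- default_connectome()
  # 1800 vPNs x round(2*8*25000/1800) = 222 edges each
  expect_identical(conn$n_edges, 1800L * 222L)
  expect_equal(conn$n_edges / (2 * 25000), 8, tolerance = 0.01)
  expect_identical(nrow(conn$W$L), 25000L)
  expect_identical(nrow(conn$W$R), 25000L)
})

test_that("crossover routes edges between hemispheres", {
  ipsi <- build_connectome(small_params(crossover = 0))
  # all left-field vPN (columns 1:900) edges stay in the left MB
  expect_equal(sum(ipsi$W$L[, 901:1800]), 0)
  expect_equal(sum(ipsi$W$R[, 1:900]), 0)
  expect_gt(sum(ipsi$W$L[, 1:900]), 0)
  contra <- build_connectome(small_params(crossover = 1))
  expect_equal(sum(contra$W$L[, 1:900]), 0)
  expect_equal(sum(contra$W$R[, 901:1800]), 0)
})

test_that("constant initialisation sets the weights the normalisation requires", {
  conn <- default_connectome()
  # vPN->KC weights are 1/K = 0.125 (coincident picks merge additively)
  x <- conn$W$L@x
  expect_true(all(abs(x / 0.125 - round(x / 0.125)) < 1e-12))
  expect_gt(mean(abs(x - 0.125) < 1e-12), 0.99)
  # KC->MBON weights are 1/(p N_KC)
  expect_true(all(conn$w_out$L == 1 / (0.05 * 25000)))
  # random modes keep the mean at the constant value
  rnd <- build_connectome(small_params(weight_init = "random_both"))
  expect_equal(mean(c(rnd$W$L@x, rnd$W$R@x)), 1 / 8, tolerance = 0.05)
  expect_equal(mean(rnd$w_out$L), 1 / (0.05 * 2000), tolerance = 0.05)
})

test_that("APL selection takes the top p fraction, index ties, no zero firing", {
  set.seed(11)
  x <- runif(25000)
  f <- apl_select(x, 0.05)
  expect_length(f, 1250)
  expect_gte(min(x[f]), max(x[-f]))
  expect_identical(apl_select(numeric(100), 0.1), integer(0))
  # all-equal positive inputs: lowest indices fire
  expect_identical(apl_select(rep(2, 25000), 0.05), 1:1250)
  # partial zero input reduces the firing set
  y <- c(rep(0, 90), rep(1, 10))
  expect_identical(apl_select(y, 0.2), 91:100)
})

test_that("anti-Hebbian training depreciates output weights as alpha^n_tot", {
  conn <- build_connectome(small_params())
  v <- process_view(centre_pano("rect_160x38"), 0)
  expect_equal(unname(mbon_novelty(conn, v)), c(1, 1))
  # three exposures to the same view: novelty drops to alpha^3 exactly
  conn3 <- train_network(conn, list(v, v, v))
  expect_equal(unname(mbon_novelty(conn3, v)), rep(0.95^3, 2),
               tolerance = 1e-12)
  expect_equal(max(conn3$n_tot$L), 3L)
  # one exposure: alpha itself
  conn1 <- train_network(conn, v)
  expect_equal(unname(mbon_novelty(conn1, v)), c(0.95, 0.95),
               tolerance = 1e-12)
  # alpha = 1 leaves the network unchanged
  cid <- train_network(build_connectome(small_params(alpha = 1)), v)
  expect_equal(unname(mbon_novelty(cid, v)), c(1, 1))
  # vPN->KC weights untouched by training
  expect_identical(conn3$W$L@x, conn$W$L@x)
})

test_that("novelty of a fixed view never increases as training accumulates", {
  conn <- build_connectome(small_params())
  views <- lapply(seq(0, 120, by = 30), function(d)
    process_view(rotate_panorama(centre_pano("rect_160x38"), d), 0))
  probe <- process_view(centre_pano("trapezoid_80"), 0)
  nov <- unname(mbon_novelty(conn, probe))
  for (v in views) {
    conn <- train_network(conn, v)
    nxt <- unname(mbon_novelty(conn, probe))
    expect_true(all(nxt <= nov + 1e-12))
    nov <- nxt
  }
})

test_that("blank scenes silence both MBONs", {
  conn <- build_connectome(small_params())
  blank <- matrix(0, 20, 90)
  expect_equal(unname(mbon_novelty(conn, blank)), c(0, 0))
})

test_that("identical seeds give bit-identical connectomes and novelties", {
  a <- build_connectome(small_params(seed = 7))
  b <- build_connectome(small_params(seed = 7))
  expect_identical(a$W$L@x, b$W$L@x)
  expect_identical(a$W$L@i, b$W$L@i)
  expect_identical(a$W$R@x, b$W$R@x)
  expect_identical(a$w_out, b$w_out)
  v <- process_view(centre_pano("rect_80x38"), 0)
  expect_identical(mbon_novelty(a, v), mbon_novelty(b, v))
})

test_that("views processed at the wrong overlap are rejected", {
  conn <- build_connectome(small_params(overlap = 8))
  v <- process_view(centre_pano("rect_160x38"), 0)
  expect_error(train_network(conn, v), "overlap")
  expect_error(mbon_novelty(conn, v), "overlap")
})
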