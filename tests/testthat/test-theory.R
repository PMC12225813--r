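test_that("FPM alignment is equivalent to equal covering fractions", {
  r <- fpm_balance_identity(40, 120, 20, 60)
  expect_equal(r$gamma_l, 0.5)
  expect_equal(r$gamma_r, 0.5)
  expect_true(r$aligned)
  r2 <- fpm_balance_identity(7, 7, 3, 3)
  expect_true(r2$aligned)
  expect_equal(r2$gamma_l, 3 / 7)
  r3 <- fpm_balance_identity(40, 120, 30, 60)
  expect_false(r3$aligned)
  expect_equal(r3$gamma_l, 0.75)
  expect_equal(r3$gamma_r, 0.5)
  expect_error(fpm_balance_identity(0, 1, 0, 0))
})

test_that("closed-form novelty is linear in the firing-set intersection", {
  expect_equal(closed_form_novelty(0.95, 0.05, 25000, 1250), 0.95)
  expect_equal(closed_form_novelty(0.95, 0.05, 25000, 0), 1)
  expect_equal(closed_form_novelty(0.95, 0.05, 25000, 625), 0.975)
  expect_error(closed_form_novelty(0.95, 0.05, 25000, 1251))
  expect_error(closed_form_novelty(0.95, 0.05, 25000, -1))
})

test_that("forward pass matches the closed form exactly after one exposure", {
  # random-vPN-weight, constant-output-weight network; random greyscale
  # patterns in place of rendered views isolate the linear law
  params <- mb_params(n_kc = 1000L, k_mean = 4, p_fire = 0.1, n_vpn = 100L,
                      crossover = 0.1, weight_init = "random_pn", seed = 21)
  conn <- build_connectome(params)
  set.seed(22)
  for (rep in 1:10) {
    u <- runif(100)
    v <- runif(100)
    trained <- train_network(conn, u)
    fu <- kc_firing_sets(conn, u)
    fv <- kc_firing_sets(conn, v)
    nov <- mbon_novelty(trained, v)
    for (h in 1:2) {
      I <- length(intersect(fu[[h]], fv[[h]]))
      expect_equal(unname(nov[h]),
                   closed_form_novelty(0.95, 0.1, 1000, I),
                   tolerance = 1e-12)
    }
  }
})

test_that("conditional firing probabilities balance at equal covering fractions", {
  params <- mb_params(n_kc = 2000L, k_mean = 4, p_fire = 0.1, n_vpn = 40L,
                      crossover = 0, weight_init = "random_pn", seed = 101)
  # test = train: conditioning set fires again with certainty
  pat1 <- nested_bar_patterns(40, 1, 1)
  r1 <- conditional_probability_mc(params, pat1$train, pat1$test, n_nets = 20)
  expect_equal(r1$L$p, 1)
  expect_equal(r1$R$p, 1)
  # balanced gammas: left and right conditional probabilities agree
  pat <- nested_bar_patterns(40, 0.5, 0.5)
  r <- conditional_probability_mc(params, pat$train, pat$test, n_nets = 200)
  se <- sqrt(r$L$se^2 + r$R$se^2)
  expect_lt(abs(r$L$p - r$R$p), 3 * se)
  # unbalanced gammas separate the hemispheres
  patu <- nested_bar_patterns(40, 0.75, 0.25)
  ru <- conditional_probability_mc(params, patu$train, patu$test,
                                   n_nets = 200)
  seu <- sqrt(ru$L$se^2 + ru$R$se^2)
  expect_gt(ru$L$p - ru$R$p, 3 * seu)
})

test_that("conditional firing probability increases with the covering fraction", {
  params <- mb_params(n_kc = 2000L, k_mean = 4, p_fire = 0.1, n_vpn = 40L,
                      crossover = 0, weight_init = "random_pn", seed = 55)
  p_hat <- se_hat <- numeric(0)
  for (g in c(0.25, 0.5, 0.75, 1)) {
    pat <- nested_bar_patterns(40, g, g)
    r <- conditional_probability_mc(params, pat$train, pat$test,
                                    n_nets = 100)
    p_hat <- c(p_hat, r$L$p)
    se_hat <- c(se_hat, r$L$se)
  }
  expect_true(all(diff(p_hat) > -2 * se_hat[-1]))
  expect_gt(p_hat[4], p_hat[1])
})
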