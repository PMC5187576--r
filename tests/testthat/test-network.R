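test_that("configuration validation rejects impossible circuits", {
  expect_error(network_config("robot", n_gc = 0), "positive")
  expect_error(network_config("robot", gamma = 0), "gamma")
  expect_error(network_config("robot", n_gc = 10),
               "exceeds its presynaptic population")
  expect_error(network_config("motor",
                              convergence = list(mf_gc = 6, go_gc = 3,
                                                 pf_go = 150, pf_ba = 50)),
               "exceeds")
  cfg <- network_config("robot")
  expect_identical(cfg$n_mf, 7L)
  expect_identical(network_config("motor")$n_mf, 5L)
  expect_identical(cfg$n_gc, 755L)
})

test_that("masks honour the configured convergence for every projection and seed", {
  cfg <- network_config("robot")
  for (seed in c(1L, 42L, 99991L)) {
    masks <- build_connectivity(cfg, seed)
    expect_true(all(colSums(masks$m_mf_gc) == 4))
    expect_true(all(colSums(masks$m_go_gc) == 3))
    expect_true(all(colSums(masks$m_pf_go) == 150))
    expect_true(all(colSums(masks$m_pf_ba) == 50))
    expect_true(all(masks$m_mf_go == 1))      # full MF->GO connectivity
    expect_true(all(masks$m_mf_gc %in% c(0, 1)))
  }
  expect_equal(sum(build_connectivity(cfg, 7L)$m_pf_go), 750)
})

test_that("a one-fiber projection forces an all-ones mask", {
  cfg <- network_config("motor", n_mf = 1L,
                        convergence = list(mf_gc = 1L, go_gc = 3L,
                                           pf_go = 150L, pf_ba = 50L))
  masks <- build_connectivity(cfg, 3L)
  expect_true(all(masks$m_mf_gc == 1))
  expect_identical(dim(masks$m_mf_gc), c(1L, 755L))
})

test_that("connectivity and weights are reproducible under a fixed seed", {
  cfg <- network_config("robot")
  m1 <- build_connectivity(cfg, 11L)
  m2 <- build_connectivity(cfg, 11L)
  expect_identical(m1, m2)
  expect_false(identical(m1, build_connectivity(cfg, 12L)))
  w1 <- initialize_weights(cfg, m1, 5L)
  w2 <- initialize_weights(cfg, m1, 5L)
  expect_identical(w1, w2)
})

test_that("initial weights respect the excitatory and inhibitory ranges", {
  cfg <- network_config("robot")
  masks <- build_connectivity(cfg, 2L)
  w <- initialize_weights(cfg, masks, 2L)
  for (nm in c("w_mf_gc", "w_mf_go", "w_pf_go", "w_pf_ba")) {
    nz <- w[[nm]][w[[nm]] != 0]
    expect_true(all(nz > 0 & nz <= 1), info = nm)
  }
  nz <- w$w_go_gc[w$w_go_gc != 0]
  expect_true(all(nz > -1 & nz < 0))
  expect_true(all(w$w_ba_pc > -1 & w$w_ba_pc < 0))
  expect_true(all(w$w_pf_pc > 0 & w$w_pf_pc <= 1))
  # masked-out entries are exactly zero
  expect_true(all(w$w_mf_gc[masks$m_mf_gc == 0] == 0))
})

test_that("truncated-normal excitatory law has mean 0.5 by symmetry", {
  set.seed(404)
  x <- flocculus:::rtrunc_norm(1e5, 0.5, 0, 1)
  expect_true(all(x > 0 & x <= 1))
  expect_lt(abs(mean(x) - 0.5), 0.005)
})

test_that("sigmoidal activation matches its closed form", {
  expect_equal(sigmoid_rate(0.5), 0.5)
  expect_equal(sigmoid_rate(0), 1 / (1 + exp(4)))
  expect_equal(sigmoid_rate(0), 0.017986, tolerance = 1e-4)
  expect_equal(sigmoid_rate(1), 0.982014, tolerance = 1e-4)
  expect_equal(sigmoid_rate(c(0.25, 0.75), sigma = 4, mu = 0.25),
               c(0.5, 1 / (1 + exp(-2))))
})

test_that("network_step reproduces a hand-computed toy evaluation", {
  for (seed in 1:10) {
    toy <- random_toy(seed)
    set.seed(seed + 100)
    y_mf <- runif(toy$config$n_mf, 0.05, 0.95)
    st <- network_state(toy$config)
    st$y_go_prev <- runif(toy$config$n_go, 0.05, 0.95)
    want <- oracle_step(y_mf, st$y_go_prev, toy$masks, toy$weights)
    got <- network_step(st, toy$weights, toy$masks, y_mf, toy$config)
    expect_equal(got$y_pf, want$y_pf, tolerance = 1e-12)
    expect_equal(got$y_go, want$y_go, tolerance = 1e-12)
    expect_equal(got$y_ba, want$y_ba, tolerance = 1e-12)
    expect_equal(got$y_pc, want$y_pc, tolerance = 1e-12)
    # current Golgi rates become the next sample's feedback
    expect_identical(got$y_go_prev, got$y_go)
  }
})

test_that("rate bounds hold after any step on finite input", {
  toy <- random_toy(3, n_mf = 4L, n_gc = 5L, n_go = 2L, n_ba = 3L)
  st <- network_state(toy$config)
  set.seed(77)
  for (k in 1:50) {
    y_mf <- runif(4, 0, 1)
    st <- network_step(st, toy$weights, toy$masks, y_mf, toy$config)
    expect_true(all(st$y_pf > 0 & st$y_pf < 1))
    expect_true(all(st$y_go > 0 & st$y_go < 1))
    expect_true(all(st$y_ba > 0 & st$y_ba < 1))
    expect_true(st$y_pc > -0.5 && st$y_pc < 0.5)
  }
})

test_that("a zero-weight Purkinje input gives the quiescent shifted rate", {
  toy <- make_toy_network()
  toy$weights$w_pf_pc[] <- 0
  toy$weights$w_ba_pc[] <- 0
  st <- network_step(network_state(toy$config), toy$weights, toy$masks,
                     rep(0.5, 2), toy$config)
  expect_equal(st$y_pc, sigmoid_rate(0) - 0.5, tolerance = 1e-12)
  expect_equal(st$y_pc, -0.482014, tolerance = 1e-5)
})

test_that("non-finite drives are surfaced, not clamped", {
  toy <- make_toy_network()
  toy$weights$w_mf_gc[1, 1] <- Inf
  expect_error(network_step(network_state(toy$config), toy$weights,
                            toy$masks, c(0.5, 0.5), toy$config),
               "non-finite")
})

test_that("CF-gated learning matches the rule and its sign convention", {
  toy <- make_toy_network()
  gamma <- 0.008
  w1 <- apply_cf_learning(toy$weights, rep(1, 3), 0.5, gamma)
  expect_equal(w1$w_pf_pc - toy$weights$w_pf_pc, rep(-0.002, 3))  # LTD
  w2 <- apply_cf_learning(toy$weights, rep(0, 3), 0.5, gamma)
  expect_equal(w2$w_pf_pc - toy$weights$w_pf_pc, rep(+0.002, 3))  # LTP
  w3 <- apply_cf_learning(toy$weights, rep(0.5, 3), 123, gamma)
  expect_identical(w3$w_pf_pc, toy$weights$w_pf_pc)   # zero-centred rate
  # brute-force check on random triples, unclipped region
  set.seed(9)
  for (k in 1:200) {
    y <- runif(3); cf <- runif(1, -1, 1); g <- runif(1, 1e-4, 0.05)
    toy$weights$w_pf_pc <- runif(3, 0.3, 0.7)
    upd <- apply_cf_learning(toy$weights, y, cf, g)
    expect_equal(upd$w_pf_pc, toy$weights$w_pf_pc - g * (y - 0.5) * cf,
                 tolerance = 1e-14)
  }
})

test_that("learning is antisymmetric under (y, cf) -> (1 - y, -cf)", {
  toy <- make_toy_network()
  toy$weights$w_pf_pc <- rep(0.5, 3)
  set.seed(31)
  for (k in 1:50) {
    y <- runif(3); cf <- runif(1, -0.5, 0.5)
    d1 <- apply_cf_learning(toy$weights, y, cf, 0.01)$w_pf_pc - 0.5
    d2 <- apply_cf_learning(toy$weights, 1 - y, -cf, 0.01)$w_pf_pc - 0.5
    expect_equal(d1, d2, tolerance = 1e-14)
  }
})

test_that("learning touches only the plastic PF-PC vector and clips it", {
  toy <- random_toy(8)
  before <- toy$weights
  out <- toy$weights
  set.seed(12)
  for (k in 1:300)
    out <- apply_cf_learning(out, runif(3), runif(1, -2, 2), 0.05)
  for (nm in setdiff(names(before), "w_pf_pc"))
    expect_identical(out[[nm]], before[[nm]], info = nm)
  expect_true(all(out$w_pf_pc >= 1e-6 & out$w_pf_pc <= 1))
  # null teaching signal leaves weights bit-identical
  frozen <- toy$weights
  for (k in 1:20) frozen <- apply_cf_learning(frozen, runif(3), 0, 0.008)
  expect_identical(frozen$w_pf_pc, toy$weights$w_pf_pc)
})

test_that("the static Purkinje guard centres the all-at-0.5 baseline", {
  cfg <- network_config("robot")
  masks <- build_connectivity(cfg, 4L)
  w <- initialize_weights(cfg, masks, 4L)
  g <- purkinje_guard(w)
  base <- 0.5 * sum(g$weights$w_pf_pc) + 0.5 * sum(g$weights$w_ba_pc)
  expect_gte(base, 0.3)
  expect_lte(base, 0.7)
  expect_gt(g$scale, 1)  # inhibition must be strengthened at this size
})
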