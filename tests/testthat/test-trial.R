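test_that("step counts follow cycles / (f * ts)", {
  tr <- cnn_control("motor", "none", cycles = 2, seed = 1, cnn = FALSE)
  expect_identical(nrow(tr$series), 2L * 200L)   # 0.5 Hz at 10 ms
  expect_identical(length(tr$rse), 2L)
  tr <- cnn_control("robot", "none", cycles = 1, seed = 1, cnn = FALSE)
  expect_identical(nrow(tr$series), 500L)        # 0.2 Hz at 10 ms
})

test_that("identical seed and configuration give bit-identical trials", {
  a <- cnn_control("motor", "SE", cycles = 3, seed = 21)
  b <- cnn_control("motor", "SE", cycles = 3, seed = 21)
  a$call <- b$call <- NULL
  expect_identical(a, b)
  c <- cnn_control("motor", "SE", cycles = 3, seed = 22)
  expect_false(identical(a$w_pf_pc_final, c$w_pf_pc_final))
})

test_that("a null climbing fiber leaves the plastic weights bit-identical", {
  tr <- cnn_control("motor", "none", cycles = 3, seed = 5)
  expect_identical(tr$w_pf_pc_final, tr$w_pf_pc_initial)
  expect_true(all(tr$series$cf == 0))
  # the network is still in the loop: its output shapes the command
  expect_gt(sd(tr$series$y_pc), 0)
  expect_false(isTRUE(all.equal(tr$series$command, tr$series$pd)))
})

test_that("the trial loop agrees with the public network_step on its first sample", {
  seed <- 13
  cfg <- flocculus_config()
  tr <- cnn_control("motor", "SE", cycles = 1, seed = seed, config = cfg)

  net_cfg <- do.call(network_config, c(list(plant = "motor"), cfg$network))
  ss <- flocculus:::derive_seeds(seed, 2L)
  masks <- build_connectivity(net_cfg, ss[1])
  weights <- initialize_weights(net_cfg, masks, ss[2])
  MW <- list(mf_gc = masks$m_mf_gc * weights$w_mf_gc,
             go_gc = masks$m_go_gc * weights$w_go_gc,
             mf_go = masks$m_mf_go * weights$w_mf_go,
             pf_go = masks$m_pf_go * weights$w_pf_go,
             pf_ba = masks$m_pf_ba * weights$w_pf_ba,
             ba_pc = weights$w_ba_pc)
  pp <- do.call(motor_params, cfg$plant$motor)
  mats <- flocculus:::motor_matrices(pp)
  disc <- flocculus:::plant_discretize(mats$A, mats$B, pp$dt_inner, 0.01)
  gains <- pd_gains("motor")
  des <- desired_trajectory(pi, 0.5, (0:199) * 0.01)
  raw <- flocculus:::pd_only_signals("motor", disc$F, disc$G, gains, des,
                                     200L, Inf)
  spec <- mossy_fiber_spec("motor")
  Y <- sigmoid_rate(sweep(raw, 2, spec$gain, `*`))
  cal <- flocculus:::calibrate_network(Y, MW, weights$w_pf_pc, 8, 0.5,
                                       net_cfg$n_go)
  expect_equal(unname(cal$scales), unname(tr$calibration))

  wcal <- weights
  wcal$w_mf_gc <- cal$MW$mf_gc; wcal$w_go_gc <- cal$MW$go_gc
  wcal$w_mf_go <- cal$MW$mf_go; wcal$w_pf_go <- cal$MW$pf_go
  wcal$w_pf_ba <- cal$MW$pf_ba; wcal$w_ba_pc <- cal$MW$ba_pc
  y_mf <- encode_mossy_fibers(c(0, pi * pi, 0, pi * pi, 0), spec)
  st <- network_step(network_state(net_cfg), wcal, masks, y_mf, net_cfg)
  expect_equal(st$y_pc, tr$series$y_pc[1], tolerance = 1e-12)
})

test_that("the battery aggregates per-seed curves with a shared PD baseline", {
  b <- cnn_battery("motor", cf_modes = c("SE", "ME"), cycles = 2,
                   n_seeds = 2, seed = 3)
  expect_identical(dim(b$rse$SE), c(2L, 2L))
  expect_identical(length(b$rse_mean$SE), 2L)
  expect_identical(length(b$baseline_rse), 2L)
  expect_false(b$baseline$cnn)
  expect_equal(b$rse_mean$SE, rowMeans(b$rse$SE))
  s <- summary(b, late = 1)
  expect_identical(nrow(s), 2L)
  # single seed: mean curve equals that seed's curve
  b1 <- cnn_battery("motor", cf_modes = "SE", cycles = 2, seeds = 77L)
  expect_equal(b1$rse_mean$SE, b1$rse$SE[, 1])
})

test_that("the PD-only baseline is seed-independent", {
  a <- cnn_control("robot", "none", cycles = 1, seed = 1, cnn = FALSE)
  b <- cnn_control("robot", "none", cycles = 1, seed = 999, cnn = FALSE)
  expect_identical(a$series, b$series)
  expect_identical(a$rse, b$rse)
})

test_that("trial objects expose the modelling-idiom methods", {
  tr <- cnn_control("motor", "SE", cycles = 2, seed = 2)
  expect_identical(coef(tr), tr$w_pf_pc_final)
  expect_identical(residuals(tr), tr$series$phi_e)
  expect_identical(fitted(tr), tr$series$phi)
  expect_output(print(tr), "motor plant")
  s <- summary(tr)
  expect_s3_class(s, "summary.cnn_trial")
  expect_output(print(s), "PF-PC weights")
  expect_true(all(c("r_cf", "r_phi_e", "r_phi_des") %in%
                    names(tr$correlations)))
  expect_identical(dim(tr$w_snapshots), c(755L, 3L))
  base <- cnn_control("motor", "none", cycles = 1, seed = 1, cnn = FALSE)
  expect_error(coef(base), "no learned weights")
})

test_that("recorded parallel-fiber history matches the streaming correlations", {
  tr <- cnn_control("motor", "SE", cycles = 1, seed = 4, record_pf = TRUE)
  expect_identical(dim(tr$pf_history), c(200L, 755L))
  pr <- gc_correlation(tr$pf_history, tr$series$cf)
  expect_equal(pr$r, tr$correlations$r_cf, tolerance = 1e-8)
  pr2 <- gc_correlation(tr$pf_history, tr$series$phi_des)
  expect_equal(pr2$r, tr$correlations$r_phi_des, tolerance = 1e-8)
})

test_that("calibration centres the initial Purkinje drive", {
  tr <- cnn_control("robot", "none", cycles = 1, seed = 6)
  expect_true(all(is.finite(tr$calibration)))
  expect_true(all(tr$calibration > 0))
  # Purkinje output must actually modulate, not sit on one rail
  expect_gt(sd(tr$series$y_pc), 0.01)
  expect_lt(abs(mean(tr$series$y_pc)), 0.45)
})

test_that("trials can be exported as portable text files", {
  tr <- cnn_control("motor", "SE", cycles = 1, seed = 9)
  dir <- tempfile("trial")
  man <- write_trial(tr, dir)
  expect_true(file.exists(file.path(dir, "series.csv")))
  expect_true(file.exists(file.path(dir, "weights.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  got <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(got$cf_mode, "SE")
  expect_identical(got$seed, 9L)
  for (f in got$files)
    expect_true(file.exists(file.path(dir, f)))
  back <- utils::read.csv(file.path(dir, "series.csv"))
  expect_equal(back$phi, tr$series$phi, tolerance = 1e-12)
})
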