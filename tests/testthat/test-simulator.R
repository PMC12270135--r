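test_that("initial population is contained, reproducible, and correctly sampled", {
  cfg <- sim_config(model = flat_tb(0.2), n = 3, seed = 7)
  pop <- initialize_population(cfg)
  ch <- cfg$channel
  expect_length(pop$x, 3)
  expect_true(all(pop$x >= 0 & pop$x <= ch$width))
  expect_true(all(pop$y >= 0 & pop$y <= ch$length))
  expect_true(all(pop$running))
  expect_identical(pop, initialize_population(cfg))  # determinism

  # log-normal sensitivity sampling: mean within 3 SE of exp(mu + sigma^2/2)
  het <- r1_test_models$heterogeneous
  cfg2 <- sim_config(model = het, n = 1e4, seed = 8)
  K <- initialize_population(cfg2)$phenotypes$K
  mu <- het$mu_K; s <- het$sigma_K
  m_true <- exp(mu + s^2 / 2)
  sd_true <- sqrt((exp(s^2) - 1) * exp(2 * mu + s^2))
  expect_lt(abs(mean(K) - m_true), 3 * sd_true / sqrt(1e4))
})

test_that("a running agent with zero rotational diffusion steps ballistically", {
  ch <- gradient_channel()
  agent <- list(x = 500, y = 1000, theta = pi / 2, running = TRUE, m = 0,
                phenotype = data.frame(phenotype_id = 1, speed = 25))
  out <- step_agent(agent, ch, flat_tb(0), dt = 0.02, rot_diff = 0)
  expect_equal(out$y, 1000.5)   # 25 um/s * 0.02 s straight up
  expect_equal(out$x, 500)
  expect_true(out$running)      # TB = 0: can never switch to tumbling
  expect_false(out$absorbed)
})

test_that("a tumbling agent does not move", {
  ch <- gradient_channel()
  agent <- list(x = 500, y = 1000, theta = 1, running = FALSE, m = 0,
                phenotype = data.frame(phenotype_id = 1, speed = 25))
  set.seed(1)
  for (i in 1:20) {
    out <- step_agent(agent, ch, flat_tb(0.5), dt = 0.02)
    expect_equal(out$x, 500)
    expect_equal(out$y, 1000)
  }
})

test_that("run-to-tumble switching frequency matches the two-state rate", {
  # TB = 0.2, tau_T = 0.2 s: lambda_RT * dt = 0.2/(0.2*0.8) * 0.02 = 0.025
  n <- 1e6
  st <- list(x = runif(n, 0, 1000), y = runif(n, 0, 2000),
             theta = runif(n, 0, 2 * pi), running = rep(TRUE, n),
             m = rep(0, n))
  ph <- data.frame(phenotype_id = seq_len(n), speed = 25)
  set.seed(42)
  res <- chemodrift:::step_population_kernel(
    st, ph, gradient_channel(), flat_tb(0.2), dt = 0.02,
    tau_tumble = 0.2, rot_diff = 0.15, tau_adapt = Inf)
  p_obs <- mean(!res$state$running)
  p_true <- 0.025
  expect_lt(abs(p_obs - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("side walls reflect specularly", {
  ch <- gradient_channel(width = 1000)
  agent <- list(x = 0.2, y = 1000, theta = pi, running = TRUE, m = 0,
                phenotype = data.frame(phenotype_id = 1, speed = 25))
  out <- step_agent(agent, ch, flat_tb(0), dt = 0.02, rot_diff = 0)
  expect_equal(out$x, 0.3)                       # -0.3 reflected to +0.3
  expect_equal(cos(out$theta), 1, tolerance = 1e-12)  # heading mirrored
  expect_true(out$y >= 0 && out$y <= ch$length)
})

test_that("crossing an open end respawns the agent at an end, heading inward", {
  ch <- gradient_channel()
  set.seed(3)
  for (i in 1:20) {
    agent <- list(x = 500, y = ch$length - 0.1, theta = pi / 2, running = TRUE,
                  m = 0, phenotype = data.frame(phenotype_id = 1, speed = 25))
    out <- step_agent(agent, ch, flat_tb(0), dt = 0.02, rot_diff = 0)
    expect_true(out$absorbed)
    expect_true(out$y %in% c(0, ch$length))
    inward <- if (out$y == 0) sin(out$theta) > 0 else sin(out$theta) < 0
    expect_true(inward)
  }
})

test_that("simulation conserves the active-agent count and containment", {
  cfg <- sim_config(model = flat_tb(0.3),
                    channel = gradient_channel(length = 300, width = 200),
                    n = 50, t_max = 20, seed = 9, record = "frames")
  sim <- run_simulation(cfg)
  counts <- table(sim$frames$t_s)
  expect_true(all(counts == 50))  # absorb => respawn keeps the count constant
  expect_true(all(sim$frames$x_um >= 0 & sim$frames$x_um <= 200))
  expect_true(all(sim$frames$y_um >= 0 & sim$frames$y_um <= 300))
  expect_gte(nrow(sim$trajectories), 50)
  # determinism: identical config and seed give identical ensembles
  sim2 <- run_simulation(cfg)
  expect_identical(sim$trajectories, sim2$trajectories)
  expect_identical(sim$frames, sim2$frames)
})

test_that("uniform-concentration tumble-time fraction converges to the model TB", {
  cfg <- sim_config(model = flat_tb(0.2), n = 1500, t_max = 40, seed = 10)
  sim <- run_simulation(cfg)
  tr <- sim$trajectories
  pooled <- weighted.mean(tr$tumble_frac, tr$duration_s)
  expect_lt(abs(pooled - 0.2), 0.01)
})

test_that("drift estimator implements the duration-weighted mean", {
  tab <- data.frame(v_y_um_s = c(1, 3), duration_s = c(1, 3))
  expect_equal(measure_drift(tab)$drift, 2.5)
  # identity: all V equal
  tab2 <- data.frame(v_y_um_s = rep(4.2, 10), duration_s = runif(10, 1, 5))
  expect_equal(measure_drift(tab2)$drift, 4.2)
  # algebraic identity with V_i = dy_i / T_i
  set.seed(12)
  dy <- rnorm(200, 0, 50); Ti <- runif(200, 0.5, 60)
  est <- measure_drift(data.frame(v_y_um_s = dy / Ti, duration_s = Ti))$drift
  expect_lt(abs(est - sum(dy) / sum(Ti)) / abs(sum(dy) / sum(Ti)), 1e-10)
  expect_error(measure_drift(data.frame(v_y_um_s = 1, duration_s = 1)))
})

test_that("config validation enforces the stepping constraints", {
  expect_error(sim_config(model = flat_tb(0.2), dt = 0.1), "tau_tumble / 5")
  expect_error(sim_config(model = flat_tb(0.2), n = 0), "n")
  expect_error(sim_config(model = homogeneous_response(1 - 1e-9, 0.1, 10, 1)))
})
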