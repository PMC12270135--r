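test_that("track generation is deterministic and exact at zero noise", {
  spec <- track_gen_spec(n = 40, noise_sigma = 0, seed = 3)
  g <- generate_tracks(spec)
  expect_equal(g$tracks$x_um, g$truth$frames$x_um)   # sigma = 0: on the path
  expect_equal(g$tracks$y_um, g$truth$frames$y_um)
  g2 <- generate_tracks(spec)
  expect_identical(g$tracks, g2$tracks)              # same seed, same bytes
  expect_identical(g$truth$per_trajectory, g2$truth$per_trajectory)

  noisy <- generate_tracks(track_gen_spec(n = 40, noise_sigma = 0.35, seed = 3))
  expect_gt(sd(noisy$tracks$x_um - g$tracks$x_um), 0.3)
})

test_that("generated ensembles carry consistent ground truth", {
  spec <- track_gen_spec(n = 300, seed = 6)
  g <- generate_tracks(spec)
  # durations within the spec's truncation range (absorption can shorten)
  expect_true(all(g$truth$per_trajectory$duration_s <= 60))
  expect_gte(min(table(g$tracks$traj_id)), 2)
  # per-trajectory biases consistent with per-frame states
  per <- g$truth$per_trajectory
  fr <- g$truth$frames
  id1 <- per$traj_id[which.max(per$n_frames)]
  expect_equal(mean(fr$state[fr$traj_id == id1] == "tumble"),
               per$tumbling_bias[per$traj_id == id1])
  # nominal bias 0.2: pooled tumble-time fraction within 3 CLT standard errors
  # of the two-state stationary value (conservative SE over trajectories)
  tb <- g$truth$pooled_tumbling_bias
  se <- sd(per$tumbling_bias) / sqrt(nrow(per))
  expect_lt(abs(tb - 0.2), 3 * se)
  # ground-truth segments tile every trajectory
  segs <- g$truth$segments
  expect_equal(sum(segs$n_frames), nrow(fr))
})

test_that("synthetic FRET traces invert through the analysis pipeline", {
  truth <- list(A0 = 1, K_D = 20, H = 2, rho = 0.2)
  stim <- data.frame(time_on = c(100, 200, 300), time_off = c(150, 250, 350),
                     conc_uM = c(5, 20, 10000))
  g <- generate_fret_trace(truth, stim, noise_sigma = 0, drift_slope = 0,
                           seed = 2)
  nt <- normalize_ratio(g$trace)
  ka <- kinase_activity(nt, g$cal_act, g$cal_inact)
  idx <- g$trace$time %in% c(120, 220, 320)
  expect_equal(ka$activity[idx],
               hill_activity(truth, c(5, 20, 10000)), tolerance = 1e-9)
  # saturating stimulus plateaus at rho * A0
  expect_equal(ka$activity[g$trace$time == 320], 0.2, tolerance = 1e-4)
  # known linear drift is removed by the baseline correction
  gd <- generate_fret_trace(truth, stim, noise_sigma = 0,
                            drift_slope = 5e-4, seed = 2)
  nd <- normalize_ratio(gd$trace)
  kd <- kinase_activity(nd, g$cal_act, g$cal_inact)
  expect_equal(kd$activity[idx], hill_activity(truth, c(5, 20, 10000)),
               tolerance = 1e-3)
})

test_that("synthetic dose-response tables reproduce the Hill truth", {
  truth <- list(A0 = 1, K_D = 20, H = 2, rho = 0)
  doses <- c(10^seq(0, 2.5, length.out = 7), 20)
  tabs <- generate_dose_response(truth, doses, noise_sigma = 0, replicates = 2,
                                 seed = 1)
  expect_equal(tabs[[1]]$activity, hill_activity(truth, sort(doses)))
  expect_identical(tabs[[1]], tabs[[2]])     # zero noise: replicates identical
  expect_equal(tabs[[1]]$activity[which(sort(doses) == 20)], 0.5,
               tolerance = 1e-12)            # A = A0/2 at L = K_D when rho = 0
})

test_that("synthetic tumbling-bias samples track the model curve", {
  m <- r1_test_models$homogeneous
  data <- generate_tb_response(m, conc = c(0, 10, 30, 100, 1000),
                               cells_per_conc = 400, noise_sigma = 0.01,
                               seed = 9)
  expect_equal(data$mean_tb, tumbling_bias(m, data$conc), tolerance = 0.01)
  expect_true(all(vapply(data$samples, length, 0L) == 400))
})
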