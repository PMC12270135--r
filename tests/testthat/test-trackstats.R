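test_that("swimmer filter applies the diffusivity and duration criteria", {
  swim <- make_line_track(speed = 20, duration = 5, id = 1L)     # fast sweep
  still <- make_track(rep(3, 251), rep(4, 251), id = 2L)         # zero variance
  short <- make_line_track(speed = 20, duration = 0.8, id = 3L)  # < 1 s
  fl <- filter_swimmers(rbind(swim, still, short), frame_rate = 50)
  cls <- setNames(fl$stats$class, fl$stats$traj_id)
  expect_equal(unname(cls["1"]), "swimmer")
  expect_equal(unname(cls["2"]), "non_swimmer")
  expect_equal(unname(cls["3"]), "discarded")
  # partition is exhaustive and disjoint
  n_all <- nrow(fl$swimmers) + nrow(fl$non_swimmers) + nrow(fl$discarded)
  expect_equal(n_all, 251 + 251 + 41)
  expect_error(filter_swimmers(transform(swim, x_um = NaN)), "non-finite")
})

test_that("local velocity fit is exact on linear tracks", {
  tr <- make_track(2 * (0:99) / 50, rep(0, 100))   # x = 2t, 50 fps
  ann <- local_velocity(tr, 50)
  expect_equal(ann$speed, rep(2, 100), tolerance = 1e-12)
  expect_equal(ann$vx, rep(2, 100), tolerance = 1e-12)
  still <- local_velocity(make_track(rep(1, 50), rep(2, 50)), 50)
  expect_equal(still$speed, rep(0, 50), tolerance = 1e-12)
  expect_equal(still$dr_mean, rep(0, 50))
})

test_that("local velocity matches an independent per-window regression", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(12:120, 1)
    t <- (0:(n - 1)) / 50
    x <- 10 * cos(2 * pi * t / 3) + cumsum(rnorm(n, 0, 0.3))
    y <- 25 * t + rnorm(n, 0, 0.4)
    ann <- local_velocity(make_track(x, y), 50)
    or <- oracle_local_velocity(x, y, 50)
    expect_lt(max(abs(ann$vx - or[, "vx"])) / max(abs(or[, "vx"])), 1e-10)
    expect_lt(max(abs(ann$vy - or[, "vy"])) / max(abs(or[, "vy"])), 1e-10)
  }
})

test_that("trajectories shorter than the window are skipped and flagged", {
  short <- make_track(1:5, 1:5, id = 7L)
  long <- make_line_track(duration = 1, id = 8L)
  ann <- local_velocity(rbind(short, long), 50)
  expect_equal(attr(ann, "skipped"), 7L)
  expect_true(all(ann$traj_id == 8L))
})

test_that("a constant-velocity track segments into a single run with v_n = 1", {
  tr <- make_line_track(speed = 25, duration = 2, theta = 0.7)
  seg <- segment_motility(local_velocity(tr, 50))
  expect_equal(seg$labels$vn, rep(1, nrow(seg$labels)), tolerance = 1e-9)
  expect_equal(nrow(seg$segments), 1)
  expect_equal(seg$segments$state, "run")
  # partition property: segment durations sum to the trajectory duration
  expect_equal(sum(seg$segments$n_frames), nrow(tr))
})

test_that("a stationary pause between runs is labeled tumble within 2 frames", {
  tr <- make_run_pause_run_track(pause_s = 0.3, jitter = 0.1)
  pf <- attr(tr, "pause_frames")
  seg <- segment_motility(local_velocity(tr, 50))
  segs <- seg$segments
  tum <- segs[segs$state == "tumble", ]
  expect_equal(nrow(tum), 1)
  expect_lt(abs(tum$start_frame - pf[1]), 3)
  expect_lt(abs(tum$end_frame - pf[2]), 3)
  # every frame gets exactly one label
  expect_equal(sum(segs$n_frames), nrow(tr))
})

test_that("an instantaneous reversal at constant speed reads as a tumble", {
  n <- 50; step <- 0.5
  x <- c(step * (0:(n - 1)), step * (n - 2:n))   # out and straight back
  tr <- make_track(x, rep(0, length(x)))
  seg <- segment_motility(local_velocity(tr, 50))
  rev_frames <- seg$labels$state[(n - 2):(n + 2)]
  expect_true(all(rev_frames == "tumble"))
})

test_that("motility summary pools state occupancy across trajectories", {
  tr1 <- make_line_track(duration = 2, id = 1L)
  seg <- segment_motility(local_velocity(tr1, 50))
  sm <- summarize_motility(seg)
  expect_equal(sm$pooled_tumbling_bias, 0)  # all-run trajectory
  expect_equal(sm$per_trajectory$tumbling_bias, 0)

  # duration-weighted pooling arithmetic on a hand-built segmentation
  lab <- data.frame(
    traj_id = rep(c(1, 2), c(500, 100)),
    frame = c(0:499, 0:99),
    speed = 25,
    state = c(rep(c("run", "tumble"), c(450, 50)),
              rep(c("run", "tumble"), c(60, 40))))
  fake <- structure(list(labels = lab, segments = NULL, frame_rate = 50),
                    class = "motility_segmentation")
  sm2 <- summarize_motility(fake)
  expect_equal(sm2$per_trajectory$tumbling_bias, c(0.1, 0.4))
  expect_equal(sm2$pooled_tumbling_bias, (0.1 * 500 + 0.4 * 100) / 600)
})

test_that("drift is antisymmetric and the chemotaxis bias is drift over speed", {
  set.seed(31)
  t <- (0:100) / 50
  up <- make_track(cumsum(rnorm(101)), 20 * t + cumsum(rnorm(101)), id = 1L)
  down <- up; down$y_um <- -down$y_um; down$traj_id <- 2L
  dr <- drift_and_bias(rbind(up, down), 50)
  expect_equal(dr$v_chem, 0)
  expect_error(measure_drift(data.frame()), "trajectories")
  # bias = V_chem / mean run speed
  two <- rbind(make_line_track(speed = 10, duration = 2, theta = pi / 2, id = 1L),
               make_line_track(speed = 10, duration = 2, theta = pi / 2, id = 2L))
  db <- drift_and_bias(two, 50, mean_run_speed = 25)
  expect_equal(db$v_chem, 10)
  expect_equal(db$bias, 0.4)
})

test_that("trackstats drift equals the simulator's internal drift", {
  cfg <- sim_config(model = flat_tb(0.15),
                    channel = gradient_channel(c_low = 0, c_high = 500),
                    n = 120, t_max = 30, seed = 14, record = "frames")
  sim <- run_simulation(cfg)
  dr <- drift_and_bias(sim$frames, frame_rate = 1 / cfg$dt)
  expect_lt(abs(dr$v_chem - sim$drift$drift) / max(abs(sim$drift$drift), 1e-9),
            1e-10)
})

test_that("run direction classes follow the angular rules with strict boundaries", {
  runs <- data.frame(
    traj_id = 1, state = "run", start_frame = 0, end_frame = 9,
    n_frames = c(10, 10, 10, 10, 4, 10), duration_s = c(10, 10, 10, 10, 4, 10) / 50,
    dx_um = c(0, 0, 5 / sqrt(2), 1, 0, 0),
    dy_um = c(5, -5, 5 / sqrt(2), 10, 5, 0))
  res <- run_direction_analysis(runs, min_frames = 5)
  expect_equal(res$runs$class, c("up", "down", "transverse", "up", "transverse"))
  expect_equal(res$runs$alpha[1], 0)
  expect_equal(res$runs$alpha[2], pi)
  expect_equal(res$runs$alpha[3], pi / 4)      # boundary -> transverse
  expect_equal(nrow(res$runs), 5)              # 4-frame run removed
  expect_equal(res$n_zero_displacement, 1)     # zero net displacement flagged
})

test_that("spreading bias is the up/down distance ratio with a one-sided test", {
  expect_equal(spreading_bias(2, 1)$mean, 2)
  expect_equal(spreading_bias(3, 3)$mean, 1)
  same <- spreading_bias(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$mean, 1)
  expect_true(is.na(same$p_value))             # degenerate: cannot reject
  set.seed(4)
  up <- spreading_bias(c(2.0, 2.2, 1.9, 2.1), c(1.0, 1.1, 0.9, 1.0))
  expect_lt(up$p_value, 0.05)
  expect_error(spreading_bias(1, 0), "positive")
})
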