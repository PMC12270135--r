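# Shared fixtures: tracks are data frames in the trackstats input schema.

make_track <- function(x, y, id = 1L, frame_rate = 50) {
  stopifnot(length(x) == length(y))
  data.frame(traj_id = id, frame = seq_along(x) - 1L,
             t_s = (seq_along(x) - 1L) / frame_rate, x_um = x, y_um = y)
}

# straight constant-speed track
make_line_track <- function(speed = 20, duration = 5, theta = 0, id = 1L,
                            frame_rate = 50, x0 = 0, y0 = 0) {
  t <- seq(0, duration, by = 1 / frame_rate)
  make_track(x0 + speed * cos(theta) * t, y0 + speed * sin(theta) * t,
             id = id, frame_rate = frame_rate)
}

# run (1 s) - stationary jitter - run (1 s) with a known middle segment
make_run_pause_run_track <- function(pause_s = 0.3, jitter = 0.1, speed = 25,
                                     frame_rate = 50, seed = 99) {
  set.seed(seed)
  n_run <- frame_rate              # 1 s per run
  n_pause <- round(pause_s * frame_rate)
  step <- speed / frame_rate
  x1 <- step * (0:(n_run - 1))
  x2 <- rep(x1[n_run], n_pause) + rnorm(n_pause, 0, jitter)
  y2 <- rnorm(n_pause, 0, jitter)
  # second run heads off at 90 degrees
  x3 <- rep(x1[n_run], n_run)
  y3 <- y2[n_pause] + step * (1:n_run)
  tr <- make_track(c(x1, x2, x3), c(rep(0, n_run), y2, y3),
                   frame_rate = frame_rate)
  attr(tr, "pause_frames") <- c(n_run, n_run + n_pause - 1L)  # 0-based range
  tr
}

# independent per-window least-squares velocity fit (the oracle for
# local_velocity): plain lm() per window, centered placement with clamping
oracle_local_velocity <- function(x, y, frame_rate, window = 10) {
  n <- length(x)
  nw <- n - window + 1
  vx <- vy <- numeric(nw)
  tt <- (0:(window - 1)) / frame_rate
  for (w in seq_len(nw)) {
    idx <- w:(w + window - 1)
    vx[w] <- coef(lm(x[idx] ~ tt))[2]
    vy[w] <- coef(lm(y[idx] ~ tt))[2]
  }
  wmap <- pmin(pmax(seq_len(n) - floor(window / 2) + 1L, 1L), nw)
  cbind(vx = vx[wmap], vy = vy[wmap])
}

r1_test_models <- r1_response_models()

flat_tb <- function(tb) homogeneous_response(tb, tb, 1, 1)
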