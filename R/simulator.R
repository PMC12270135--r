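#' Linear-gradient channel geometry
#'
#' Rectangular simulation channel with solid side walls at `x = 0` and
#' `x = width` and open ends at `y = 0` and `y = length`. The attractant
#' concentration is linear along the channel axis,
#' `c(y) = c_low + (c_high - c_low) * y / length`, and constant in `x`; the
#' gradient axis is `+y`.
#'
#' @param length Channel length along the gradient (um, default 2000).
#' @param width Channel width (um, default 1000).
#' @param c_low Concentration at `y = 0` (uM).
#' @param c_high Concentration at `y = length` (uM).
#' @return Object of class `gradient_channel`.
#' @export
gradient_channel <- function(length = 2000, width = 1000,
                             c_low = 0, c_high = 0) {
  stopifnot(length > 0, width > 0, c_low >= 0, c_high >= 0)
  structure(list(length = length, width = width,
                 c_low = c_low, c_high = c_high),
            class = "gradient_channel")
}

#' Attractant concentration at a channel position
#'
#' @param channel A [gradient_channel()].
#' @param y Position(s) along the gradient axis (um).
#' @return Concentration(s) in uM.
#' @export
conc_at <- function(channel, y) {
  channel$c_low + (channel$c_high - channel$c_low) * y / channel$length
}

#' Simulation configuration
#'
#' Collects all parameters of a run-and-tumble population simulation. Motility
#' is a two-state Markov process: a running cell switches to tumbling at rate
#' `TB / (tau_tumble * (1 - TB))` (so that the stationary fraction of time
#' spent tumbling is exactly the model tumbling bias TB at the local
#' concentration) and a tumbling cell resumes running at rate
#' `1 / tau_tumble`, with a fresh uniform heading. Runs advance the cell at
#' its phenotype speed while the heading diffuses rotationally; tumbles do
#' not displace the cell.
#'
#' @param model A response model ([homogeneous_response()] or
#'   [heterogeneous_response()]).
#' @param channel A [gradient_channel()].
#' @param n Number of concurrently simulated agents; every agent yields at
#'   least one trajectory, so at least `n` trajectories are collected.
#' @param dt Time step (s, default 0.02); must satisfy `dt <= tau_tumble / 5`.
#' @param t_max Simulated residence time (s, default 60); trajectories still
#'   inside the channel are terminated at `t_max`.
#' @param tau_tumble Mean tumble duration (s, default 0.2).
#' @param rot_diff Rotational diffusion during runs (rad^2/s, default 0.15).
#' @param tau_adapt Slow-adaptation time constant (s); `Inf` (default)
#'   disables adaptation.
#' @param preadapted If `TRUE`, agents start with their concentration memory
#'   equilibrated to the local concentration (`m = c(y)`); default `FALSE`
#'   (naive cells, `m = 0`), reflecting cells freshly introduced into the
#'   gradient.
#' @param speed,speed_sd Run-speed parameters passed to [sample_phenotypes()].
#' @param seed Integer RNG seed; simulations are reproducible given the seed.
#' @param record `"drift"` (per-trajectory summaries only) or `"frames"`
#'   (additionally keep per-frame positions and motility states; memory grows
#'   as `n * t_max / dt`).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(model, channel = gradient_channel(), n = 15000,
                       dt = 0.02, t_max = 60, tau_tumble = 0.2,
                       rot_diff = 0.15, tau_adapt = Inf, preadapted = FALSE,
                       speed = 25, speed_sd = 0, seed = 1,
                       record = c("drift", "frames"),
                       sensing = c("step_end", "step_start")) {
  stopifnot(inherits(model, "response_model"),
            inherits(channel, "gradient_channel"))
  if (n < 1) stop("n must be >= 1")
  if (dt <= 0) stop("dt must be positive")
  if (dt > tau_tumble / 5)
    stop("dt must be <= tau_tumble / 5 for the switching probabilities to be valid")
  if (t_max <= 0) stop("t_max must be positive")
  if (tau_adapt <= 0) stop("tau_adapt must be positive (Inf disables adaptation)")
  if (inherits(model, "homogeneous_response") && model$tb0 >= 1 - 1e-6)
    stop("model tumbling bias reaches 1; switching rate undefined")
  structure(list(model = model, channel = channel, n = as.integer(n), dt = dt,
                 t_max = t_max, tau_tumble = tau_tumble, rot_diff = rot_diff,
                 tau_adapt = tau_adapt, preadapted = preadapted,
                 speed = speed, speed_sd = speed_sd, seed = as.integer(seed),
                 record = match.arg(record), sensing = match.arg(sensing)),
            class = "sim_config")
}

#' Initialise an agent population
#'
#' Seeds the RNG from the configuration and draws `n` agents with positions
#' uniform over the channel rectangle, headings uniform on `[0, 2*pi)`, all
#' running, with phenotypes drawn once per agent from the response model
#' (degenerate for the homogeneous model). The adaptation memory starts at 0
#' (naive) or at the local concentration when `preadapted = TRUE`.
#'
#' @param config A [sim_config()].
#' @return List of state vectors (`x`, `y`, `theta`, `running`, `m`) plus the
#'   phenotype data frame, of class `agent_population`.
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  ch <- config$channel
  y <- stats::runif(n, 0, ch$length)
  pop <- list(
    x = stats::runif(n, 0, ch$width),
    y = y,
    theta = stats::runif(n, 0, 2 * pi),
    running = rep(TRUE, n),
    m = if (config$preadapted && is.finite(config$tau_adapt)) conc_at(ch, y)
        else rep(0, n),
    phenotypes = sample_phenotypes(config$model, n, config$speed,
                                   config$speed_sd))
  class(pop) <- "agent_population"
  pop
}

# Tumbling bias of every agent at its effective concentration. For the
# homogeneous model all agents share the model curve; for the heterogeneous
# model each agent uses its own (tb0, K).
population_tb <- function(model, L_eff, phenotypes) {
  if (inherits(model, "homogeneous_response")) tumbling_bias(model, L_eff)
  else tumbling_bias(model, L_eff, phenotypes)
}

# Draw respawn states for k agents entering through the open ends: end chosen
# uniformly, lateral position uniform, heading uniform over inward directions.
respawn_states <- function(k, channel) {
  top <- stats::runif(k) < 0.5
  y <- ifelse(top, channel$length, 0)
  u <- stats::runif(k, 0, pi)
  theta <- ifelse(top, pi + u, u)  # inward: sin(theta) < 0 at top end, > 0 at bottom
  list(x = stats::runif(k, 0, channel$width), y = y, theta = theta %% (2 * pi))
}

#' Advance one agent by a single time step
#'
#' Single-agent version of the population stepping kernel, mainly useful for
#' testing the stepping contract. A running agent advances `speed * dt` along
#' its heading, then the heading takes a Gaussian rotational-diffusion step of
#' variance `2 * rot_diff * dt`, and the agent switches to tumbling with
#' probability `lambda_RT * dt`, `lambda_RT = TB / (tau_tumble * (1 - TB))`.
#' A tumbling agent stays in place and resumes running with probability
#' `dt / tau_tumble`, drawing a fresh uniform heading. Side walls reflect
#' specularly; crossing an open end absorbs the agent and respawns it at a
#' random end with an inward heading (the returned agent carries
#' `absorbed = TRUE` in that case).
#'
#' @param agent List with fields `x`, `y`, `theta`, `running`, `m` and
#'   `phenotype` (one row of a [sample_phenotypes()] frame).
#' @param channel A [gradient_channel()].
#' @param model A response model.
#' @param dt Time step (s).
#' @param tau_tumble,rot_diff,tau_adapt As in [sim_config()].
#' @return The updated agent (same fields, plus `absorbed`).
#' @export
step_agent <- function(agent, channel, model, dt, tau_tumble = 0.2,
                       rot_diff = 0.15, tau_adapt = Inf,
                       sensing = "step_end") {
  st <- list(x = agent$x, y = agent$y, theta = agent$theta,
             running = agent$running, m = agent$m)
  res <- step_population_kernel(st, agent$phenotype, channel, model, dt,
                                tau_tumble, rot_diff, tau_adapt, sensing)
  out <- res$state
  absorbed <- res$absorbed
  if (absorbed) {
    rs <- respawn_states(1, channel)
    out$x <- rs$x; out$y <- rs$y; out$theta <- rs$theta
    out$running <- TRUE; out$m <- 0
  }
  c(out, list(phenotype = agent$phenotype, absorbed = absorbed))
}

# Vectorised stepping kernel. `state` holds equal-length vectors x, y, theta,
# running, m; `phenotypes` one row per agent. Returns the updated state (with
# out-of-channel agents flagged `absorbed`, their position/clock NOT advanced
# past the last in-channel sample) without respawning them.
step_population_kernel <- function(state, phenotypes, channel, model, dt,
                                   tau_tumble, rot_diff, tau_adapt,
                                   sensing = "step_end") {
  x <- state$x; y <- state$y; theta <- state$theta
  run <- state$running
  nr <- sum(run)
  if (nr > 0) {
    v <- phenotypes$speed[run]
    x[run] <- x[run] + v * cos(theta[run]) * dt
    y[run] <- y[run] + v * sin(theta[run]) * dt
    theta[run] <- theta[run] + stats::rnorm(nr, 0, sqrt(2 * rot_diff * dt))
    # specular reflection at the side walls
    lo <- x < 0
    if (any(lo)) { x[lo] <- -x[lo]; theta[lo] <- pi - theta[lo] }
    hi <- x > channel$width
    if (any(hi)) { x[hi] <- 2 * channel$width - x[hi]; theta[hi] <- pi - theta[hi] }
    theta <- theta %% (2 * pi)
  }

  # concentration governing this step's switching decision: sensed at the
  # position reached during the step ("step_end", default) or at the step's
  # start ("step_start"); see the methods vignette for why this matters
  y_sense <- if (sensing == "step_end")
    pmin(pmax(y, 0), channel$length) else state$y
  L_local <- conc_at(channel, y_sense)
  L_eff <- pmax(L_local - state$m, 0)
  tb <- pmin(population_tb(model, L_eff, phenotypes), 1 - 1e-6)
  lam_rt <- tb / (tau_tumble * (1 - tb))

  u <- stats::runif(length(x))
  to_tumble <- run & (u < pmin(lam_rt * dt, 1))
  to_run <- !run & (u < dt / tau_tumble)
  running <- run
  running[to_tumble] <- FALSE
  running[to_run] <- TRUE
  k <- sum(to_run)
  if (k > 0) theta[to_run] <- stats::runif(k, 0, 2 * pi)

  absorbed <- y < 0 | y > channel$length
  if (any(absorbed)) {  # discard the exiting move; caller respawns
    x[absorbed] <- state$x[absorbed]
    y[absorbed] <- state$y[absorbed]
  }

  m <- update_adaptation(state$m, L_local, dt, tau_adapt)
  list(state = list(x = x, y = y, theta = theta, running = running, m = m),
       absorbed = absorbed)
}

#' Run a population simulation
#'
#' Simulates `config$n` agents for `config$t_max` of model time, collecting
#' one trajectory per channel residency: a trajectory ends when its agent
#' crosses an open end (absorption; the agent is respawned at a random end
#' and starts a new trajectory, so the number of active agents is constant)
#' or when the simulation reaches `t_max`. The exiting step itself is
#' discarded, so every recorded position lies inside the channel.
#'
#' @param config A [sim_config()].
#' @return Object of class `simulation_result` with elements
#'   \describe{
#'     \item{trajectories}{data frame with one row per trajectory:
#'       `traj_id`, `phenotype_id`, `y0_um`, `dy_um`, `duration_s`,
#'       `v_y_um_s` (`= dy_um / duration_s`), `tumble_frac`, `absorbed`.
#'       Residencies shorter than one step are dropped.}
#'     \item{drift}{[measure_drift()] of the trajectory table.}
#'     \item{frames}{when `record = "frames"`, a data frame `traj_id`,
#'       `frame`, `t_s`, `x_um`, `y_um`, `state`, `phenotype_id` sampled at
#'       every step; otherwise `NULL`.}
#'     \item{config}{the configuration (seed, gradient endpoints, model).}
#'   }
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pop <- initialize_population(config)
  n <- config$n
  ch <- config$channel
  nsteps <- round(config$t_max / config$dt)
  frames_mode <- config$record == "frames"

  state <- pop[c("x", "y", "theta", "running", "m")]
  phen <- pop$phenotypes

  # per-agent open-trajectory bookkeeping
  cur_id <- seq_len(n)
  next_id <- n + 1L
  y0 <- state$y
  t0 <- rep(0L, n)                       # step index at trajectory start
  tumble_n <- as.integer(!state$running) # state occupancy counts (incl. step 0)
  total_n <- rep(1L, n)

  # closed-trajectory accumulators
  acc <- vector("list", 256); acc_i <- 0L
  close_traj <- function(idx, y_end, step) {
    dur <- (step - t0[idx]) * config$dt
    acc_i <<- acc_i + 1L
    if (acc_i > length(acc)) length(acc) <<- 2L * length(acc)
    acc[[acc_i]] <<- data.frame(
      traj_id = cur_id[idx], phenotype_id = phen$phenotype_id[idx],
      y0_um = y0[idx], dy_um = y_end - y0[idx], duration_s = dur,
      tumble_frac = tumble_n[idx] / total_n[idx],
      absorbed = step < nsteps)
  }

  if (frames_mode) {
    Xm <- matrix(NA_real_, n, nsteps + 1L)
    Ym <- matrix(NA_real_, n, nsteps + 1L)
    Sm <- matrix(NA_integer_, n, nsteps + 1L)  # 1 = run, 0 = tumble
    Tm <- matrix(NA_integer_, n, nsteps + 1L)
    Xm[, 1L] <- state$x; Ym[, 1L] <- state$y
    Sm[, 1L] <- as.integer(state$running); Tm[, 1L] <- cur_id
  }

  for (s in seq_len(nsteps)) {
    res <- step_population_kernel(state, phen, ch, config$model, config$dt,
                                  config$tau_tumble, config$rot_diff,
                                  config$tau_adapt, config$sensing)
    state <- res$state
    out <- which(res$absorbed)
    if (length(out) > 0) {
      close_traj(out, state$y[out], s - 1L)
      rs <- respawn_states(length(out), ch)
      state$x[out] <- rs$x; state$y[out] <- rs$y; state$theta[out] <- rs$theta
      state$running[out] <- TRUE
      state$m[out] <- if (config$preadapted && is.finite(config$tau_adapt))
        conc_at(ch, rs$y) else 0
      cur_id[out] <- seq.int(next_id, length.out = length(out))
      next_id <- next_id + length(out)
      y0[out] <- state$y[out]; t0[out] <- s
      tumble_n[out] <- 0L; total_n[out] <- 0L
    }
    tumble_n <- tumble_n + as.integer(!state$running)
    total_n <- total_n + 1L
    if (frames_mode) {
      Xm[, s + 1L] <- state$x; Ym[, s + 1L] <- state$y
      Sm[, s + 1L] <- as.integer(state$running); Tm[, s + 1L] <- cur_id
    }
  }
  close_traj(seq_len(n), state$y, nsteps)

  traj <- do.call(rbind, acc[seq_len(acc_i)])
  traj <- traj[traj$duration_s > 0, , drop = FALSE]
  traj <- traj[order(traj$traj_id), , drop = FALSE]
  traj$v_y_um_s <- traj$dy_um / traj$duration_s
  rownames(traj) <- NULL

  frames <- NULL
  if (frames_mode) {
    # flatten agent-major so each trajectory's samples are contiguous in time
    tid <- as.vector(t(Tm)); xx <- as.vector(t(Xm)); yy <- as.vector(t(Ym))
    st <- as.vector(t(Sm))
    stp <- rep(0:nsteps, times = n)
    keep <- tid %in% traj$traj_id
    o <- order(tid[keep], stp[keep])
    tid <- tid[keep][o]; xx <- xx[keep][o]; yy <- yy[keep][o]
    st <- st[keep][o]; stp <- stp[keep][o]
    frame <- stats::ave(stp, tid, FUN = function(z) z - z[1L])
    frames <- data.frame(
      traj_id = tid, frame = as.integer(frame), t_s = stp * config$dt,
      x_um = xx, y_um = yy, state = ifelse(st == 1L, "run", "tumble"),
      phenotype_id = traj$phenotype_id[match(tid, traj$traj_id)])
  }

  structure(list(trajectories = traj, drift = measure_drift(traj),
                 frames = frames, config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Run-and-tumble simulation: %d trajectories (%d agents, %.0f s)\n",
              nrow(x$trajectories), x$config$n, x$config$t_max))
  cat(sprintf("  gradient: %.3g -> %.3g uM over %.0f um\n",
              x$config$channel$c_low, x$config$channel$c_high,
              x$config$channel$length))
  cat(sprintf("  drift V_chem = %.4f +/- %.4f um/s\n", x$drift$drift, x$drift$sem))
  invisible(x)
}

#' Duration-weighted chemotactic drift of a trajectory ensemble
#'
#' Computes the population drift along the gradient axis,
#' \deqn{V_{chem} = \frac{\sum_i V_i T_i}{\sum_i T_i}}
#' where \eqn{V_i} is trajectory i's mean velocity along `+y` and \eqn{T_i}
#' its duration. When \eqn{V_i = \Delta y_i / T_i} this equals the total `y`
#' displacement over the total time. The standard error is the
#' duration-weighted SEM over trajectories, using the effective sample size
#' `(sum w)^2 / sum w^2`.
#'
#' @param trajectories Data frame with columns `v_y_um_s` and `duration_s`
#'   (e.g. the `trajectories` element of a [run_simulation()] result).
#' @return List with `drift` (um/s), `sem` (um/s) and `n` (number of
#'   trajectories).
#' @export
measure_drift <- function(trajectories) {
  v <- trajectories$v_y_um_s
  w <- trajectories$duration_s
  if (is.null(v) || is.null(w) || length(v) < 2)
    stop("need at least 2 trajectories with durations")
  stopifnot(all(w > 0))
  sw <- sum(w)
  drift <- sum(v * w) / sw
  neff <- sw^2 / sum(w^2)
  wvar <- sum(w * (v - drift)^2) / sw * neff / (neff - 1)
  list(drift = drift, sem = sqrt(wvar / neff), n = length(v))
}
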