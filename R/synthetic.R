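#' Specification for synthetic tracking data
#'
#' Describes a synthetic "movie": how many tracks to emit, the acquisition
#' (frame rate, localisation noise), the ground-truth response model and
#' gradient driving the underlying run-and-tumble dynamics, and the track
#' duration distribution (exponential, truncated to mimic finite residency in
#' a field of view).
#'
#' @param n Number of trajectories to emit.
#' @param model Ground-truth response model (default: homogeneous with
#'   TB = 0.2 at all concentrations).
#' @param channel Gradient/geometry ([gradient_channel()]); the default has a
#'   uniform zero concentration.
#' @param frame_rate Frames/s (default 50; also sets the simulation step).
#' @param noise_sigma Isotropic Gaussian localisation noise, um (default
#'   0.35, about half a pixel at 0.7 um/px).
#' @param duration_mean Mean of the exponential track-duration distribution
#'   (s, default 4).
#' @param duration_range Truncation bounds for durations (s, default
#'   `c(1, 60)`).
#' @param speed,speed_sd,tau_tumble,rot_diff Motility parameters, as in
#'   [sim_config()].
#' @param seed RNG seed.
#' @return Object of class `track_gen_spec`.
#' @export
track_gen_spec <- function(n = 500,
                           model = homogeneous_response(0.2, 0.2, 1, 1),
                           channel = gradient_channel(),
                           frame_rate = 50, noise_sigma = 0.35,
                           duration_mean = 4, duration_range = c(1, 60),
                           speed = 25, speed_sd = 0, tau_tumble = 0.2,
                           rot_diff = 0.15, seed = 1) {
  stopifnot(n >= 1, frame_rate > 0, noise_sigma >= 0,
            duration_range[1] > 0, duration_range[2] > duration_range[1])
  structure(list(n = n, model = model, channel = channel,
                 frame_rate = frame_rate, noise_sigma = noise_sigma,
                 duration_mean = duration_mean,
                 duration_range = duration_range, speed = speed,
                 speed_sd = speed_sd, tau_tumble = tau_tumble,
                 rot_diff = rot_diff, seed = as.integer(seed)),
            class = "track_gen_spec")
}

#' Generate synthetic 2-D tracking data with ground truth
#'
#' Runs the run-and-tumble simulator at the acquisition frame rate, samples
#' each agent's first channel residency, truncates it to a duration drawn
#' from the spec's distribution, and adds isotropic Gaussian localisation
#' noise to the emitted positions. The unobservable truth (noise-free
#' positions, per-frame motility states, per-trajectory tumbling bias, true
#' run segments) is returned alongside. Deterministic given the spec seed.
#'
#' @param spec A [track_gen_spec()].
#' @return List with
#'   \describe{
#'     \item{tracks}{data frame `traj_id`, `frame`, `t_s`, `x_um`, `y_um`
#'       (noisy positions) — the trackstats input schema.}
#'     \item{truth}{list with `frames` (true positions and `state` per
#'       frame), `per_trajectory` (true tumbling bias and duration),
#'       `segments` (true run/tumble segments with net displacements from the
#'       true positions), `pooled_tumbling_bias`, `model`, `spec`.}
#'   }
#' @export
generate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_gen_spec"))
  set.seed(spec$seed)
  lo <- spec$duration_range[1]; hi <- spec$duration_range[2]
  dur <- stats::rexp(spec$n, 1 / spec$duration_mean)
  while (any(bad <- dur < lo | dur > hi))
    dur[bad] <- stats::rexp(sum(bad), 1 / spec$duration_mean)

  cfg <- sim_config(model = spec$model, channel = spec$channel, n = spec$n,
                    dt = 1 / spec$frame_rate, t_max = max(dur),
                    tau_tumble = spec$tau_tumble, rot_diff = spec$rot_diff,
                    speed = spec$speed, speed_sd = spec$speed_sd,
                    seed = spec$seed + 1L, record = "frames")
  sim <- run_simulation(cfg)
  fr <- sim$frames[sim$frames$traj_id <= spec$n, , drop = FALSE]
  maxf <- round(dur * spec$frame_rate)                  # frames 0..maxf kept
  fr <- fr[fr$frame <= maxf[fr$traj_id], , drop = FALSE]
  nk <- table(factor(fr$traj_id, levels = sort(unique(fr$traj_id))))
  fr <- fr[fr$traj_id %in% as.integer(names(nk)[nk >= 2]), , drop = FALSE]

  set.seed(spec$seed + 2L)
  tracks <- data.frame(
    traj_id = fr$traj_id, frame = fr$frame, t_s = fr$frame / spec$frame_rate,
    x_um = fr$x_um + stats::rnorm(nrow(fr), 0, spec$noise_sigma),
    y_um = fr$y_um + stats::rnorm(nrow(fr), 0, spec$noise_sigma))
  attr(tracks, "frame_rate") <- spec$frame_rate

  truth_frames <- data.frame(traj_id = fr$traj_id, frame = fr$frame,
                             x_um = fr$x_um, y_um = fr$y_um,
                             state = fr$state)
  g <- factor(fr$traj_id, levels = unique(fr$traj_id))
  per <- data.frame(
    traj_id = as.integer(levels(g)),
    n_frames = as.integer(table(g)),
    tumbling_bias = as.numeric(tapply(fr$state == "tumble", g, mean)))
  per$duration_s <- (per$n_frames - 1) / spec$frame_rate
  segments <- true_segments(truth_frames, spec$frame_rate)
  list(tracks = tracks,
       truth = list(frames = truth_frames, per_trajectory = per,
                    segments = segments,
                    pooled_tumbling_bias = mean(fr$state == "tumble"),
                    model = spec$model, spec = spec))
}

#' Run/tumble segments from per-frame ground-truth state labels
#'
#' Collapses per-frame motility states (e.g. the `frames` element of a
#' [run_simulation()] result or the truth sidecar of [generate_tracks()])
#' into maximal constant-state segments with net displacements, the same
#' schema produced by the trajectory-analysis segmentation, so simulated
#' ensembles can feed [run_direction_analysis()] directly.
#'
#' @param truth_frames Data frame with `traj_id`, `frame`, `x_um`, `y_um`,
#'   `state`.
#' @param frame_rate Frames/s.
#' @return Segment data frame (`traj_id`, `state`, `start_frame`,
#'   `end_frame`, `n_frames`, `duration_s`, `dx_um`, `dy_um`).
#' @export
true_segments <- function(truth_frames, frame_rate) {
  sp <- split(truth_frames,
              factor(truth_frames$traj_id, levels = unique(truth_frames$traj_id)))
  seg <- lapply(sp, function(d) {
    r <- rle(d$state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    data.frame(traj_id = d$traj_id[1], state = r$values,
               start_frame = d$frame[starts], end_frame = d$frame[ends],
               n_frames = r$lengths, duration_s = r$lengths / frame_rate,
               dx_um = d$x_um[ends] - d$x_um[starts],
               dy_um = d$y_um[ends] - d$y_um[starts])
  })
  out <- do.call(rbind, seg)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic FRET trace with stimulus steps
#'
#' Builds a YFP/CFP ratio time series from a ground-truth Hill dose-response:
#' activity is `A0` while unstimulated and `A(L)` (per the truth) while a
#' stimulus of concentration `L` is applied; activity maps linearly onto the
#' ratio scale between the two calibration levels; a multiplicative linear
#' drift `(1 + drift_slope * t)` and additive Gaussian noise are then
#' applied.
#'
#' @param truth A [fit_hill()]-like list (`A0`, `K_D`, `H`, `rho`).
#' @param stimuli Data frame with columns `time_on`, `time_off`, `conc_uM`
#'   (non-overlapping, sorted).
#' @param noise_sigma Additive ratio noise SD.
#' @param drift_slope Relative baseline drift per second.
#' @param dt Sampling interval (s, default 1).
#' @param t_end End of the recording (default: 60 s past the last stimulus).
#' @param ratio_act,ratio_inact Raw ratio levels at A = 1 and A = 0.
#' @param seed RNG seed.
#' @return List with `trace` (a [fret_trace()] whose events carry the
#'   add/remove annotations), `truth_activity` (noise-free activity per time
#'   point), and the calibration levels on the corrected scale
#'   (`cal_act`, `cal_inact`) as produced by [normalize_ratio()]'s
#'   normalisation of an ideal drift-free trace.
#' @export
generate_fret_trace <- function(truth, stimuli, noise_sigma = 0,
                                drift_slope = 0, dt = 1,
                                t_end = NULL, ratio_act = 1.05,
                                ratio_inact = 0.85, seed = 1) {
  stopifnot(all(c("time_on", "time_off", "conc_uM") %in% names(stimuli)),
            !is.unsorted(stimuli$time_on, strictly = TRUE),
            all(stimuli$time_off > stimuli$time_on))
  set.seed(seed)
  if (is.null(t_end)) t_end <- max(stimuli$time_off) + 60
  time <- seq(0, t_end, by = dt)
  A <- rep(truth$A0, length(time))
  for (i in seq_len(nrow(stimuli))) {
    on <- time >= stimuli$time_on[i] & time < stimuli$time_off[i]
    A[on] <- hill_activity(truth, stimuli$conc_uM[i])
  }
  clean <- ratio_inact + A * (ratio_act - ratio_inact)
  ratio <- clean * (1 + drift_slope * time) +
    stats::rnorm(length(time), 0, noise_sigma)
  events <- rbind(
    data.frame(time = stimuli$time_on, action = "add", compound = "MeAsp",
               conc_uM = stimuli$conc_uM),
    data.frame(time = stimuli$time_off, action = "remove", compound = "MeAsp",
               conc_uM = stimuli$conc_uM))
  events <- events[order(events$time), , drop = FALSE]
  r0 <- ratio_inact + truth$A0 * (ratio_act - ratio_inact)  # unstimulated level
  list(trace = fret_trace(time, pmax(ratio, 1e-6), events),
       truth_activity = A,
       cal_act = ratio_act / r0, cal_inact = ratio_inact / r0)
}

#' Generate replicate synthetic dose-response tables
#'
#' @param truth A Hill-truth list (`A0`, `K_D`, `H`, `rho`).
#' @param doses Concentrations (uM, positive).
#' @param noise_sigma Additive activity noise SD.
#' @param replicates Number of tables.
#' @param seed RNG seed.
#' @return List of `replicates` data frames (`conc_uM`, `activity`).
#' @export
generate_dose_response <- function(truth, doses, noise_sigma = 0.03,
                                   replicates = 1, seed = 1) {
  stopifnot(all(doses > 0))
  set.seed(seed)
  doses <- sort(doses)
  A <- hill_activity(truth, doses)
  lapply(seq_len(replicates), function(i)
    data.frame(conc_uM = doses,
               activity = A + stats::rnorm(length(doses), 0, noise_sigma)))
}

#' Generate synthetic tumbling-bias response data
#'
#' Draws per-cell tumbling biases at each concentration from a ground-truth
#' response model, emulating the per-trajectory biases measured by tracking a
#' population at homogeneous attractant levels. For a homogeneous truth, the
#' per-cell biases scatter around the model curve with Gaussian measurement
#' noise; for a heterogeneous truth, cells are drawn from the phenotype
#' distribution (measurement noise added on top).
#'
#' @param model Ground-truth response model.
#' @param conc Concentrations (uM, strictly increasing).
#' @param cells_per_conc Number of cells per concentration.
#' @param noise_sigma Per-cell measurement noise on the bias.
#' @param seed RNG seed.
#' @return A [tb_response_data()] with samples.
#' @export
generate_tb_response <- function(model, conc, cells_per_conc = 500,
                                 noise_sigma = 0.01, seed = 1) {
  set.seed(seed)
  samples <- lapply(conc, function(l) {
    tb <- if (inherits(model, "homogeneous_response"))
      rep(tumbling_bias(model, l), cells_per_conc)
    else
      tumbling_bias(model, l, sample_phenotypes(model, cells_per_conc))
    pmin(pmax(tb + stats::rnorm(cells_per_conc, 0, noise_sigma), 0), 1)
  })
  tb_response_data(conc, samples = samples)
}
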