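#' Separate swimmers from non-swimmers
#'
#' Applies the tracking pipeline's diffusivity criterion: trajectories
#' shorter than `min_duration` are discarded outright; the remainder are
#' classified as swimmers when the time-averaged positional variance per unit
#' time,
#' \deqn{(\langle (x-\langle x\rangle)^2\rangle + \langle (y-\langle
#'   y\rangle)^2\rangle) / T_i,}
#' exceeds `threshold` (default 0.61 um^2/s, chosen just above the diffusivity
#' of non-motile cells).
#'
#' @param tracks Trajectory data frame with columns `traj_id`, `frame`,
#'   `x_um`, `y_um` (e.g. from [read_trajectories()] or the `frames` element
#'   of a simulation).
#' @param frame_rate Acquisition rate (frames/s, default 50).
#' @param threshold Diffusivity criterion (um^2/s).
#' @param min_duration Minimum trajectory duration (s).
#' @return List with data frames `swimmers`, `non_swimmers`, `discarded`
#'   (the partition is exhaustive and disjoint) and `stats` (per-trajectory
#'   duration and diffusivity statistic).
#' @export
filter_swimmers <- function(tracks, frame_rate = 50, threshold = 0.61,
                            min_duration = 1) {
  check_tracks(tracks)
  ids <- unique(tracks$traj_id)
  sp <- split(tracks, factor(tracks$traj_id, levels = ids))
  stat <- vapply(sp, function(d) {
    Ti <- (nrow(d) - 1) / frame_rate
    v <- mean((d$x_um - mean(d$x_um))^2) + mean((d$y_um - mean(d$y_um))^2)
    c(Ti, if (Ti > 0) v / Ti else 0)
  }, numeric(2))
  stats <- data.frame(traj_id = ids, duration_s = stat[1, ],
                      diffusivity = stat[2, ])
  short <- stats$duration_s < min_duration
  swim <- !short & stats$diffusivity > threshold
  nsw <- !short & !swim
  list(swimmers = tracks[tracks$traj_id %in% ids[swim], , drop = FALSE],
       non_swimmers = tracks[tracks$traj_id %in% ids[nsw], , drop = FALSE],
       discarded = tracks[tracks$traj_id %in% ids[short], , drop = FALSE],
       stats = cbind(stats,
                     class = ifelse(short, "discarded",
                                    ifelse(swim, "swimmer", "non_swimmer"))))
}

check_tracks <- function(tracks) {
  need <- c("traj_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss) > 0)
    stop("trajectory table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(tracks$x_um)) || any(!is.finite(tracks$y_um)))
    stop("non-finite coordinates in trajectory table")
  invisible(tracks)
}

#' Sliding-window velocity and step-displacement annotation
#'
#' For each frame of each trajectory, fits the local linear model
#' `r(t') = r0 + v (t' - t)` by least squares over a 10-frame sliding window
#' and records the fitted velocity, together with the mean and
#' root-mean-square frame-to-frame displacement over the same window and the
#' residual variance of the fit (used downstream to estimate localisation
#' noise). The window is centered on the frame; frames within half a window
#' of either end reuse the nearest full window. Trajectories shorter than the
#' window are skipped and reported in the `skipped` attribute.
#'
#' @param tracks Trajectory data frame (`traj_id`, `frame`, `x_um`, `y_um`).
#' @param frame_rate Frames/s.
#' @param window Window width in frames (default 10).
#' @return Data frame with one row per annotated frame: `traj_id`, `frame`,
#'   `vx`, `vy`, `speed` (um/s), `dr_mean` (um, raw mean frame step),
#'   `dr_corr` (um, mean frame step debiased for localisation noise),
#'   `resid_var` (um^2, window fit residual variance) and `sigma2_hat`
#'   (um^2, the per-trajectory localisation-noise variance, the median of
#'   `resid_var` across windows). Attribute `skipped` lists trajectory ids
#'   too short to annotate.
#' @export
local_velocity <- function(tracks, frame_rate = 50, window = 10) {
  check_tracks(tracks)
  ids <- unique(tracks$traj_id)
  sp <- split(tracks, factor(tracks$traj_id, levels = ids))
  out <- vector("list", length(sp))
  skipped <- c()
  for (i in seq_along(sp)) {
    d <- sp[[i]]
    d <- d[order(d$frame), , drop = FALSE]
    ann <- annotate_one_track(d$x_um, d$y_um, frame_rate, window)
    if (is.null(ann)) { skipped <- c(skipped, ids[i]); next }
    out[[i]] <- cbind(data.frame(traj_id = d$traj_id, frame = d$frame), ann)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "frame_rate") <- frame_rate
  attr(res, "window") <- window
  res
}

# Least-squares window fits for one track, vectorised over windows via
# embed(). Window w covers frames w .. w+k-1; frame i maps to the window in
# which it sits centered (clamped at the track ends).
annotate_one_track <- function(x, y, f, k) {
  n <- length(x)
  if (n < k) return(NULL)
  tc <- ((0:(k - 1)) - (k - 1) / 2) / f      # centered window times (s)
  Stt <- sum(tc^2)
  wts <- rev(tc / Stt)                       # embed() reverses time order
  Xe <- stats::embed(x, k); Ye <- stats::embed(y, k)
  vx <- drop(Xe %*% wts); vy <- drop(Ye %*% wts)
  xbar <- rowMeans(Xe); ybar <- rowMeans(Ye)
  Sxx <- rowSums(Xe^2) - k * xbar^2
  Syy <- rowSums(Ye^2) - k * ybar^2
  rss <- pmax(Sxx - vx^2 * Stt, 0) + pmax(Syy - vy^2 * Stt, 0)
  resid_var <- rss / (2 * k - 4)
  sig2 <- stats::median(resid_var)          # per-trajectory noise variance
  d2 <- diff(x)^2 + diff(y)^2
  dr_mean <- rowMeans(stats::embed(sqrt(d2), k - 1))  # k-1 steps per window
  # per-step displacement debiased for localisation noise (a squared frame
  # step carries a 4 sigma^2 noise contribution), then window-averaged: keeps
  # the run/tumble self-normalisation of the raw mean while removing the
  # noise floor
  d_corr <- sqrt(pmax(d2 - 4 * sig2, 0))
  dr_corr <- rowMeans(stats::embed(d_corr, k - 1))
  nw <- n - k + 1
  wmap <- pmin(pmax(seq_len(n) - floor(k / 2) + 1L, 1L), nw)
  data.frame(vx = vx[wmap], vy = vy[wmap],
             speed = sqrt(vx[wmap]^2 + vy[wmap]^2),
             dr_mean = dr_mean[wmap], dr_corr = dr_corr[wmap],
             resid_var = resid_var[wmap], sigma2_hat = sig2)
}

#' Run/tumble segmentation by local ballisticity
#'
#' Labels each annotated frame `run` or `tumble` by thresholding the
#' normalized ballisticity \eqn{v_n(t)}, the ratio of the window-fitted speed
#' to the step-displacement speed `frame_rate * dr`; for straight
#' constant-speed motion \eqn{v_n = 1}, while during tumbles the fitted
#' velocity averages out and \eqn{v_n} drops. Frames with \eqn{v_n \ge}
#' `v_th` (default 0.785) are runs.
#'
#' With `noise_correct = TRUE` (default) the step displacement is debiased
#' for localisation noise before forming the ratio: the per-trajectory noise
#' variance `sigma^2` is estimated as the median across windows of the local
#' linear-fit residual variance, `4 sigma^2` (the noise contribution to a
#' squared frame-to-frame step) is subtracted from each squared step, and the
#' debiased steps are averaged over the window. Windows whose corrected step
#' displacement vanishes are assigned \eqn{v_n = 0} (tumble). With
#' noise-free input the correction vanishes and the raw ballisticity ratio is
#' recovered exactly.
#'
#' Detected tumble stretches shorter than `min_tumble_frames` are relabeled
#' as run: the sliding window smears any genuine pause or reorientation over
#' at least half a window of frames, so isolated 1-2 frame tumble labels are
#' threshold noise rather than resolvable events.
#'
#' @param annotation Output of [local_velocity()].
#' @param v_th Ballisticity threshold (dimensionless).
#' @param noise_correct Debias the step displacement for localisation noise.
#' @param min_tumble_frames Minimum believable tumble length in frames
#'   (default 3); shorter detected tumbles are relabeled run. Use 1 to keep
#'   raw labels.
#' @return List with `labels` (the annotation frame plus columns `vn` and
#'   `state`) and `segments` (one row per maximal constant-state stretch:
#'   `traj_id`, `state`, `start_frame`, `end_frame`, `n_frames`,
#'   `duration_s`, `dx_um`, `dy_um`), of class `motility_segmentation`.
#' @export
segment_motility <- function(annotation, v_th = 0.785, noise_correct = TRUE,
                             min_tumble_frames = 3) {
  f <- attr(annotation, "frame_rate")
  if (is.null(f)) stop("annotation must come from local_velocity()")
  ids <- unique(annotation$traj_id)
  sp <- split(annotation, factor(annotation$traj_id, levels = ids))
  lab <- vector("list", length(sp))
  seg <- vector("list", length(sp))
  for (i in seq_along(sp)) {
    a <- sp[[i]]
    drc <- if (noise_correct) a$dr_corr else a$dr_mean
    vn <- ifelse(drc > 1e-12, a$speed / (f * drc), 0)
    state <- ifelse(vn >= v_th, "run", "tumble")
    if (min_tumble_frames > 1) {
      r0 <- rle(state)
      r0$values[r0$values == "tumble" & r0$lengths < min_tumble_frames] <- "run"
      state <- inverse.rle(r0)
    }
    a$vn <- vn
    a$state <- state
    lab[[i]] <- a
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seg[[i]] <- data.frame(
      traj_id = a$traj_id[1], state = r$values,
      start_frame = a$frame[starts], end_frame = a$frame[ends],
      n_frames = r$lengths, duration_s = r$lengths / f,
      dx_um = NA_real_, dy_um = NA_real_)
  }
  labels <- do.call(rbind, lab)
  segments <- do.call(rbind, seg)
  rownames(labels) <- rownames(segments) <- NULL
  attr(labels, "frame_rate") <- f
  structure(list(labels = labels, segments = segments, frame_rate = f),
            class = "motility_segmentation")
}

# Attach net displacements to segments from the raw positions.
segment_displacements <- function(segmentation, tracks) {
  seg <- segmentation$segments
  key <- paste(tracks$traj_id, tracks$frame)
  i0 <- match(paste(seg$traj_id, seg$start_frame), key)
  i1 <- match(paste(seg$traj_id, seg$end_frame), key)
  seg$dx_um <- tracks$x_um[i1] - tracks$x_um[i0]
  seg$dy_um <- tracks$y_um[i1] - tracks$y_um[i0]
  seg
}

#' Tumbling-bias and run-speed summary of a segmented ensemble
#'
#' Computes the tumbling bias `t_tumble / (t_run + t_tumble)` per trajectory
#' (for distributions, weighted by trajectory duration) and pooled over the
#' whole ensemble by summing state occupancy times across trajectories, plus
#' the mean run speed over run-labeled frames.
#'
#' @param segmentation A [segment_motility()] result.
#' @return List of class `motility_summary`: `per_trajectory` (data frame
#'   `traj_id`, `n_frames`, `duration_s`, `tumbling_bias`, `mean_run_speed`),
#'   `pooled_tumbling_bias`, `mean_run_speed` (pooled over run frames), and
#'   `weights` (trajectory durations, for distribution work).
#' @export
summarize_motility <- function(segmentation) {
  stopifnot(inherits(segmentation, "motility_segmentation"))
  lab <- segmentation$labels
  f <- segmentation$frame_rate
  if (nrow(lab) == 0) stop("no labeled frames")
  ids <- unique(lab$traj_id)
  g <- factor(lab$traj_id, levels = ids)
  n_frames <- as.integer(table(g))
  tumble <- tapply(lab$state == "tumble", g, sum)
  runspeed <- tapply(ifelse(lab$state == "run", lab$speed, NA), g,
                     function(z) mean(z, na.rm = TRUE))
  per <- data.frame(traj_id = ids, n_frames = n_frames,
                    duration_s = n_frames / f,
                    tumbling_bias = as.numeric(tumble) / n_frames,
                    mean_run_speed = as.numeric(runspeed))
  run_frames <- lab$state == "run"
  structure(list(
    per_trajectory = per,
    pooled_tumbling_bias = sum(lab$state == "tumble") / nrow(lab),
    mean_run_speed = if (any(run_frames)) mean(lab$speed[run_frames]) else NaN,
    weights = per$duration_s), class = "motility_summary")
}

#' @export
print.motility_summary <- function(x, ...) {
  cat(sprintf("Motility summary over %d trajectories\n", nrow(x$per_trajectory)))
  cat(sprintf("  pooled tumbling bias = %.4f\n", x$pooled_tumbling_bias))
  cat(sprintf("  mean run speed = %.2f um/s\n", x$mean_run_speed))
  invisible(x)
}

#' Chemotactic drift velocity and chemotaxis bias
#'
#' Duration-weighted drift of an ensemble along the gradient axis (`+y` by
#' convention, positive towards high attractant):
#' `V_chem = sum(V_i T_i) / sum(T_i)` with `V_i` each trajectory's mean `y`
#' velocity, i.e. net `y` displacement over duration. The chemotaxis bias is
#' `V_chem` normalized by the mean run speed.
#'
#' @param tracks Trajectory data frame (`traj_id`, `frame`, `x_um`, `y_um`).
#' @param frame_rate Frames/s.
#' @param mean_run_speed Optional mean run speed (um/s) for the bias; from a
#'   [summarize_motility()] result.
#' @return List with `v_chem`, `sem`, `n` and (when a speed is given) `bias`.
#' @export
drift_and_bias <- function(tracks, frame_rate = 50, mean_run_speed = NULL) {
  check_tracks(tracks)
  ids <- unique(tracks$traj_id)
  sp <- split(tracks, factor(tracks$traj_id, levels = ids))
  per <- vapply(sp, function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    Ti <- (nrow(d) - 1) / frame_rate
    c(d$y_um[nrow(d)] - d$y_um[1], Ti)
  }, numeric(2))
  tab <- data.frame(v_y_um_s = per[1, ] / per[2, ], duration_s = per[2, ])
  est <- measure_drift(tab)
  out <- list(v_chem = est$drift, sem = est$sem, n = est$n)
  if (!is.null(mean_run_speed)) out$bias <- est$drift / mean_run_speed
  out
}

#' Directional run analysis
#'
#' Classifies run segments by their net-displacement direction relative to
#' the gradient axis, `alpha = acos(dy / sqrt(dx^2 + dy^2))` in `[0, pi]`:
#' runs with `alpha < pi/4` go up the gradient, runs with `alpha > 3*pi/4` go
#' down, and everything else (boundaries included) is transverse. Runs
#' shorter than `min_frames` are removed before classification; runs with
#' exactly zero net displacement are classed transverse and counted in
#' `n_zero_displacement`.
#'
#' @param segments Run/tumble segment table with displacement columns (from
#'   [segment_displacements()] or ground-truth segments); only rows with
#'   `state == "run"` are used.
#' @param min_frames Minimum run length in frames (default 5).
#' @return List with `runs` (kept runs plus `alpha`, `class`), `means` (mean
#'   run duration per class, s), `n` (runs per class) and
#'   `n_zero_displacement`.
#' @export
run_direction_analysis <- function(segments, min_frames = 5) {
  runs <- segments[segments$state == "run" &
                     segments$n_frames >= min_frames, , drop = FALSE]
  if (any(!is.finite(runs$dx_um)) || any(!is.finite(runs$dy_um)))
    stop("run segments need net displacements (see segment_displacements)")
  disp <- sqrt(runs$dx_um^2 + runs$dy_um^2)
  zero <- disp == 0
  alpha <- rep(NA_real_, nrow(runs))
  alpha[!zero] <- acos(pmin(pmax(runs$dy_um[!zero] / disp[!zero], -1), 1))
  cls <- rep("transverse", nrow(runs))
  cls[!zero & alpha < pi / 4] <- "up"
  cls[!zero & alpha > 3 * pi / 4] <- "down"
  runs$alpha <- alpha
  runs$class <- cls
  means <- tapply(runs$duration_s, factor(cls, levels = c("up", "down", "transverse")),
                  mean)
  list(runs = runs, means = means,
       n = table(factor(cls, levels = c("up", "down", "transverse"))),
       n_zero_displacement = sum(zero))
}

#' Spreading bias on gradient plates
#'
#' Ratio of the distances from the inoculation point to the edges of an
#' expanding colony facing up versus down the chemical gradient. For
#' replicate plates, returns the mean ratio, its standard error, and a
#' one-sided t test against 1 (no bias, alternative: biased up the gradient).
#'
#' @param d_up,d_down Distances (same units), one value per replicate,
#'   positive.
#' @return List with `ratio` (per replicate), `mean`, `sem` and `p_value`
#'   (NA when the test is degenerate, e.g. constant ratios or a single
#'   replicate).
#' @export
spreading_bias <- function(d_up, d_down) {
  if (length(d_up) != length(d_down)) stop("d_up and d_down lengths differ")
  if (any(d_down <= 0) || any(d_up <= 0)) stop("distances must be positive")
  ratio <- d_up / d_down
  n <- length(ratio)
  sem <- if (n > 1) stats::sd(ratio) / sqrt(n) else NA_real_
  p <- if (n > 1 && stats::sd(ratio) > 0)
    stats::t.test(ratio, mu = 1, alternative = "greater")$p.value
  else NA_real_
  list(ratio = ratio, mean = mean(ratio), sem = sem, p_value = p)
}

#' Full trajectory-analysis pipeline for one movie
#'
#' Convenience wrapper chaining [filter_swimmers()], [local_velocity()],
#' [segment_motility()], [summarize_motility()], [segment_displacements()]
#' and [drift_and_bias()] with the acquisition defaults (50 frames/s).
#'
#' @param tracks Trajectory data frame (`traj_id`, `frame`, `x_um`, `y_um`).
#' @param frame_rate Frames/s.
#' @param window,v_th,noise_correct,min_tumble_frames Segmentation
#'   parameters, see [local_velocity()] and [segment_motility()].
#' @param threshold,min_duration Swimmer-filter parameters.
#' @return List with `filter`, `segmentation`, `segments` (with
#'   displacements), `summary`, `drift`.
#' @export
track_summary <- function(tracks, frame_rate = 50, window = 10, v_th = 0.785,
                          noise_correct = TRUE, min_tumble_frames = 3,
                          threshold = 0.61, min_duration = 1) {
  fl <- filter_swimmers(tracks, frame_rate, threshold, min_duration)
  if (nrow(fl$swimmers) == 0) stop("no swimmer trajectories")
  ann <- local_velocity(fl$swimmers, frame_rate, window)
  seg <- segment_motility(ann, v_th, noise_correct, min_tumble_frames)
  segs <- segment_displacements(seg, fl$swimmers)
  sm <- summarize_motility(seg)
  dr <- drift_and_bias(fl$swimmers, frame_rate, sm$mean_run_speed)
  list(filter = fl, segmentation = seg, segments = segs, summary = sm,
       drift = dr)
}
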