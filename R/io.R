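#' Read a trajectory CSV
#'
#' Reads particle-tracking output with columns `traj_id`, `frame`, `x`, `y`
#' (or `x_um`, `y_um`), converts pixel coordinates to micrometres when
#' `unit = "px"` (default 0.7 um/px, the tracking pipeline's calibration),
#' sorts frames within trajectories, and splits trajectories at gaps in the
#' frame index into separate contiguous segments (new ids suffixed `.2`,
#' `.3`, ...; reported via a message).
#'
#' @param path CSV file path.
#' @param unit `"um"` or `"px"`.
#' @param pixel_size um per pixel (used when `unit = "px"`).
#' @param frame_rate Frames/s, stored as an attribute.
#' @return Data frame `traj_id`, `frame`, `t_s`, `x_um`, `y_um` with
#'   attribute `frame_rate`.
#' @export
read_trajectories <- function(path, unit = c("um", "px"), pixel_size = 0.7,
                              frame_rate = 50) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  d <- utils::read.csv(path)
  names(d)[names(d) == "x_um"] <- "x"
  names(d)[names(d) == "y_um"] <- "y"
  miss <- setdiff(c("traj_id", "frame", "x", "y"), names(d))
  if (length(miss) > 0)
    stop("trajectory CSV ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  if (!is.numeric(d$x) || !is.numeric(d$y))
    stop("non-numeric coordinates in ", path)
  if (anyDuplicated(d[c("traj_id", "frame")]) > 0)
    stop("duplicate (traj_id, frame) pairs in ", path)
  scale <- if (unit == "px") pixel_size else 1
  d <- d[order(d$traj_id, d$frame), , drop = FALSE]
  # split at frame-index gaps
  new_id <- as.character(d$traj_id)
  sp <- split(seq_len(nrow(d)), d$traj_id)
  n_split <- 0L
  for (idx in sp) {
    gaps <- c(0L, cumsum(diff(d$frame[idx]) != 1L))
    if (gaps[length(gaps)] > 0L) {
      n_split <- n_split + 1L
      new_id[idx] <- ifelse(gaps == 0L, new_id[idx],
                            paste0(new_id[idx], ".", gaps + 1L))
    }
  }
  if (n_split > 0)
    message(n_split, " trajectorie(s) split at frame gaps")
  out <- data.frame(traj_id = new_id, frame = d$frame,
                    t_s = d$frame / frame_rate,
                    x_um = d$x * scale, y_um = d$y * scale)
  rownames(out) <- NULL
  attr(out, "frame_rate") <- frame_rate
  out
}

#' Write a trajectory table to CSV
#'
#' @param tracks Data frame with at least `traj_id`, `frame`, `x_um`, `y_um`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(tracks, path) {
  check_tracks(tracks)
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis summary as JSON
#'
#' Serialises a (possibly nested) list of results; `NaN`/`NA` statistics are
#' written as explicit JSON nulls, never dropped. Numbers are written at full
#' precision.
#'
#' @param results Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON summary
#'
#' @param path File written by [write_summary()].
#' @return The parsed list.
#' @export
read_summary <- function(path) {
  if (!file.exists(path)) stop("summary file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Build a response model from a plain parameter list
#'
#' Maps the response-model block of a pipeline configuration onto a model
#' object: `list(kind = "homogeneous", tb0, tb_inf, K, H)` or
#' `list(kind = "heterogeneous", mu_K, sigma_K, rho, H_cell, basal = list(...))`.
#'
#' @param spec Named list as above.
#' @return A response model.
#' @export
model_from_spec <- function(spec) {
  if (is.null(spec$kind)) stop("response-model spec needs a 'kind'")
  if (spec$kind == "homogeneous")
    homogeneous_response(spec$tb0, spec$tb_inf, spec$K, spec$H)
  else if (spec$kind == "heterogeneous")
    heterogeneous_response(spec$mu_K, spec$sigma_K, spec$basal, spec$rho,
                           if (is.null(spec$H_cell)) 10 else spec$H_cell)
  else stop("unknown response-model kind: ", spec$kind)
}

# Rolling polynomial hash of a serialised R object; gives outputs a stable
# configuration fingerprint without external dependencies. The serialisation
# header (which embeds the R version) is skipped.
config_hash <- function(x) {
  bytes <- as.double(serialize(x, NULL, version = 2)[-(1:14)])
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the simulate -> trackstats pipeline from a configuration list
#'
#' Executes the end-to-end workflow: obtain trajectories (either generated by
#' the simulator via a `simulate` block or read from `tracks_file`), run the
#' trajectory-analysis pipeline, and optionally write the outputs (summary
#' JSON, run-segment CSV, per-trajectory CSV) under `out_dir`. Outputs carry
#' provenance (configuration hash, seed, package version) and the run is
#' deterministic for a fixed configuration and seed.
#'
#' @param config Named list with fields
#'   \describe{
#'     \item{seed}{integer seed (required).}
#'     \item{simulate}{optional list: `n`, `model` (see [model_from_spec()]),
#'       `gradient` (list `c_low`, `c_high`, `length`, `width`),
#'       `noise_sigma`, `frame_rate`, plus any [track_gen_spec()] field.}
#'     \item{tracks_file}{optional path to a trajectory CSV (with optional
#'       `unit`, `pixel_size`, `frame_rate`), used when `simulate` is absent.}
#'     \item{trackstats}{optional list of [track_summary()] arguments.}
#'     \item{out_dir}{optional output directory (created if needed).}
#'   }
#' @return List with `tracks`, `analysis` (the [track_summary()] bundle),
#'   `summary` (the written summary list) and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("pipeline config needs a seed")
  frame_rate <- 50
  if (!is.null(config$simulate)) {
    s <- config$simulate
    model <- if (inherits(s$model, "response_model")) s$model
             else model_from_spec(s$model)
    ch <- if (is.null(s$gradient)) gradient_channel()
          else gradient_channel(
            length = if (is.null(s$gradient$length)) 2000 else s$gradient$length,
            width = if (is.null(s$gradient$width)) 1000 else s$gradient$width,
            c_low = s$gradient$c_low, c_high = s$gradient$c_high)
    spec <- track_gen_spec(
      n = if (is.null(s$n)) 500 else s$n, model = model, channel = ch,
      frame_rate = if (is.null(s$frame_rate)) 50 else s$frame_rate,
      noise_sigma = if (is.null(s$noise_sigma)) 0.35 else s$noise_sigma,
      seed = config$seed)
    frame_rate <- spec$frame_rate
    tracks <- generate_tracks(spec)$tracks
  } else if (!is.null(config$tracks_file)) {
    frame_rate <- if (is.null(config$frame_rate)) 50 else config$frame_rate
    tracks <- read_trajectories(
      config$tracks_file,
      unit = if (is.null(config$unit)) "um" else config$unit,
      pixel_size = if (is.null(config$pixel_size)) 0.7 else config$pixel_size,
      frame_rate = frame_rate)
  } else stop("config needs either a 'simulate' block or a 'tracks_file'")

  ts_args <- c(list(tracks = tracks, frame_rate = frame_rate),
               config$trackstats)
  analysis <- do.call(track_summary, ts_args)

  provenance <- list(
    package = "chemodrift",
    version = as.character(utils::packageVersion("chemodrift")),
    seed = config$seed,
    config_hash = config_hash(config))
  summary <- list(
    provenance = provenance,
    n_swimmers = length(unique(analysis$filter$swimmers$traj_id)),
    n_non_swimmers = length(unique(analysis$filter$non_swimmers$traj_id)),
    n_discarded = length(unique(analysis$filter$discarded$traj_id)),
    pooled_tumbling_bias = analysis$summary$pooled_tumbling_bias,
    mean_run_speed_um_s = analysis$summary$mean_run_speed,
    v_chem_um_s = analysis$drift$v_chem,
    v_chem_sem_um_s = analysis$drift$sem,
    chemotaxis_bias = analysis$drift$bias)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_summary(summary, file.path(config$out_dir, "summary.json"))
    utils::write.csv(analysis$segments,
                     file.path(config$out_dir, "runs.csv"), row.names = FALSE)
    utils::write.csv(analysis$summary$per_trajectory,
                     file.path(config$out_dir, "per_trajectory.csv"),
                     row.names = FALSE)
  }
  list(tracks = tracks, analysis = analysis, summary = summary,
       provenance = provenance)
}
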