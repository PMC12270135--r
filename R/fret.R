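#' FRET trace container
#'
#' A FRET time series (YFP/CFP ratio, proportional to chemotaxis pathway
#' activity) together with its stimulus annotations.
#'
#' @param time Time points (s), strictly increasing.
#' @param ratio YFP/CFP ratios, positive.
#' @param events Data frame of stimulus annotations with columns `time` (s),
#'   `action` (`"add"` or `"remove"`), `compound`, `conc_uM`.
#' @return Object of class `fret_trace`.
#' @export
fret_trace <- function(time, ratio, events = NULL) {
  stopifnot(length(time) == length(ratio), !is.unsorted(time, strictly = TRUE),
            all(ratio > 0))
  if (is.null(events))
    events <- data.frame(time = numeric(), action = character(),
                         compound = character(), conc_uM = numeric())
  stopifnot(all(c("time", "action") %in% names(events)))
  structure(list(time = time, ratio = ratio, events = events),
            class = "fret_trace")
}

# Logical mask of time points at which no stimulus is active (before the
# first addition and between a removal and the next addition).
unstimulated_mask <- function(trace) {
  ev <- trace$events[order(trace$events$time), , drop = FALSE]
  active <- 0
  mask <- rep(TRUE, length(trace$time))
  if (nrow(ev) == 0) return(mask)
  bounds <- c(ev$time, Inf)
  state <- cumsum(ifelse(ev$action == "add", 1L, -1L))
  for (i in seq_len(nrow(ev))) {
    if (state[i] > 0)
      mask[trace$time >= ev$time[i] & trace$time < bounds[i + 1]] <- FALSE
  }
  mask
}

#' Baseline-correct and normalize a FRET trace
#'
#' Fits a polynomial baseline (default linear) to the unstimulated segments
#' of the trace, divides it out, and normalizes so that the first corrected
#' point equals 1, mirroring the usual correction "for the baseline drift,
#' normalized to the value at the beginning of the experiment".
#'
#' @param trace A [fret_trace()].
#' @param degree Polynomial order of the baseline, 0-2 (default 1).
#' @param min_baseline_points Minimum number of unstimulated points required.
#' @return The corrected `fret_trace` (same events), with the fitted baseline
#'   stored in attribute `baseline`.
#' @export
normalize_ratio <- function(trace, degree = 1, min_baseline_points = 10) {
  stopifnot(inherits(trace, "fret_trace"), degree %in% 0:2)
  mask <- unstimulated_mask(trace)
  if (sum(mask) < min_baseline_points)
    stop("no (or too short) unstimulated segment for baseline correction")
  df <- data.frame(t = trace$time[mask], r = trace$ratio[mask])
  fit <- if (degree == 0) stats::lm(r ~ 1, df) else
    stats::lm(r ~ stats::poly(t, degree, raw = TRUE), df)
  base <- as.numeric(stats::predict(fit, newdata = data.frame(t = trace$time)))
  if (any(base <= 0)) stop("fitted baseline crosses zero")
  corrected <- trace$ratio / base
  corrected <- corrected / corrected[1]
  out <- fret_trace(trace$time, corrected, trace$events)
  attr(out, "baseline") <- base
  out
}

#' Calibrated kinase activity from a corrected FRET trace
#'
#' Maps corrected YFP/CFP ratios linearly onto relative kinase activity using
#' two calibration levels measured on the same corrected scale: the ratio at
#' full activation (`A = 1`, e.g. under 300 uM NiCl2) and at full
#' inactivation (`A = 0`, e.g. under 100 uM MeAsp + 50 uM serine):
#' `A = (ratio - ratio_inact) / (ratio_act - ratio_inact)`. The mapping is
#' affine-invariant: rescaling the ratio scale together with the calibration
#' levels leaves `A` unchanged.
#'
#' In addition to the activity series, response amplitudes are computed for
#' each `add` event as the activity at the extremum of the initial ratio
#' change: the corrected ratio is averaged over `pre_points` samples before
#' the stimulus, the extremal excursion from that level within
#' `post_window` seconds after it is found, and both are mapped to activity.
#'
#' @param trace A corrected [fret_trace()] (see [normalize_ratio()]).
#' @param ratio_act Corrected ratio at full activation (A = 1).
#' @param ratio_inact Corrected ratio at full inactivation (A = 0).
#' @param pre_points Samples averaged before each stimulus (default 5).
#' @param post_window Search window after each stimulus (s, default 30).
#' @return List with `activity` (per time point), `responses` (data frame:
#'   one row per `add` event with `conc_uM`, `pre_activity`,
#'   `post_activity`), and the calibration levels.
#' @export
kinase_activity <- function(trace, ratio_act, ratio_inact, pre_points = 5,
                            post_window = 30) {
  stopifnot(inherits(trace, "fret_trace"))
  if (ratio_act == ratio_inact)
    stop("calibration levels equal: zero dynamic range")
  to_act <- function(r) (r - ratio_inact) / (ratio_act - ratio_inact)
  activity <- to_act(trace$ratio)
  adds <- trace$events[trace$events$action == "add", , drop = FALSE]
  responses <- NULL
  if (nrow(adds) > 0) {
    rows <- lapply(seq_len(nrow(adds)), function(i) {
      t0 <- adds$time[i]
      pre_idx <- utils::tail(which(trace$time < t0), pre_points)
      post_idx <- which(trace$time >= t0 & trace$time <= t0 + post_window)
      if (length(pre_idx) == 0 || length(post_idx) == 0) return(NULL)
      pre <- mean(trace$ratio[pre_idx])
      post <- trace$ratio[post_idx][which.max(abs(trace$ratio[post_idx] - pre))]
      data.frame(time = t0,
                 conc_uM = if ("conc_uM" %in% names(adds)) adds$conc_uM[i] else NA,
                 pre_activity = to_act(pre), post_activity = to_act(post))
    })
    responses <- do.call(rbind, rows)
  }
  list(activity = activity, responses = responses,
       ratio_act = ratio_act, ratio_inact = ratio_inact)
}

#' Fit a Hill dose-response curve to kinase activity data
#'
#' Nonlinear least squares of the dose dependence of relative kinase
#' activity. The wildtype form is
#' \deqn{A(L) = A_0 \left(1 - \frac{L^H}{L^H + K_D^H}\right)}
#' and the residual variant multiplies the Hill term by `(1 - rho)` so the
#' activity plateaus at `A0 * rho` at saturating attractant (accounting for
#' pathway activity that is not fully inhibited even by high attractant):
#' \deqn{A(L) = A_0 \left(1 - (1-\rho)\frac{L^H}{L^H + K_D^H}\right).}
#' At `L = K_D` the curve passes through `A0 (1 + rho) / 2`.
#'
#' Initialisation: `A0 = max(A)`, `K_D` = geometric mid-dose, `H = 1`,
#' `rho = min(A)/max(A)`; all parameters bounded positive, `rho` in [0, 1].
#' Flat activity data leaves `K_D` unidentifiable and is flagged.
#'
#' @param dose Data frame with columns `conc_uM` (strictly increasing,
#'   `>= 0`) and `activity`.
#' @param variant `"wildtype"` (`rho` fixed at 0) or `"residual"`.
#' @return Object of class `hill_fit`: list with `A0`, `K_D`, `H`, `rho`,
#'   `variant`, `residuals`, `converged`, `identifiable`.
#' @export
fit_hill <- function(dose, variant = c("wildtype", "residual")) {
  variant <- match.arg(variant)
  stopifnot(all(c("conc_uM", "activity") %in% names(dose)))
  dose <- dose[order(dose$conc_uM), , drop = FALSE]
  if (nrow(dose) < 4) stop("need at least 4 doses")
  if (diff(range(dose$activity)) < 1e-4)
    return(structure(list(A0 = mean(dose$activity), K_D = NA_real_,
                          H = NA_real_, rho = NA_real_, variant = variant,
                          residuals = dose$activity - mean(dose$activity),
                          converged = FALSE, identifiable = FALSE),
                     class = "hill_fit"))
  pos <- dose$conc_uM[dose$conc_uM > 0]
  start <- list(A0 = max(dose$activity),
                K_D = exp(mean(log(range(pos)))), H = 1)
  df <- data.frame(L = dose$conc_uM, A = dose$activity)
  if (variant == "wildtype") {
    fit <- try(minpack.lm::nlsLM(
      A ~ A0 * (1 - L^H / (L^H + K_D^H)), data = df, start = start,
      lower = c(A0 = 1e-8, K_D = 1e-8, H = 0.05),
      upper = c(A0 = 10, K_D = 1e9, H = 25),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  } else {
    start$rho <- min(max(min(dose$activity), 0) / max(dose$activity), 0.9)
    fit <- try(minpack.lm::nlsLM(
      A ~ A0 * (1 - (1 - rho) * L^H / (L^H + K_D^H)), data = df, start = start,
      lower = c(A0 = 1e-8, K_D = 1e-8, H = 0.05, rho = 0),
      upper = c(A0 = 10, K_D = 1e9, H = 25, rho = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }
  if (inherits(fit, "try-error"))
    return(structure(list(A0 = NA_real_, K_D = NA_real_, H = NA_real_,
                          rho = NA_real_, variant = variant, residuals = NULL,
                          converged = FALSE, identifiable = TRUE),
                     class = "hill_fit"))
  p <- as.list(stats::coef(fit))
  structure(list(A0 = p$A0, K_D = p$K_D, H = p$H,
                 rho = if (variant == "wildtype") 0 else p$rho,
                 variant = variant, residuals = stats::residuals(fit),
                 converged = TRUE, identifiable = TRUE),
            class = "hill_fit")
}

#' Evaluate a Hill fit
#'
#' @param fit A [fit_hill()] result (or a list with `A0`, `K_D`, `H`, `rho`).
#' @param L Concentration(s), uM.
#' @return Predicted activity.
#' @export
hill_activity <- function(fit, L) {
  rho <- if (is.null(fit$rho)) 0 else fit$rho
  fit$A0 * (1 - (1 - rho) * (1 - hill_factor(L, fit$K_D, fit$H)))
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill dose-response fit (%s form)\n", x$variant))
  if (!x$identifiable) {
    cat("  flat activity data: K_D unidentifiable\n")
    return(invisible(x))
  }
  cat(sprintf("  A0 = %.4g, K_D = %.4g uM, H = %.3g, rho = %.3g\n",
              x$A0, x$K_D, x$H, x$rho))
  invisible(x)
}
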