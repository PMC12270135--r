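#' Homogeneous tumbling-bias response model
#'
#' Population-level Hill-type dependence of the tumbling bias on the ambient
#' attractant concentration. Every cell is assumed identical:
#' \deqn{TB(L) = TB_\infty + (TB_0 - TB_\infty)\,\frac{K_r^{H_r}}{L^{H_r} + K_r^{H_r}}}
#' so the bias falls from the basal value `tb0` at \eqn{L = 0} to the residual
#' value `tb_inf` at saturating attractant, with half-response concentration
#' `K` and Hill exponent `H`.
#'
#' @param tb0 Basal tumbling bias at zero attractant, in `[0, 1]`.
#' @param tb_inf Residual tumbling bias at saturating attractant,
#'   `0 <= tb_inf <= tb0`.
#' @param K Half-response concentration (uM), positive.
#' @param H Hill exponent, positive.
#' @return An object of class `c("homogeneous_response", "response_model")`.
#' @seealso [heterogeneous_response()], [tumbling_bias()], [fit_response_model()]
#' @export
#' @examples
#' m <- homogeneous_response(tb0 = 0.25, tb_inf = 0.05, K = 30, H = 1.5)
#' tumbling_bias(m, L = c(0, 30, 1e6))
homogeneous_response <- function(tb0, tb_inf, K, H) {
  stopifnot(is.numeric(tb0), is.numeric(tb_inf), is.numeric(K), is.numeric(H),
            length(tb0) == 1, length(tb_inf) == 1, length(K) == 1, length(H) == 1)
  if (tb_inf < 0 || tb0 > 1 || tb_inf > tb0)
    stop("need 0 <= tb_inf <= tb0 <= 1")
  if (K <= 0) stop("K must be positive")
  if (H <= 0) stop("H must be positive")
  if (tb0 >= 1 - 1e-6)
    stop("tb0 >= 1 - 1e-6: run->tumble switching rate undefined at TB = 1")
  structure(list(tb0 = tb0, tb_inf = tb_inf, K = K, H = H),
            class = c("homogeneous_response", "response_model"))
}

#' Heterogeneous tumbling-bias response model
#'
#' Population model in which each cell responds sharply to attractant but at a
#' cell-specific threshold. Cell \eqn{i} carries a basal bias \eqn{TB_{0,i}}
#' drawn from a basal-bias distribution and a sensitivity \eqn{K_i} drawn from
#' a log-normal distribution, and responds as
#' \deqn{TB_i(L) = \rho\,TB_{0,i} + (1-\rho)\,TB_{0,i}\,
#'   \frac{K_i^{H_c}}{L^{H_c} + K_i^{H_c}}}
#' with a shared residual fraction `rho` (so even at saturating attractant a
#' cell keeps a fraction `rho` of its basal bias) and a steep cell-level Hill
#' exponent `H_cell`. Population-averaged responses are obtained by averaging
#' over the phenotype distribution, which makes the population curve much
#' shallower than any individual cell's.
#'
#' @param mu_K Mean of `log(K)` for the log-normal sensitivity distribution
#'   (K in uM).
#' @param sigma_K Standard deviation of `log(K)`, positive.
#' @param basal Basal-bias distribution: either
#'   `list(kind = "beta", a = , b = )` or
#'   `list(kind = "empirical", sample = <numeric vector of biases>)`.
#' @param rho Shared residual fraction in `[0, 1]`.
#' @param H_cell Cell-level Hill exponent (default 10; large values approach a
#'   step response).
#' @return An object of class `c("heterogeneous_response", "response_model")`.
#' @export
heterogeneous_response <- function(mu_K, sigma_K, basal, rho, H_cell = 10) {
  stopifnot(length(mu_K) == 1, length(sigma_K) == 1, length(rho) == 1)
  if (sigma_K < 0) stop("sigma_K must be >= 0")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (H_cell <= 0) stop("H_cell must be positive")
  if (!is.list(basal) || is.null(basal$kind))
    stop("basal must be list(kind = \"beta\", a, b) or list(kind = \"empirical\", sample)")
  if (basal$kind == "beta") {
    if (is.null(basal$a) || is.null(basal$b) || basal$a <= 0 || basal$b <= 0)
      stop("beta basal distribution needs positive shape parameters a and b")
  } else if (basal$kind == "empirical") {
    s <- basal$sample
    if (is.null(s) || !is.numeric(s) || length(s) < 1 ||
        any(!is.finite(s)) || any(s < 0) || any(s > 1))
      stop("empirical basal sample must be biases in [0, 1]")
  } else stop("unknown basal kind: ", basal$kind)
  structure(list(mu_K = mu_K, sigma_K = sigma_K, basal = basal, rho = rho,
                 H_cell = H_cell),
            class = c("heterogeneous_response", "response_model"))
}

#' @export
print.homogeneous_response <- function(x, ...) {
  cat("Homogeneous tumbling-bias response\n")
  cat(sprintf("  TB0 = %.4g, TBinf = %.4g, K = %.4g uM, H = %.3g\n",
              x$tb0, x$tb_inf, x$K, x$H))
  invisible(x)
}

#' @export
print.heterogeneous_response <- function(x, ...) {
  cat("Heterogeneous tumbling-bias response\n")
  cat(sprintf("  log-normal K: mu_K = %.4g, sigma_K = %.4g (median K = %.4g uM)\n",
              x$mu_K, x$sigma_K, exp(x$mu_K)))
  if (x$basal$kind == "beta")
    cat(sprintf("  basal TB ~ Beta(%.4g, %.4g)\n", x$basal$a, x$basal$b))
  else
    cat(sprintf("  basal TB: empirical sample of %d cells\n",
                length(x$basal$sample)))
  cat(sprintf("  residual fraction rho = %.4g, cell Hill H_c = %.3g\n",
              x$rho, x$H_cell))
  invisible(x)
}

# Hill occupancy K^H / (L^H + K^H), computed as 1 / (1 + (L/K)^H) so large L
# cannot overflow. Vectorised over L and K jointly.
hill_factor <- function(L, K, H) {
  1 / (1 + (L / K)^H)
}

#' Tumbling bias of a phenotype at a given attractant concentration
#'
#' Evaluates the concentration -> tumbling-bias mapping of a response model.
#' For a homogeneous model the phenotype argument is ignored; for a
#' heterogeneous model a phenotype data frame (columns `tb0`, `K`) from
#' [sample_phenotypes()] must be supplied, and `L` is recycled against its
#' rows.
#'
#' @param model A [homogeneous_response()] or [heterogeneous_response()].
#' @param L Attractant concentration(s), uM, `>= 0`.
#' @param phenotype Phenotype data frame for heterogeneous models.
#' @return Numeric vector of tumbling biases in `[0, 1]`, non-increasing in `L`.
#' @export
tumbling_bias <- function(model, L, phenotype = NULL) {
  stopifnot(all(L >= 0))
  UseMethod("tumbling_bias")
}

#' @export
tumbling_bias.homogeneous_response <- function(model, L, phenotype = NULL) {
  model$tb_inf + (model$tb0 - model$tb_inf) * hill_factor(L, model$K, model$H)
}

#' @export
tumbling_bias.heterogeneous_response <- function(model, L, phenotype = NULL) {
  if (is.null(phenotype) || is.null(phenotype$tb0) || is.null(phenotype$K))
    stop("heterogeneous model requires a phenotype with tb0 and K")
  phenotype$tb0 * (model$rho + (1 - model$rho) *
                     hill_factor(L, phenotype$K, model$H_cell))
}

#' Draw cell phenotypes from a response model
#'
#' Samples per-cell parameters from the phenotype distribution of a response
#' model. For the homogeneous model the distribution is degenerate: every cell
#' is identical and only the swimming speed can vary. For the heterogeneous
#' model each cell gets a basal bias and a log-normal sensitivity. Cells whose
#' basal bias would make the run-to-tumble switching rate undefined
#' (`tb0 >= 1 - 1e-6`) are rejected and redrawn.
#'
#' @param model A response model.
#' @param n Number of cells.
#' @param speed Mean run speed (um/s, default 25).
#' @param speed_sd Standard deviation of per-cell run speed; when positive,
#'   speeds are drawn from a normal distribution truncated at zero.
#' @return Data frame with `n` rows and columns `speed`, plus `tb0`, `K`
#'   for heterogeneous models. Uses the current RNG state.
#' @export
sample_phenotypes <- function(model, n, speed = 25, speed_sd = 0) {
  stopifnot(n >= 1)
  sp <- if (speed_sd > 0) {
    s <- stats::rnorm(n, speed, speed_sd)
    while (any(s <= 0)) s[s <= 0] <- stats::rnorm(sum(s <= 0), speed, speed_sd)
    s
  } else rep(speed, n)
  if (inherits(model, "homogeneous_response"))
    return(data.frame(phenotype_id = seq_len(n), speed = sp))
  tb0 <- draw_basal(model$basal, n)
  bad <- tb0 >= 1 - 1e-6
  while (any(bad)) {
    tb0[bad] <- draw_basal(model$basal, sum(bad))
    bad <- tb0 >= 1 - 1e-6
  }
  K <- stats::rlnorm(n, model$mu_K, model$sigma_K)
  data.frame(phenotype_id = seq_len(n), speed = sp, tb0 = tb0, K = K)
}

draw_basal <- function(basal, n) {
  if (basal$kind == "beta") stats::rbeta(n, basal$a, basal$b)
  else sample(basal$sample, n, replace = TRUE)
}

#' Population-averaged tumbling bias predicted by a heterogeneous model
#'
#' Monte-Carlo average of the cell-level response over the phenotype
#' distribution, returning both the population mean and the sampled
#' distribution of biases at each concentration. At `L = 0` the Hill factor is
#' 1 for every cell, so the predicted distribution is the basal-bias
#' distribution itself.
#'
#' @param model A [heterogeneous_response()].
#' @param L Attractant concentration(s), uM.
#' @param n_mc Number of Monte-Carlo phenotypes (`>= 1000`).
#' @return List with `mean` (numeric, one per concentration), `se`
#'   (Monte-Carlo standard error of each mean) and `samples` (list of numeric
#'   vectors of cell biases, one per concentration).
#' @export
predict_population_tb <- function(model, L, n_mc = 10000) {
  stopifnot(inherits(model, "heterogeneous_response"), n_mc >= 1000)
  ph <- sample_phenotypes(model, n_mc)
  samples <- lapply(L, function(l) tumbling_bias(model, l, ph))
  list(mean = vapply(samples, mean, 0),
       se = vapply(samples, function(s) stats::sd(s) / sqrt(length(s)), 0),
       samples = samples)
}

# Deterministic quantile-grid prediction of the per-concentration TB
# distribution under a heterogeneous model: evaluates the response on the
# outer product of basal and sensitivity quantiles, giving smooth decile
# predictions for optimisation. Used by the heterogeneous fit.
predict_tb_quantile_grid <- function(mu_K, sigma_K, a, b, rho, H_cell, L,
                                     probs = seq(0.1, 0.9, by = 0.1),
                                     m_basal = 64, m_K = 64) {
  pb <- (seq_len(m_basal) - 0.5) / m_basal
  pk <- (seq_len(m_K) - 0.5) / m_K
  tb0 <- stats::qbeta(pb, a, b)
  K <- stats::qlnorm(pk, mu_K, sigma_K)
  lapply(L, function(l) {
    h <- hill_factor(l, K, H_cell)          # length m_K
    tb <- outer(tb0, rho + (1 - rho) * h)   # m_basal x m_K
    list(mean = mean(tb),
         deciles = stats::quantile(tb, probs, names = FALSE, type = 7))
  })
}

#' Container for measured tumbling-bias response data
#'
#' Bundles the population-mean tumbling bias measured at a series of
#' attractant concentrations, optionally with the per-cell (per-trajectory)
#' tumbling-bias samples at each concentration needed to fit the
#' heterogeneous model.
#'
#' @param conc Attractant concentrations (uM), non-negative and strictly
#'   increasing.
#' @param mean_tb Population-mean tumbling bias at each concentration
#'   (computed from `samples` when omitted).
#' @param samples Optional list (one element per concentration) of numeric
#'   vectors of per-cell tumbling biases.
#' @return Object of class `tb_response_data`.
#' @export
tb_response_data <- function(conc, mean_tb = NULL, samples = NULL) {
  stopifnot(all(conc >= 0), !is.unsorted(conc, strictly = TRUE))
  if (is.null(mean_tb)) {
    if (is.null(samples)) stop("provide mean_tb or samples")
    mean_tb <- vapply(samples, mean, 0)
  }
  stopifnot(length(mean_tb) == length(conc), all(mean_tb >= 0), all(mean_tb <= 1))
  if (!is.null(samples)) stopifnot(length(samples) == length(conc))
  structure(list(conc = conc, mean_tb = mean_tb, samples = samples),
            class = "tb_response_data")
}

#' Fit a tumbling-bias response model to measured data
#'
#' Homogeneous fits use nonlinear least squares of the population Hill curve
#' on the mean biases. Heterogeneous fits minimise the summed squared
#' difference between the nine deciles of the predicted and observed
#' tumbling-bias distributions across concentrations, over the sensitivity
#' log-normal parameters, the residual fraction and the Beta basal-bias
#' parameters; the cell-level Hill exponent is held fixed (it is barely
#' identifiable from decile data and its exact value matters little once the
#' cell response is much sharper than the population's).
#'
#' Flat data (no concentration dependence) leaves the half-response
#' concentration unidentifiable; such fits are flagged via
#' `identifiable = FALSE` instead of silently returning a model.
#'
#' @param data A [tb_response_data()].
#' @param kind `"homogeneous"` or `"heterogeneous"`.
#' @param H_cell Fixed cell-level Hill exponent for heterogeneous fits.
#' @param control Optimiser control list passed to [stats::optim()]
#'   (heterogeneous fits only).
#' @return List with elements `model` (the fitted response model), `kind`,
#'   `converged`, `identifiable`, `residuals` (per-concentration mean-bias
#'   residuals), and for heterogeneous fits `objective` (final decile
#'   distance).
#' @export
fit_response_model <- function(data, kind = c("homogeneous", "heterogeneous"),
                               H_cell = 10, control = list(maxit = 2000)) {
  stopifnot(inherits(data, "tb_response_data"))
  kind <- match.arg(kind)
  flat <- diff(range(data$mean_tb)) < 1e-3
  if (kind == "homogeneous") fit_response_homogeneous(data, flat)
  else fit_response_heterogeneous(data, flat, H_cell, control)
}

fit_response_homogeneous <- function(data, flat) {
  if (length(data$conc) < 4)
    stop("homogeneous fit needs at least 4 concentrations")
  if (flat) {
    return(list(model = NULL, kind = "homogeneous", converged = FALSE,
                identifiable = FALSE, residuals = data$mean_tb - mean(data$mean_tb)))
  }
  df <- data.frame(L = data$conc, tb = data$mean_tb)
  start <- list(tb0 = max(df$tb), tb_inf = max(min(df$tb), 1e-4),
                K = max(stats::median(df$L[df$L > 0]), 1), H = 1)
  fit <- try(minpack.lm::nlsLM(
    tb ~ tb_inf + (tb0 - tb_inf) / (1 + (L / K)^H),
    data = df, start = start,
    lower = c(tb0 = 1e-6, tb_inf = 0, K = 1e-6, H = 0.05),
    upper = c(tb0 = 1 - 1e-6, tb_inf = 1, K = 1e9, H = 25),
    control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(model = NULL, kind = "homogeneous", converged = FALSE,
                identifiable = TRUE, residuals = NULL))
  }
  p <- as.list(stats::coef(fit))
  p$tb_inf <- min(p$tb_inf, p$tb0)  # guard against roundoff crossing
  model <- homogeneous_response(p$tb0, p$tb_inf, p$K, p$H)
  list(model = model, kind = "homogeneous", converged = TRUE,
       identifiable = TRUE,
       residuals = data$mean_tb - tumbling_bias(model, data$conc))
}

fit_response_heterogeneous <- function(data, flat, H_cell, control) {
  if (is.null(data$samples))
    stop("heterogeneous fit needs per-concentration tumbling-bias samples")
  if (flat) {
    return(list(model = NULL, kind = "heterogeneous", converged = FALSE,
                identifiable = FALSE, residuals = NULL))
  }
  probs <- seq(0.1, 0.9, by = 0.1)
  obs <- lapply(data$samples, stats::quantile, probs = probs, names = FALSE)
  # start values: basal distribution from the lowest-concentration sample by
  # Beta method of moments; rho from the high/low mean-bias ratio; K from the
  # concentration range.
  s0 <- pmin(pmax(data$samples[[1]], 1e-4), 1 - 1e-4)
  mb <- mean(s0); vb <- max(stats::var(s0), 1e-6)
  common <- max(mb * (1 - mb) / vb - 1, 0.1)
  a0 <- max(mb * common, 0.05); b0 <- max((1 - mb) * common, 0.05)
  rho0 <- min(max(min(data$mean_tb) / max(data$mean_tb), 0.02), 0.9)
  pos <- data$conc[data$conc > 0]
  muK0 <- log(stats::median(pos))
  theta0 <- c(mu_K = muK0, log_sigma_K = log(0.7),
              logit_rho = stats::qlogis(rho0), log_a = log(a0), log_b = log(b0))
  objective <- function(theta) {
    mu_K <- theta[1]; sigma_K <- exp(theta[2])
    rho <- stats::plogis(theta[3]); a <- exp(theta[4]); b <- exp(theta[5])
    pred <- predict_tb_quantile_grid(mu_K, sigma_K, a, b, rho, H_cell,
                                     data$conc, probs)
    sum(vapply(seq_along(pred),
               function(i) sum((pred[[i]]$deciles - obs[[i]])^2), 0))
  }
  opt <- stats::optim(theta0, objective, method = "Nelder-Mead",
                      control = control)
  th <- opt$par
  model <- heterogeneous_response(
    mu_K = th[1], sigma_K = exp(th[2]),
    basal = list(kind = "beta", a = exp(th[4]), b = exp(th[5])),
    rho = stats::plogis(th[3]), H_cell = H_cell)
  pred <- predict_tb_quantile_grid(model$mu_K, model$sigma_K,
                                   model$basal$a, model$basal$b,
                                   model$rho, H_cell, data$conc, probs)
  list(model = model, kind = "heterogeneous",
       converged = opt$convergence == 0, identifiable = TRUE,
       residuals = data$mean_tb - vapply(pred, function(p) p$mean, 0),
       objective = opt$value)
}

#' Hour-scale adaptation update of the concentration memory
#'
#' Advances the slow adaptation variable `m` (a concentration memory, uM) one
#' Euler step towards the locally sensed concentration:
#' `m' = m + dt * (L_local - m) / tau_adapt`. The effective concentration the
#' response model then sees is `max(L_local - m, 0)`, so a cell exposed to a
#' constant attractant level for times much longer than `tau_adapt` gradually
#' recovers its basal tumbling bias. `tau_adapt = Inf` disables adaptation
#' (`m` is left unchanged).
#'
#' @param m Current memory (uM, `>= 0`); vectorised.
#' @param L_local Locally sensed concentration (uM, `>= 0`).
#' @param dt Time step (s).
#' @param tau_adapt Adaptation time constant (s, `> 0`, possibly `Inf`).
#' @return Updated memory `m'`.
#' @export
update_adaptation <- function(m, L_local, dt, tau_adapt) {
  stopifnot(tau_adapt > 0, dt > 0)
  if (!is.finite(tau_adapt)) return(m)
  m + dt * (L_local - m) / tau_adapt
}

#' Reference response models for the evolved adaptation-deficient strain
#'
#' Canonical parameter sets representing the tumbling-bias response of an
#' evolved, adaptation-deficient (delta-cheR) strain to MeAsp: a basal bias
#' around 0.25 falling to a residual bias around 0.05 at saturating
#' attractant, with half-response near 30 uM. The heterogeneous counterpart
#' matches the homogeneous population mean at both extremes (broad Beta basal
#' distribution with mean 0.25; residual fraction 0.2; log-normal sensitivity
#' with median 30 uM) while individual cells respond much more sharply
#' (`H_cell = 10`).
#'
#' @return Named list with elements `homogeneous` and `heterogeneous`.
#' @export
r1_response_models <- function() {
  list(
    homogeneous = homogeneous_response(tb0 = 0.25, tb_inf = 0.05,
                                       K = 30, H = 1.5),
    heterogeneous = heterogeneous_response(
      mu_K = log(30), sigma_K = 1,
      basal = list(kind = "beta", a = 1.2, b = 3.6),
      rho = 0.2, H_cell = 10)
  )
}
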