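test_that("homogeneous Hill response hits its anchor points", {
  m <- homogeneous_response(tb0 = 0.25, tb_inf = 0.05, K = 30, H = 1.5)
  expect_equal(tumbling_bias(m, 0), 0.25)
  expect_equal(tumbling_bias(m, 30), (0.25 + 0.05) / 2)   # midpoint at L = K
  expect_equal(tumbling_bias(m, 1e12), 0.05, tolerance = 1e-6)
  # midpoint holds for any Hill exponent
  for (H in c(0.5, 1, 2, 8)) {
    mh <- homogeneous_response(0.3, 0.1, 50, H)
    expect_equal(tumbling_bias(mh, 50), 0.2)
  }
})

test_that("response curves are monotone non-increasing and within [0, 1]", {
  set.seed(1)
  L <- c(0, 10^seq(-1, 4, length.out = 40))
  for (i in 1:20) {
    tb0 <- runif(1, 0.05, 0.9); tbi <- runif(1, 0, tb0)
    m <- homogeneous_response(tb0, tbi, 10^runif(1, 0, 3), runif(1, 0.3, 6))
    tb <- tumbling_bias(m, L)
    expect_true(all(diff(tb) <= 1e-12))
    expect_true(all(tb >= 0 & tb <= 1))
  }
  het <- r1_test_models$heterogeneous
  ph <- sample_phenotypes(het, 50)
  for (j in 1:50) {
    tb <- tumbling_bias(het, L, ph[rep(j, length(L)), ])
    expect_true(all(diff(tb) <= 1e-12))
    expect_true(all(tb >= 0 & tb <= 1))
  }
})

test_that("degenerate heterogeneous model collapses to the homogeneous formula", {
  rho <- 0.2; tb0 <- 0.25; K <- 30; Hc <- 10
  het <- heterogeneous_response(mu_K = log(K), sigma_K = 1e-12,
                                basal = list(kind = "empirical", sample = tb0),
                                rho = rho, H_cell = Hc)
  hom <- homogeneous_response(tb0 = tb0, tb_inf = rho * tb0, K = K, H = Hc)
  ph <- sample_phenotypes(het, 5)
  L <- c(0, 1, 10, 30, 100, 1000)
  for (l in L)
    expect_equal(tumbling_bias(het, l, ph),
                 rep(tumbling_bias(hom, l), 5), tolerance = 1e-9)
})

test_that("population-mean prediction matches quadrature over the phenotype measure", {
  het <- r1_test_models$heterogeneous
  a <- het$basal$a; b <- het$basal$b
  quad_mean <- function(L) {
    e_hill <- if (L == 0) 1 else
      integrate(function(k) 1 / (1 + (L / k)^het$H_cell) *
                  dlnorm(k, het$mu_K, het$sigma_K), 0, Inf,
                rel.tol = 1e-10)$value
    (a / (a + b)) * (het$rho + (1 - het$rho) * e_hill)
  }
  set.seed(7)
  pred <- predict_population_tb(het, c(0, 10, 30, 100, 1000), n_mc = 1e5)
  expected <- vapply(c(0, 10, 30, 100, 1000), quad_mean, 0)
  expect_true(all(abs(pred$mean - expected) < 3 * pred$se))
  # at L = 0 the prediction is the basal-bias distribution itself
  expect_equal(pred$mean[1], mean(pred$samples[[1]]))
  expect_true(abs(pred$mean[1] - a / (a + b)) < 3 * pred$se[1])
})

test_that("adaptation memory relaxes exponentially and switches off at tau = Inf", {
  tau <- 100; L <- 50; dt <- 0.01
  m <- 0
  for (i in seq_len(tau / dt)) m <- update_adaptation(m, L, dt, tau)  # t = tau
  expect_equal(m, L * (1 - exp(-1)), tolerance = 1e-3)
  expect_equal(update_adaptation(0, 50, 0.02, Inf), 0)
  expect_equal(update_adaptation(3, 50, 0.02, Inf), 3)
})

test_that("homogeneous fit recovers known parameters from noisy means", {
  truth <- homogeneous_response(0.25, 0.05, 30, 1.5)
  conc <- c(0, 5, 15, 30, 60, 120, 500, 3000)
  set.seed(11)
  err <- replicate(11, {
    tb <- tumbling_bias(truth, conc) + rnorm(length(conc), 0, 0.01)
    fit <- fit_response_model(tb_response_data(conc, mean_tb = pmax(tb, 0)),
                              "homogeneous")
    expect_true(fit$converged)
    expect_true(fit$identifiable)
    vapply(c("tb0", "tb_inf", "K", "H"),
           function(p) abs(fit$model[[p]] - truth[[p]]) / abs(truth[[p]]), 0)
  })
  expect_true(all(apply(err, 1, median) < 0.15))
})

test_that("flat tumbling-bias data is flagged unidentifiable, not fitted", {
  conc <- c(0, 10, 100, 1000)
  flat <- tb_response_data(conc, mean_tb = rep(0.2, 4))
  fit <- fit_response_model(flat, "homogeneous")
  expect_false(fit$identifiable)
  expect_null(fit$model)
  flat_het <- tb_response_data(conc, mean_tb = rep(0.2, 4),
                               samples = replicate(4, rep(0.2, 50),
                                                   simplify = FALSE))
  fit2 <- fit_response_model(flat_het, "heterogeneous")
  expect_false(fit2$identifiable)
})

test_that("heterogeneous fit recovers sensitivity hyperparameters", {
  truth <- r1_test_models$heterogeneous
  data <- generate_tb_response(truth,
                               conc = c(0, 1, 3, 10, 30, 100, 300, 1000, 3000),
                               cells_per_conc = 500, noise_sigma = 0.01,
                               seed = 5)
  fit <- fit_response_model(data, "heterogeneous", H_cell = truth$H_cell)
  expect_true(fit$identifiable)
  expect_lt(abs(fit$model$mu_K - truth$mu_K) / abs(truth$mu_K), 0.2)
  expect_lt(abs(fit$model$sigma_K - truth$sigma_K) / truth$sigma_K, 0.2)
})

test_that("invalid response parameters are rejected", {
  expect_error(homogeneous_response(0.2, 0.3, 10, 1), "tb_inf")
  expect_error(homogeneous_response(0.2, 0.1, -1, 1), "K")
  expect_error(homogeneous_response(1, 0.1, 10, 1))
  expect_error(heterogeneous_response(1, -0.1, list(kind = "beta", a = 1, b = 1), 0.2))
  expect_error(heterogeneous_response(1, 1, list(kind = "beta", a = 1, b = 1), 1.2))
  expect_error(tumbling_bias(r1_test_models$heterogeneous, 10), "phenotype")
})
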