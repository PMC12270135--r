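#!/usr/bin/env Rscript
# Fit the homogeneous and heterogeneous tumbling-bias response models to a
# synthetic stand-in for the measured dose dependence of the evolved
# adaptation-deficient strain's tumbling bias on MeAsp, and export the fitted
# curves and parameters. The synthetic data are drawn from the package's
# reference R1-like heterogeneous model, so the heterogeneous fit is also a
# self-consistency (parameter recovery) check.

suppressMessages(library(chemodrift))
dir.create("results", showWarnings = FALSE)
set.seed(1)

truth <- r1_response_models()$heterogeneous
conc <- c(0, 1, 3, 10, 30, 100, 300, 1000, 3000)
message("generating per-cell tumbling-bias samples at ", length(conc),
        " MeAsp concentrations (500 cells each) ...")
data <- generate_tb_response(truth, conc, cells_per_conc = 500,
                             noise_sigma = 0.01, seed = 1)

hom <- fit_response_model(data, "homogeneous")
het <- fit_response_model(data, "heterogeneous", H_cell = truth$H_cell)

message("homogeneous fit:")
print(hom$model)
message("heterogeneous fit (truth: mu_K = ", round(truth$mu_K, 3),
        ", sigma_K = ", truth$sigma_K, "):")
print(het$model)

grid <- 10^seq(-1, 4, length.out = 60)
pred_het <- predict_population_tb(het$model, grid, n_mc = 20000)
curves <- data.frame(
  conc_uM = grid,
  tb_homogeneous = tumbling_bias(hom$model, grid),
  tb_heterogeneous = pred_het$mean)
write.csv(curves, "results/response_curves.csv", row.names = FALSE)
write.csv(data.frame(conc_uM = data$conc, mean_tb = data$mean_tb),
          "results/response_data_means.csv", row.names = FALSE)

write_summary(list(
  homogeneous = hom$model[c("tb0", "tb_inf", "K", "H")],
  heterogeneous = list(mu_K = het$model$mu_K, sigma_K = het$model$sigma_K,
                       rho = het$model$rho, H_cell = het$model$H_cell,
                       basal_a = het$model$basal$a, basal_b = het$model$basal$b),
  heterogeneous_truth = list(mu_K = truth$mu_K, sigma_K = truth$sigma_K,
                             rho = truth$rho),
  converged = list(homogeneous = hom$converged, heterogeneous = het$converged)),
  "results/response_fits.json")
message("wrote results/response_fits.json, results/response_curves.csv")
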