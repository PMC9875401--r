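#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis: 1000 joint draws from the declared
# parameter distributions (beta for probabilities/utilities, gamma for
# costs, lognormal for ratios). Writes the incremental scatter
# (results/psa_scatter.csv, one row per draw, for a cost-effectiveness
# plane), the acceptability curve (results/ceac.csv) and a summary.

library(icmcea)

seed <- 2026
params <- load_parameters(base_case_bundle())
n <- param_value(params, "structural.psa_samples")
psa <- run_psa(params, n = n, seed = seed)

dir.create("results", showWarnings = FALSE)
write.csv(psa$samples, "results/psa_scatter.csv", row.names = FALSE)
cc <- ceac(psa, seq(0, 250000, by = 5000))
write.csv(cc, "results/ceac.csv", row.names = FALSE)

summ <- list(
  n = psa$n, n_failed = psa$n_failed, seed = seed,
  mean_icer = psa$mean_icer,
  means = as.list(psa$means),
  cri_95 = psa$cri_95,
  prob_ce_50k = cc$prob_cost_effective[cc$threshold == 50000],
  prob_ce_150k = cc$prob_cost_effective[cc$threshold == 150000])
jsonlite::write_json(summ, "results/psa_summary.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("PSA: %d draws (seed %d, %d failed).\n", psa$n, seed, psa$n_failed))
cat(sprintf("  mean ICER (ratio of mean increments): $%s/QALY\n",
            formatC(psa$mean_icer, format = "d", big.mark = ",")))
cat(sprintf("  incremental cost  95%% CrI: $%s to $%s\n",
            formatC(psa$cri_95$delta_cost[1], format = "d", big.mark = ","),
            formatC(psa$cri_95$delta_cost[2], format = "d", big.mark = ",")))
cat(sprintf("  incremental QALYs 95%% CrI: %.3f to %.3f\n",
            psa$cri_95$delta_qaly[1], psa$cri_95$delta_qaly[2]))
cat(sprintf("  P(cost-effective): %.0f%% at $50k/QALY, %.0f%% at $150k/QALY\n",
            100 * summ$prob_ce_50k, 100 * summ$prob_ce_150k))
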