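#!/usr/bin/env Rscript

# Step 2 -- sequential population PK/PD estimation.
#
# Individual PK parameters are fixed at their empirical-Bayes (MAP) values
# under the two-compartment population PK model with allometric body-weight
# scaling; then the population PD parameters of the PASI turnover model
# (kout, Imax, the IIV of kout and the residual log-SD, with IC50 fixed at
# 0.07 mg/L and the B2 baseline method) are estimated by marginal maximum
# likelihood. A prediction-corrected VPC checks the fitted model.

suppressPackageStartupMessages(library(utkmipd))

res_dir <- "results"
cohort <- read_event_csv(file.path(res_dir, "cohort.csv"))

pk_pop <- pk_population()
pk_ind <- map_cohort_pk(cohort, pk_pop)
blq <- sum(vapply(pk_ind, `[[`, integer(1), "n_blq"))
cat(sprintf("MAP PK estimation done for %d patients (%d BLQ samples excluded)\n",
            length(pk_ind), blq))

fit <- fit_population_pd(cohort, pk_ind, seed = 20240102)
print(fit)

est <- fit$estimates
jsonlite::write_json(
  list(estimates = est, rse_percent = as.list(fit$rse),
       objective = fit$objective),
  file.path(res_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
write.csv(fit$eb, file.path(res_dir, "individual_pd.csv"), row.names = FALSE)

model_hat <- pop_model(pk = pk_pop, kout_pop = est$kout_pop,
                       Imax_pop = est$Imax_pop, IC50 = est$IC50,
                       omega_kout = est$omega_kout, sigma_pd = est$sigma_pd)
v <- pcvpc(model_hat, cohort, pk_ind, n_sim = 200, bins = 4, seed = 20240103)
write.csv(v$table, file.path(res_dir, "pcvpc_pd.csv"), row.names = FALSE)
inside <- with(v$table, mean(observed >= sim_lo & observed <= sim_hi))
cat(sprintf("pcVPC: %.0f%% of observed percentiles inside their simulated bands\n",
            100 * inside))
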