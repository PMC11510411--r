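#!/usr/bin/env Rscript

# Step 3 -- individual conditional distributions.
#
# For each patient, the conditional distribution p(psi_i | y_i) of the
# individual parameters is sampled by random-walk Metropolis-Hastings
# (burn-in 500, thinning 10), and 100 clones -- complete individual
# parameter vectors -- are retained to carry parameter uncertainty into the
# dosing simulations.

suppressPackageStartupMessages(library(utkmipd))

res_dir <- "results"
cohort <- read_event_csv(file.path(res_dir, "cohort.csv"))
fitj <- jsonlite::read_json(file.path(res_dir, "fit.json"), simplifyVector = TRUE)

pk_pop <- pk_population()
pk_ind <- map_cohort_pk(cohort, pk_pop)
est <- fitj$estimates
model_hat <- pop_model(pk = pk_pop, kout_pop = est$kout_pop,
                       Imax_pop = est$Imax_pop, IC50 = est$IC50,
                       omega_kout = est$omega_kout, sigma_pd = est$sigma_pd)

clones <- clone_cohort(cohort, model_hat, pk_ind, n_draws = 100,
                       master_seed = 20240104)
write.csv(as.data.frame(clones), file.path(res_dir, "clones.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(master_seed = 20240104, burn = attr(clones, "burn"),
       thin = attr(clones, "thin"),
       accept_rate = as.list(round(attr(clones, "accept_rate"), 3))),
  file.path(res_dir, "clones_meta.json"), auto_unbox = TRUE)

rates <- attr(clones, "accept_rate")
cat(sprintf("sampled 100 clones for %d patients\n", length(cohort)))
cat(sprintf("acceptance rates: median %.2f, range %.2f-%.2f\n",
            median(rates), min(rates), max(rates)))
cat(sprintf("kout uncertainty per patient (CV of clone kout): median %.0f%%\n",
            100 * median(tapply(clones$kout, clones$id,
                                function(x) sd(x) / mean(x)))))
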