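#!/usr/bin/env Rscript

# Step 5 -- drug-cost arithmetic of the selected regimens.
#
# Per-dose price of the 45 mg pre-filled syringe: EUR 2915.4. The first
# treatment year counts induction doses at weeks 0 and 4 followed by
# maintenance spacing; later years count floor(52/interval) doses. The
# labelled maintenance regimen (q12w) serves as the comparator: moving a
# patient from q12w to q16w drops one maintenance dose per year, a 25%
# saving.

suppressPackageStartupMessages(library(utkmipd))

res_dir <- "results"
price <- 2915.4
decisions <- read.csv(file.path(res_dir, "decisions.csv"))

ref <- annual_cost(regimen(45, 16), price = price, year = "first")
cat(sprintf("45 mg q16w, first year: %d doses, EUR %.1f\n", ref$n_doses, ref$cost))
cat(sprintf("maintenance saving q12w -> q16w: %.0f%%\n",
            cost_saving(regimen(45, 12), regimen(45, 16))))

rows <- lapply(seq_len(nrow(decisions)), function(i) {
  cur <- parse_regimen(decisions$current[i])[[1]]
  sel <- if (is.na(decisions$selected[i])) NULL
         else parse_regimen(decisions$selected[i])[[1]]
  c_cur <- annual_cost(cur, price = price, year = "maintenance")
  c_sel <- if (is.null(sel)) list(n_doses = NA_integer_, cost = NA_real_)
           else annual_cost(sel, price = price, year = "maintenance")
  data.frame(id = decisions$id[i], classification = decisions$classification[i],
             current = decisions$current[i], selected = decisions$selected[i],
             doses_current = c_cur$n_doses, doses_selected = c_sel$n_doses,
             cost_current = c_cur$cost, cost_selected = c_sel$cost,
             saving_pct = if (is.null(sel)) NA_real_ else cost_saving(cur, sel))
})
costs <- do.call(rbind, rows)
write.csv(costs, file.path(res_dir, "cost_impact.csv"), row.names = FALSE)

ok <- !is.na(costs$cost_selected)
cat(sprintf("cohort maintenance-year drug cost (decided patients): EUR %.0f -> EUR %.0f (%+.1f%%)\n",
            sum(costs$cost_current[ok]), sum(costs$cost_selected[ok]),
            100 * (sum(costs$cost_selected[ok]) / sum(costs$cost_current[ok]) - 1)))
cat(sprintf("patients with a cost saving: %d; with added cost: %d\n",
            sum(costs$saving_pct > 0, na.rm = TRUE),
            sum(costs$saving_pct < 0, na.rm = TRUE)))
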