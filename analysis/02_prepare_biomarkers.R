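#!/usr/bin/env Rscript
# Step 2 — construct biomarker intake estimates from the raw records.
#
# Applies the completeness rules (missed voids, PABA recovery), converts
# urinary nitrogen to protein (81% excretion, Kjeldahl 6.25) and potassium
# excretion to intake (80%), calibrates the sucrose + fructose sugar
# biomarker for age and sex, computes TEE = (REE + AEE)/0.9 with the >5%
# weight-change exclusion, and summarizes first-visit geometric means with
# nutrient densities (biomarker densities over TEE).
#
# Reads results/ from step 1; writes results/prepared_urine.tsv,
# results/prepared_energy.tsv, results/table2_geometric_means.tsv.

suppressPackageStartupMessages(library(dietvalid))

out_dir <- "results"
urine <- utils::read.table(file.path(out_dir, "urine_records.tsv"),
                           header = TRUE, sep = "\t", comment.char = "#")
energy <- utils::read.table(file.path(out_dir, "energy_records.tsv"),
                            header = TRUE, sep = "\t", comment.char = "#")
covs <- utils::read.table(file.path(out_dir, "covariates.tsv"),
                          header = TRUE, sep = "\t", comment.char = "#")

up <- prepare_urine_records(urine, covs, mode = "main")
ep <- prepare_energy_records(energy)
write_cohort(up, file.path(out_dir, "prepared_urine.tsv"))
write_cohort(ep, file.path(out_dir, "prepared_energy.tsv"))

cat(sprintf("Urine collections: %d, excluded (>=2 missed voids): %d.\n",
            nrow(up), sum(up$paba_status == "excluded")))
cat(sprintf("Energy records excluded for >5%% weight change: %d of %d.\n",
            sum(ep$tee_excluded), nrow(ep)))

first <- up[up$occasion == 1L & up$paba_status != "excluded", ]
tee1 <- ep$tee[ep$occasion == 1L][match(first$participant_id,
                                        ep$participant_id[ep$occasion == 1L])]
rows <- list()
gm_row <- function(label, values) {
  g <- geometric_mean_ci(values[!is.na(values) & values > 0])
  data.frame(measure = label, n = g$n,
             geometric_mean = round_half_up(g$geometric_mean, 2),
             ci_lo = round_half_up(g$ci[1], 2),
             ci_hi = round_half_up(g$ci[2], 2))
}
rows[["p"]] <- gm_row("protein_biomarker_g", first$protein_biomarker)
rows[["k"]] <- gm_row("potassium_biomarker_g", first$potassium_biomarker)
rows[["t"]] <- gm_row("tee_MJ", ep$tee[ep$occasion == 1L])
rows[["pd"]] <- gm_row("protein_density_g_per_MJ",
                       nutrient_density(first$protein_biomarker, tee1))
rows[["kd"]] <- gm_row("potassium_density_g_per_MJ",
                       nutrient_density(first$potassium_biomarker, tee1))
tab <- do.call(rbind, rows)
write_cohort(tab, file.path(out_dir, "table2_geometric_means.tsv"))
cat("First-visit biomarker geometric means:\n")
print(tab, row.names = FALSE)
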