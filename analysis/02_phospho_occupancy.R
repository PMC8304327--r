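#!/usr/bin/env Rscript
# Phosphosite occupancy from the simulated PRM experiment: fragment areas ->
# peptide H/L ratios -> (x, y, z) triplets -> per-replicate occupancies ->
# per-site summaries with a CM vs intracellular comparison, co-occupancy
# bounds and phosphate stoichiometry.  Run analysis/01_simulate_assays.R
# first.

suppressMessages(library(hsp90cl))
in_dir <- "results/synthetic"
out_dir <- "results/occupancy"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

transitions <- read_transition_report(file.path(in_dir, "prm_transitions.tsv"))
quants <- peptide_areas_from_transitions(transitions)
z_tbl <- protein_reference_ratio(
  quants[quants$modified_sequence %in% cl_normalization_peptides(), ])
triplets <- assemble_ratio_triplets(quants, cl_peptide_panel(), z_tbl)
est <- occupancy_from_triplets(triplets)
write_result_tsv(est, file.path(out_dir, "occupancy_estimates.tsv"))

est$group <- est$sample_id
summary <- summarize_and_compare(est, comparison = "intracellular")
write_result_tsv(summary, file.path(out_dir, "occupancy_summary.tsv"))

message("Per-peptide occupancy (mean +/- sd, %):")
for (i in seq_len(nrow(summary))) {
  message(sprintf("  %-22s %-5s %-14s %5.1f%% +/- %4.1f  adj p = %s",
                  summary$site_id[i], summary$variant[i], summary$group[i],
                  100 * summary$mean_occ[i], 100 * summary$sd_occ[i],
                  ifelse(is.na(summary$adj_p[i]), "NA",
                         sprintf("%.3g", summary$adj_p[i]))))
}

# co-occupancy window and stoichiometry from the intracellular marginals
per_site <- tapply(est$occ_light[est$valid & est$group == "intracellular"],
                   est$site_id[est$valid & est$group == "intracellular"], mean)
b <- co_occupancy_bounds(per_site[["S226"]], per_site[["S255"]])
stoich <- phosphate_stoichiometry(per_site)
co_tbl <- data.frame(
  quantity = c("occ_S226", "occ_S255", "both_sites_lower", "both_sites_upper",
               "both_sites_independent", "mol_phosphate_per_mol"),
  value = c(per_site[["S226"]], per_site[["S255"]], b$lower, b$upper,
            b$independent, stoich))
write_result_tsv(co_tbl, file.path(out_dir, "co_occupancy.tsv"))
message(sprintf(paste0("Doubly phosphorylated monomers: %.0f%% (independent",
                       " %.1f%%) to %.0f%%; %.2f mol phosphate/mol protein"),
                100 * b$lower, 100 * b$independent, 100 * b$upper, stoich))
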