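#!/usr/bin/env Rscript
# Forward-simulates every assay of the study at its design conditions and
# writes the input tables (in the same TSV/CSV dialects the readers consume)
# plus machine-readable ground truth under results/synthetic/.
#
# Conditions simulated:
#   * SILAC/PRM occupancy: S226 and S255 at 95% occupancy in the light
#     (native) channel, near-complete dephosphorylation (1%) in the heavy
#     reference, 3 replicates; plus a conditioned-medium-like sample with
#     lower occupancy (S255 -10%, S226 -2.5%).
#   * co-IP interactome: label-free 3 conditions x 6 replicates; SILAC 4
#     replicates with most true interactors binding more to the AA mutant.
#   * limited proteolysis: full-length fractions 35%/10% (WT) and 22%/6%
#     (AA) at 7 and 14 ng/uL trypsin, cleavage at K607.
#   * secretion CWB: secreted fractions 1.6% (WT) and 4.5% (AA) over a 3%
#     accidental-release baseline.

suppressMessages(library(hsp90cl))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed")) == 1) args[i + 1] else 1)
out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("Simulating PRM occupancy experiment (intracellular + CM-like) ...")
intra <- simulate_prm_experiment(
  prm_truth(p_light = c(S226 = 0.95, S255 = 0.95), q_heavy = 0.01, sigma = 0.05),
  sample_id = "intracellular", seed = seed)
cm <- simulate_prm_experiment(
  prm_truth(p_light = c(S226 = 0.925, S255 = 0.85), q_heavy = 0.01, sigma = 0.05),
  sample_id = "CM", seed = seed + 1)
write_transition_report(rbind(intra$transitions, cm$transitions),
                        file.path(out_dir, "prm_transitions.tsv"))
truth <- rbind(cbind(sample_id = "intracellular", intra$truth),
               cbind(sample_id = "CM", cm$truth))
write_result_tsv(truth, file.path(out_dir, "prm_truth.tsv"))

message("Simulating label-free and SILAC co-IP protein-group tables ...")
lf <- simulate_coip_tables(
  coip_truth(n_background = 250, n_true = 50, enrichment_log2 = 4, sigma = 0.5),
  mode = "labelfree", seed = seed)
write_protein_groups(lf$groups, file.path(out_dir, "coip_labelfree_proteinGroups.tsv"))
write_result_tsv(lf$design, file.path(out_dir, "coip_labelfree_design.tsv"))
write_result_tsv(lf$truth, file.path(out_dir, "coip_labelfree_truth.tsv"))

# most interactors bind more to AA (negative WT-vs-AA shift); one
# CACYBP-like exception prefers the phosphorylated WT
shift <- c(rep(-0.5, 35), rep(0, 14), 0.5)
sl <- simulate_coip_tables(
  coip_truth(n_background = 33, n_true = 50, wt_aa_shift_log2 = shift,
             sigma = 0.1),
  mode = "silac", seed = seed)
write_protein_groups(sl$groups, file.path(out_dir, "coip_silac_proteinGroups.tsv"))
write_result_tsv(sl$design, file.path(out_dir, "coip_silac_design.tsv"))
write_result_tsv(sl$truth, file.path(out_dir, "coip_silac_truth.tsv"))

message("Simulating limited-proteolysis band intensities ...")
lp <- simulate_proteolysis_bands(sigma = 0.05, seed = seed)
utils::write.csv(lp$bands, file.path(out_dir, "proteolysis_bands.csv"),
                 row.names = FALSE)
write_result_tsv(lp$truth, file.path(out_dir, "proteolysis_truth.tsv"))

message("Simulating secretion CWB signals ...")
cwb <- simulate_cwb_signals(secreted = c(WT = 0.016, AA = 0.045),
                            baseline = 0.03, sigma = 0.1, seed = seed)
utils::write.csv(cwb$measurements, file.path(out_dir, "cwb_secretion.csv"),
                 row.names = FALSE)
write_result_tsv(cwb$truth, file.path(out_dir, "cwb_truth.tsv"))

write_provenance(file.path(out_dir, "provenance.txt"), seed,
                 config = list(step = "01_simulate_assays"))
message("Done: synthetic inputs written to ", out_dir)
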