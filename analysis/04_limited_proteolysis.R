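#!/usr/bin/env Rscript
# Limited-proteolysis conformational readouts from the simulated gel-band
# peptide intensities: full-length fraction remaining per trypsin dose with a
# WT vs AA comparison, and band-A/lane ratios grouped by side of the K607
# cleavage site.  Run analysis/01_simulate_assays.R first.

suppressMessages(library(hsp90cl))
in_dir <- "results/synthetic"
out_dir <- "results/proteolysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

bands <- read_band_matrix(file.path(in_dir, "proteolysis_bands.csv"),
                          protein_length = 724)

## full-length fraction remaining --------------------------------------------
ffl <- fraction_full_length(bands)
write_result_tsv(ffl, file.path(out_dir, "fraction_full_length.tsv"))
med <- stats::aggregate(ratio ~ genotype + dose, ffl, stats::median)
message("Median full-length fraction remaining (band A vs dose 0):")
for (i in order(med$dose, med$genotype)) {
  message(sprintf("  %-3s dose %2.0f ng/uL: %4.0f%%",
                  med$genotype[i], med$dose[i], 100 * med$ratio[i]))
}
cmp <- compare_genotypes(ffl[ffl$dose > 0, ], group_col = "genotype",
                         levels = c("WT", "AA"))
write_result_tsv(cmp, file.path(out_dir, "wt_vs_aa.tsv"))
message("WT vs AA (Welch t on per-peptide ratios, BH across doses):")
for (i in seq_len(nrow(cmp))) {
  message(sprintf("  dose %2.0f: WT %4.1f%% vs AA %4.1f%%, adj p = %.2g",
                  cmp$dose[i], 100 * cmp$mean_1[i], 100 * cmp$mean_2[i],
                  cmp$adj_p[i]))
}

## band-A / lane ratios by side of the cleavage site --------------------------
bvl <- band_vs_lane_ratio(bands)
bvl <- assign_cleavage_side(bvl, site = 607)
write_result_tsv(bvl, file.path(out_dir, "band_vs_lane.tsv"))
side_cmp <- compare_genotypes(bvl[bvl$side != "spanning" & bvl$dose > 0, ],
                              group_col = "side",
                              levels = c("before", "after"))
write_result_tsv(side_cmp, file.path(out_dir, "before_vs_after_k607.tsv"))
message("Band-A/lane ratio, peptides before vs after K607 (signed difference):")
for (i in seq_len(nrow(side_cmp))) {
  message(sprintf("  dose %2.0f: before %4.2f, after %4.2f, diff %+.2f, adj p = %.2g",
                  side_cmp$dose[i], side_cmp$mean_1[i], side_cmp$mean_2[i],
                  side_cmp$diff[i], side_cmp$adj_p[i]))
}
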