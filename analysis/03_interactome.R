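#!/usr/bin/env Rscript
# Differential AP-MS interactome analysis of the simulated co-IP tables:
#  - label-free (iBAQ): QC/count/presence filters, control-only imputation,
#    bait-condition vs control t-tests with BH, specific-interactor calls
#    (adj p < 0.05 and mean log2 difference >= 3);
#  - SILAC (H/L): filters, bait normalization, one-sample tests of the
#    WT-vs-AA ratios, regulated-interactor calls;
#  - hypergeometric over-representation of annotation terms among the
#    AA-enriched interactors.
# Run analysis/01_simulate_assays.R first.

suppressMessages(library(hsp90cl))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(i <- which(args == "--seed")) == 1) args[i + 1] else 1)
in_dir <- "results/synthetic"
out_dir <- "results/interactome"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

read_design <- function(path) {
  d <- utils::read.delim(path)
  d$is_control <- as.logical(d$is_control)
  d
}

## label-free specificity analysis -------------------------------------------
groups <- read_protein_groups(file.path(in_dir, "coip_labelfree_proteinGroups.tsv"))
design <- read_design(file.path(in_dir, "coip_labelfree_design.tsv"))
kept <- filter_protein_groups(groups, design, mode = "labelfree")
message(nrow(groups), " protein groups; ", nrow(kept), " pass QC filters (",
        nrow(attr(kept, "removed")), " removed)")
write_result_tsv(attr(kept, "removed"), file.path(out_dir, "labelfree_removed.tsv"))

mat <- quant_matrix(kept, design, mode = "labelfree")
imp <- impute_controls(mat, design, seed = seed)
message(sum(imp$imputed), " missing control cells imputed")
calls <- call_interactors(imp$mat, design, mode = "labelfree",
                          bait_condition = "WT", exclude = "BAIT_HSP90AB1")
write_result_tsv(calls, file.path(out_dir, "labelfree_calls.tsv"))
truth <- utils::read.delim(file.path(in_dir, "coip_labelfree_truth.tsv"))
tp <- sum(calls$specific & calls$group_id %in% truth$group_id[truth$is_true_interactor])
message(sum(calls$specific), " specific interactors called (", tp,
        " of 50 simulated true interactors recovered)")

## SILAC WT-vs-AA analysis ----------------------------------------------------
sgroups <- read_protein_groups(file.path(in_dir, "coip_silac_proteinGroups.tsv"))
sdesign <- read_design(file.path(in_dir, "coip_silac_design.tsv"))
skept <- filter_protein_groups(sgroups, sdesign, mode = "silac")
smat <- quant_matrix(skept, sdesign, mode = "silac")
snorm <- bait_normalize(smat, "BAIT_HSP90AB1")
scalls <- call_interactors(snorm, sdesign, mode = "silac",
                           exclude = "BAIT_HSP90AB1")
write_result_tsv(scalls, file.path(out_dir, "silac_calls.tsv"))
# volcano-ready table: mean log2 H/L (WT/AA) vs -log10 adjusted p
volcano <- data.frame(group_id = scalls$group_id,
                      mean_log2_hl = scalls$mean_log2_diff,
                      neg_log10_adj_p = -log10(scalls$adj_p))
write_result_tsv(volcano, file.path(out_dir, "silac_volcano.tsv"))
message(sum(scalls$regulated), " regulated interactors (",
        sum(scalls$direction == "up_in_AA"), " stronger in AA, ",
        sum(scalls$direction == "up_in_WT"), " stronger in WT)")

## annotation over-representation among AA-enriched interactors ---------------
background <- scalls$group_id
hits <- scalls$group_id[scalls$regulated & scalls$mean_log2_diff < 0]
struth <- utils::read.delim(file.path(in_dir, "coip_silac_truth.tsv"))
annotations <- list(
  chaperone_machine = struth$group_id[struth$is_true_interactor &
                                        !is.na(struth$wt_aa_shift_log2) &
                                        struth$wt_aa_shift_log2 < 0],
  unshifted_interactors = struth$group_id[struth$is_true_interactor &
                                            !is.na(struth$wt_aa_shift_log2) &
                                            struth$wt_aa_shift_log2 == 0],
  background_set = struth$group_id[!struth$is_true_interactor]
)
annotations <- lapply(annotations, intersect, background)
enr <- enrichment_test(hits, background, annotations)
write_result_tsv(enr, file.path(out_dir, "enrichment.tsv"))
message("Annotation over-representation among AA-enriched interactors:")
for (i in seq_len(nrow(enr))) {
  message(sprintf("  %-22s GeneRatio %d/%d  adj p = %.3g",
                  enr$term[i], enr$k[i], enr$K[i], enr$adj_p[i]))
}

write_provenance(file.path(out_dir, "provenance.txt"), seed,
                 config = list(step = "03_interactome"))
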