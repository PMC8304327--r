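toy_groups <- function() {
  ids <- c("keep", "few_unique", "decoy", "patchy")
  g <- tibble::tibble(
    group_id = ids,
    protein_ids = ids,
    gene_names = ids,
    reverse = c(FALSE, FALSE, TRUE, FALSE),
    contaminant = FALSE, only_by_site = FALSE,
    unique_peptides = c(2L, 1L, 4L, 3L),
    peptides = c(4L, 4L, 6L, 5L),
    msms_count = c(6L, 6L, 9L, 8L)
  )
  design <- coip_design("labelfree", n_replicates = 6)
  for (j in seq_len(nrow(design))) {
    g[[paste0("ibaq_", design$sample[j])]] <- 2^25
    g[[paste0("idtype_", design$sample[j])]] <- TRUE
  }
  # "patchy": identified in only 5 of 6 replicates of every condition
  for (cond in unique(design$condition)) {
    first <- design$sample[design$condition == cond][1]
    g[[paste0("idtype_", first)]][4] <- FALSE
  }
  list(groups = g, design = design)
}

test_that("count, decoy and presence filters reproduce hand-computed decisions", {
  toy <- toy_groups()
  kept <- filter_protein_groups(toy$groups, toy$design, mode = "labelfree")
  expect_equal(kept$group_id, "keep")
  removed <- attr(kept, "removed")
  expect_equal(removed$reason[removed$group_id == "few_unique"], "unique_peptides")
  expect_equal(removed$reason[removed$group_id == "decoy"], "decoy")
  expect_equal(removed$reason[removed$group_id == "patchy"], "presence")
})

test_that("filters handle empty tables and the stricter SILAC presence rule", {
  toy <- toy_groups()
  empty <- toy$groups[0, ]
  expect_equal(nrow(filter_protein_groups(empty, toy$design, "labelfree")), 0)

  design <- coip_design("silac", n_replicates = 4)
  g <- toy$groups[1, c("group_id", "protein_ids", "gene_names", "reverse",
                       "contaminant", "only_by_site", "unique_peptides",
                       "peptides", "msms_count")]
  for (s in design$sample) {
    g[[paste0("hl_", s)]] <- 1.2
    g[[paste0("idtype_", s)]] <- TRUE
  }
  expect_equal(nrow(filter_protein_groups(g, design, "silac")), 1)
  g[["idtype_rep3"]] <- FALSE   # missing MS/MS in 1 of 4 replicates -> removed
  kept <- filter_protein_groups(g, design, "silac")
  expect_equal(nrow(kept), 0)
  expect_equal(attr(kept, "removed")$reason, "presence")
})

test_that("filters are monotone in the count variables", {
  toy <- toy_groups()
  base <- filter_protein_groups(toy$groups, toy$design, "labelfree")
  boosted <- toy$groups
  boosted$unique_peptides <- boosted$unique_peptides + 5L
  boosted$peptides <- boosted$peptides + 5L
  boosted$msms_count <- boosted$msms_count + 5L
  more <- filter_protein_groups(boosted, toy$design, "labelfree")
  expect_true(all(base$group_id %in% more$group_id))
})

test_that("imputation touches only missing cells of control samples", {
  sim <- simulate_coip_tables(coip_truth(n_background = 60, n_true = 20,
                                         control_missingness = 0.7),
                              mode = "labelfree", seed = 31)
  mat <- quant_matrix(sim$groups, sim$design, "labelfree")
  # plant a missing value in a bait column: must remain missing
  mat[5, "WT_2"] <- NA
  imp <- impute_controls(mat, sim$design, seed = 1)
  ctrl <- sim$design$sample[sim$design$is_control]
  expect_true(is.na(imp$mat[5, "WT_2"]))
  changed <- (is.na(mat) & !is.na(imp$mat)) |
    (!is.na(mat) & !is.na(imp$mat) & imp$mat != mat)
  expect_true(all(colnames(changed)[colSums(changed, na.rm = TRUE) > 0] %in% ctrl))
  expect_identical(which(imp$imputed), which(is.na(mat) &
                                               !is.na(imp$mat)))
  # untouched when nothing is missing in controls
  full <- mat; full[is.na(full)] <- 20
  imp2 <- impute_controls(full, sim$design, seed = 1)
  expect_identical(imp2$mat, full)
  # fixed seed -> identical imputations
  imp3 <- impute_controls(mat, sim$design, seed = 1)
  expect_identical(imp$mat, imp3$mat)
})

test_that("bait normalization zeroes the bait and is shift-invariant", {
  mat <- rbind(BAIT = c(2, 3), G1 = c(2, 3), G2 = c(4, 1))
  colnames(mat) <- c("r1", "r2")
  norm <- bait_normalize(mat, "BAIT")
  expect_equal(unname(norm["BAIT", ]), c(0, 0))
  expect_equal(unname(norm["G1", ]), c(0, 0))
  expect_equal(unname(norm["G2", ]), c(2, -2))
  shifted <- mat; shifted[, 1] <- shifted[, 1] + 5
  expect_equal(bait_normalize(shifted, "BAIT"), norm)
  mat2 <- mat; mat2["BAIT", 2] <- NA
  expect_error(bait_normalize(mat2, "BAIT"), "r2")
})

test_that("label-free interactor calls apply both the BH and fold-change rules", {
  design <- coip_design("labelfree", n_replicates = 3)
  mat <- rbind(
    strong = c(3.0, 3.1, 2.9, 0, 0, 0, 0.0, 0.1, -0.1),
    flat   = c(0.0, 0.1, -0.1, 0, 0, 0, 0.0, 0.1, -0.1),
    small  = c(2.0, 2.1, 1.9, 0, 0, 0, 0.0, 0.1, -0.1)
  )
  colnames(mat) <- design$sample
  calls <- call_interactors(mat, design, "labelfree", bait_condition = "WT")
  strong <- calls[calls$group_id == "strong", ]
  expect_equal(strong$mean_log2_diff, 3.0, tolerance = 1e-12)
  expect_equal(strong$t, 36.74, tolerance = 1e-3)
  expect_true(strong$specific)
  expect_false(calls$specific[calls$group_id == "flat"])
  # significant but below the fold-change threshold: not specific
  small <- calls[calls$group_id == "small", ]
  expect_lt(small$adj_p, 0.05)
  expect_false(small$specific)
})

test_that("SILAC calls are one-sample tests of bait-normalized ratios", {
  design <- coip_design("silac", n_replicates = 4)
  mat <- rbind(
    BAIT = c(0.5, 0.6, 0.4, 0.5),
    up_wt = c(1.3, 1.4, 1.2, 1.5),
    down  = c(-0.2, -0.25, -0.15, -0.2),
    flat  = c(0.51, 0.49, 0.52, 0.48)
  )
  colnames(mat) <- design$sample
  norm <- bait_normalize(mat, "BAIT")
  calls <- call_interactors(norm, design, "silac", exclude = "BAIT")
  expect_false("BAIT" %in% calls$group_id)
  expect_equal(calls$direction[calls$group_id == "up_wt"], "up_in_WT")
  expect_equal(calls$direction[calls$group_id == "down"], "up_in_AA")
  expect_false(calls$regulated[calls$group_id == "flat"])
})

test_that("hypergeometric enrichment matches the exact combinatorial value", {
  background <- paste0("P", 1:20)
  hits <- paste0("P", 1:5)
  ann <- list(term_a = paste0("P", c(1, 2, 3, 10, 11)),  # k = 3 of K = 5
              all_term = background)
  res <- enrichment_test(hits, background, ann)
  expect_equal(res$p[res$term == "term_a"], 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$gene_ratio[res$term == "term_a"], 3 / 5)
  # K = N: any draw is fully annotated, p = 1
  expect_equal(res$p[res$term == "all_term"], 1)
  # degenerate empty draw
  res0 <- enrichment_test(character(0), background, ann)
  expect_true(all(res0$p == 1))
  expect_error(enrichment_test(c("P1", "QX"), background, ann), "subset")
})
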