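#' Ground-truth parameters for the co-IP simulator
#'
#' Describes an AP-MS experiment with a tagged bait, a double-mutant bait and
#' an untagged negative control.  Defaults mirror the study design: label-free
#' mode has 3 conditions (WT, AA, control) with 6 replicates each (two
#' experiments of three); SILAC mode has 4 heavy/light replicates with WT in
#' the heavy channel.
#'
#' @param n_background number of non-interacting background protein groups.
#' @param n_true number of true bait interactors.
#' @param enrichment_log2 per-interactor log2 enrichment over control in bait
#'   pulldowns (scalar or length `n_true`).
#' @param wt_aa_shift_log2 per-interactor WT-vs-AA log2 shift (scalar or
#'   length `n_true`); negative values mean more binding to the AA mutant.
#' @param control_missingness probability that a true interactor is missing
#'   (not quantified) in a negative-control sample.
#' @param sigma replicate-to-replicate sd of log2 quantities.
#' @param baseline_log2 mean log2 iBAQ of the background distribution.
#' @param count_fail_fraction fraction of groups drawn with identification
#'   counts failing the QC count filters (< 2 unique peptides, < 4 peptides or
#'   < 6 MS/MS counts).
#' @param n_decoys,n_contaminants numbers of injected decoy ("Reverse") and
#'   contaminant rows.
#' @param bait_offset_log2 SILAC-mode bait log2 H/L offset (unequal WT/AA
#'   amounts), exercised by bait normalization.
#' @return a `coip_truth` list.
#' @export
coip_truth <- function(n_background = 250, n_true = 50,
                       enrichment_log2 = 4, wt_aa_shift_log2 = 0,
                       control_missingness = 0.8, sigma = 0.5,
                       baseline_log2 = 25, count_fail_fraction = 0.05,
                       n_decoys = 8, n_contaminants = 5,
                       bait_offset_log2 = 0.5) {
  stopifnot(n_background >= 0, n_true >= 0,
            control_missingness >= 0, control_missingness <= 1,
            sigma >= 0, count_fail_fraction >= 0, count_fail_fraction <= 1)
  recycle <- function(x) if (n_true == 0) numeric(0) else rep_len(x, n_true)
  structure(list(
    n_background = n_background, n_true = n_true,
    enrichment_log2 = recycle(enrichment_log2),
    wt_aa_shift_log2 = recycle(wt_aa_shift_log2),
    control_missingness = control_missingness, sigma = sigma,
    baseline_log2 = baseline_log2, count_fail_fraction = count_fail_fraction,
    n_decoys = n_decoys, n_contaminants = n_contaminants,
    bait_offset_log2 = bait_offset_log2
  ), class = "coip_truth")
}

#' Experimental design table for simulated co-IP experiments
#'
#' @param mode "labelfree" or "silac".
#' @param n_replicates replicates per condition (default 6 label-free, 4
#'   SILAC).
#' @return tibble with columns `sample`, `condition`, `replicate`,
#'   `is_control`.
#' @export
coip_design <- function(mode = c("labelfree", "silac"), n_replicates = NULL) {
  mode <- match.arg(mode)
  if (mode == "labelfree") {
    n_replicates <- n_replicates %||% 6L
    conds <- c("WT", "AA", "ctrl")
    tibble::tibble(
      sample = paste0(rep(conds, each = n_replicates), "_",
                      rep(seq_len(n_replicates), times = length(conds))),
      condition = rep(conds, each = n_replicates),
      replicate = rep(seq_len(n_replicates), times = length(conds)),
      is_control = rep(conds == "ctrl", each = n_replicates)
    )
  } else {
    n_replicates <- n_replicates %||% 4L
    tibble::tibble(
      sample = paste0("rep", seq_len(n_replicates)),
      condition = "HL",
      replicate = seq_len(n_replicates),
      is_control = FALSE
    )
  }
}

#' Forward-simulate MaxQuant-style protein-group tables for co-IP experiments
#'
#' Label-free mode draws per-sample log2 iBAQ values Normal around condition
#' means: true interactors are enriched in bait (WT/AA) conditions and missing
#' in control samples with the configured probability; background groups share
#' one mean everywhere.  SILAC mode draws one normalized log2 H/L ratio per
#' replicate (WT heavy / AA light) around each group's true shift plus the
#' bait offset.  Identification-count columns are drawn so that a configurable
#' fraction of groups fails the QC count filters, and decoy/contaminant rows
#' are injected; per-sample identified-by-MS/MS flags accompany every
#' quantified value.
#'
#' @param truth a [coip_truth()] object.
#' @param mode "labelfree" or "silac".
#' @param n_replicates optional override of the design's replicate count.
#' @param seed integer seed.
#' @return list with `groups` (canonical protein-group tibble, see
#'   [read_protein_groups()]), `design` (sample sheet) and `truth`
#'   (per-group ground truth).
#' @export
simulate_coip_tables <- function(truth = coip_truth(),
                                 mode = c("labelfree", "silac"),
                                 n_replicates = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "coip_truth"))
  design <- coip_design(mode, n_replicates)
  if (nrow(design) == 0) stop("design has no replicates")
  withr::local_seed(sub_seed(seed, 1L))

  n_real <- truth$n_background + truth$n_true + 1L  # + bait
  ids <- c("BAIT_HSP90AB1",
           if (truth$n_true > 0) sprintf("INT%03d", seq_len(truth$n_true)),
           if (truth$n_background > 0) sprintf("BG%04d", seq_len(truth$n_background)))
  is_bait <- ids == "BAIT_HSP90AB1"
  is_true <- grepl("^INT", ids)

  # identification counts; a random fraction fails the QC count filters
  n_all <- n_real + truth$n_decoys + truth$n_contaminants
  unique_peptides <- 2L + stats::rpois(n_all, 6)
  peptides <- unique_peptides + stats::rpois(n_all, 3)
  msms_count <- pmax(peptides * 2L + stats::rpois(n_all, 4), 6L)
  fail <- stats::runif(n_all) < truth$count_fail_fraction
  fail[1] <- FALSE  # bait always passes
  if (any(fail)) {
    which_rule <- sample(1:3, sum(fail), replace = TRUE)
    unique_peptides[fail][which_rule == 1] <- 1L
    peptides[fail][which_rule == 2] <- 3L
    msms_count[fail][which_rule == 3] <- 5L
    peptides <- pmax(peptides, unique_peptides)
  }

  all_ids <- c(ids,
               if (truth$n_decoys > 0) sprintf("REV%03d", seq_len(truth$n_decoys)),
               if (truth$n_contaminants > 0) sprintf("CON%03d", seq_len(truth$n_contaminants)))
  groups <- tibble::tibble(
    group_id = all_ids,
    protein_ids = all_ids,
    gene_names = ifelse(all_ids == "BAIT_HSP90AB1", "HSP90AB1", all_ids),
    reverse = grepl("^REV", all_ids),
    contaminant = grepl("^CON", all_ids),
    only_by_site = FALSE,
    unique_peptides = unique_peptides,
    peptides = peptides,
    msms_count = msms_count
  )

  if (mode == "labelfree") {
    for (j in seq_len(nrow(design))) {
      cond <- design$condition[j]
      mu <- rep(truth$baseline_log2, n_all)
      if (cond %in% c("WT", "AA") && truth$n_true > 0) {
        shift <- if (cond == "AA") -truth$wt_aa_shift_log2 else 0
        mu[which(is_true)] <- truth$baseline_log2 + truth$enrichment_log2 + shift
      }
      mu[1] <- truth$baseline_log2 + if (cond == "ctrl") 0 else 8  # bait dominates pulldowns
      v <- stats::rnorm(n_all, mu, truth$sigma)
      if (cond == "ctrl" && truth$n_true > 0) {
        drop <- which(is_true)[stats::runif(truth$n_true) < truth$control_missingness]
        v[drop] <- NA_real_
      }
      # quantities are stored on the linear iBAQ scale, as MaxQuant exports them
      groups[[paste0("ibaq_", design$sample[j])]] <- 2^v
      groups[[paste0("idtype_", design$sample[j])]] <- !is.na(v)
    }
  } else {
    shift <- rep(0, n_all)
    if (truth$n_true > 0) shift[which(is_true)] <- truth$wt_aa_shift_log2
    for (j in seq_len(nrow(design))) {
      mu <- truth$bait_offset_log2 + shift
      sdv <- ifelse(seq_len(n_all) == 1, truth$sigma / 5, truth$sigma)
      v <- stats::rnorm(n_all, mu, sdv)
      groups[[paste0("hl_", design$sample[j])]] <- 2^v
      groups[[paste0("idtype_", design$sample[j])]] <- TRUE
    }
  }

  truth_tbl <- tibble::tibble(
    group_id = all_ids,
    is_bait = all_ids == "BAIT_HSP90AB1",
    is_true_interactor = grepl("^INT", all_ids),
    enrichment_log2 = NA_real_,
    wt_aa_shift_log2 = NA_real_
  )
  if (truth$n_true > 0) {
    idx <- match(sprintf("INT%03d", seq_len(truth$n_true)), all_ids)
    truth_tbl$enrichment_log2[idx] <- truth$enrichment_log2
    truth_tbl$wt_aa_shift_log2[idx] <- truth$wt_aa_shift_log2
  }
  list(groups = groups, design = design, truth = truth_tbl)
}
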