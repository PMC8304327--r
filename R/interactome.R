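#' Extract the per-sample quantity matrix from a protein-group table
#'
#' Pulls the canonical `ibaq_<sample>` (label-free) or `hl_<sample>` (SILAC)
#' columns in design order and log2-transforms them (natural-scale values are
#' converted on ingest; log base 2 is used everywhere downstream).
#'
#' @param groups canonical protein-group tibble.
#' @param design sample sheet, see [coip_design()].
#' @param mode "labelfree" or "silac".
#' @return numeric matrix, rows = groups (rownames = group_id), columns =
#'   samples.
#' @export
quant_matrix <- function(groups, design, mode = c("labelfree", "silac")) {
  mode <- match.arg(mode)
  prefix <- if (mode == "labelfree") "ibaq_" else "hl_"
  cols <- paste0(prefix, design$sample)
  missing_cols <- setdiff(cols, names(groups))
  if (length(missing_cols) > 0) {
    stop("design/sample-column mismatch; missing: ",
         paste(missing_cols, collapse = ", "))
  }
  m <- log2(as.matrix(groups[, cols]))
  dimnames(m) <- list(groups$group_id, design$sample)
  m
}

ident_matrix <- function(groups, design) {
  cols <- paste0("idtype_", design$sample)
  missing_cols <- setdiff(cols, names(groups))
  if (length(missing_cols) > 0) {
    stop("design/sample-column mismatch; missing: ",
         paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(groups[, cols])
  dimnames(m) <- list(groups$group_id, design$sample)
  m
}

#' QC, count and presence filters for protein groups
#'
#' Removes decoy (reverse), potential-contaminant and only-identified-by-site
#' groups; groups with fewer than 2 unique peptides, 4 peptides or 6 MS/MS
#' counts in total; and groups failing the presence rule: identified by MS/MS
#' in all replicates of at least one condition (label-free) or in all
#' replicates (SILAC).  Removal reasons are recorded per group in the
#' `removed` attribute of the result.
#'
#' @param groups canonical protein-group tibble.
#' @param design sample sheet.
#' @param mode "labelfree" or "silac".
#' @param min_unique,min_peptides,min_msms count thresholds (defaults 2/4/6).
#' @return the surviving rows; attribute `removed` is a tibble
#'   (group_id, reason).
#' @export
filter_protein_groups <- function(groups, design,
                                  mode = c("labelfree", "silac"),
                                  min_unique = 2, min_peptides = 4,
                                  min_msms = 6) {
  mode <- match.arg(mode)
  idm <- ident_matrix(groups, design)
  if (mode == "labelfree") {
    conds <- unique(design$condition)
    all_in_cond <- matrix(
      unlist(lapply(conds, function(cc) {
        rowSums(!idm[, design$condition == cc, drop = FALSE]) == 0
      })),
      nrow = nrow(groups))
    presence_ok <- rowSums(all_in_cond) > 0
  } else {
    presence_ok <- rowSums(!idm) == 0
  }
  reason <- dplyr::case_when(
    groups$reverse ~ "decoy",
    groups$contaminant ~ "contaminant",
    groups$only_by_site ~ "only_by_site",
    groups$unique_peptides < min_unique ~ "unique_peptides",
    groups$peptides < min_peptides ~ "peptides",
    groups$msms_count < min_msms ~ "msms_count",
    !presence_ok ~ "presence",
    TRUE ~ NA_character_
  )
  kept <- groups[is.na(reason), ]
  removed <- tibble::tibble(group_id = groups$group_id[!is.na(reason)],
                            reason = reason[!is.na(reason)])
  attr(kept, "removed") <- removed
  kept
}

#' Impute missing values in negative-control samples
#'
#' Missing values are imputed only in co-IP negative-control samples — the
#' minimum needed to run a t-test against the controls — by drawing from a
#' down-shifted Gaussian: per control sample s with observed mean
#' \eqn{\mu_s} and sd \eqn{\sigma_s} (of log2 quantities), imputed values are
#' \eqn{N(\mu_s - \mathrm{shift}\,\sigma_s, (\mathrm{width}\,\sigma_s)^2)},
#' the de-facto AP-MS convention for left-censored missingness.  Cells in
#' non-control samples are never touched.
#'
#' @param mat log2 quantity matrix from [quant_matrix()].
#' @param design sample sheet; `is_control` marks negative-control samples.
#' @param seed integer seed (imputation is the only stochastic step of the
#'   label-free pipeline).
#' @param shift,width down-shift and width in units of the per-sample sd
#'   (defaults 1.8 and 0.3).
#' @return list with `mat` (imputed matrix) and `imputed` (logical mask of
#'   the cells that were filled).
#' @export
impute_controls <- function(mat, design, seed = 1L, shift = 1.8, width = 0.3) {
  control_samples <- design$sample[design$is_control]
  if (length(control_samples) == 0) stop("no control samples in design")
  if (sum(is.finite(mat)) < 20) {
    stop("need at least 20 observed values to estimate imputation moments")
  }
  withr::local_seed(sub_seed(seed, 4L))
  imputed <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  global_mu <- mean(mat[is.finite(mat)])
  global_sd <- stats::sd(mat[is.finite(mat)])
  for (s in control_samples) {
    col <- mat[, s]
    obs <- col[is.finite(col)]
    if (length(obs) == 0) {
      warning("control sample ", s,
              " has no observed values; using global moments")
      mu <- global_mu; sdv <- global_sd
    } else {
      mu <- mean(obs); sdv <- stats::sd(obs)
      if (!is.finite(sdv) || sdv == 0) sdv <- global_sd
    }
    fill <- !is.finite(col)
    mat[fill, s] <- stats::rnorm(sum(fill), mu - shift * sdv, width * sdv)
    imputed[fill, s] <- TRUE
  }
  list(mat = mat, imputed = imputed)
}

#' Align per-replicate log2 ratios on the bait
#'
#' Subtracts the bait group's log2 ratio from every group's log2 ratio within
#' each replicate, so the bait sits exactly at 0 and unequal bait amounts
#' between channels cancel.  Invariant to adding a constant to all ratios of
#' a replicate.
#'
#' @param mat log2 ratio matrix (rows = groups, rownames = group_id).
#' @param bait_group group_id of the bait row.
#' @return the normalized matrix.
#' @export
bait_normalize <- function(mat, bait_group) {
  if (!bait_group %in% rownames(mat)) stop("bait group not found: ", bait_group)
  bait <- mat[bait_group, ]
  missing_rep <- colnames(mat)[!is.finite(bait)]
  if (length(missing_rep) > 0) {
    stop("bait not quantified in replicate(s): ",
         paste(missing_rep, collapse = ", "))
  }
  sweep(mat, 2, bait, "-")
}

#' Call specific interactors / regulated interactors
#'
#' Label-free mode: two-sample Student t-test on log2 iBAQ values,
#' bait-condition vs (imputed) negative-control samples, Benjamini-Hochberg
#' correction across all tested groups; a group is a specific interactor when
#' its adjusted p-value is under `alpha` and its mean log2 difference over
#' control is at least `min_log2_specific` (the "fold change of 3 in log2
#' scale" criterion, i.e. 8-fold linear).
#'
#' SILAC mode: each replicate carries both conditions in one bait-normalized
#' log2 H/L ratio, so the WT-vs-AA comparison is a one-sample Student t-test
#' of those ratios against 0 per group, BH-adjusted; a group is regulated
#' when adjusted p < `alpha`, and `min_log2_highlight` only classifies the
#' display direction (`up_in_WT` / `up_in_AA`).
#'
#' @param mat log2 quantity matrix (label-free: imputed; silac:
#'   bait-normalized ratios with heavy = WT).
#' @param design sample sheet.
#' @param mode "labelfree" or "silac".
#' @param bait_condition label-free condition to test (default "WT").
#' @param alpha BH significance threshold (default 0.05).
#' @param min_log2_specific fold-change threshold for specificity (default 3).
#' @param min_log2_highlight display threshold for the SILAC direction call
#'   (default 0.4).
#' @param exclude group_ids excluded from testing (e.g. the bait itself in
#'   SILAC mode, which is 0 by construction).
#' @return tibble per tested group: `group_id`, `mean_log2_diff`, `t`, `p`,
#'   `adj_p`, `specific` (label-free) or `regulated` (silac), `direction`.
#' @export
call_interactors <- function(mat, design, mode = c("labelfree", "silac"),
                             bait_condition = "WT", alpha = 0.05,
                             min_log2_specific = 3, min_log2_highlight = 0.4,
                             exclude = NULL) {
  mode <- match.arg(mode)
  keep <- !(rownames(mat) %in% exclude)
  mat <- mat[keep, , drop = FALSE]
  if (mode == "labelfree") {
    bait_cols <- design$sample[design$condition == bait_condition]
    ctrl_cols <- design$sample[design$is_control]
    if (length(bait_cols) < 2 || length(ctrl_cols) < 2) {
      stop("need at least 2 replicates per group for the t-test")
    }
    tt <- row_t_test(mat[, bait_cols, drop = FALSE],
                     mat[, ctrl_cols, drop = FALSE], var_equal = TRUE)
    adj_p <- stats::p.adjust(tt$p, method = "BH")
    specific <- !is.na(adj_p) & adj_p < alpha &
      tt$mean_diff >= min_log2_specific
    tibble::tibble(
      group_id = rownames(mat),
      mean_log2_diff = tt$mean_diff, t = tt$t, p = tt$p, adj_p = adj_p,
      specific = specific,
      direction = dplyr::case_when(
        specific & tt$mean_diff > 0 ~ paste0("up_in_", bait_condition),
        TRUE ~ "none")
    )
  } else {
    if (ncol(mat) < 2) stop("need at least 2 replicates for the t-test")
    tt <- row_t_test_one(mat, mu = 0)
    adj_p <- stats::p.adjust(tt$p, method = "BH")
    regulated <- !is.na(adj_p) & adj_p < alpha
    tibble::tibble(
      group_id = rownames(mat),
      mean_log2_diff = tt$mean, t = tt$t, p = tt$p, adj_p = adj_p,
      regulated = regulated,
      direction = dplyr::case_when(
        regulated & tt$mean >= min_log2_highlight ~ "up_in_WT",
        regulated & tt$mean <= -min_log2_highlight ~ "up_in_AA",
        TRUE ~ "none")
    )
  }
}

#' Hypergeometric over-representation test for annotation terms
#'
#' For each term: population N = |background|, successes K = annotated
#' background proteins, draws n = |hits|, observed overlap k; the one-sided
#' upper-tail p-value is P(X >= k) from the hypergeometric distribution, with
#' Benjamini-Hochberg correction across terms.  GeneRatio = k / K (enriched
#' proteins with the term over background proteins with the term).
#'
#' @param hits character vector of hit IDs (must be a subset of background).
#' @param background character vector of all identified IDs.
#' @param annotations named list: term -> character vector of annotated IDs
#'   (restricted to the background before testing).
#' @return tibble per term: `term`, `k`, `K`, `n`, `N`, `gene_ratio`, `p`,
#'   `adj_p`.
#' @export
enrichment_test <- function(hits, background, annotations) {
  hits <- unique(hits); background <- unique(background)
  if (!all(hits %in% background)) {
    stop("hits must be a subset of the background")
  }
  N <- length(background)
  n <- length(hits)
  res <- purrr::map_dfr(names(annotations), function(term) {
    ann <- intersect(unique(annotations[[term]]), background)
    K <- length(ann)
    k <- length(intersect(hits, ann))
    p <- if (n == 0 || K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term = term, k = k, K = K, n = n, N = N,
                   gene_ratio = if (K > 0) k / K else NA_real_, p = p)
  })
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res
}
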