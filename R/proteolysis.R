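#' Assign peptides to a side of the cleavage site
#'
#' A peptide span (1-based inclusive) is `before` when it ends before the
#' residue following the site (end < site + 1), `after` when it starts after
#' the site (start > site), and `spanning` otherwise.  Spanning peptides are
#' excluded from side-group statistics.
#'
#' @param panel tibble with columns `peptide`, `start`, `end`.
#' @param site 1-based residue index of the cleavage site (default 607).
#' @return the panel with a `side` column appended.
#' @export
assign_cleavage_side <- function(panel, site = 607) {
  side <- dplyr::case_when(
    panel$end < site + 1 ~ "before",
    panel$start > site ~ "after",
    TRUE ~ "spanning"
  )
  dplyr::mutate(panel, side = side)
}

#' Fraction of full-length protein remaining per trypsin dose
#'
#' Per peptide: the ratio of its band-A intensity at the given dose to its
#' band-A intensity at dose 0 — a per-peptide readout of how much full-length
#' protein survived digestion.  Peptides with a zero or missing dose-0
#' baseline are excluded (recorded in the `excluded` attribute).
#'
#' @param bands long band-peptide matrix (peptide, genotype, dose, band,
#'   intensity).
#' @param band_full name of the full-length band (default "A").
#' @return tibble per (genotype, dose > 0 and 0, peptide): `ratio`; the
#'   `excluded` attribute lists dropped peptides.
#' @export
fraction_full_length <- function(bands, band_full = "A") {
  a <- bands[bands$band == band_full, ]
  base <- a[a$dose == 0, c("peptide", "genotype", "intensity")]
  names(base)[3] <- "baseline"
  merged <- dplyr::left_join(a, base, by = c("peptide", "genotype"))
  ok <- !is.na(merged$baseline) & merged$baseline > 0
  excluded <- unique(merged$peptide[!ok])
  out <- merged[ok, ]
  out$ratio <- out$intensity / out$baseline
  out <- out[, c("peptide", "start", "end", "genotype", "dose", "ratio")]
  attr(out, "excluded") <- excluded
  out
}

#' Per-peptide band-A versus whole-lane intensity ratio
#'
#' Ratio of a peptide's intensity in the full-length band to its summed
#' intensity over all analyzed bands of the lane (band A included), per
#' (genotype, dose).  Always in \[0, 1\].  Peptides absent from every band of
#' a lane are flagged undefined.
#'
#' @param bands long band-peptide matrix.
#' @param band_full name of the full-length band (default "A").
#' @return tibble per (genotype, dose, peptide): `band_a`, `lane_total`,
#'   `ratio` (NA when undefined).
#' @export
band_vs_lane_ratio <- function(bands, band_full = "A") {
  bands |>
    dplyr::group_by(.data$peptide, .data$start, .data$end,
                    .data$genotype, .data$dose) |>
    dplyr::summarise(
      band_a = sum(.data$intensity[.data$band == band_full], na.rm = TRUE),
      lane_total = sum(.data$intensity, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(ratio = dplyr::if_else(.data$lane_total > 0,
                                         .data$band_a / .data$lane_total,
                                         NA_real_))
}

#' Compare per-peptide ratios between two groups
#'
#' Two-sided Welch t-test on per-peptide ratios — WT vs AA at each dose, or
#' before-site vs after-site peptides at each dose — with Benjamini-Hochberg
#' adjustment across doses.  Peptides are pseudo-replicates here (they share
#' one protein molecule population); the p-values rank evidence rather than
#' support population inference.  Groups with fewer than `min_n` peptides are
#' skipped; fully degenerate groups return p = 1 when the means agree.
#'
#' @param ratios tibble with columns `dose`, `ratio` and a grouping column.
#' @param group_col name of the two-level grouping column (e.g. "genotype" or
#'   "side").
#' @param levels optional two group labels to compare (defaults to the first
#'   two present).
#' @param min_n minimum peptides per group (default 3).
#' @return tibble per dose: `dose`, `mean_1`, `mean_2`, `diff`, `p`, `adj_p`,
#'   `skipped`.
#' @export
compare_genotypes <- function(ratios, group_col = "genotype", levels = NULL,
                              min_n = 3) {
  g <- ratios[[group_col]]
  levels <- levels %||% unique(g)[1:2]
  res <- purrr::map_dfr(sort(unique(ratios$dose)), function(d) {
    r1 <- ratios$ratio[ratios$dose == d & g == levels[1]]
    r2 <- ratios$ratio[ratios$dose == d & g == levels[2]]
    r1 <- r1[!is.na(r1)]; r2 <- r2[!is.na(r2)]
    if (length(r1) < min_n || length(r2) < min_n) {
      return(tibble::tibble(dose = d, mean_1 = NA_real_, mean_2 = NA_real_,
                            diff = NA_real_, p = NA_real_, skipped = TRUE))
    }
    p <- if (stats::sd(r1) == 0 && stats::sd(r2) == 0) {
      if (mean(r1) == mean(r2)) 1 else 0
    } else {
      stats::t.test(r1, r2, var.equal = FALSE)$p.value
    }
    tibble::tibble(dose = d, mean_1 = mean(r1), mean_2 = mean(r2),
                   diff = mean(r1) - mean(r2), p = p, skipped = FALSE)
  })
  res$adj_p <- NA_real_
  tested <- !is.na(res$p)
  res$adj_p[tested] <- stats::p.adjust(res$p[tested], method = "BH")
  res
}
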