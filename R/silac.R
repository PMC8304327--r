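#' Sum fragment areas into peptide-level heavy/light quantities
#'
#' Transition records are grouped by (modified sequence, precursor charge,
#' sample, replicate); the peptide area per channel is the plain sum of its
#' fragment areas.  A peptide with no non-missing fragment in a channel gets a
#' missing area there and is flagged; its H/L ratio is then missing.
#'
#' @param records transition-record tibble, see [read_transition_report()].
#' @return tibble with one row per (peptide, sample, replicate):
#'   `modified_sequence`, `sample_id`, `replicate`, `area_light`,
#'   `area_heavy`, `hl_ratio`, `flag`.
#' @export
peptide_areas_from_transitions <- function(records) {
  sums <- records |>
    dplyr::group_by(.data$modified_sequence, .data$precursor_charge,
                    .data$label_channel, .data$sample_id, .data$replicate) |>
    dplyr::summarise(
      area = if (all(is.na(.data$area))) NA_real_ else
        sum(.data$area, na.rm = TRUE),
      .groups = "drop"
    )
  wide <- sums |>
    tidyr::pivot_wider(names_from = "label_channel", values_from = "area",
                       names_prefix = "area_")
  if (!"area_light" %in% names(wide)) wide$area_light <- NA_real_
  if (!"area_heavy" %in% names(wide)) wide$area_heavy <- NA_real_
  wide <- wide |>
    dplyr::group_by(.data$modified_sequence, .data$sample_id, .data$replicate) |>
    dplyr::summarise(
      area_light = sum(.data$area_light, na.rm = FALSE),
      area_heavy = sum(.data$area_heavy, na.rm = FALSE),
      .groups = "drop"
    )
  wide |>
    dplyr::mutate(
      hl_ratio = dplyr::if_else(
        !is.na(.data$area_light) & !is.na(.data$area_heavy) &
          .data$area_light > 0 & .data$area_heavy > 0,
        .data$area_heavy / .data$area_light, NA_real_),
      flag = dplyr::case_when(
        is.na(.data$area_light) & is.na(.data$area_heavy) ~ "both_channels_missing",
        is.na(.data$area_heavy) | !(.data$area_heavy > 0) ~ "heavy_missing",
        is.na(.data$area_light) | !(.data$area_light > 0) ~ "light_missing",
        TRUE ~ "ok"
      )
    )
}

#' Whole-protein reference ratio z from normalization peptides
#'
#' z is the median of the normalization peptides' H/L ratios per
#' (sample, replicate) — the whole-protein heavy/light mixing ratio the
#' occupancy algebra divides against.  The median is robust to one aberrant
#' peptide; the number of contributing peptides is reported.
#'
#' @param quants peptide quantity tibble from
#'   [peptide_areas_from_transitions()], restricted to normalization peptides.
#' @return tibble with `sample_id`, `replicate`, `z`, `n_peptides`.
#' @export
protein_reference_ratio <- function(quants) {
  out <- quants |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::summarise(
      z = stats::median(.data$hl_ratio[!is.na(.data$hl_ratio)]),
      n_peptides = sum(!is.na(.data$hl_ratio)),
      .groups = "drop"
    )
  if (any(out$n_peptides == 0)) {
    bad <- out[out$n_peptides == 0, ]
    stop("no valid normalization-peptide ratio for replicate(s): ",
         paste(paste0(bad$sample_id, "/", bad$replicate), collapse = ", "))
  }
  out
}

#' Assemble (x, y, z) ratio triplets for the occupancy algebra
#'
#' For each (site, peptide variant, sample, replicate): x is the H/L ratio of
#' the phosphopeptide, y that of its unmodified counterpart (identical
#' backbone), z the whole-protein reference ratio.  Only complete triplets
#' with finite positive x, y, z are returned; incomplete ones are dropped
#' with a reason recorded in the `dropped` attribute.
#'
#' @param quants peptide quantity tibble.
#' @param panel site/pair panel, see [cl_peptide_panel()].
#' @param z_table per-replicate z from [protein_reference_ratio()].
#' @return tibble with `site_id`, `variant`, `phospho_sequence`, `sample_id`,
#'   `replicate`, `x`, `y`, `z`; the `dropped` attribute lists skipped
#'   combinations and why.
#' @export
assemble_ratio_triplets <- function(quants, panel, z_table) {
  combos <- tidyr::crossing(panel,
                            dplyr::distinct(z_table, .data$sample_id,
                                            .data$replicate))
  lookup <- function(seqs, samples, reps) {
    idx <- match(paste(seqs, samples, reps),
                 paste(quants$modified_sequence, quants$sample_id,
                       quants$replicate))
    quants$hl_ratio[idx]
  }
  combos$x <- lookup(combos$phospho_sequence, combos$sample_id, combos$replicate)
  combos$y <- lookup(combos$unmodified_sequence, combos$sample_id, combos$replicate)
  combos$z <- z_table$z[match(paste(combos$sample_id, combos$replicate),
                              paste(z_table$sample_id, z_table$replicate))]
  reason <- dplyr::case_when(
    is.na(combos$x) ~ "phosphopeptide ratio missing",
    is.na(combos$y) ~ "unmodified counterpart missing",
    is.na(combos$z) ~ "protein reference ratio missing",
    !(combos$x > 0 & combos$y > 0 & combos$z > 0) ~ "nonpositive ratio",
    TRUE ~ NA_character_
  )
  dropped <- combos[!is.na(reason), c("site_id", "variant", "sample_id", "replicate")]
  dropped$reason <- reason[!is.na(reason)]
  out <- combos[is.na(reason),
                c("site_id", "variant", "phospho_sequence", "sample_id",
                  "replicate", "x", "y", "z")]
  attr(out, "dropped") <- dropped
  out
}

#' Input-normalized phosphopeptide abundance and condition contrast
#'
#' Normalizes phosphopeptide areas by the input (lysate) protein abundance to
#' compensate for up-/down-regulation of the protein, then contrasts treated
#' vs control conditions: fold change of the mean normalized abundances plus
#' a two-sided Student t-test per (site, condition) with Benjamini-Hochberg
#' correction across all tested contrasts.
#'
#' @param data tibble with columns `site_id`, `condition`, `replicate`,
#'   `phospho_area`, `input_abundance`; exactly one condition must equal
#'   `control`.
#' @param control name of the reference condition (default "control").
#' @return tibble per (site, condition): `fold_change`, `p`, `adj_p`, `n`.
#' @export
stress_response_abundance <- function(data, control = "control") {
  if (any(is.na(data$input_abundance) | data$input_abundance <= 0)) {
    stop("zero or missing input protein abundance")
  }
  data$normalized <- data$phospho_area / data$input_abundance
  ctrl <- data[data$condition == control, ]
  if (nrow(ctrl) == 0) stop("no rows for control condition '", control, "'")
  res <- data |>
    dplyr::filter(.data$condition != control) |>
    dplyr::group_by(.data$site_id, .data$condition) |>
    dplyr::summarise(
      fold_change = mean(.data$normalized) /
        mean(ctrl$normalized[ctrl$site_id == .data$site_id[1]]),
      p = {
        ref <- ctrl$normalized[ctrl$site_id == .data$site_id[1]]
        trt <- .data$normalized
        if (length(ref) >= 2 && length(trt) >= 2) {
          if (stats::sd(c(ref - mean(ref), trt - mean(trt))) == 0) {
            if (mean(ref) == mean(trt)) 1 else 0
          } else {
            stats::t.test(trt, ref, var.equal = TRUE)$p.value
          }
        } else NA_real_
      },
      n = dplyr::n(),
      .groups = "drop"
    )
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res
}
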