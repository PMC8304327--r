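#' Absolute compartment ratio from paired CWB measurements
#'
#' Each signal is first scaled up to the whole sample (total =
#' signal / fraction_analyzed); the absolute ratio is then
#' total_CM / (total_CM + total_input), the fraction of the protein found in
#' the conditioned medium.  Invariant to rescaling both compartments' signals
#' by the same constant.  Vectorised over replicates.
#'
#' @param cm_signal,cm_fraction CM signal and its analyzed fraction.
#' @param input_signal,input_fraction lysate (input) signal and analyzed
#'   fraction.
#' @return numeric vector of ratios in \[0, 1\]; NA (with a warning) where
#'   both totals are zero.
#' @export
absolute_ratio <- function(cm_signal, cm_fraction, input_signal,
                           input_fraction) {
  if (any(c(cm_fraction, input_fraction) <= 0 |
          c(cm_fraction, input_fraction) > 1)) {
    stop("fraction_analyzed must be in (0, 1]")
  }
  total_cm <- cm_signal / cm_fraction
  total_input <- input_signal / input_fraction
  both_zero <- total_cm + total_input == 0
  if (any(both_zero)) warning("both totals zero; ratio undefined")
  out <- total_cm / (total_cm + total_input)
  out[both_zero] <- NA_real_
  out
}

#' Absolute CM ratios for every (target, construct, replicate)
#'
#' Pairs the CM and lysate rows of a CWB measurement table and applies
#' [absolute_ratio()].
#'
#' @param measurements CWB tibble, see [read_cwb_measurements()].
#' @return tibble with `target`, `construct`, `replicate`, `ratio`.
#' @export
cwb_absolute_ratios <- function(measurements) {
  wide <- measurements |>
    dplyr::select("target", "construct", "replicate", "compartment",
                  "signal", "fraction_analyzed") |>
    tidyr::pivot_wider(names_from = "compartment",
                       values_from = c("signal", "fraction_analyzed"))
  req <- c("signal_CM", "signal_lysate", "fraction_analyzed_CM",
           "fraction_analyzed_lysate")
  if (!all(req %in% names(wide))) {
    stop("measurements must contain both CM and lysate rows per replicate")
  }
  wide$ratio <- absolute_ratio(wide$signal_CM, wide$fraction_analyzed_CM,
                               wide$signal_lysate,
                               wide$fraction_analyzed_lysate)
  wide[, c("target", "construct", "replicate", "ratio")]
}

#' Baseline-corrected secreted fraction per construct
#'
#' The non-secreted control protein's (beta-actin) absolute ratio measures
#' accidental protein release; its mean — pooled across constructs by
#' default — is subtracted from each HA absolute ratio.  Negative corrected
#' values are reported and flagged, not clamped, so group means stay
#' unbiased.  Constructs are compared with a two-sided Student t-test on the
#' corrected per-replicate values.
#'
#' @param ratios tibble from [cwb_absolute_ratios()] with targets "HA" and
#'   "actin".
#' @param per_construct_baseline use a per-construct actin baseline instead
#'   of one pooled baseline (default FALSE).
#' @param var_equal Student (TRUE, default) or Welch for the construct
#'   comparison.
#' @return list with `estimates` (per construct: mean, sd, n, baseline,
#'   n_negative) , `corrected` (per-replicate corrected values) and
#'   `comparisons` (pairwise t-tests).
#' @export
secreted_fraction <- function(ratios, per_construct_baseline = FALSE,
                              var_equal = TRUE) {
  actin <- ratios[ratios$target == "actin", ]
  ha <- ratios[ratios$target == "HA", ]
  if (nrow(actin) == 0) stop("no actin (baseline control) measurements")
  if (per_construct_baseline) {
    base_tbl <- actin |>
      dplyr::group_by(.data$construct) |>
      dplyr::summarise(baseline = mean(.data$ratio), .groups = "drop")
    ha <- dplyr::left_join(ha, base_tbl, by = "construct")
  } else {
    ha$baseline <- mean(actin$ratio)
  }
  ha$corrected <- ha$ratio - ha$baseline
  estimates <- ha |>
    dplyr::group_by(.data$construct) |>
    dplyr::summarise(
      mean_secreted = mean(.data$corrected),
      sd_secreted = if (dplyr::n() >= 2) stats::sd(.data$corrected) else NA_real_,
      n = dplyr::n(),
      baseline = .data$baseline[1],
      n_negative = sum(.data$corrected < 0),
      .groups = "drop"
    )
  constructs <- unique(ha$construct)
  comparisons <- if (length(constructs) >= 2) {
    pairs <- utils::combn(constructs, 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      a <- ha$corrected[ha$construct == pr[1]]
      b <- ha$corrected[ha$construct == pr[2]]
      p <- if (length(a) >= 2 && length(b) >= 2) {
        if (stats::sd(a) == 0 && stats::sd(b) == 0) {
          if (mean(a) == mean(b)) 1 else 0
        } else {
          stats::t.test(a, b, var.equal = var_equal)$p.value
        }
      } else NA_real_
      tibble::tibble(construct_1 = pr[1], construct_2 = pr[2], p = p)
    })
  } else {
    tibble::tibble(construct_1 = character(), construct_2 = character(),
                   p = double())
  }
  list(estimates = estimates, corrected = ha, comparisons = comparisons)
}

#' Nucleotide-probe binding normalized by bait amount
#'
#' Desthiobiotin (ATP/ADP active-site probe) signal normalized by the HA-tag
#' signal of the same replicate; per (construct, nucleotide) group mean, sd
#' and n, plus a two-sided Student t-test comparing constructs within each
#' nucleotide.
#'
#' @param data tibble with columns `construct`, `nucleotide`, `replicate`,
#'   `desthiobiotin`, `ha`.
#' @param var_equal Student (TRUE, default) or Welch.
#' @return list with `normalized` (per replicate), `summary` (per group) and
#'   `comparisons` (per nucleotide).
#' @export
probe_binding <- function(data, var_equal = TRUE) {
  if (any(is.na(data$ha) | data$ha <= 0)) {
    bad <- which(is.na(data$ha) | data$ha <= 0)
    stop("HA signal must be positive; offending replicate row(s): ",
         paste(bad, collapse = ", "))
  }
  data$normalized <- data$desthiobiotin / data$ha
  summary <- data |>
    dplyr::group_by(.data$construct, .data$nucleotide) |>
    dplyr::summarise(
      mean_norm = mean(.data$normalized),
      sd_norm = if (dplyr::n() >= 2) stats::sd(.data$normalized) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
  comparisons <- purrr::map_dfr(unique(data$nucleotide), function(nuc) {
    sub <- data[data$nucleotide == nuc, ]
    constructs <- unique(sub$construct)
    if (length(constructs) < 2) {
      return(tibble::tibble(nucleotide = nuc, p = NA_real_))
    }
    a <- sub$normalized[sub$construct == constructs[1]]
    b <- sub$normalized[sub$construct == constructs[2]]
    p <- if (length(a) >= 2 && length(b) >= 2) {
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) 1 else 0
      } else {
        stats::t.test(a, b, var.equal = var_equal)$p.value
      }
    } else NA_real_
    tibble::tibble(nucleotide = nuc, p = p)
  })
  list(normalized = data, summary = summary, comparisons = comparisons)
}
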