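#' Phosphosite occupancy from a heavy/light ratio triplet
#'
#' The core algebra.  The light channel is the native sample with occupancy
#' p_L; the heavy channel is the phosphatase-treated reference with residual
#' occupancy p_H.  Under the two-state mixing model the observed H/L ratios
#' are x = z p_H / p_L for the phosphopeptide and y = z (1 - p_H) / (1 - p_L)
#' for its unmodified counterpart, with z the whole-protein mixing ratio.
#' Inverting:
#' \deqn{a = \frac{z - y}{x - z}, \qquad b = a \cdot \frac{x}{y},}
#' \deqn{\mathrm{occ}_{light} = \frac{a}{a + 1} = p_L, \qquad
#'       \mathrm{occ}_{heavy} = \frac{b}{b + 1} = p_H.}
#' Algebraically occ_light also equals (z - y)/(x - y), which is asserted as
#' a numerical invariant in the test-suite.
#'
#' Degenerate triplets with x within relative `tol` of z are flagged
#' `x_equals_z` and marked invalid (a diverges there).  Occupancies outside
#' \[0, 1\] — possible under noise — are reported unclamped and flagged
#' `out_of_range`; silent clamping would bias group means.
#'
#' @param x,y,z positive finite H/L ratios of the phosphopeptide, its
#'   unmodified counterpart, and the whole protein.  Vectorised.
#' @param tol relative degeneracy tolerance for |x - z| / z (default 1e-6).
#' @return tibble with `a`, `b`, `occ_light`, `occ_heavy`, `valid`, `flag`
#'   (one of `ok`, `x_equals_z`, `out_of_range`).
#' @export
compute_occupancy <- function(x, y, z, tol = 1e-6) {
  if (any(!is.finite(x) | !is.finite(y) | !is.finite(z)) ||
      any(x <= 0 | y <= 0 | z <= 0)) {
    stop("x, y, z must be positive and finite")
  }
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  degenerate <- abs(x - z) / z < tol
  a <- (z - y) / (x - z)
  b <- a * (x / y)
  occ_light <- a / (a + 1)
  occ_heavy <- b / (b + 1)
  out_of_range <- !degenerate &
    (occ_light < 0 | occ_light > 1 | occ_heavy < 0 | occ_heavy > 1)
  flag <- dplyr::case_when(degenerate ~ "x_equals_z",
                           out_of_range ~ "out_of_range",
                           TRUE ~ "ok")
  occ_light[degenerate] <- NA_real_
  occ_heavy[degenerate] <- NA_real_
  tibble::tibble(a = a, b = b, occ_light = occ_light, occ_heavy = occ_heavy,
                 valid = !degenerate, flag = flag)
}

#' Occupancy estimates for a table of ratio triplets
#'
#' Applies [compute_occupancy()] to each row of a triplet table from
#' [assemble_ratio_triplets()], carrying the site/variant/replicate metadata
#' through.
#'
#' @param triplets tibble with columns `x`, `y`, `z` plus metadata.
#' @param tol degeneracy tolerance, see [compute_occupancy()].
#' @return the input with estimate columns appended.
#' @export
occupancy_from_triplets <- function(triplets, tol = 1e-6) {
  est <- compute_occupancy(triplets$x, triplets$y, triplets$z, tol = tol)
  dplyr::bind_cols(triplets, est)
}

#' Frechet bounds on co-occupancy of two phosphosites
#'
#' Given marginal occupancies p1 and p2 at two sites, the fraction of
#' monomers phosphorylated at both is at least max(0, p1 + p2 - 1) and at
#' most min(p1, p2); under independence it would be p1 * p2.  With both
#' marginals at 0.95 this gives the 90--95\% doubly-phosphorylated window.
#'
#' @param p1,p2 occupancies in \[0, 1\].
#' @return list with `lower`, `upper`, `independent`.
#' @export
co_occupancy_bounds <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) {
    stop("occupancies must lie in [0, 1]")
  }
  list(lower = pmax(0, p1 + p2 - 1),
       upper = pmin(p1, p2),
       independent = p1 * p2)
}

#' Moles of phosphate per mole of protein
#'
#' The expected phosphate stoichiometry is the sum of the per-site
#' occupancies (each site contributes its occupancy in expectation).
#'
#' @param occupancies numeric vector of per-site occupancies in \[0, 1\].
#' @return total moles phosphate per mole protein.
#' @export
phosphate_stoichiometry <- function(occupancies) {
  if (any(occupancies < 0 | occupancies > 1)) {
    stop("occupancies must lie in [0, 1]")
  }
  if (length(occupancies) == 0) return(0)
  sum(occupancies)
}

#' Summarize occupancy estimates and compare groups
#'
#' Per (site, peptide variant, group): mean, sample sd (n - 1 denominator)
#' and n over valid estimates.  Estimates flagged `out_of_range` are included
#' only while the excess beyond \[0, 1\] is at most `max_excess` (default
#' 0.05); larger excursions are excluded as unreliable.  If a `comparison`
#' group is named, every other group is tested against it with a two-sided
#' two-sample t-test (Student by default, Welch optionally) and
#' Benjamini-Hochberg adjustment across the peptide variants tested together;
#' groups lacking a comparator get adjusted p = NA.
#'
#' @param estimates tibble from [occupancy_from_triplets()] with a `group`
#'   column (compartment / cell line label).
#' @param comparison optional name of the reference group.
#' @param which_channel `"light"` (native sample, default) or `"heavy"`.
#' @param var_equal Student (TRUE, default) or Welch.
#' @param max_excess inclusion tolerance for out-of-range estimates.
#' @return tibble per (site_id, variant, group): `mean_occ`, `sd_occ`, `n`,
#'   `p`, `adj_p`.
#' @export
summarize_and_compare <- function(estimates, comparison = NULL,
                                  which_channel = c("light", "heavy"),
                                  var_equal = TRUE, max_excess = 0.05) {
  which_channel <- match.arg(which_channel)
  occ_col <- paste0("occ_", which_channel)
  est <- estimates
  est$occ <- est[[occ_col]]
  excess <- pmax(est$occ - 1, -est$occ, 0)
  est <- est[est$valid & !is.na(est$occ) & excess <= max_excess, ]

  summ <- est |>
    dplyr::group_by(.data$site_id, .data$variant, .data$group) |>
    dplyr::summarise(
      mean_occ = mean(.data$occ),
      sd_occ = if (dplyr::n() >= 2) stats::sd(.data$occ) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
  summ$p <- NA_real_
  if (!is.null(comparison)) {
    for (i in seq_len(nrow(summ))) {
      if (summ$group[i] == comparison) next
      grp <- est$occ[est$site_id == summ$site_id[i] &
                       est$variant == summ$variant[i] &
                       est$group == summ$group[i]]
      ref <- est$occ[est$site_id == summ$site_id[i] &
                       est$variant == summ$variant[i] &
                       est$group == comparison]
      if (length(grp) >= 2 && length(ref) >= 2) {
        if (stats::sd(grp) == 0 && stats::sd(ref) == 0) {
          summ$p[i] <- if (mean(grp) == mean(ref)) 1 else 0
        } else {
          summ$p[i] <- stats::t.test(grp, ref, var.equal = var_equal)$p.value
        }
      }
    }
  }
  summ$adj_p <- NA_real_
  tested <- !is.na(summ$p)
  summ$adj_p[tested] <- stats::p.adjust(summ$p[tested], method = "BH")
  summ
}
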