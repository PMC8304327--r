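#' Forward-simulate capillary-western signals for the secretion assay
#'
#' Generates HA-tag and beta-actin signals for conditioned medium (CM) and
#' cell lysate.  The HA-tagged construct partitions into the CM according to
#' its true secreted fraction plus the accidental-release baseline shared with
#' actin (a non-secreted protein, so actin's CM fraction is the baseline
#' alone).  Observed signals are the compartment amount scaled by the analyzed
#' fraction of that compartment, times multiplicative log-normal noise.
#'
#' The baseline-corrected estimator ([secreted_fraction()]) inverts this model
#' exactly at \eqn{\sigma = 0}.
#'
#' @param secreted named numeric vector of true secreted fractions per
#'   construct (defaults mirror a WT-like 1.6\% and a mutant-like 4.5\%).
#' @param baseline accidental-release fraction shared by all proteins
#'   (default 0.03).
#' @param sigma multiplicative noise sd (log scale).
#' @param n_replicates replicates per construct.
#' @param fraction_analyzed named numeric vector with elements `CM` and
#'   `lysate`, each in (0, 1]: the portion of each compartment loaded on the
#'   instrument.
#' @param seed integer seed.
#' @return list with `measurements` (CWB measurement tibble) and `truth`.
#' @export
simulate_cwb_signals <- function(secreted = c(WT = 0.016, AA = 0.045),
                                 baseline = 0.03, sigma = 0.1,
                                 n_replicates = 3,
                                 fraction_analyzed = c(CM = 0.2, lysate = 0.05),
                                 seed = 1L) {
  stopifnot(all(secreted >= 0), baseline >= 0, baseline + max(secreted) < 1,
            sigma >= 0, n_replicates >= 1)
  if (any(fraction_analyzed <= 0 | fraction_analyzed > 1)) {
    stop("fraction_analyzed must be in (0, 1]")
  }
  withr::local_seed(sub_seed(seed, 3L))

  ha_amount <- 100; actin_amount <- 500
  rows <- list()
  for (construct in names(secreted)) {
    cm_frac_ha <- secreted[[construct]] + baseline
    for (r in seq_len(n_replicates)) {
      for (comp in c("CM", "lysate")) {
        fa <- fraction_analyzed[[comp]]
        amt_ha <- ha_amount * if (comp == "CM") cm_frac_ha else 1 - cm_frac_ha
        amt_actin <- actin_amount * if (comp == "CM") baseline else 1 - baseline
        noise <- function() exp(stats::rnorm(1, 0, sigma))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          target = c("HA", "actin"), compartment = comp,
          construct = construct, nucleotide = "none", replicate = r,
          signal = c(amt_ha * fa * noise(), amt_actin * fa * noise()),
          fraction_analyzed = fa
        )
      }
    }
  }
  truth <- tibble::tibble(construct = names(secreted),
                          secreted_fraction = unname(secreted),
                          baseline = baseline, sigma = sigma)
  list(measurements = dplyr::bind_rows(rows), truth = truth)
}
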