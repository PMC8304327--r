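#' Default peptide panel for the limited-proteolysis simulator
#'
#' Tryptic-sized peptide spans covering the bait from the N-terminal region to
#' the C terminus, including peptides before, spanning and after the dominant
#' C-domain cleavage site at K607.
#'
#' @return tibble with columns `peptide`, `start`, `end` (1-based inclusive).
#' @export
proteolysis_peptide_panel <- function() {
  spans <- list(
    c(42, 55), c(110, 124), c(180, 196), c(250, 263), c(310, 322),
    c(380, 395), c(440, 452), c(500, 514), c(560, 575), c(600, 615),
    c(620, 635), c(650, 664), c(668, 679)
  )
  tibble::tibble(
    peptide = sprintf("PEP_%03d_%03d", vapply(spans, `[`, 0, 1),
                      vapply(spans, `[`, 0, 2)),
    start = vapply(spans, `[`, 0, 1),
    end = vapply(spans, `[`, 0, 2)
  )
}

#' Forward-simulate gel-band peptide intensities for limited proteolysis
#'
#' Models an on-bead partial trypsin digestion with one dominant cleavage
#' site: at dose d the full-length fraction is F(d) (per genotype, from the
#' config); the cleaved fraction 1 - F(d) splits at the site.  Peptide
#' intensity in band A (full length) is proportional to F(d); the cleaved
#' portion of peptides located after the site is reallocated to a
#' small-fragment band for d > 0, while peptides spanning the site exist only
#' in the full-length molecule.  Multiplicative log-normal noise is applied
#' per (peptide, band, dose) row.
#'
#' @param fractions named list per genotype of named numeric vectors
#'   `dose -> full-length fraction`; the dose set must include 0 (where the
#'   fraction is 1).
#' @param panel peptide span panel, see [proteolysis_peptide_panel()].
#' @param site 1-based residue index of the dominant cleavage site
#'   (default 607, the reported major tryptic site in the C domain).
#' @param protein_length bait length used to validate spans (default 724,
#'   human Hsp90beta).
#' @param sigma multiplicative noise sd (log scale).
#' @param seed integer seed.
#' @return list with `bands` (long band-peptide matrix: peptide, start, end,
#'   genotype, dose, band, intensity) and `truth` (genotype, dose,
#'   frac_full_length).
#' @export
simulate_proteolysis_bands <- function(
    fractions = list(WT = c("0" = 1, "7" = 0.35, "14" = 0.10),
                     AA = c("0" = 1, "7" = 0.22, "14" = 0.06)),
    panel = proteolysis_peptide_panel(),
    site = 607, protein_length = 724,
    sigma = 0.05, seed = 1L) {
  stopifnot(length(fractions) >= 1, sigma >= 0)
  for (g in names(fractions)) {
    doses <- as.numeric(names(fractions[[g]]))
    if (!0 %in% doses) stop("dose set for genotype ", g, " must include 0")
    if (any(fractions[[g]] < 0 | fractions[[g]] > 1)) {
      stop("full-length fractions must be in [0, 1]")
    }
  }
  if (any(panel$start < 1 | panel$end > protein_length | panel$start > panel$end)) {
    stop("peptide span outside protein length ", protein_length)
  }
  withr::local_seed(sub_seed(seed, 2L))

  base_scale <- 1e5
  side <- assign_cleavage_side(panel, site = site)
  rows <- list()
  for (g in names(fractions)) {
    eps <- stats::rlnorm(nrow(panel), meanlog = log(base_scale), sdlog = 0.4)
    for (d_name in names(fractions[[g]])) {
      d <- as.numeric(d_name)
      f <- fractions[[g]][[d_name]]
      for (i in seq_len(nrow(panel))) {
        noise <- function() exp(stats::rnorm(1, 0, sigma))
        a_int <- eps[i] * f * noise()
        rows[[length(rows) + 1L]] <- tibble::tibble(
          peptide = panel$peptide[i], start = panel$start[i],
          end = panel$end[i], genotype = g, dose = d,
          band = "A", intensity = a_int
        )
        if (d > 0 && side$side[i] == "after" && f < 1) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            peptide = panel$peptide[i], start = panel$start[i],
            end = panel$end[i], genotype = g, dose = d,
            band = "F12", intensity = eps[i] * (1 - f) * noise()
          )
        }
      }
    }
  }
  truth <- dplyr::bind_rows(lapply(names(fractions), function(g) {
    tibble::tibble(genotype = g,
                   dose = as.numeric(names(fractions[[g]])),
                   frac_full_length = unname(fractions[[g]]))
  }))
  list(bands = dplyr::bind_rows(rows), truth = truth)
}
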