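#' Default charged-linker peptide panel
#'
#' The targeted-MS panel used for occupancy runs: for each phosphosite one
#' peptide without missed cleavage and one with missed cleavage(s) near the
#' site (acidic stretches around S226/S255 inhibit trypsin/LysC, so both
#' species are always present and are quantified separately).  Phosphopeptides
#' use inline \code{"pS"} notation; the unmodified counterpart shares the
#' identical backbone.
#'
#' @return tibble with columns `site_id`, `variant`, `phospho_sequence`,
#'   `unmodified_sequence`.
#' @export
cl_peptide_panel <- function() {
  tibble::tribble(
    ~site_id, ~variant, ~phospho_sequence,      ~unmodified_sequence,
    "S226",  "noMC",   "EIpSDDEAEEEK",          "EISDDEAEEEK",
    "S226",  "MC",     "EKEIpSDDEAEEEK",        "EKEISDDEAEEEK",
    "S255",  "noMC",   "IEDVGpSDEEDDSGK",       "IEDVGSDEEDDSGK",
    "S255",  "MC",     "IEDVGpSDEEDDSGKDKK",    "IEDVGSDEEDDSGKDKK"
  )
}

#' Default normalization peptides
#'
#' Unique bait peptides far from the charged linker used to derive the
#' whole-protein heavy/light ratio z.
#'
#' @return character vector of peptide sequences.
#' @export
cl_normalization_peptides <- function() {
  c("SIYYITGESK", "YIDQEELNK", "EGLELPEDEEEK")
}

#' Ground-truth parameters for the PRM occupancy simulator
#'
#' @param p_light named numeric vector of per-site light-channel occupancies
#'   in \[0, 1\] (the native sample).
#' @param q_heavy per-site heavy-channel residual occupancy in \[0, 1\].  The
#'   heavy reference is phosphatase-treated; dephosphorylation is
#'   near-complete but not assumed perfect, so the default is 0.01.
#' @param rho heavy/light protein mixing ratio (> 0).
#' @param sigma multiplicative log-normal noise sd on observed areas
#'   (log scale).
#' @param mc_fraction fraction of each site's peptide pool in the
#'   missed-cleavage variant, shared between channels (samples are mixed
#'   before digestion).
#' @return a `prm_truth` list.
#' @export
prm_truth <- function(p_light = c(S226 = 0.95, S255 = 0.95),
                      q_heavy = 0.01, rho = 1, sigma = 0.1,
                      mc_fraction = 0.3) {
  stopifnot(all(p_light >= 0 & p_light <= 1),
            all(q_heavy >= 0 & q_heavy <= 1),
            rho > 0, sigma >= 0,
            mc_fraction >= 0, mc_fraction <= 1)
  if (length(q_heavy) == 1) q_heavy <- stats::setNames(
    rep(q_heavy, length(p_light)), names(p_light))
  structure(list(p_light = p_light, q_heavy = q_heavy, rho = rho,
                 sigma = sigma, mc_fraction = mc_fraction),
            class = "prm_truth")
}

#' Forward-simulate a SILAC PRM occupancy experiment
#'
#' Emulates the two-channel design in which the native (light) bait is mixed
#' with a phosphatase-treated heavy reference before digestion.  For each
#' peptide species k and channel c the expected fragment area is
#' \deqn{A_c \cdot f_k(\mathrm{form} \mid \mathrm{occupancy}_c) \cdot m_v
#'   \cdot \varepsilon_k \cdot \varphi_{frag},}
#' with \eqn{A_{light} = 1}, \eqn{A_{heavy} = \rho}, \eqn{f_k} the
#' phospho-form fraction implied by the channel's occupancy, \eqn{m_v} the
#' missed-cleavage split, \eqn{\varepsilon_k} a per-species log-normal
#' ionization factor shared between channels, and fixed fragment proportions
#' (three fragments per peptide).  Observed areas are the expectation times
#' independent \eqn{\exp(N(0, \sigma^2))} noise per row.
#'
#' At \eqn{\sigma = 0} the per-peptide H/L ratios are therefore independent of
#' \eqn{\varepsilon_k} and \eqn{m_v}, and the downstream occupancy algebra
#' inverts the model exactly.
#'
#' @param truth a [prm_truth()] object.
#' @param panel site/peptide-pair panel, see [cl_peptide_panel()].
#' @param norm_peptides character vector of normalization peptide sequences
#'   (at least one is required: the whole-protein ratio z is undefined
#'   without them).
#' @param n_replicates number of replicates (default 3).
#' @param sample_id sample label written into the transition records.
#' @param seed integer seed; identical seeds give identical tables.
#' @return list with `transitions` (a transition-record tibble) and `truth`
#'   (machine-readable per-site ground-truth tibble).
#' @export
simulate_prm_experiment <- function(truth = prm_truth(),
                                    panel = cl_peptide_panel(),
                                    norm_peptides = cl_normalization_peptides(),
                                    n_replicates = 3,
                                    sample_id = "sample1",
                                    seed = 1L) {
  stopifnot(inherits(truth, "prm_truth"), n_replicates >= 1)
  if (length(norm_peptides) < 1) {
    stop("peptide panel must include normalization peptides (z undefined otherwise)")
  }
  missing_sites <- setdiff(panel$site_id, names(truth$p_light))
  if (length(missing_sites) > 0) {
    stop("no truth occupancy for site(s): ", paste(missing_sites, collapse = ", "))
  }
  withr::local_seed(sub_seed(seed, 0L))

  frag <- c(y3 = 0.2, y5 = 0.3, y7 = 0.5)
  base_scale <- 1e6

  # species table: one phospho + one unmodified species per (site, variant),
  # plus normalization peptides
  pair_species <- dplyr::bind_rows(
    tibble::tibble(site_id = panel$site_id, variant = panel$variant,
                   sequence = panel$phospho_sequence, form = "phospho"),
    tibble::tibble(site_id = panel$site_id, variant = panel$variant,
                   sequence = panel$unmodified_sequence, form = "unmodified")
  )
  norm_species <- tibble::tibble(site_id = NA_character_, variant = NA_character_,
                                 sequence = norm_peptides, form = "normalization")
  species <- dplyr::bind_rows(pair_species, norm_species)

  rows <- list()
  for (r in seq_len(n_replicates)) {
    # per-species ionization factor, drawn once per replicate, shared channels
    eps <- stats::rlnorm(nrow(species), meanlog = log(base_scale), sdlog = 0.5)
    for (i in seq_len(nrow(species))) {
      sp <- species[i, ]
      if (sp$form == "normalization") {
        f_light <- 1; f_heavy <- 1; mv <- 1
      } else {
        p <- truth$p_light[[sp$site_id]]
        q <- truth$q_heavy[[sp$site_id]]
        if (sp$form == "phospho") { f_light <- p; f_heavy <- q }
        else { f_light <- 1 - p; f_heavy <- 1 - q }
        mv <- if (sp$variant == "MC") truth$mc_fraction else 1 - truth$mc_fraction
      }
      for (chan in c("light", "heavy")) {
        amp <- if (chan == "light") 1 else truth$rho
        f <- if (chan == "light") f_light else f_heavy
        expected <- amp * f * mv * eps[i] * frag
        noise <- exp(stats::rnorm(length(frag), 0, truth$sigma))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          modified_sequence = sp$sequence,
          precursor_charge = 2L,
          fragment_ion = names(frag),
          label_channel = chan,
          sample_id = sample_id,
          replicate = r,
          area = unname(expected * noise)
        )
      }
    }
  }
  transitions <- dplyr::bind_rows(rows)
  truth_tbl <- tibble::tibble(
    site_id = names(truth$p_light),
    p_light = unname(truth$p_light),
    q_heavy = unname(truth$q_heavy[names(truth$p_light)]),
    rho = truth$rho,
    sigma = truth$sigma
  )
  list(transitions = transitions, truth = truth_tbl)
}
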