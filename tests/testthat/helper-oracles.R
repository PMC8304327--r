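# Independent oracles and fixture builders used across the suite.

# Forward two-state mixing model: light channel has occupancy p_l, heavy
# channel p_h, heavy/light protein amount rho.  Returns the observable
# (x, y, z) H/L ratio triplet.
forward_triplet <- function(p_l, p_h, rho = 1) {
  list(x = rho * p_h / p_l,
       y = rho * (1 - p_h) / (1 - p_l),
       z = rho)
}

# Grid-search inversion of the forward model: minimizes the squared ratio
# residual over p_light on a 1e-4 grid, then zooms.  Independent of the
# closed-form algebra in compute_occupancy().
grid_invert_occupancy <- function(x, y, z) {
  obj <- function(p_l) {
    p_h <- x * p_l / z                      # matches the x ratio exactly
    y_hat <- z * (1 - p_h) / (1 - p_l)
    ifelse(p_h < 0 | p_h > 1, Inf, (y_hat - y)^2)
  }
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  vals <- obj(grid)
  best <- grid[which.min(vals)]
  step <- 1e-4
  for (zoom in 1:8) {
    grid <- seq(max(1e-12, best - step), min(1 - 1e-12, best + step),
                length.out = 41)
    vals <- obj(grid)
    best <- grid[which.min(vals)]
    step <- step / 10
  }
  list(occ_light = best, occ_heavy = x * best / z)
}

# panel of n synthetic phospho/unmodified peptide pairs (one variant each),
# for Monte-Carlo recovery checks at larger n than the 2-site default panel
synthetic_pair_panel <- function(n) {
  tibble::tibble(
    site_id = sprintf("X%03d", seq_len(n)),
    variant = "noMC",
    phospho_sequence = sprintf("AAApSEE%03dK", seq_len(n)),
    unmodified_sequence = sprintf("AAASEE%03dK", seq_len(n))
  )
}

# run the full PRM -> triplet -> occupancy pipeline on a simulation result
occupancy_pipeline <- function(sim, panel = cl_peptide_panel(),
                               norm_peptides = cl_normalization_peptides()) {
  quants <- peptide_areas_from_transitions(sim$transitions)
  z_tbl <- protein_reference_ratio(
    quants[quants$modified_sequence %in% norm_peptides, ])
  triplets <- assemble_ratio_triplets(quants, panel, z_tbl)
  occupancy_from_triplets(triplets)
}

# label-free co-IP pipeline: filter -> impute controls -> call interactors
labelfree_calls <- function(sim, seed, bait_condition = "WT") {
  kept <- filter_protein_groups(sim$groups, sim$design, mode = "labelfree")
  mat <- quant_matrix(kept, sim$design, mode = "labelfree")
  imp <- impute_controls(mat, sim$design, seed = seed)
  call_interactors(imp$mat, sim$design, mode = "labelfree",
                   bait_condition = bait_condition,
                   exclude = "BAIT_HSP90AB1")
}
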