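# Shared fixtures, all generated in code.

# Random strand breaks in a cube of given side (nm); small sides force dense
# clustering, large sides force isolation.
random_breaks <- function(n, side_nm, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      x_nm = runif(n, 0, side_nm),
      y_nm = runif(n, 0, side_nm),
      z_nm = runif(n, 0, side_nm),
      strand = rbinom(n, 1, 0.5),
      track_id = 1L
    )
  })
}

# Breaks at explicit positions on the x axis with given strands.
axis_breaks <- function(x_nm, strand) {
  tibble::tibble(x_nm = x_nm, y_nm = 0, z_nm = 0,
                 strand = as.integer(strand), track_id = 1L)
}

# Depositions at the origin with given energies.
point_depositions <- function(edep_eV, track_id = 1L) {
  n <- length(edep_eV)
  tibble::tibble(x_nm = rep(0, n), y_nm = rep(0, n), z_nm = rep(0, n),
                 edep_eV = edep_eV, track_id = as.integer(track_id),
                 particle = "e-")
}

# A tiny valid phase space in the vial frame around a given placement.
toy_phase_space <- function(placement, per_cell = 2, radionuclide = "Lu-177",
                            nt = 100, seed = 42) {
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(placement)), function(i) {
      k <- per_cell
      u <- matrix(rnorm(3 * k), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      data.frame(
        name = rep(c("e-", "gamma"), length.out = k),
        ekin_MeV = runif(k, 0.01, 1),
        x_um = placement$x_um[i] + 3.75 * u[, 1],
        y_um = placement$y_um[i] + 3.75 * u[, 2],
        z_um = placement$z_um[i] + 3.75 * u[, 3],
        dx = -u[, 1], dy = -u[, 2], dz = -u[, 3],
        weight = 1,
        event_id = seq_len(k),
        cell_id = placement$cell_id[i]
      )
    }))
    phase_space(rows, radionuclide = radionuclide, nt = nt, frame = "vial")
  })
}

# Fixed-energy deterministic track model (every deposition breaks if accepted).
fixed_model <- function(particle = "alpha", density = 100,
                        value_eV = 100, range = c(0, 10)) {
  track_model(particle, density,
              list(family = "fixed", value_eV = value_eV), range)
}

# Minimal pipeline configuration for smoke tests.
demo_config <- function(seed = 1, n_cells = 20, n_primaries = 30,
                        replicates = 2) {
  list(
    vial = list(radius_mm = 7.2, height_mm = 49.12),
    cells = list(n = n_cells, radius_um = 3.75, nucleus_radius_um = 3.1),
    tracks = list(n_primaries = n_primaries, alpha_fraction = 1),
    nuclide = list(name = "Ra-223", half_life_h = 274.32,
                   d_blood_mGy_mL_per_MBq = 80),
    run = list(seed = seed, replicates = replicates)
  )
}
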