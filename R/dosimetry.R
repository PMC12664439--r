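#' Per-event energy tally of a scoring run
#'
#' Holds the energy deposited in all scored nuclei per primary event (keV),
#' the number of simulated nuclear transformations `nt`, and the number of
#' cells. Events that deposited nothing are part of the tally as explicit
#' zeros: when `nt` exceeds the number of supplied energies the tally is
#' padded with zeros up to `nt`.
#'
#' @param per_event_energy_keV Non-negative energies (keV), one per event.
#' @param nt Number of simulated nuclear transformations (>= length of the
#'   energy vector). Default: the number of energies supplied.
#' @param n_cells Number of scored cells. Default 1000.
#' @return A `run_tally`.
#' @export
run_tally <- function(per_event_energy_keV, nt = length(per_event_energy_keV),
                      n_cells = 1000) {
  stop_if_not_positive(per_event_energy_keV = per_event_energy_keV,
                       .allow_zero = TRUE)
  stop_if_not_positive(n_cells = n_cells)
  if (nt < length(per_event_energy_keV)) {
    abort("`nt` cannot be smaller than the number of recorded events.")
  }
  e <- c(per_event_energy_keV,
         rep(0, nt - length(per_event_energy_keV)))
  structure(list(per_event_energy_keV = e, nt = nt, n_cells = n_cells),
            class = "run_tally")
}

#' Mean energy deposited in a lymphocyte nucleus per nuclear transformation
#'
#' `sum(E_i) / (N_cells * nt)` in keV per transformation: the total energy
#' scored across all nuclei divided by the number of cells and the number of
#' simulated decays.
#'
#' @param tally A [run_tally()].
#' @return keV per nuclear transformation.
#' @export
mean_deposited_energy <- function(tally) {
  stopifnot(inherits(tally, "run_tally"))
  if (tally$nt < 1) abort("`nt` must be >= 1.")
  sum(tally$per_event_energy_keV) / (tally$n_cells * tally$nt)
}

#' History-by-history uncertainty of the mean deposited energy
#'
#' Standard error of the per-event mean, scaled by the cell count:
#' `(1 / N_cells) * sqrt((sum(E^2)/N - (sum(E)/N)^2) / (N - 1))` with
#' `N = nt` and zero-deposit events included as zeros. Equal to the
#' conventional `sd(E) / sqrt(N) / N_cells`.
#'
#' @param tally A [run_tally()].
#' @return keV per nuclear transformation.
#' @export
deposited_energy_uncertainty <- function(tally) {
  stopifnot(inherits(tally, "run_tally"))
  e <- tally$per_event_energy_keV
  N <- tally$nt
  if (N < 2) abort("History-by-history uncertainty needs at least 2 events.")
  v <- (sum(e^2) / N - (sum(e) / N)^2) / (N - 1)
  sqrt(max(v, 0)) / tally$n_cells
}

#' Nuclear transformations per becquerel during one hour of irradiation
#'
#' Decay integral of unit initial activity over 1 h:
#' `(1 - exp(-lambda * 3600 s)) / lambda` with `lambda = ln 2 / half-life`,
#' which tends to 3600 for long-lived nuclides. Set
#' `decay_corrected = FALSE` to ignore decay during the hour (plain
#' `A * 3600`).
#'
#' @param half_life_h Half-life in hours.
#' @param decay_corrected Account for decay during the hour (default TRUE).
#' @return Transformations per Bq in 1 h (at most 3600).
#' @examples
#' transformations_per_hour(6.0067)  # ~3.40e3
#' @export
transformations_per_hour <- function(half_life_h, decay_corrected = TRUE) {
  stop_if_not_positive(half_life_h = half_life_h)
  if (!decay_corrected) return(3600)
  lambda_s <- log(2) / (half_life_h * 3600)
  (1 - exp(-lambda_s * 3600)) / lambda_s
}

#' Activity represented by a number of simulated transformations
#'
#' `A [MBq] = nt / (N1h * 1e6)`: the activity whose 1-hour decay count equals
#' the simulated event count.
#'
#' @param nt Simulated nuclear transformations.
#' @param N1h Transformations per Bq in 1 h ([transformations_per_hour()]).
#' @return Activity (MBq).
#' @export
activity_from_events <- function(nt, N1h) {
  stop_if_not_positive(N1h = N1h)
  stop_if_not_positive(nt = nt, .allow_zero = TRUE)
  nt / (N1h * 1e6)
}

#' Absorbed dose to whole blood
#'
#' `D [mGy] = A [MBq] * d_blood [mGy mL / MBq] / volume [mL]` for the 8 mL
#' vial convention.
#'
#' @param A_MBq Activity (MBq).
#' @param d_blood_mGy_mL_per_MBq Whole-blood absorbed dose coefficient.
#' @param volume_mL Blood volume (mL). Default 8.
#' @return Absorbed dose (mGy).
#' @export
blood_dose <- function(A_MBq, d_blood_mGy_mL_per_MBq, volume_mL = 8) {
  stop_if_not_positive(volume_mL = volume_mL)
  stop_if_not_positive(A_MBq = A_MBq, d_blood_mGy_mL_per_MBq = d_blood_mGy_mL_per_MBq,
                       .allow_zero = TRUE)
  A_MBq * d_blood_mGy_mL_per_MBq / volume_mL
}

#' Lymphocyte-nucleus absorbed dose coefficient
#'
#' Converts the mean energy per transformation into the nucleus dose
#' coefficient `d_lymph` (mGy mL / MBq), defined so that
#' `D_nucleus = A [MBq] * d_lymph / volume` mirrors the whole-blood
#' convention and makes `d_lymph` directly comparable with `d_blood`:
#' `d_lymph = (E_per_nt [J] / mass [kg]) * N1h * 1e6 * volume * 1e3`.
#'
#' @param E_per_nt_keV Mean deposited energy (keV per transformation).
#' @param nucleus_mass_kg Nucleus mass (kg); ~1.25e-13 for a 3.1 um water
#'   sphere, see [nucleus_metrics()].
#' @param N1h Transformations per Bq in 1 h.
#' @param volume_mL Blood volume (mL). Default 8.
#' @return Dose coefficient (mGy mL / MBq).
#' @export
lymph_dose_coefficient <- function(E_per_nt_keV, nucleus_mass_kg, N1h,
                                   volume_mL = 8) {
  stop_if_not_positive(nucleus_mass_kg = nucleus_mass_kg, N1h = N1h,
                       volume_mL = volume_mL)
  stop_if_not_positive(E_per_nt_keV = E_per_nt_keV, .allow_zero = TRUE)
  gy_per_nt <- E_per_nt_keV * KEV_TO_JOULE / nucleus_mass_kg
  gy_per_nt * N1h * 1e6 * volume_mL * 1e3
}

#' Double-strand breaks per cell and per milligray
#'
#' `DSB_MC = total DSB / (N_cells * D_blood)`, the simulation counterpart of
#' the experimentally scored radiation-induced foci per cell per mGy.
#'
#' @param total_dsb Total DSB count over all cells.
#' @param n_cells Number of cells.
#' @param D_blood_mGy Absorbed dose to blood (mGy), strictly positive.
#' @return DSB per cell per mGy.
#' @export
dsb_per_cell_per_mGy <- function(total_dsb, n_cells, D_blood_mGy) {
  stop_if_not_positive(n_cells = n_cells, D_blood_mGy = D_blood_mGy)
  stop_if_not_positive(total_dsb = total_dsb, .allow_zero = TRUE)
  total_dsb / (n_cells * D_blood_mGy)
}

#' Standard deviation over independent-seed replicates
#'
#' Sample standard deviation (n - 1 denominator) across k >= 2 runs of the
#' same configuration under different seeds — the replicate uncertainty
#' attached to `DSB_MC` and the alpha-track coefficients.
#'
#' @param values Numeric vector, one value per replicate.
#' @return Standard deviation.
#' @export
seed_replicate_sd <- function(values) {
  if (length(values) < 2) abort("Replicate SD needs at least 2 runs.")
  stats::sd(values)
}

#' Radionuclide context for dose conversions
#'
#' @param name Radionuclide label.
#' @param half_life_h Half-life (hours).
#' @param d_blood_mGy_mL_per_MBq Whole-blood dose coefficient (external input
#'   from a macroscopic transport calculation or measurement).
#' @param blood_volume_mL Vial blood volume (mL). Default 8.
#' @param decay_corrected Passed to [transformations_per_hour()].
#' @return A `nuclide_context` list including the derived `N1h`.
#' @export
nuclide_context <- function(name, half_life_h, d_blood_mGy_mL_per_MBq,
                            blood_volume_mL = 8, decay_corrected = TRUE) {
  stop_if_not_positive(half_life_h = half_life_h,
                       d_blood_mGy_mL_per_MBq = d_blood_mGy_mL_per_MBq,
                       blood_volume_mL = blood_volume_mL)
  structure(
    list(name = name, half_life_h = half_life_h,
         d_blood_mGy_mL_per_MBq = d_blood_mGy_mL_per_MBq,
         blood_volume_mL = blood_volume_mL,
         N1h = transformations_per_hour(half_life_h, decay_corrected)),
    class = "nuclide_context"
  )
}
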