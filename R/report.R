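#' Cluster-complexity report per cell and per milligray
#'
#' Normalises the damage tallies of a scored exposure by `N_cells * D_blood`:
#' clusters per cell per mGy broken down by cluster size (number of strand
#' breaks), and the SSB / complex SSB / simple DSB / complex DSB rates — the
#' tabular analog of the damage-complexity histograms.
#'
#' @param summaries Track damage summaries ([score_exposure()]).
#' @param n_cells Number of cells the exposure represents.
#' @param D_blood_mGy Absorbed dose to blood (mGy), strictly positive.
#' @return A `cluster_report` tibble with columns `kind`
#'   (`"cluster_size"` rows plus the class rates), `size` (cluster size, `NA`
#'   for class rates), and `rate` (per cell per mGy).
#' @export
build_cluster_report <- function(summaries, n_cells, D_blood_mGy) {
  stop_if_not_positive(n_cells = n_cells, D_blood_mGy = D_blood_mGy)
  summaries <- as_tibble(summaries)
  norm <- n_cells * D_blood_mGy
  sizes <- unlist(summaries$cluster_sizes)
  size_tab <- if (length(sizes)) table(sizes) else table(integer(0))
  per_size <- tibble(
    kind = "cluster_size",
    size = as.integer(names(size_tab)),
    rate = as.numeric(size_tab) / norm
  )
  rates <- tibble(
    kind = c("ssb", "complex_ssb", "simple_dsb", "complex_dsb", "dsb_total"),
    size = NA_integer_,
    rate = c(sum(summaries$n_ssb), sum(summaries$n_complex_ssb),
             sum(summaries$n_simple_dsb), sum(summaries$n_complex_dsb),
             sum(summaries$n_dsb)) / norm
  )
  out <- dplyr::bind_rows(per_size, rates)
  attr(out, "n_cells") <- n_cells
  attr(out, "D_blood_mGy") <- D_blood_mGy
  class(out) <- c("cluster_report", class(tibble()))
  out
}

#' Read a run configuration file
#'
#' YAML with sections `vial` (`radius_mm`, `height_mm`), `cells` (`n`,
#' `radius_um`, `nucleus_radius_um`), `tracks` (`n_primaries`,
#' `alpha_fraction`, optional `depositions_file`), `damage` (any
#' [damage_parameters()] argument), `nuclide` (`name`, `half_life_h`,
#' `d_blood_mGy_mL_per_MBq`), and `run` (`seed` — required, never defaulted —
#' `nt`, `replicates`, `thresholds`).
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

config_get <- function(config, keys, default = NULL, required = FALSE) {
  node <- config
  for (k in keys) {
    node <- node[[k]]
    if (is.null(node)) break
  }
  if (is.null(node)) {
    if (required) {
      abort(sprintf("Configuration key `%s` is required and has no default.",
                    paste(keys, collapse = ".")))
    }
    return(default)
  }
  node
}

#' Run the full damage pipeline
#'
#' Orchestrates the chain: place cells in the vial, generate a synthetic
#' nucleus exposure (or read a depositions file), score strand breaks and
#' clusters per primary, convert to doses, and build the cluster and
#' alpha-track reports. The run is repeated for `run.replicates` independent
#' seeds (seed, seed+1, ...) and replicate standard deviations are attached to
#' the headline rates. A manifest records every input, seed and parameter so
#' the run can be reproduced byte-identically.
#'
#' The configuration must name a `run.seed`; no seed is ever chosen silently.
#'
#' @param config Configuration list (see [read_run_config()]) or a YAML path.
#' @return A `lymphdsb_run` list: `placement`, `summaries` (first replicate),
#'   `dose`, `cluster_report`, `alpha_report`, `replicates` (per-replicate
#'   headline values), `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- config_get(config, c("run", "seed"), required = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  vial <- stage("geometry", vial_geometry(
    radius_mm = config_get(config, c("vial", "radius_mm"), 7.2),
    height_mm = config_get(config, c("vial", "height_mm"), 49.12)
  ))
  n_cells <- config_get(config, c("cells", "n"), 1000)
  nucleus_radius_um <- config_get(config, c("cells", "nucleus_radius_um"), 3.1)
  placement <- stage("placement", place_cells(
    n = n_cells, vial = vial,
    cell_radius_um = config_get(config, c("cells", "radius_um"), 3.75),
    nucleus_radius_um = nucleus_radius_um,
    seed = seed
  ))

  damage_args <- config_get(config, "damage", list())
  params <- stage("damage-parameters",
                  do.call(damage_parameters, damage_args))

  nuclide <- stage("nuclide", nuclide_context(
    name = config_get(config, c("nuclide", "name"), required = TRUE),
    half_life_h = config_get(config, c("nuclide", "half_life_h"), required = TRUE),
    d_blood_mGy_mL_per_MBq =
      config_get(config, c("nuclide", "d_blood_mGy_mL_per_MBq"), required = TRUE)
  ))

  n_primaries <- config_get(config, c("tracks", "n_primaries"), 500)
  alpha_fraction <- config_get(config, c("tracks", "alpha_fraction"), 1)
  depositions_file <- config_get(config, c("tracks", "depositions_file"))
  k <- config_get(config, c("run", "replicates"), 5)
  nt <- config_get(config, c("run", "nt"), n_primaries)
  th <- alpha_thresholds(
    min_length_um = config_get(config, c("run", "thresholds", "min_length_um"), 0.75),
    min_dsb = config_get(config, c("run", "thresholds", "min_dsb"), 7)
  )

  models <- list()
  weights <- numeric()
  if (alpha_fraction > 0) {
    models <- c(models, list(alpha_track_model()))
    weights <- c(weights, alpha_fraction)
  }
  if (alpha_fraction < 1) {
    models <- c(models, list(electron_track_model()))
    weights <- c(weights, 1 - alpha_fraction)
  }

  run_once <- function(rep_seed) {
    exposure <- stage("track-generation", {
      if (!is.null(depositions_file)) {
        read_exposure(depositions_file, nucleus_radius_um = nucleus_radius_um)
      } else {
        generate_nucleus_exposure(n_primaries, models, weights,
                                  nucleus_radius_um = nucleus_radius_um,
                                  seed = rep_seed)
      }
    })
    summaries <- stage("scoring",
                       score_exposure(exposure, params,
                                      seed = derive_seed(rep_seed, 7919)))
    dose <- stage("dosimetry", {
      tally <- run_tally(summaries$deposited_energy_eV / 1000, nt = nt,
                         n_cells = n_cells)
      A <- activity_from_events(nt, nuclide$N1h)
      D <- blood_dose(A, nuclide$d_blood_mGy_mL_per_MBq,
                      nuclide$blood_volume_mL)
      mass <- nucleus_metrics(nucleus_radius_um)$mass_kg
      list(
        E_per_nt_keV = mean_deposited_energy(tally),
        E_per_nt_se_keV = deposited_energy_uncertainty(tally),
        activity_MBq = A,
        D_blood_mGy = D,
        d_lymph_mGy_mL_per_MBq = lymph_dose_coefficient(
          mean_deposited_energy(tally), mass, nuclide$N1h,
          nuclide$blood_volume_mL),
        dsb_per_cell_per_mGy = dsb_per_cell_per_mGy(sum(summaries$n_dsb),
                                                    n_cells, D)
      )
    })
    alpha_rows <- dplyr::filter(summaries, .data$particle == "alpha")
    alpha_report <- stage("alpha-analysis", {
      if (nrow(alpha_rows)) {
        kept <- apply_track_thresholds(alpha_rows, th)
        list(
          n_tracks = nrow(alpha_rows),
          n_tracks_thresholded = nrow(kept),
          tracks_per_100cells_per_mGy = alpha_tracks_per_100cells_per_mGy(
            nrow(alpha_rows), n_cells, dose$D_blood_mGy),
          tracks_per_100cells_per_mGy_thresholded =
            alpha_tracks_per_100cells_per_mGy(nrow(kept), n_cells,
                                              dose$D_blood_mGy),
          dsb_per_um = if (sum(alpha_rows$alpha_track_length_um) > 0)
            linear_dsb_density(alpha_rows) else NA_real_,
          dsb_per_um_thresholded = if (nrow(kept) &&
                                       sum(kept$alpha_track_length_um) > 0)
            linear_dsb_density(kept) else NA_real_
        )
      } else {
        list(n_tracks = 0L, n_tracks_thresholded = 0L,
             tracks_per_100cells_per_mGy = 0,
             tracks_per_100cells_per_mGy_thresholded = 0,
             dsb_per_um = NA_real_, dsb_per_um_thresholded = NA_real_)
      }
    })
    list(summaries = summaries, dose = dose, alpha_report = alpha_report)
  }

  rep_seeds <- seed + seq_len(k) - 1L
  reps <- lapply(rep_seeds, run_once)
  first <- reps[[1]]

  replicates <- purrr::map2_dfr(reps, rep_seeds, function(r, s) {
    tibble(seed = s,
           dsb_per_cell_per_mGy = r$dose$dsb_per_cell_per_mGy,
           dsb_per_um = r$alpha_report$dsb_per_um,
           tracks_per_100cells_per_mGy = r$alpha_report$tracks_per_100cells_per_mGy,
           E_per_nt_keV = r$dose$E_per_nt_keV)
  })

  dose <- first$dose
  dose$dsb_per_cell_per_mGy_sd <- if (k >= 2)
    seed_replicate_sd(replicates$dsb_per_cell_per_mGy) else NA_real_
  dose <- structure(dose, class = "dose_result")

  cluster_report <- build_cluster_report(first$summaries, n_cells,
                                         dose$D_blood_mGy)

  manifest <- list(
    package_version = as.character(utils::packageVersion("lymphdsb")),
    seed = seed,
    replicate_seeds = rep_seeds,
    n_cells = n_cells,
    n_primaries = n_primaries,
    nt = nt,
    alpha_fraction = alpha_fraction,
    depositions_file = depositions_file,
    vial = unclass(vial),
    nucleus_radius_um = nucleus_radius_um,
    damage_parameters = unclass(params),
    nuclide = unclass(nuclide),
    thresholds = unclass(th),
    replicates = k
  )

  structure(
    list(placement = placement, summaries = first$summaries, dose = dose,
         cluster_report = cluster_report, alpha_report = first$alpha_report,
         replicates = replicates, manifest = manifest),
    class = "lymphdsb_run"
  )
}
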