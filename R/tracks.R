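#' Synthetic track model
#'
#' Stand-in for full track-structure transport: a particle crossing the
#' nucleus is a straight chord carrying a 1-D Poisson process of point energy
#' depositions. The linear deposition density (per um) may depend on kinetic
#' energy — for alphas it is derived from a user-editable LET table divided by
#' the mean single-deposition energy — and deposition energies are i.i.d. from
#' a named sampler (default lognormal, median 60 eV).
#'
#' The defaults are placeholders calibrated for order-of-magnitude sanity
#' only; edit the LET table or density to study other regimes.
#'
#' @param particle_name Particle label (`"alpha"`, `"e-"`, ...).
#' @param density Either a single number (depositions per um) or a function of
#'   kinetic energy in MeV returning depositions per um.
#' @param sampler Named list describing the per-deposition energy distribution:
#'   `list(family = "lognormal", meanlog, sdlog)` or
#'   `list(family = "fixed", value_eV)`.
#' @param ekin_range_MeV Length-2 numeric, the admissible kinetic energies.
#' @return A `track_model`.
#' @export
track_model <- function(particle_name, density, sampler, ekin_range_MeV) {
  if (!is.function(density)) {
    stop_if_not_positive(density = density, .allow_zero = TRUE)
    d <- density
    density <- function(ekin_MeV) rep(d, length(ekin_MeV))
  }
  stopifnot(length(ekin_range_MeV) == 2, ekin_range_MeV[1] <= ekin_range_MeV[2])
  sampler <- validate_sampler(sampler)
  structure(
    list(particle_name = particle_name, density = density, sampler = sampler,
         ekin_range_MeV = ekin_range_MeV),
    class = "track_model"
  )
}

validate_sampler <- function(sampler) {
  if (!is.list(sampler) || is.null(sampler$family)) {
    abort("`sampler` must be a named list with a `family` element.")
  }
  switch(sampler$family,
    lognormal = {
      stopifnot(is.numeric(sampler$meanlog), is.numeric(sampler$sdlog),
                sampler$sdlog >= 0)
    },
    fixed = stop_if_not_positive(value_eV = sampler$value_eV),
    abort(sprintf("Unknown sampler family '%s' (use 'lognormal' or 'fixed').",
                  sampler$family))
  )
  sampler
}

sample_deposition_energies <- function(n, sampler) {
  switch(sampler$family,
    lognormal = rlnorm(n, meanlog = sampler$meanlog, sdlog = sampler$sdlog),
    fixed = rep(sampler$value_eV, n)
  )
}

mean_deposition_energy_eV <- function(sampler) {
  switch(sampler$family,
    lognormal = exp(sampler$meanlog + sampler$sdlog^2 / 2),
    fixed = sampler$value_eV
  )
}

#' Placeholder alpha LET table in liquid water
#'
#' Two-column table (kinetic energy in MeV, electronic LET in keV/um) with the
#' Bragg-peak shape of alpha stopping in water: rising to ~226 keV/um near
#' 0.7 MeV then falling towards ~80 keV/um at 8 MeV. Values are round-number
#' placeholders for order-of-magnitude studies, not evaluated stopping-power
#' data; users substitute their own table for quantitative work.
#'
#' @return A tibble with `ekin_MeV`, `let_keV_um`.
#' @export
default_alpha_let_table <- function() {
  tibble(
    ekin_MeV   = c(0.01, 0.05, 0.1, 0.3, 0.5, 0.7, 1, 2, 3, 4, 5, 6, 7, 8.36),
    let_keV_um = c(45,   90,  120, 180, 210, 226, 219, 170, 140, 120, 105, 95, 86, 78)
  )
}

#' Default alpha and electron track models
#'
#' `alpha_track_model()` interpolates the LET table linearly in kinetic energy
#' and converts LET to a deposition density by dividing by the sampler's mean
#' single-deposition energy. `electron_track_model()` uses a constant sparse
#' density (default 0.5/um, the low-LET regime).
#'
#' @param let_table LET table as from [default_alpha_let_table()].
#' @param sampler Per-deposition energy sampler; default lognormal with median
#'   60 eV, sdlog 0.8.
#' @param ekin_range_MeV Admissible kinetic energies (MeV); alphas default to
#'   the 0.01–8.36 MeV span seen in the source phase spaces.
#' @param density_per_um Electron deposition density (per um).
#' @return A `track_model`.
#' @export
alpha_track_model <- function(let_table = default_alpha_let_table(),
                              sampler = list(family = "lognormal",
                                             meanlog = log(60), sdlog = 0.8),
                              ekin_range_MeV = c(0.01, 8.36)) {
  sampler <- validate_sampler(sampler)
  mean_edep <- mean_deposition_energy_eV(sampler)
  tab <- as_tibble(let_table)
  stopifnot(all(c("ekin_MeV", "let_keV_um") %in% names(tab)))
  density <- function(ekin_MeV) {
    let <- stats::approx(tab$ekin_MeV, tab$let_keV_um, xout = ekin_MeV,
                         rule = 2)$y
    let * 1000 / mean_edep  # keV/um -> eV/um -> depositions/um
  }
  track_model("alpha", density, sampler, ekin_range_MeV)
}

#' @rdname alpha_track_model
#' @export
electron_track_model <- function(density_per_um = 0.5,
                                 sampler = list(family = "lognormal",
                                                meanlog = log(60), sdlog = 0.8),
                                 ekin_range_MeV = c(1e-5, 2.3)) {
  track_model("e-", density_per_um, sampler, ekin_range_MeV)
}

#' Chord length of a straight ray through the spherical nucleus
#'
#' For an entry point on the sphere surface and a unit direction, the chord is
#' `-2 (e . u)` when the direction points inward (`e . u < 0`), the standard
#' circle-chord result `2 sqrt(r^2 - b^2)` at impact parameter `b`. Tangent
#' rays give 0; outward rays give 0 with a warning.
#'
#' @param entry Length-3 numeric, point on the sphere (same units as radius).
#' @param direction Length-3 unit vector.
#' @param nucleus_radius Sphere radius.
#' @return Chord length in the units of `entry`, in `[0, 2 * radius]`.
#' @examples
#' chord_length(c(-3.1, 0, 0), c(1, 0, 0), 3.1)  # diameter 6.2
#' @export
chord_length <- function(entry, direction, nucleus_radius) {
  stopifnot(length(entry) == 3, length(direction) == 3)
  stop_if_not_positive(nucleus_radius = nucleus_radius)
  if (abs(sqrt(sum(entry^2)) - nucleus_radius) > 1e-6 * nucleus_radius) {
    abort("`entry` must lie on the nucleus surface.")
  }
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) abort("`direction` must be a unit vector.")
  proj <- sum(entry * direction)
  if (proj > 1e-12 * nucleus_radius) {
    warn("Direction points outward from the nucleus; chord length is 0.")
    return(0)
  }
  max(0, -2 * proj)
}

#' Generate one synthetic particle track through the nucleus
#'
#' Depositions are placed at Poisson-process positions along the straight
#' chord from `entry` in `direction`, with linear density `model$density`
#' evaluated at the track's kinetic energy, and energies drawn i.i.d. from the
#' model's sampler. The generation is deterministic for a fixed seed.
#' `generate_alpha_track()` additionally reports the chord as the alpha track
#' length inside the nucleus; `generate_electron_track()` reports depositions
#' only.
#'
#' @param entry Entry point on the nucleus surface (um, nucleus-local).
#' @param direction Unit direction (pointing inward).
#' @param kinetic_energy_MeV Kinetic energy; must fall in the model's range.
#' @param model A [track_model()].
#' @param seed Integer seed.
#' @param nucleus_radius_um Nucleus radius (um).
#' @param track_id Track identifier attached to the depositions.
#' @return `generate_alpha_track()`: list with `depositions` (tibble `x_nm`,
#'   `y_nm`, `z_nm`, `edep_eV`, `track_id`, `particle`) and `chord_um`.
#'   `generate_electron_track()`: the depositions tibble.
#' @export
generate_alpha_track <- function(entry, direction, kinetic_energy_MeV, model,
                                 seed, nucleus_radius_um = 3.1, track_id = 1L) {
  deps <- generate_track_depositions(entry, direction, kinetic_energy_MeV,
                                     model, seed, nucleus_radius_um, track_id)
  list(depositions = deps$depositions, chord_um = deps$chord_um)
}

#' @rdname generate_alpha_track
#' @export
generate_electron_track <- function(entry, direction, kinetic_energy_MeV, model,
                                    seed, nucleus_radius_um = 3.1,
                                    track_id = 1L) {
  generate_track_depositions(entry, direction, kinetic_energy_MeV, model, seed,
                             nucleus_radius_um, track_id)$depositions
}

generate_track_depositions <- function(entry, direction, kinetic_energy_MeV,
                                       model, seed, nucleus_radius_um,
                                       track_id) {
  stopifnot(inherits(model, "track_model"))
  rng <- model$ekin_range_MeV
  if (kinetic_energy_MeV < rng[1] || kinetic_energy_MeV > rng[2]) {
    abort(sprintf("Kinetic energy %.4g MeV outside the model range [%g, %g] MeV.",
                  kinetic_energy_MeV, rng[1], rng[2]))
  }
  chord <- chord_length(entry, direction, nucleus_radius_um)
  density <- model$density(kinetic_energy_MeV)
  deps <- with_local_seed(seed, {
    n <- if (chord > 0 && density > 0) rpois(1, density * chord) else 0L
    if (n == 0) {
      empty_depositions()
    } else {
      s_um <- sort(runif(n, 0, chord))
      pos_nm <- (rep(entry, each = n) + outer(s_um, direction)) * 1000
      tibble(
        x_nm = pos_nm[, 1], y_nm = pos_nm[, 2], z_nm = pos_nm[, 3],
        edep_eV = sample_deposition_energies(n, model$sampler),
        track_id = as.integer(track_id),
        particle = model$particle_name
      )
    }
  })
  # numerical guard: endpoints of the chord are on the surface
  r_nm <- sqrt(deps$x_nm^2 + deps$y_nm^2 + deps$z_nm^2)
  stopifnot(all(r_nm <= nucleus_radius_um * 1000 * (1 + 1e-9)))
  list(depositions = deps, chord_um = chord)
}

empty_depositions <- function() {
  tibble(x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
         edep_eV = numeric(), track_id = integer(), particle = character())
}

#' Generate a full nucleus exposure from a mixture of track models
#'
#' Primaries enter at points uniform over the nucleus surface with inward
#' cosine-weighted directions (the isotropic-fluence entry law), each primary
#' drawing its particle type from the mixture weights and its kinetic energy
#' uniformly over the model's range. Per-track seeds are derived from the
#' master seed as `seed + track index`, so large exposures are reproducible
#' and tracks are independent.
#'
#' @param n_primaries Number of primary particles.
#' @param models List of [track_model()]s.
#' @param weights Mixture weights, summing to 1.
#' @param nucleus_radius_um Nucleus radius (um).
#' @param seed Master integer seed.
#' @return A `nucleus_exposure`: list with `depositions` (one tibble for all
#'   tracks) and `tracks` (per-track metadata: `track_id`, `particle`,
#'   `ekin_MeV`, `chord_um`, `alpha_track_length_um`), plus the radius and
#'   seed as attributes.
#' @export
generate_nucleus_exposure <- function(n_primaries, models, weights = NULL,
                                      nucleus_radius_um = 3.1, seed) {
  if (inherits(models, "track_model")) models <- list(models)
  if (length(models) == 0) abort("Empty track-model mixture.")
  if (is.null(weights)) weights <- rep(1 / length(models), length(models))
  if (length(weights) != length(models) || abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must match `models` and sum to 1.")
  }
  stop_if_not_positive(nucleus_radius_um = nucleus_radius_um)
  if (n_primaries == 0) {
    return(new_nucleus_exposure(empty_depositions(),
                                empty_track_table(), nucleus_radius_um, seed))
  }
  stop_if_not_positive(n_primaries = n_primaries)

  setup <- with_local_seed(seed, {
    which_model <- sample.int(length(models), n_primaries, replace = TRUE,
                              prob = weights)
    # uniform point on the sphere
    u <- runif(n_primaries, -1, 1)
    phi <- runif(n_primaries, 0, 2 * pi)
    sq <- sqrt(1 - u^2)
    entry <- cbind(sq * cos(phi), sq * sin(phi), u) * nucleus_radius_um
    # cosine-weighted inward direction about the inward normal
    ct <- sqrt(runif(n_primaries))        # cos(theta) ~ sqrt(U)
    st <- sqrt(1 - ct^2)
    psi <- runif(n_primaries, 0, 2 * pi)
    ekin_u <- runif(n_primaries)
    list(which_model = which_model, entry = entry, ct = ct, st = st,
         psi = psi, ekin_u = ekin_u)
  })

  deps_list <- vector("list", n_primaries)
  tracks <- vector("list", n_primaries)
  for (i in seq_len(n_primaries)) {
    m <- models[[setup$which_model[i]]]
    e <- setup$entry[i, ]
    inward <- -e / sqrt(sum(e^2))
    # orthonormal basis around the inward normal
    a <- if (abs(inward[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- a - sum(a * inward) * inward
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(inward[2] * t1[3] - inward[3] * t1[2],
            inward[3] * t1[1] - inward[1] * t1[3],
            inward[1] * t1[2] - inward[2] * t1[1])
    dir <- setup$ct[i] * inward +
      setup$st[i] * (cos(setup$psi[i]) * t1 + sin(setup$psi[i]) * t2)
    rng <- m$ekin_range_MeV
    ekin <- rng[1] + setup$ekin_u[i] * (rng[2] - rng[1])
    gen <- generate_track_depositions(e, dir, ekin, m, derive_seed(seed, i),
                                      nucleus_radius_um, track_id = i)
    deps_list[[i]] <- gen$depositions
    tracks[[i]] <- tibble(
      track_id = i, particle = m$particle_name, ekin_MeV = ekin,
      chord_um = gen$chord_um,
      alpha_track_length_um = if (m$particle_name == "alpha") gen$chord_um else NA_real_
    )
  }
  new_nucleus_exposure(dplyr::bind_rows(deps_list), dplyr::bind_rows(tracks),
                       nucleus_radius_um, seed)
}

empty_track_table <- function() {
  tibble(track_id = integer(), particle = character(), ekin_MeV = numeric(),
         chord_um = numeric(), alpha_track_length_um = numeric())
}

new_nucleus_exposure <- function(depositions, tracks, nucleus_radius_um, seed) {
  structure(
    list(depositions = depositions, tracks = tracks),
    nucleus_radius_um = nucleus_radius_um,
    seed = seed,
    class = "nucleus_exposure"
  )
}

#' @export
print.nucleus_exposure <- function(x, ...) {
  cat(sprintf(
    "<nucleus_exposure> %d tracks, %d depositions, nucleus radius %.3g um\n",
    nrow(x$tracks), nrow(x$depositions), attr(x, "nucleus_radius_um")
  ))
  invisible(x)
}

#' Write / read a nucleus exposure as CSV
#'
#' Two plain-text files: `<path>` with the depositions
#' (`x_nm,y_nm,z_nm,edep_eV,track_id,particle`) and `<path>` with `.tracks.csv`
#' appended holding per-track metadata, so externally generated deposition
#' lists can be scored with [score_exposure()].
#'
#' @param exposure A `nucleus_exposure`.
#' @param path Deposition CSV path.
#' @param nucleus_radius_um Radius to attach on read (um).
#' @return `read_exposure()` returns a `nucleus_exposure`.
#' @export
write_exposure <- function(exposure, path) {
  stopifnot(inherits(exposure, "nucleus_exposure"))
  readr::write_csv(exposure$depositions, path)
  readr::write_csv(exposure$tracks, paste0(path, ".tracks.csv"))
  invisible(path)
}

#' @rdname write_exposure
#' @export
read_exposure <- function(path, nucleus_radius_um = 3.1) {
  deps <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("x_nm", "y_nm", "z_nm", "edep_eV", "track_id", "particle")
  missing <- setdiff(need, names(deps))
  if (length(missing)) {
    abort(sprintf("Deposition file '%s' missing columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  tpath <- paste0(path, ".tracks.csv")
  tracks <- if (file.exists(tpath)) {
    readr::read_csv(tpath, show_col_types = FALSE, progress = FALSE)
  } else {
    deps %>%
      dplyr::distinct(.data$track_id, .data$particle) %>%
      mutate(ekin_MeV = NA_real_, chord_um = NA_real_,
             alpha_track_length_um = NA_real_)
  }
  new_nucleus_exposure(as_tibble(deps), as_tibble(tracks), nucleus_radius_um,
                       seed = NA_integer_)
}
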