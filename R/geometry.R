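#' Cylindrical irradiation vial geometry
#'
#' The blood sample is held in a nominally 8 mL cylindrical vial. The default
#' dimensions (7.2 mm radius, 49.12 mm height) give 7.9996 mL, consistent with
#' the 8 mL nominal volume to well under 1%.
#'
#' @param radius_mm Inner radius of the cylinder (mm).
#' @param height_mm Height of the cylinder (mm).
#' @param nominal_volume_mL Optional declared volume; when supplied the derived
#'   volume must agree within 1% or construction fails.
#' @return A `vial_geometry` list with `radius_mm`, `height_mm`, `volume_mL`.
#' @examples
#' vial_geometry()  # ~8 mL
#' @export
vial_geometry <- function(radius_mm = 7.2, height_mm = 49.12,
                          nominal_volume_mL = NULL) {
  stop_if_not_positive(radius_mm = radius_mm, height_mm = height_mm)
  volume_mL <- pi * radius_mm^2 * height_mm / 1000  # mm^3 -> mL
  if (!is.null(nominal_volume_mL)) {
    stop_if_not_positive(nominal_volume_mL = nominal_volume_mL)
    if (abs(volume_mL - nominal_volume_mL) / nominal_volume_mL > 0.01) {
      abort(sprintf(
        "Vial volume inconsistency: pi*r^2*h = %.4f mL but nominal volume is %.4f mL (>1%% apart).",
        volume_mL, nominal_volume_mL
      ))
    }
  }
  structure(
    list(radius_mm = radius_mm, height_mm = height_mm, volume_mL = volume_mL),
    class = "vial_geometry"
  )
}

#' @export
print.vial_geometry <- function(x, ...) {
  cat(sprintf(
    "<vial_geometry> radius %.3g mm, height %.4g mm, volume %.4g mL\n",
    x$radius_mm, x$height_mm, x$volume_mL
  ))
  invisible(x)
}

#' Randomly pack non-overlapping lymphocyte spheres into the vial
#'
#' Cells are modelled as equal spheres placed uniformly at random inside the
#' cylindrical vial by rejection sampling: a candidate centre is drawn uniform
#' in the cylinder shrunk by one cell radius (so the whole sphere fits), and
#' rejected if it overlaps any previously accepted cell. At the study
#' conditions (1000 cells of 3.75 um radius in 8 mL) the packing fraction is
#' ~1e-5 and rejections are rare.
#'
#' Coordinates are in micrometres in a right-handed frame with the origin at
#' the cylinder's axis midpoint and the axis along z.
#'
#' @param n Number of cells to place.
#' @param vial A [vial_geometry()].
#' @param cell_radius_um Cell (sphere) radius in um. Default 3.75.
#' @param nucleus_radius_um Nucleus radius in um, carried as metadata and
#'   required to be smaller than the cell radius. Default 3.1.
#' @param seed Integer seed; the same seed reproduces identical centres.
#' @param max_attempts Rejection attempts allowed per cell before failing.
#' @return A `cell_placement` tibble with columns `cell_id`, `x_um`, `y_um`,
#'   `z_um` and attributes `vial`, `cell_radius_um`, `nucleus_radius_um`,
#'   `seed`.
#' @examples
#' p <- place_cells(50, vial_geometry(), seed = 1)
#' nrow(p)
#' @export
place_cells <- function(n, vial = vial_geometry(), cell_radius_um = 3.75,
                        nucleus_radius_um = 3.1, seed,
                        max_attempts = 1e6) {
  stop_if_not_positive(n = n, cell_radius_um = cell_radius_um,
                       nucleus_radius_um = nucleus_radius_um,
                       max_attempts = max_attempts)
  if (nucleus_radius_um >= cell_radius_um) {
    abort("`nucleus_radius_um` must be smaller than `cell_radius_um`.")
  }
  r_max <- vial$radius_mm * 1000 - cell_radius_um   # um
  z_half <- vial$height_mm * 1000 / 2 - cell_radius_um
  if (r_max <= 0 || z_half <= 0) {
    abort("`cell_radius_um` does not fit inside the vial cross-section.")
  }
  min_d2 <- (2 * cell_radius_um)^2

  centers <- with_local_seed(seed, {
    xs <- numeric(n); ys <- numeric(n); zs <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        # uniform over the disc via sqrt-radius, uniform in z
        rr <- r_max * sqrt(runif(1))
        th <- runif(1, 0, 2 * pi)
        cand <- c(rr * cos(th), rr * sin(th), runif(1, -z_half, z_half))
        if (i > 1) {
          j <- seq_len(i - 1)
          d2 <- (xs[j] - cand[1])^2 + (ys[j] - cand[2])^2 + (zs[j] - cand[3])^2
          if (min(d2) < min_d2) next
        }
        xs[i] <- cand[1]; ys[i] <- cand[2]; zs[i] <- cand[3]
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf(
          "Packing failure: cell %d could not be placed after %d attempts exhausted.",
          i, as.integer(max_attempts)
        ))
      }
    }
    list(xs, ys, zs)
  })

  new_cell_placement(
    tibble(cell_id = seq_len(n), x_um = centers[[1]], y_um = centers[[2]],
           z_um = centers[[3]]),
    vial = vial, cell_radius_um = cell_radius_um,
    nucleus_radius_um = nucleus_radius_um, seed = as.integer(seed)
  )
}

new_cell_placement <- function(df, vial, cell_radius_um, nucleus_radius_um,
                               seed = NA_integer_) {
  out <- as_tibble(df)
  attr(out, "vial") <- vial
  attr(out, "cell_radius_um") <- cell_radius_um
  attr(out, "nucleus_radius_um") <- nucleus_radius_um
  attr(out, "seed") <- seed
  class(out) <- c("cell_placement", class(tibble()))
  out
}

validate_cell_placement <- function(p) {
  vial <- attr(p, "vial")
  rc <- attr(p, "cell_radius_um")
  if (nrow(p) == 0) abort("Placement validation failed: no cells.")
  rad <- sqrt(p$x_um^2 + p$y_um^2)
  if (any(rad > vial$radius_mm * 1000 - rc + 1e-9)) {
    abort("Placement validation failed: a centre is within one cell radius of the cylinder wall.")
  }
  if (any(abs(p$z_um) > vial$height_mm * 1000 / 2 - rc + 1e-9)) {
    abort("Placement validation failed: a centre is within one cell radius of an end cap.")
  }
  if (nrow(p) > 1 && min_pairwise_distance(p$x_um, p$y_um, p$z_um) < 2 * rc - 1e-9) {
    abort("Placement validation failed: two cells overlap.")
  }
  invisible(p)
}

# Minimum pairwise Euclidean distance; chunked O(n^2), adequate to n ~ few 1e3.
min_pairwise_distance <- function(x, y, z) {
  n <- length(x)
  best <- Inf
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d2 <- (x[j] - x[i])^2 + (y[j] - y[i])^2 + (z[j] - z[i])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Write / read a cell placement file
#'
#' Plain-text CSV with one header line then `cell_id,x_um,y_um,z_um` per cell
#' (the recorded coordinates file of the vial-scale model). `read_placement()`
#' re-validates all placement invariants on load.
#'
#' @param p A `cell_placement`.
#' @param path File path.
#' @param vial,cell_radius_um,nucleus_radius_um Geometry the stored centres
#'   must satisfy (the file stores coordinates only).
#' @return `write_placement()` returns `path` invisibly; `read_placement()`
#'   returns a validated `cell_placement`.
#' @export
write_placement <- function(p, path) {
  stopifnot(inherits(p, "cell_placement"))
  readr::write_csv(as_tibble(p)[, c("cell_id", "x_um", "y_um", "z_um")], path)
  invisible(path)
}

#' @rdname write_placement
#' @export
read_placement <- function(path, vial = vial_geometry(), cell_radius_um = 3.75,
                           nucleus_radius_um = 3.1) {
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("Could not parse placement file '%s': %s", path, conditionMessage(e)))
  )
  required <- c("cell_id", "x_um", "y_um", "z_um")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("Placement file '%s' is missing columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort(sprintf("Placement file '%s' contains no cells.", path))
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad)) {
    abort(sprintf("Placement file '%s': malformed record at data line %d.", path, bad[1]))
  }
  p <- new_cell_placement(df[required], vial = vial,
                          cell_radius_um = cell_radius_um,
                          nucleus_radius_um = nucleus_radius_um)
  validate_cell_placement(p)
  p
}

#' Reference geometric constants of the DNA / nucleus model
#'
#' Bundle of the constants from which the sensitive-volume fraction is
#' derived: B-DNA rise per base pair 0.34 nm, DNA cylinder radius 1.1 nm,
#' diploid genome size 6.4e9 bp, genome mass 6.41 pg (male; female 6.51 pg),
#' DNA mass density 1.7 g/mL, and the world sphere that encloses the cell by
#' 0.01 um for phase-space positioning.
#'
#' @param cell_radius_um Cell radius (um).
#' @return A named list.
#' @export
geometry_constants <- function(cell_radius_um = 3.75) {
  list(
    bp_length_nm = 0.34,
    dna_radius_nm = 1.1,
    n_bp = 6.4e9,
    genome_mass_pg = 6.41,
    genome_mass_female_pg = 6.51,
    dna_density_g_per_mL = 1.7,
    world_radius_um = cell_radius_um + 0.01
  )
}

#' Sensitive-volume fraction from cylinder DNA geometry
#'
#' The DNA of the diploid genome is modelled as one long cylinder (radius
#' `dna_radius_nm`, length `bp_length_nm * n_bp`); the sensitive-volume
#' probability is that cylinder's volume over the spherical nucleus volume.
#' With the defaults this is ~0.066, reported as 7% at integer-percent
#' rounding.
#'
#' @param dna_radius_nm DNA cylinder radius (nm).
#' @param bp_length_nm Rise per base pair (nm/bp).
#' @param n_bp Genome size (bp); 0 is allowed and yields 0.
#' @param nucleus_radius_um Nucleus radius (um).
#' @return Unrounded fraction.
#' @examples
#' sensitive_fraction_geometric()           # ~0.066
#' round_percent(sensitive_fraction_geometric())  # 7
#' @export
sensitive_fraction_geometric <- function(dna_radius_nm = 1.1,
                                         bp_length_nm = 0.34,
                                         n_bp = 6.4e9,
                                         nucleus_radius_um = 3.1) {
  stop_if_not_positive(dna_radius_nm = dna_radius_nm, bp_length_nm = bp_length_nm,
                       nucleus_radius_um = nucleus_radius_um)
  stop_if_not_positive(n_bp = n_bp, .allow_zero = TRUE)
  r_um <- dna_radius_nm * 1e-3
  len_um <- bp_length_nm * 1e-3 * n_bp
  dna_volume <- pi * r_um^2 * len_um
  dna_volume / sphere_volume(nucleus_radius_um)
}

#' Sensitive-volume fraction from genome mass and DNA density
#'
#' Molecular alternative to [sensitive_fraction_geometric()]: the DNA volume
#' is genome mass over DNA mass density (pg / (g/mL) gives um^3 directly) and
#' the fraction is that volume over the nucleus volume. A 6.41 pg genome at
#' 1.7 g/mL in a 124.8 um^3 nucleus gives ~0.030, reported as 3%.
#'
#' @param genome_mass_pg Genome mass (pg); 0 allowed.
#' @param dna_density_g_per_mL DNA mass density (g/mL).
#' @param nucleus_volume_um3 Nucleus volume (um^3).
#' @return Unrounded fraction.
#' @export
sensitive_fraction_molecular <- function(genome_mass_pg = 6.41,
                                         dna_density_g_per_mL = 1.7,
                                         nucleus_volume_um3 = sphere_volume(3.1)) {
  stop_if_not_positive(dna_density_g_per_mL = dna_density_g_per_mL,
                       nucleus_volume_um3 = nucleus_volume_um3)
  stop_if_not_positive(genome_mass_pg = genome_mass_pg, .allow_zero = TRUE)
  # pg / (g/mL) = 1e-12 g / (g / 1e12 um^3) = um^3
  (genome_mass_pg / dna_density_g_per_mL) / nucleus_volume_um3
}

#' Sphere volume
#' @param radius_um Radius (um).
#' @return Volume (um^3).
#' @export
sphere_volume <- function(radius_um) 4 / 3 * pi * radius_um^3

#' Nucleus volume, mass and geometric cross-section
#'
#' @param nucleus_radius_um Nucleus radius (um). Default 3.1.
#' @param density_kg_per_m3 Mass density (kg/m^3). Default 1000 (water).
#' @return A one-row tibble with `volume_um3`, `mass_kg`, `cross_section_um2`.
#' @examples
#' nucleus_metrics()  # 124.8 um^3, 1.25e-13 kg, 30.2 um^2
#' @export
nucleus_metrics <- function(nucleus_radius_um = 3.1, density_kg_per_m3 = 1000) {
  stop_if_not_positive(nucleus_radius_um = nucleus_radius_um,
                       density_kg_per_m3 = density_kg_per_m3)
  volume_um3 <- sphere_volume(nucleus_radius_um)
  tibble(
    volume_um3 = volume_um3,
    mass_kg = volume_um3 * 1e-18 * density_kg_per_m3,  # um^3 -> m^3
    cross_section_um2 = pi * nucleus_radius_um^2
  )
}
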