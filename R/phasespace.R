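PS_COLUMNS <- c("name", "ekin_MeV", "x_um", "y_um", "z_um",
                "dx", "dy", "dz", "weight", "event_id", "cell_id")

ANTINEUTRINO_ALIASES <- c("anti_nu_e", "nu_e-bar", "nu_e_bar", "anti-nu_e",
                          "antineutrino", "anti_nu_mu", "anti_nu_tau")

#' Construct a phase space of particle records
#'
#' A phase space is the set of particle states recorded on the surface of each
#' lymphocyte sphere: particle name, kinetic energy (MeV), hit position (um),
#' direction (unit vector), statistical weight, the primary event id, and the
#' id of the cell whose surface was crossed. The coordinate frame is explicit
#' metadata (`"vial"` or `"cell-local"`), never inferred.
#'
#' @param records A data frame with columns `name`, `ekin_MeV`, `x_um`, `y_um`,
#'   `z_um`, `dx`, `dy`, `dz`, `weight`, `event_id`, `cell_id`.
#' @param radionuclide Source label, e.g. `"Ra-223"`.
#' @param nt Number of simulated nuclear transformations behind the records.
#' @param frame `"vial"` or `"cell-local"`.
#' @return A `phase_space` tibble with metadata attributes.
#' @export
phase_space <- function(records, radionuclide, nt, frame = c("vial", "cell-local")) {
  frame <- match.arg(frame)
  df <- as_tibble(records)
  missing <- setdiff(PS_COLUMNS, names(df))
  if (length(missing)) {
    abort(sprintf("Phase-space records are missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  df <- df[PS_COLUMNS]
  if (nrow(df)) {
    if (any(df$ekin_MeV < 0)) abort("Kinetic energies must be >= 0.")
    nrm <- sqrt(df$dx^2 + df$dy^2 + df$dz^2)
    if (any(abs(nrm - 1) > 1e-6)) {
      abort("Direction vectors must be unit length within 1e-6.")
    }
    if (any(df$weight <= 0)) abort("Weights must be > 0.")
  }
  if (!is.numeric(nt) || length(nt) != 1 || nt < 1) {
    abort("`nt` (nuclear transformations) must be a count >= 1.")
  }
  new_phase_space(df, radionuclide = radionuclide, nt = nt, frame = frame)
}

new_phase_space <- function(df, radionuclide, nt, frame) {
  out <- as_tibble(df)
  attr(out, "radionuclide") <- radionuclide
  attr(out, "nt") <- nt
  attr(out, "frame") <- frame
  class(out) <- c("phase_space", class(tibble()))
  out
}

#' Phase-space metadata
#' @param ps A `phase_space`.
#' @return Named list with `radionuclide`, `nt`, `frame`.
#' @export
ps_metadata <- function(ps) {
  stopifnot(inherits(ps, "phase_space"))
  list(radionuclide = attr(ps, "radionuclide"),
       nt = attr(ps, "nt"),
       frame = attr(ps, "frame"))
}

#' Translate phase-space positions to cell-local origins
#'
#' Each record's position is shifted by the centre of the cell whose surface
#' it crossed, so all per-cell phase spaces share a common origin at (0,0,0)
#' and can be merged into a single total phase space. Directions are
#' unchanged. Refuses to translate a phase space that is already cell-local.
#'
#' @param ps A `phase_space` in the vial frame.
#' @param placement The [place_cells()] result giving each `cell_id`'s centre.
#' @return A `phase_space` in the cell-local frame.
#' @export
translate_to_cell_origin <- function(ps, placement) {
  stopifnot(inherits(ps, "phase_space"))
  if (attr(ps, "frame") != "vial") {
    abort("Phase space is already cell-local; refusing to translate twice.")
  }
  idx <- match(ps$cell_id, placement$cell_id)
  if (anyNA(idx)) {
    bad <- unique(ps$cell_id[is.na(idx)])
    abort(sprintf("Unknown cell_id(s) in phase space: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  df <- as_tibble(ps)
  df$x_um <- df$x_um - placement$x_um[idx]
  df$y_um <- df$y_um - placement$y_um[idx]
  df$z_um <- df$z_um - placement$z_um[idx]
  new_phase_space(df, radionuclide = attr(ps, "radionuclide"),
                  nt = attr(ps, "nt"), frame = "cell-local")
}

#' Merge cell-local phase spaces into a total phase space
#'
#' All per-cell databases are summed into a single source database. Inputs
#' must already be cell-local and share radionuclide and `nt`; records keep
#' input order (list order, then record order). Particles crossing several
#' cells appear once per crossing — each crossing is an independent source
#' particle.
#'
#' @param ps_list Non-empty list of cell-local `phase_space` objects.
#' @return A single `phase_space`.
#' @export
merge_phase_spaces <- function(ps_list) {
  if (!is.list(ps_list) || length(ps_list) == 0 ||
      inherits(ps_list, "phase_space")) {
    abort("`ps_list` must be a non-empty list of phase_space objects.")
  }
  meta <- lapply(ps_list, ps_metadata)
  frames <- vapply(meta, `[[`, "", "frame")
  if (any(frames != "cell-local")) {
    abort("All phase spaces must be cell-local before merging (translate first).")
  }
  nuclides <- vapply(meta, function(m) as.character(m$radionuclide), "")
  if (length(unique(nuclides)) != 1) {
    abort(sprintf("Cannot merge phase spaces of different radionuclides: %s",
                  paste(unique(nuclides), collapse = ", ")))
  }
  nts <- vapply(meta, function(m) as.numeric(m$nt), 0)
  if (length(unique(nts)) != 1) {
    abort("Cannot merge phase spaces with different `nt`.")
  }
  df <- dplyr::bind_rows(lapply(ps_list, as_tibble))
  new_phase_space(df, radionuclide = nuclides[1], nt = nts[1],
                  frame = "cell-local")
}

#' Remove anti-neutrino records
#'
#' Anti-neutrinos from beta decay deposit no energy in the cell and are
#' stripped to shrink the database. Matching is case-insensitive over common
#' generator spellings (`anti_nu_e`, `nu_e-bar`, ...). All other records pass
#' through untouched.
#'
#' @param ps A `phase_space`.
#' @return The filtered `phase_space` (possibly empty, which is valid and
#'   yields zero dose downstream).
#' @export
strip_antineutrinos <- function(ps) {
  stopifnot(inherits(ps, "phase_space"))
  keep <- !(tolower(ps$name) %in% ANTINEUTRINO_ALIASES)
  df <- as_tibble(ps)[keep, , drop = FALSE]
  new_phase_space(df, radionuclide = attr(ps, "radionuclide"),
                  nt = attr(ps, "nt"), frame = attr(ps, "frame"))
}

#' Read / write phase-space files
#'
#' CSV container with header
#' `name,ekin_MeV,x_um,y_um,z_um,dx,dy,dz,weight,event_id,cell_id` and a
#' leading comment block carrying the metadata (`# radionuclide=`, `# nt=`,
#' `# frame=`). Round-trips are lossless to double precision.
#'
#' @param ps A `phase_space`.
#' @param path File path.
#' @param format Only `"csv"` is supported as the on-disk container.
#' @return `read_phase_space()` returns a `phase_space`;
#'   `write_phase_space()` returns `path` invisibly.
#' @export
write_phase_space <- function(ps, path, format = "csv") {
  stopifnot(inherits(ps, "phase_space"))
  check_ps_format(format)
  meta <- ps_metadata(ps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# radionuclide=%s", meta$radionuclide),
    sprintf("# nt=%s", format(meta$nt, scientific = FALSE)),
    sprintf("# frame=%s", meta$frame),
    paste(PS_COLUMNS, collapse = ",")
  ), con)
  if (nrow(ps)) {
    df <- as_tibble(ps)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    writeLines(do.call(paste, c(unname(as.list(df)), sep = ",")), con)
  }
  invisible(path)
}

#' @rdname write_phase_space
#' @export
read_phase_space <- function(path, format = "csv") {
  check_ps_format(format)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(sprintf("^# %s=", key), meta_lines, value = TRUE)
    if (!length(hit)) abort(sprintf("Phase-space file '%s' lacks metadata '%s'.", path, key))
    sub(sprintf("^# %s=", key), "", hit[1])
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  missing <- setdiff(PS_COLUMNS, names(df))
  if (length(missing)) {
    abort(sprintf("Phase-space file '%s' schema error; missing columns: %s",
                  path, paste(missing, collapse = ", ")))
  }
  phase_space(df, radionuclide = get_meta("radionuclide"),
              nt = as.numeric(get_meta("nt")),
              frame = get_meta("frame"))
}

check_ps_format <- function(format) {
  if (identical(format, "csv")) return(invisible(TRUE))
  if (identical(format, "hdf5")) {
    abort(paste("HDF5 phase-space files are not supported by this package;",
                "use format = 'csv' (same fields, one column per dataset)."))
  }
  abort(sprintf("Unknown phase-space format '%s'; use 'csv'.", format))
}
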