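#' Experiment-based alpha-track detectability thresholds
#'
#' Microscopy resolves an alpha track only when it is long enough and carries
#' enough damage foci: the defaults keep tracks strictly longer than 0.75 um
#' and with strictly more than 7 DSBs (both comparisons strict, so boundary
#' values are excluded).
#'
#' @param min_length_um Track length threshold (um), strict `>`.
#' @param min_dsb DSB-count threshold, strict `>`.
#' @return An `alpha_thresholds` list.
#' @export
alpha_thresholds <- function(min_length_um = 0.75, min_dsb = 7) {
  stop_if_not_positive(min_length_um = min_length_um, min_dsb = min_dsb,
                       .allow_zero = TRUE)
  structure(list(min_length_um = min_length_um, min_dsb = min_dsb),
            class = "alpha_thresholds")
}

#' Filter alpha-track summaries by detectability thresholds
#'
#' Keeps tracks with `alpha_track_length_um > min_length_um` and
#' `n_dsb > min_dsb`. Every summary must carry a track length; a missing
#' length is an error naming the offending track.
#'
#' @param summaries Track damage summaries ([score_exposure()]), alpha rows.
#' @param thresholds An [alpha_thresholds()].
#' @return The filtered summaries tibble.
#' @export
apply_track_thresholds <- function(summaries, thresholds = alpha_thresholds()) {
  summaries <- as_tibble(summaries)
  if (!"alpha_track_length_um" %in% names(summaries) ||
      anyNA(summaries$alpha_track_length_um)) {
    bad <- if ("alpha_track_length_um" %in% names(summaries)) {
      summaries$track_id[is.na(summaries$alpha_track_length_um)]
    } else summaries$track_id
    abort(sprintf("Summaries lack an alpha track length for track_id(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  dplyr::filter(summaries,
                .data$alpha_track_length_um > thresholds$min_length_um,
                .data$n_dsb > thresholds$min_dsb)
}

#' Alpha tracks per 100 cells per milligray
#'
#' `100 * n_tracks / (N_cells * D_blood)` — the simulation counterpart of the
#' visually counted alpha-track yield.
#'
#' @param n_tracks Number of (possibly threshold-filtered) alpha tracks.
#' @param n_cells Number of cells.
#' @param D_blood_mGy Absorbed dose to blood (mGy), strictly positive.
#' @return Alpha tracks per 100 cells per mGy.
#' @export
alpha_tracks_per_100cells_per_mGy <- function(n_tracks, n_cells, D_blood_mGy) {
  stop_if_not_positive(n_cells = n_cells, D_blood_mGy = D_blood_mGy)
  stop_if_not_positive(n_tracks = n_tracks, .allow_zero = TRUE)
  100 * n_tracks / (n_cells * D_blood_mGy)
}

#' Linear DSB density along alpha tracks
#'
#' Ratio of sums: total DSB count over total alpha track length (um) across
#' the included tracks — not the mean of per-track ratios — so duplicating the
#' track set leaves the density unchanged.
#'
#' @param summaries Track damage summaries with `n_dsb` and
#'   `alpha_track_length_um`.
#' @return DSB per um.
#' @export
linear_dsb_density <- function(summaries) {
  summaries <- as_tibble(summaries)
  total_len <- sum(summaries$alpha_track_length_um, na.rm = TRUE)
  if (!is.finite(total_len) || total_len <= 0) {
    abort("Total alpha track length must be > 0 to form a linear DSB density.")
  }
  sum(summaries$n_dsb) / total_len
}
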