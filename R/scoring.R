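#' Damage-model parameters
#'
#' Constants of the strand-break scorer. `spoints_prob` is the probability
#' that an energy deposition falls in the DNA-occupied sensitive fraction of
#' the nucleus (default 0.07, the geometric cylinder-model value). Deposition
#' energies below `emin_damage_eV` (5 eV) never break the backbone; the break
#' probability rises linearly to 1 at `emax_damage_eV` (37.5 eV). Two breaks
#' closer than `eps_nm` (3.4 nm, ~10 bp at 0.34 nm/bp) with `min_pts = 2`
#' define a double-strand break candidate; `strand_prob` is the Bernoulli
#' probability that a break sits on strand 1.
#'
#' @param spoints_prob Sensitive-volume probability in `[0, 1]`.
#' @param emin_damage_eV,emax_damage_eV Linear damage ramp endpoints (eV).
#' @param eps_nm Clustering radius (nm), strict less-than.
#' @param min_pts DBSCAN MinPts (>= 2).
#' @param strand_prob Probability a break lies on strand 1.
#' @param bp_length_nm Rise per base pair (nm); under defaults
#'   `eps_nm == 10 * bp_length_nm`.
#' @return A `damage_parameters` list.
#' @export
damage_parameters <- function(spoints_prob = 0.07,
                              emin_damage_eV = 5,
                              emax_damage_eV = 37.5,
                              eps_nm = 3.4,
                              min_pts = 2,
                              strand_prob = 0.5,
                              bp_length_nm = 0.34) {
  if (spoints_prob < 0 || spoints_prob > 1) abort("`spoints_prob` must be in [0, 1].")
  if (strand_prob < 0 || strand_prob > 1) abort("`strand_prob` must be in [0, 1].")
  if (emin_damage_eV >= emax_damage_eV) abort("`emin_damage_eV` must be < `emax_damage_eV`.")
  stop_if_not_positive(eps_nm = eps_nm, bp_length_nm = bp_length_nm)
  if (min_pts < 2) abort("`min_pts` must be >= 2.")
  structure(
    list(spoints_prob = spoints_prob, emin_damage_eV = emin_damage_eV,
         emax_damage_eV = emax_damage_eV, eps_nm = eps_nm,
         min_pts = as.integer(min_pts), strand_prob = strand_prob,
         bp_length_nm = bp_length_nm),
    class = "damage_parameters"
  )
}

#' Strand-break probability of a single energy deposition
#'
#' Clamped linear ramp: 0 for deposition energies at or below the 5 eV
#' minimum, 1 at or above the 37.5 eV maximum, and
#' `(E - EMin) / (EMax - EMin)` between — monotone non-decreasing in E.
#'
#' @param E_eV Deposition energy or energies (eV), non-negative.
#' @param params A [damage_parameters()].
#' @return Probability in `[0, 1]`, vectorised over `E_eV`.
#' @examples
#' damage_probability(c(5, 21.25, 37.5, 100))
#' @export
damage_probability <- function(E_eV, params = damage_parameters()) {
  stop_if_not_positive(E_eV = E_eV, .allow_zero = TRUE)
  pmin(1, pmax(0, (E_eV - params$emin_damage_eV) /
                 (params$emax_damage_eV - params$emin_damage_eV)))
}

#' Sample strand breaks from energy depositions
#'
#' Each deposition is independently accepted as a strand break with combined
#' probability `spoints_prob * damage_probability(E)` (one Bernoulli draw —
#' statistically identical to drawing the sensitive-volume hit and the damage
#' ramp sequentially, with half the random-stream length). Accepted breaks
#' keep the deposition position and draw a strand label
#' Bernoulli(`strand_prob`). Deterministic per seed.
#'
#' @param depositions Tibble with `x_nm`, `y_nm`, `z_nm`, `edep_eV` and
#'   optionally `track_id`.
#' @param params A [damage_parameters()].
#' @param seed Integer seed.
#' @return Strand-break tibble: `x_nm`, `y_nm`, `z_nm`, `strand` (0/1),
#'   `track_id`.
#' @export
sample_breaks <- function(depositions, params = damage_parameters(), seed) {
  depositions <- as_tibble(depositions)
  n <- nrow(depositions)
  if (n == 0) return(empty_breaks())
  p_accept <- params$spoints_prob * damage_probability(depositions$edep_eV, params)
  with_local_seed(seed, {
    keep <- runif(n) < p_accept
    kept <- depositions[keep, , drop = FALSE]
    strand <- as.integer(runif(nrow(kept)) < params$strand_prob)
    tibble(
      x_nm = kept$x_nm, y_nm = kept$y_nm, z_nm = kept$z_nm,
      strand = strand,
      track_id = if ("track_id" %in% names(kept)) kept$track_id else
        rep(NA_integer_, nrow(kept))
    )
  })
}

empty_breaks <- function() {
  tibble(x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
         strand = integer(), track_id = integer())
}

#' Classify break clusters into SSB / complex SSB / simple and complex DSB
#'
#' Isolated breaks are single-strand breaks (SSB). A cluster whose members all
#' lie on one strand is a complex SSB (2 or more SSBs). A cluster with both
#' strands represented is a DSB: simple when it has exactly 2 members, complex
#' when it has 3 or more members with at least one break on the opposite
#' strand. The cluster-size histogram counts clusters (size >= 2) by member
#' count.
#'
#' @param clusters,isolated As returned by [cluster_breaks()].
#' @return One-row tibble: `n_breaks`, `n_ssb`, `n_complex_ssb`, `n_dsb`,
#'   `n_simple_dsb`, `n_complex_dsb`, and `cluster_sizes` (list-column of the
#'   integer sizes of all clusters).
#' @export
classify_clusters <- function(clusters, isolated) {
  if (nrow(clusters) && any(clusters$size < 2)) {
    abort("Internal consistency error: cluster of size < 2.")
  }
  both <- clusters$both_strands
  simple_dsb <- sum(both & clusters$size == 2)
  complex_dsb <- sum(both & clusters$size >= 3)
  tibble(
    n_breaks = nrow(isolated) + sum(clusters$size),
    n_ssb = nrow(isolated),
    n_complex_ssb = sum(!both),
    n_dsb = simple_dsb + complex_dsb,
    n_simple_dsb = simple_dsb,
    n_complex_dsb = complex_dsb,
    cluster_sizes = list(as.integer(clusters$size))
  )
}

#' Score the damage of a single primary track
#'
#' Composes [sample_breaks()] -> [cluster_breaks()] -> [classify_clusters()]
#' for the depositions of one primary particle (with its secondaries). The
#' summary also carries the total deposited energy (all depositions, accepted
#' or not) and, for alphas, the track length inside the nucleus supplied by
#' the generator.
#'
#' @param depositions Depositions of one track (single `track_id`).
#' @param params A [damage_parameters()].
#' @param seed Integer seed.
#' @param particle Particle label for the summary (taken from the depositions
#'   when present).
#' @param alpha_track_length_um Track length (um) for alphas, `NA` otherwise.
#' @return One-row track damage summary tibble: `track_id`, `particle`,
#'   damage counts as in [classify_clusters()], `deposited_energy_eV`,
#'   `alpha_track_length_um`.
#' @export
score_track <- function(depositions, params = damage_parameters(), seed,
                        particle = NULL, alpha_track_length_um = NA_real_) {
  depositions <- as_tibble(depositions)
  tids <- unique(depositions$track_id)
  if (length(tids) > 1) {
    abort(sprintf("score_track() expects one track; got track_ids %s.",
                  paste(head(tids, 5), collapse = ", ")))
  }
  if (is.null(particle)) {
    particle <- if (nrow(depositions)) depositions$particle[1] else NA_character_
  }
  brk <- sample_breaks(depositions, params, seed)
  cl <- cluster_breaks(brk, params)
  counts <- classify_clusters(cl$clusters, cl$isolated)
  dplyr::bind_cols(
    tibble(
      track_id = if (length(tids)) as.integer(tids) else NA_integer_,
      particle = particle
    ),
    counts,
    tibble(
      deposited_energy_eV = sum(depositions$edep_eV),
      alpha_track_length_um = alpha_track_length_um
    )
  )
}

#' Score a whole nucleus exposure, one summary per primary
#'
#' Applies [score_track()] to every primary track of an exposure. Clustering
#' never crosses track boundaries: breaks from different primaries are never
#' joined, mirroring per-particle damage bookkeeping. Per-track seeds are
#' derived from the master seed plus the track id.
#'
#' @param exposure A `nucleus_exposure` from [generate_nucleus_exposure()] or
#'   [read_exposure()].
#' @param params A [damage_parameters()].
#' @param seed Master integer seed for the break sampling.
#' @return Tibble of track damage summaries, one row per primary (including
#'   tracks with zero depositions).
#' @export
score_exposure <- function(exposure, params = damage_parameters(), seed) {
  stopifnot(inherits(exposure, "nucleus_exposure"))
  tracks <- exposure$tracks
  deps_by_track <- split(exposure$depositions,
                         factor(exposure$depositions$track_id,
                                levels = tracks$track_id))
  out <- purrr::map_dfr(seq_len(nrow(tracks)), function(i) {
    tr <- tracks[i, ]
    score_track(deps_by_track[[as.character(tr$track_id)]],
                params = params,
                seed = derive_seed(seed, tr$track_id),
                particle = tr$particle,
                alpha_track_length_um = tr$alpha_track_length_um)
  })
  if (nrow(out)) out$track_id <- as.integer(tracks$track_id)
  class(out) <- c("track_summaries", class(out))
  out
}
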