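#' @export
print.damage_parameters <- function(x, ...) {
  cat(sprintf(
    paste0("<damage_parameters> SPointsProb %.3g, ramp %.3g-%.3g eV, ",
           "eps %.3g nm, MinPts %d, strand_prob %.2g\n"),
    x$spoints_prob, x$emin_damage_eV, x$emax_damage_eV, x$eps_nm, x$min_pts,
    x$strand_prob
  ))
  invisible(x)
}

#' @export
print.dose_result <- function(x, ...) {
  cat("<dose_result>\n")
  cat(sprintf("  E per nt:     %.4g +/- %.2g keV/nt\n",
              x$E_per_nt_keV, x$E_per_nt_se_keV))
  cat(sprintf("  activity:     %.4g MBq\n", x$activity_MBq))
  cat(sprintf("  D_blood:      %.4g mGy\n", x$D_blood_mGy))
  cat(sprintf("  d_lymph:      %.4g mGy*mL/MBq\n", x$d_lymph_mGy_mL_per_MBq))
  cat(sprintf("  DSB/cell/mGy: %.4g", x$dsb_per_cell_per_mGy))
  if (is.finite(x$dsb_per_cell_per_mGy_sd %||% NA)) {
    cat(sprintf(" (replicate sd %.2g)", x$dsb_per_cell_per_mGy_sd))
  }
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lymphdsb_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<lymphdsb_run> %s: %d cells, %d primaries, seed %d, %d replicate(s)\n",
              m$nuclide$name, m$n_cells, m$n_primaries, m$seed, m$replicates))
  print(x$dose)
  ar <- x$alpha_report
  if (ar$n_tracks > 0) {
    cat(sprintf("  alpha tracks: %d (%d past thresholds), %.3g DSB/um\n",
                ar$n_tracks, ar$n_tracks_thresholded, ar$dsb_per_um))
  }
  invisible(x)
}

#' Tidy a pipeline run into per-track rows
#'
#' @param x A `lymphdsb_run`.
#' @param ... Unused.
#' @return The per-track damage summary tibble (first replicate), without the
#'   list-column.
#' @export
tidy.lymphdsb_run <- function(x, ...) {
  out <- as_tibble(x$summaries)
  out$n_clusters <- vapply(out$cluster_sizes, length, 0L)
  dplyr::select(out, -"cluster_sizes")
}

#' One-row summary of a pipeline run
#'
#' @param x A `lymphdsb_run`.
#' @param ... Unused.
#' @return One-row tibble with the headline dosimetry and damage quantities.
#' @export
glance.lymphdsb_run <- function(x, ...) {
  d <- x$dose
  a <- x$alpha_report
  tibble(
    radionuclide = x$manifest$nuclide$name,
    n_cells = x$manifest$n_cells,
    n_primaries = x$manifest$n_primaries,
    E_per_nt_keV = d$E_per_nt_keV,
    activity_MBq = d$activity_MBq,
    D_blood_mGy = d$D_blood_mGy,
    d_lymph_mGy_mL_per_MBq = d$d_lymph_mGy_mL_per_MBq,
    dsb_per_cell_per_mGy = d$dsb_per_cell_per_mGy,
    dsb_per_cell_per_mGy_sd = d$dsb_per_cell_per_mGy_sd,
    alpha_tracks_per_100cells_per_mGy = a$tracks_per_100cells_per_mGy,
    alpha_dsb_per_um = a$dsb_per_um
  )
}

#' Plot a cell placement
#'
#' Axial (x-y) view of the packed cell centres inside the vial wall.
#'
#' @param object A `cell_placement`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cell_placement <- function(object, ...) {
  vial <- attr(object, "vial")
  r_um <- vial$radius_mm * 1000
  circle <- tibble(
    t = seq(0, 2 * pi, length.out = 200),
    x_um = r_um * cos(.data$t),
    y_um = r_um * sin(.data$t)
  )
  ggplot(as_tibble(object), aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_path(data = circle, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%d lymphocytes in the vial (axial view)", nrow(object)),
      x = "x (um)", y = "y (um)"
    )
}

#' Plot a cluster-complexity report
#'
#' Clusters per cell per mGy by cluster size (number of strand breaks), the
#' damage-complexity histogram.
#'
#' @param object A `cluster_report` from [build_cluster_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_report <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$kind == "cluster_size")
  ggplot(df, aes(x = factor(.data$size), y = .data$rate)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "cluster size (strand breaks)",
      y = expression("clusters" %.% "cell"^-1 %.% "mGy"^-1),
      title = "DNA damage complexity"
    )
}

#' Plot the damage-probability ramp
#'
#' @param params A [damage_parameters()].
#' @param emax_plot_eV Upper energy bound of the plot (eV).
#' @return A ggplot of the clamped linear break-probability ramp.
#' @export
plot_damage_probability <- function(params = damage_parameters(),
                                    emax_plot_eV = 60) {
  df <- tibble(E_eV = seq(0, emax_plot_eV, length.out = 400))
  df$p <- damage_probability(df$E_eV, params)
  ggplot(df, aes(x = .data$E_eV, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "deposition energy (eV)", y = "break probability",
                  title = "Damage-probability ramp")
}
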