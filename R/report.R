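#' Per-frame ensemble metric report
#'
#' Computes the standard trajectory summary for every frame — superposed
#' backbone RMSD to the first frame, radius of gyration, percent
#' helicity, hydrophobic/hydrophilic SASA partition, salt-bridge count
#' and interchain hydrophobic-contact count — plus means over a trailing
#' window of frames (the usual "averaged over the last N" reporting
#' convention for trajectories).
#'
#' @param ensemble a [structure_ensemble()].
#' @param selection selection used for the RMSD superposition, default
#'   `"backbone"`.
#' @param trailing number of trailing frames averaged for the summary
#'   row; clipped to the trajectory length with a warning. Default: all
#'   frames.
#' @param sasa compute the (relatively expensive) SASA partition per
#'   frame (default `TRUE`).
#' @param salt_cutoff,contact_cutoff distance cutoffs in Angstrom.
#' @param n_sphere_points quadrature points for [sasa_partition()].
#' @return list with `per_frame` (data frame, one row per frame) and
#'   `trailing_mean` (named numeric vector over the trailing window),
#'   plus the configuration used.
#' @export
ensemble_report <- function(ensemble, selection = "backbone",
                            trailing = NULL, sasa = TRUE,
                            salt_cutoff = 4.0, contact_cutoff = 5.0,
                            n_sphere_points = 240) {
  nf <- n_frames(ensemble)
  if (is.null(trailing)) trailing <- nf
  if (trailing > nf) {
    warning("trailing window (", trailing, ") longer than trajectory (",
            nf, "); clipped")
    trailing <- nf
  }
  rmsd <- rmsd_series(ensemble, selection = selection, unit = "nm")
  rows <- lapply(seq_len(nf), function(f) {
    hel <- helicity(ensemble, frame = f)
    sb <- salt_bridges(ensemble, frame = f, cutoff = salt_cutoff)
    hc <- hydrophobic_contacts(ensemble, frame = f,
                               cutoff = contact_cutoff)
    row <- data.frame(
      frame = f,
      rmsd_nm = rmsd[f],
      rg_nm = radius_of_gyration(ensemble, frame = f),
      pct_helicity = hel$percent_helical,
      n_salt_bridges = nrow(sb),
      n_hydrophobic_contacts = nrow(hc))
    if (sasa) {
      sp <- sasa_partition(ensemble, frame = f,
                           n_sphere_points = n_sphere_points)
      row$sasa_total_nm2 <- sp$total_nm2
      row$sasa_hydrophobic_nm2 <- sp$hydrophobic_nm2
      row$sasa_hydrophilic_nm2 <- sp$hydrophilic_nm2
    }
    row
  })
  per_frame <- do.call(rbind, rows)
  tail_rows <- per_frame[(nf - trailing + 1):nf, -1, drop = FALSE]
  list(per_frame = per_frame,
       trailing_mean = colMeans(tail_rows),
       trailing = trailing,
       config = list(selection = selection, salt_cutoff = salt_cutoff,
                     contact_cutoff = contact_cutoff,
                     n_sphere_points = n_sphere_points))
}
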