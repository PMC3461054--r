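## Deterministic quasi-uniform points on the unit sphere (golden-spiral
## construction) for the Shrake-Rupley quadrature.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area by the Shrake-Rupley method
#'
#' Rolls a probe sphere over the van der Waals surface: each atom is
#' inflated by the probe radius, a quasi-uniform point quadrature is
#' placed on the inflated sphere, and the accessible area is the
#' inflated-sphere area times the fraction of points outside every
#' neighbouring inflated sphere. Bondi radii are used; atoms with an
#' unknown element get `default_radius` with a warning.
#'
#' The per-residue areas are partitioned into hydrophobic and
#' hydrophilic classes at the residue level (hydrophobic set:
#' Ala, Val, Leu, Ile, Met, Phe, Trp, Pro, Gly by default).
#'
#' @param ensemble a [structure_ensemble()].
#' @param frame frame index, default 1.
#' @param probe_radius probe (solvent) radius in Angstrom, default 1.4.
#' @param n_sphere_points quadrature points per atom, default 960.
#' @param hydrophobic_set 3-letter residue names counted as hydrophobic.
#' @param default_radius fallback van der Waals radius (Angstrom).
#' @param include_hydrogens include H atoms (default `FALSE`; united-atom
#'   convention).
#' @return object of class `sasa_partition`: list with `total_nm2`,
#'   `hydrophobic_nm2`, `hydrophilic_nm2`, `per_residue` (data frame
#'   with `chain`, `resno`, `resid`, `area_nm2`, `class`) and
#'   `per_atom_A2`.
#' @export
sasa_partition <- function(ensemble, frame = 1, probe_radius = 1.4,
                           n_sphere_points = 960,
                           hydrophobic_set = HYDROPHOBIC_RESID3,
                           default_radius = 1.5,
                           include_hydrogens = FALSE) {
  at <- ensemble$atoms
  keep <- if (include_hydrogens) rep(TRUE, nrow(at)) else at$element != "H"
  idx <- which(keep)
  xyz <- frame_coords(ensemble, frame)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  xyz <- xyz[idx, , drop = FALSE]
  el <- at$element[idx]
  r <- BONDI_RADII[el]
  if (any(is.na(r))) {
    warning("unknown element(s) ", paste(unique(el[is.na(r)]),
                                         collapse = ", "),
            "; using radius ", default_radius, " A")
    r[is.na(r)] <- default_radius
  }
  re <- unname(r) + probe_radius
  n <- length(idx)
  pts <- sphere_points(n_sphere_points)
  area <- numeric(n)
  ## pairwise neighbour prefilter
  maxr <- max(re)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nb <- which(d < re[i] + re & seq_len(n) != i)
    p <- sweep(pts * re[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      acc <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        if (!any(acc)) break
        dj2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
        acc <- acc & dj2 > re[j]^2
      }
      frac <- mean(acc)
    } else frac <- 1
    area[i] <- 4 * pi * re[i]^2 * frac
  }
  per_atom <- data.frame(at[idx, , drop = FALSE], area_A2 = area)
  key <- interaction(per_atom$chain, per_atom$resno, drop = TRUE)
  per_res <- do.call(rbind, lapply(split(per_atom, key), function(d)
    data.frame(chain = d$chain[1], resno = d$resno[1], resid = d$resid[1],
               area_nm2 = sum(d$area_A2) / 100)))
  per_res <- per_res[order(per_res$chain, per_res$resno), ]
  rownames(per_res) <- NULL
  per_res$class <- ifelse(per_res$resid %in% hydrophobic_set,
                          "hydrophobic", "hydrophilic")
  phob <- sum(per_res$area_nm2[per_res$class == "hydrophobic"])
  phil <- sum(per_res$area_nm2[per_res$class == "hydrophilic"])
  structure(list(total_nm2 = phob + phil, hydrophobic_nm2 = phob,
                 hydrophilic_nm2 = phil, per_residue = per_res,
                 per_atom_A2 = area, probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points),
            class = "sasa_partition")
}

#' @export
print.sasa_partition <- function(x, ...) {
  cat(sprintf(
    "SASA (probe %.1f A, %d pts): total %.2f nm^2 = %.2f hydrophobic + %.2f hydrophilic\n",
    x$probe_radius, x$n_sphere_points, x$total_nm2, x$hydrophobic_nm2,
    x$hydrophilic_nm2))
  invisible(x)
}
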