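#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares superposition of a mobile coordinate set onto a
#' reference by the closed-form SVD solution, constrained to a proper
#' rotation (determinant +1).
#'
#' @param reference,mobile `n x 3` coordinate matrices with matching
#'   rows (n >= 3).
#' @return list with `rotation` (3x3), `translation` (length 3; the
#'   superposed coordinates are `mobile %*% t(rotation)` plus the
#'   translation), `rmsd` (Angstrom) and `coords` (the transformed
#'   mobile set).
#' @examples
#' x <- matrix(rnorm(18), ncol = 3)
#' kabsch_superpose(x, x)$rmsd
#' @export
kabsch_superpose <- function(reference, mobile) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (!all(dim(reference) == dim(mobile)))
    stop("reference and mobile must have identical dimensions")
  if (nrow(reference) < 3)
    stop("underdetermined: need at least 3 atoms, got ", nrow(reference))
  cr <- colMeans(reference); cm <- colMeans(mobile)
  A <- sweep(reference, 2, cr); B <- sweep(mobile, 2, cm)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- B %*% t(R)
  moved <- sweep(moved, 2, cr, `+`)
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  list(rotation = R, translation = cr - as.numeric(R %*% cm),
       rmsd = rmsd, coords = moved)
}

#' RMSD of each frame to a reference frame
#'
#' Superposes every frame of the ensemble onto the reference frame over
#' the given atom selection (Kabsch) and reports the post-fit RMSD.
#'
#' @param ensemble a [structure_ensemble()].
#' @param selection selection for [select_atoms()]; default `"backbone"`.
#' @param reference reference frame index, default 1.
#' @param unit `"angstrom"` (default) or `"nm"`.
#' @return numeric vector of per-frame RMSD values.
#' @export
rmsd_series <- function(ensemble, selection = "backbone", reference = 1,
                        unit = c("angstrom", "nm")) {
  unit <- match.arg(unit)
  idx <- select_atoms(ensemble, selection)
  ref <- frame_coords(ensemble, reference)[idx, , drop = FALSE]
  out <- vapply(seq_len(n_frames(ensemble)), function(f) {
    kabsch_superpose(ref,
                     frame_coords(ensemble, f)[idx, , drop = FALSE])$rmsd
  }, 0)
  if (unit == "nm") out <- out / 10
  out
}

#' Per-atom root-mean-square fluctuation
#'
#' Superposes all frames onto the ensemble mean structure (the mean is
#' recomputed once after an initial superposition to frame 1, then all
#' frames are refit to it), and reports
#' \eqn{RMSF_i = \sqrt{\langle |x_i - \bar x_i|^2 \rangle}} for each
#' selected atom. With the default `"calpha"` selection this is the
#' per-residue backbone fluctuation profile.
#'
#' @inheritParams rmsd_series
#' @param selection selection for [select_atoms()]; default `"calpha"`.
#' @return data frame with columns `chain`, `resno`, `elety`,
#'   `rmsf` (Angstrom).
#' @export
rmsf <- function(ensemble, selection = "calpha") {
  nf <- n_frames(ensemble)
  if (nf < 2) stop("RMSF undefined for a single frame")
  idx <- select_atoms(ensemble, selection)
  ref <- frame_coords(ensemble, 1)[idx, , drop = FALSE]
  fitted <- array(NA_real_, dim = c(length(idx), 3, nf))
  for (f in seq_len(nf))
    fitted[, , f] <- kabsch_superpose(
      ref, frame_coords(ensemble, f)[idx, , drop = FALSE])$coords
  mean_struct <- apply(fitted, c(1, 2), mean)
  for (f in seq_len(nf))
    fitted[, , f] <- kabsch_superpose(
      mean_struct, frame_coords(ensemble, f)[idx, , drop = FALSE])$coords
  mean_struct <- apply(fitted, c(1, 2), mean)
  dev2 <- vapply(seq_len(nf), function(f)
    rowSums((fitted[, , f] - mean_struct)^2), numeric(length(idx)))
  if (is.null(dim(dev2))) dev2 <- matrix(dev2, nrow = length(idx))
  at <- ensemble$atoms[idx, , drop = FALSE]
  data.frame(chain = at$chain, resno = at$resno, elety = at$elety,
             rmsf = sqrt(rowMeans(dev2)))
}

#' Mass-weighted radius of gyration of one frame
#'
#' \deqn{R_g = \sqrt{\sum_i m_i |x_i - x_{com}|^2 / \sum_i m_i}}
#'
#' @param ensemble a [structure_ensemble()].
#' @param frame frame index, default 1.
#' @param selection selection for [select_atoms()]; default `"heavy"`.
#' @param unit `"nm"` (default, for side-by-side reading with trajectory
#'   reports) or `"angstrom"`.
#' @return radius of gyration (scalar).
#' @export
radius_of_gyration <- function(ensemble, frame = 1, selection = "heavy",
                               unit = c("nm", "angstrom")) {
  unit <- match.arg(unit)
  idx <- select_atoms(ensemble, selection)
  if (length(idx) < 2) stop("need at least 2 atoms")
  xyz <- frame_coords(ensemble, frame)[idx, , drop = FALSE]
  el <- ensemble$atoms$element[idx]
  m <- ELEMENT_MASS[el]
  if (any(is.na(m))) {
    warning("unknown element(s) ", paste(unique(el[is.na(m)]),
                                         collapse = ", "),
            "; using mass 12")
    m[is.na(m)] <- 12
  }
  if (sum(m) <= 0) stop("zero total mass")
  com <- colSums(xyz * m) / sum(m)
  rg <- sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  if (unit == "nm") rg / 10 else rg
}
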