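#' Geometric helicity from the C-alpha trace
#'
#' Assigns helical residues from C-alpha geometry alone (in the spirit of
#' P-SEA), so that ensembles without hydrogens or backbone carbonyls can
#' still be scored: position `i` starts a helical window when
#' \eqn{d(i, i+3) \in [4.7, 5.7]} A and \eqn{d(i, i+4) \in [5.8, 6.7]} A;
#' all residues covered by a satisfying window (`i` .. `i+4`) are marked
#' helical. Percent helicity is helical residues over assignable
#' residues. Chains shorter than 5 residues are excluded and flagged.
#'
#' @param ensemble a [structure_ensemble()].
#' @param frame frame index, default 1.
#' @param d13 allowed range for the i,i+3 C-alpha distance (Angstrom).
#' @param d14 allowed range for the i,i+4 C-alpha distance (Angstrom).
#' @return list with `percent_helical`, `n_helical`, `n_assignable`,
#'   `codes` (data frame `chain`, `resno`, `code` with `"H"`/`"-"`),
#'   `excluded_chains`.
#' @export
helicity <- function(ensemble, frame = 1, d13 = c(4.7, 5.7),
                     d14 = c(5.8, 6.7)) {
  at <- ensemble$atoms
  ca <- which(at$elety == "CA")
  if (!length(ca)) stop("no C-alpha atoms in ensemble")
  xyz <- frame_coords(ensemble, frame)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  codes <- list(); excluded <- character()
  for (ch in unique(at$chain[ca])) {
    idx <- ca[at$chain[ca] == ch]
    idx <- idx[order(at$resno[idx])]
    n <- length(idx)
    if (n < 5) { excluded <- c(excluded, ch); next }
    x <- xyz[idx, , drop = FALSE]
    helical <- rep(FALSE, n)
    for (i in seq_len(n - 4)) {
      a3 <- sqrt(sum((x[i + 3, ] - x[i, ])^2))
      a4 <- sqrt(sum((x[i + 4, ] - x[i, ])^2))
      if (a3 >= d13[1] && a3 <= d13[2] && a4 >= d14[1] && a4 <= d14[2])
        helical[i:(i + 4)] <- TRUE
    }
    codes[[ch]] <- data.frame(chain = ch, resno = at$resno[idx],
                              code = ifelse(helical, "H", "-"))
  }
  if (!length(codes))
    stop("no chain with >= 5 residues; helicity undefined")
  tab <- do.call(rbind, codes)
  rownames(tab) <- NULL
  n_hel <- sum(tab$code == "H")
  list(percent_helical = 100 * n_hel / nrow(tab),
       n_helical = n_hel, n_assignable = nrow(tab), codes = tab,
       excluded_chains = excluded)
}

#' Helical runs as a BED-like annotation table
#'
#' Collapses the per-residue helicity codes of [helicity()] into runs.
#'
#' @param hel result of [helicity()].
#' @return data frame with columns `chain`, `start`, `end`, `code`.
#' @export
helical_runs <- function(hel) {
  out <- list()
  for (ch in unique(hel$codes$chain)) {
    d <- hel$codes[hel$codes$chain == ch, ]
    r <- rle(d$code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    out[[ch]] <- data.frame(chain = ch, start = d$resno[starts],
                            end = d$resno[ends], code = r$values)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
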