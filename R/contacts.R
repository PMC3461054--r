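ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))

## Charged-group atom tables for one frame. Terminal groups are included:
## the backbone N of each chain's first residue (protonated amine) and
## any OXT (C-terminal carboxylate).
charged_groups <- function(atoms) {
  acidic <- logical(nrow(atoms)); basic <- logical(nrow(atoms))
  for (res in names(ACIDIC_ATOMS))
    acidic <- acidic | (atoms$resid == res &
                          atoms$elety %in% ACIDIC_ATOMS[[res]])
  acidic <- acidic | atoms$elety == "OXT"
  for (res in names(BASIC_ATOMS))
    basic <- basic | (atoms$resid == res &
                        atoms$elety %in% BASIC_ATOMS[[res]])
  for (ch in unique(atoms$chain)) {
    in_ch <- atoms$chain == ch
    first_res <- min(atoms$resno[in_ch])
    basic <- basic | (in_ch & atoms$resno == first_res &
                        atoms$elety == "N")
  }
  list(acidic = which(acidic), basic = which(basic))
}

#' Detect salt bridges in one frame
#'
#' A salt bridge is recorded for each (acidic residue, basic residue)
#' pair whose minimum distance between side-chain charged-group heavy
#' atoms (Asp OD1/OD2, Glu OE1/OE2, C-terminal OXT vs Lys NZ,
#' Arg NH1/NH2/NE, N-terminal backbone N) is at or below the cutoff.
#' One bridge is reported per residue pair (the minimum-distance atom
#' pair), with an interchain flag.
#'
#' @param ensemble a [structure_ensemble()].
#' @param frame frame index, default 1.
#' @param cutoff distance cutoff in Angstrom, default 4.0.
#' @return data frame with one row per bridge: acidic and basic
#'   chain/residue/atom, `distance` (Angstrom), `interchain`.
#' @export
salt_bridges <- function(ensemble, frame = 1, cutoff = 4.0) {
  at <- ensemble$atoms
  xyz <- frame_coords(ensemble, frame)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  grp <- charged_groups(at)
  empty <- data.frame(
    acidic_chain = character(), acidic_resno = integer(),
    acidic_resid = character(), acidic_atom = character(),
    basic_chain = character(), basic_resno = integer(),
    basic_resid = character(), basic_atom = character(),
    distance = numeric(), interchain = logical())
  if (!length(grp$acidic) || !length(grp$basic)) return(empty)
  rows <- list()
  for (ia in grp$acidic) {
    d <- sqrt(colSums((t(xyz[grp$basic, , drop = FALSE]) - xyz[ia, ])^2))
    hit <- which(d <= cutoff)
    for (h in hit) {
      ib <- grp$basic[h]
      if (at$chain[ia] == at$chain[ib] && at$resno[ia] == at$resno[ib])
        next  # e.g. OXT vs own terminal N
      rows[[length(rows) + 1]] <- data.frame(
        acidic_chain = at$chain[ia], acidic_resno = at$resno[ia],
        acidic_resid = at$resid[ia], acidic_atom = at$elety[ia],
        basic_chain = at$chain[ib], basic_resno = at$resno[ib],
        basic_resid = at$resid[ib], basic_atom = at$elety[ib],
        distance = d[h],
        interchain = at$chain[ia] != at$chain[ib])
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  ## deduplicate to the minimum-distance atom pair per residue pair
  key <- paste(out$acidic_chain, out$acidic_resno, out$basic_chain,
               out$basic_resno)
  out <- do.call(rbind, lapply(split(out, key), function(d)
    d[which.min(d$distance), ]))
  rownames(out) <- NULL
  out[order(out$acidic_chain, out$acidic_resno), ]
}

#' Detect hydrophobic residue contacts in one frame
#'
#' Residue pairs, both from the hydrophobic set and (by default) on
#' different chains, whose minimum side-chain heavy-atom distance is at
#' or below the cutoff. Side-chain atoms exclude the backbone
#' (N, CA, C, O, OXT); for glycine the CA is used as the side-chain
#' proxy.
#'
#' @inheritParams salt_bridges
#' @param cutoff distance cutoff in Angstrom, default 5.0.
#' @param interchain_only count only interchain pairs (default `TRUE`).
#' @param hydrophobic_set 3-letter residue names counted as hydrophobic.
#' @return data frame with one row per contact pair (`chain1`, `resno1`,
#'   `resid1`, `chain2`, `resno2`, `resid2`, `distance`).
#' @export
hydrophobic_contacts <- function(ensemble, frame = 1, cutoff = 5.0,
                                 interchain_only = TRUE,
                                 hydrophobic_set = HYDROPHOBIC_RESID3) {
  at <- ensemble$atoms
  xyz <- frame_coords(ensemble, frame)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  side <- at$resid %in% hydrophobic_set & at$element != "H" &
    (!(at$elety %in% c("N", "CA", "C", "O", "OXT")) |
       (at$resid == "GLY" & at$elety == "CA"))
  idx <- which(side)
  empty <- data.frame(chain1 = character(), resno1 = integer(),
                      resid1 = character(), chain2 = character(),
                      resno2 = integer(), resid2 = character(),
                      distance = numeric())
  if (!length(idx)) return(empty)
  key <- paste(at$chain[idx], at$resno[idx])
  groups <- split(idx, key)
  ids <- names(groups)
  n <- length(groups)
  rows <- list()
  for (i in seq_len(max(n - 1, 0))) for (j in (i + 1):n) {
    gi <- groups[[i]]; gj <- groups[[j]]
    if (interchain_only && at$chain[gi[1]] == at$chain[gj[1]]) next
    if (!interchain_only && at$chain[gi[1]] == at$chain[gj[1]] &&
        abs(at$resno[gi[1]] - at$resno[gj[1]]) < 2) next
    dmin <- min(sqrt(outer(rowSums(xyz[gi, , drop = FALSE]^2),
                           rowSums(xyz[gj, , drop = FALSE]^2), `+`) -
                       2 * xyz[gi, , drop = FALSE] %*%
                       t(xyz[gj, , drop = FALSE])))
    if (dmin <= cutoff)
      rows[[length(rows) + 1]] <- data.frame(
        chain1 = at$chain[gi[1]], resno1 = at$resno[gi[1]],
        resid1 = at$resid[gi[1]], chain2 = at$chain[gj[1]],
        resno2 = at$resno[gj[1]], resid2 = at$resid[gj[1]],
        distance = dmin)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-frame minimum distance between residue groups
#'
#' Tracks, across all frames, the minimum heavy-atom distance between
#' each specified pair of residues (e.g. the partners of a salt bridge).
#'
#' @param ensemble a [structure_ensemble()].
#' @param pairs list of pair specs; each is a list with elements `a` and
#'   `b`, themselves lists with `chain`, `resno` and optionally `atoms`
#'   (atom-name subset).
#' @return data frame with columns `frame`, `time` (if the ensemble has
#'   times), one column per pair named `<chainA><resnoA>-<chainB><resnoB>`.
#' @export
distance_timeline <- function(ensemble, pairs) {
  at <- ensemble$atoms
  get_idx <- function(spec) {
    keep <- at$chain == spec$chain & at$resno == spec$resno &
      at$element != "H"
    if (!is.null(spec$atoms)) keep <- keep & at$elety %in% spec$atoms
    idx <- which(keep)
    if (!length(idx))
      stop("lookup error: no atoms for chain ", spec$chain,
           " residue ", spec$resno)
    idx
  }
  cols <- lapply(pairs, function(p) {
    ia <- get_idx(p$a); ib <- get_idx(p$b)
    vapply(seq_len(n_frames(ensemble)), function(f) {
      xyz <- frame_coords(ensemble, f)
      if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
      min(sqrt(outer(rowSums(xyz[ia, , drop = FALSE]^2),
                     rowSums(xyz[ib, , drop = FALSE]^2), `+`) -
                 2 * xyz[ia, , drop = FALSE] %*%
                 t(xyz[ib, , drop = FALSE])))
    }, 0)
  })
  names(cols) <- vapply(pairs, function(p)
    paste0(p$a$chain, p$a$resno, "-", p$b$chain, p$b$resno), "")
  out <- data.frame(frame = seq_len(n_frames(ensemble)), cols,
                    check.names = FALSE)
  if (!is.null(ensemble$times)) out <- cbind(out[1], time = ensemble$times,
                                             out[-1])
  out
}
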