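## Internal element tables: atomic masses (u) and Bondi van der Waals
## radii (Angstrom). Unknown elements fall back to defaults with warning.
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974, FE = 55.845, ZN = 65.38,
                  MG = 24.305, "NA" = 22.990, CL = 35.45, K = 39.098)
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
WATER_RESID <- c("HOH", "WAT", "SOL", "TIP", "TIP3", "SPC")

HYDROPHOBIC_RESID3 <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP",
                        "PRO", "GLY")
AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

guess_element <- function(elety, elesy = NULL) {
  el <- toupper(trimws(ifelse(is.null(elesy), "", elesy)))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    ## first alphabetic character of the atom name, after stripping
    ## leading digits (e.g. "1HG1" -> H, "CA" -> C, "OD1" -> O)
    nm <- toupper(gsub("^[0-9]+", "", trimws(elety[miss])))
    el[miss] <- substr(nm, 1, 1)
  }
  el
}

#' Construct a structure ensemble
#'
#' An ordered set of conformations (frames) sharing one atom table —
#' the in-memory form of a multi-model PDB file.
#'
#' @param atoms data frame with one row per atom: columns `chain`,
#'   `resno`, `resid` (3-letter residue name), `elety` (atom name) and
#'   optionally `element`.
#' @param coords numeric array `c(n_atoms, 3, n_frames)` of coordinates
#'   in Angstrom (a single `n_atoms x 3` matrix is accepted for one
#'   frame).
#' @param times optional frame times (ps).
#' @return object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(atoms, coords, times = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (nrow(atoms) != dim(coords)[1])
    stop("atom table (", nrow(atoms), " rows) does not match coordinate ",
         "array (", dim(coords)[1], " atoms)")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(atoms$element))
    atoms$element <- guess_element(atoms$elety)
  if (!is.null(times) && length(times) != dim(coords)[3])
    stop("times length must equal the number of frames")
  structure(list(atoms = atoms, coords = coords, times = times),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("structure_ensemble: %d frames x %d atoms, %d chains, %d residues\n",
              n_frames(x), nrow(x$atoms),
              length(unique(x$atoms$chain)),
              nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a [structure_ensemble()].
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' Extract one frame as an n x 3 coordinate matrix
#' @param ensemble a [structure_ensemble()].
#' @param i frame index.
#' @export
frame_coords <- function(ensemble, i = 1) {
  ensemble$coords[, , i, drop = TRUE]
}

#' Read a conformational ensemble from a multi-model PDB file
#'
#' MODEL/ENDMDL records define the frames; a single-model file yields a
#' one-frame ensemble. Water molecules (and, by default, all other
#' HETATM records) are excluded; the number of excluded atoms is
#' reported via message. Parsing is delegated to [bio3d::read.pdb()]
#' after a consistency pre-scan of per-model atom counts.
#'
#' @param path PDB file path.
#' @param keep_hetatm keep non-water HETATM records (default `FALSE`).
#' @return a [structure_ensemble()].
#' @export
read_ensemble <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  model_ends <- which(trimws(rec) == "ENDMDL")
  if (length(model_starts) != length(model_ends) ||
      (length(model_starts) && any(model_ends < model_starts)))
    stop("parse error: unbalanced MODEL/ENDMDL records (",
         length(model_starts), " MODEL vs ", length(model_ends),
         " ENDMDL); file may be truncated near line ",
         if (length(model_starts)) utils::tail(model_starts, 1) else 1)
  if (length(model_starts) > 1) {
    counts <- mapply(function(s, e)
      sum(rec[s:e] %in% c("ATOM  ", "HETATM")), model_starts, model_ends)
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      stop("format error: model ", bad, " has ", counts[bad],
           " atoms but model 1 has ", counts[1])
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- !(at$resid %in% WATER_RESID)
  if (!keep_hetatm) keep <- keep & at$type == "ATOM"
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("read_ensemble: excluded ", n_dropped,
            " HETATM/water atom(s)")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms left after HETATM/water filtering")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nfr <- nrow(xyz)
  idx <- which(keep)
  coords <- array(NA_real_, dim = c(nrow(at), 3, nfr))
  for (f in seq_len(nfr)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[, , f] <- m[idx, , drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      resid = at$resid, elety = at$elety,
                      element = guess_element(at$elety, at$elesy),
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  structure_ensemble(atoms, coords)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits standard MODEL/ENDMDL-delimited ATOM records readable by
#' [read_ensemble()] and by common structure viewers.
#'
#' @param ensemble a [structure_ensemble()].
#' @param path output path.
#' @export
write_ensemble <- function(ensemble, path) {
  at <- ensemble$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(ensemble, f)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)),
      ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
      at$resid, at$chain, at$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms of an ensemble
#'
#' @param ensemble a [structure_ensemble()].
#' @param selection either a preset name — `"all"`, `"heavy"` (non-H),
#'   `"backbone"` (N, CA, C, O), `"calpha"` (CA) — or a list with any of
#'   `chain` (chain ids), `resno` (residue numbers or `c(lo, hi)` range
#'   given as `resno_range`), `elety` (atom-name set).
#' @return integer vector of atom indices into the ensemble's atom table.
#' @export
select_atoms <- function(ensemble, selection = "all") {
  at <- ensemble$atoms
  keep <- rep(TRUE, nrow(at))
  if (is.character(selection)) {
    keep <- switch(selection,
      all = keep,
      heavy = at$element != "H",
      backbone = at$elety %in% c("N", "CA", "C", "O"),
      calpha = at$elety == "CA",
      stop("unknown selection preset: ", selection))
  } else if (is.list(selection)) {
    g <- function(nm) selection[[nm, exact = TRUE]]
    if (!is.null(g("chain"))) keep <- keep & at$chain %in% g("chain")
    if (!is.null(g("resno"))) keep <- keep & at$resno %in% g("resno")
    if (!is.null(g("resno_range")))
      keep <- keep & at$resno >= g("resno_range")[1] &
        at$resno <= g("resno_range")[2]
    if (!is.null(g("elety"))) keep <- keep & at$elety %in% g("elety")
  } else stop("selection must be a preset name or a list")
  idx <- which(keep)
  if (length(idx) == 0) stop("empty atom selection")
  idx
}
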