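AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Kyte-Doolittle hydropathy, used by the register scanner.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)

#' Construct a protein sequence with full-protein numbering
#'
#' @param id sequence identifier.
#' @param residues one-letter amino-acid string (20-letter alphabet; `X`
#'   is allowed and flagged with a warning).
#' @param numbering_offset residue number of the first residue in
#'   full-protein coordinates (>= 1), so that stalk fragments keep their
#'   parent numbering.
#' @return object of class `protein_sequence`.
#' @examples
#' protein_sequence("stalk", "LEALEGKLEALEGK", numbering_offset = 425)
#' @export
protein_sequence <- function(id, residues, numbering_offset = 1) {
  residues <- toupper(gsub("\\s", "", residues))
  letters1 <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(letters1), c(AA20, "X"))
  if (length(bad))
    stop("invalid residue letter(s): ", paste(bad, collapse = ", "))
  if (any(letters1 == "X"))
    warning("sequence ", id, " contains ", sum(letters1 == "X"),
            " 'X' residue(s)")
  if (numbering_offset < 1) stop("numbering_offset must be >= 1")
  structure(list(id = id, residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("protein_sequence %s: %d aa, residues %d-%d\n", x$id, n,
              x$numbering_offset, x$numbering_offset + n - 1L))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param numbering_offset offset applied to every sequence (recycle a
#'   vector for per-sequence offsets).
#' @return list of [protein_sequence()] objects, named by FASTA id.
#' @export
read_fasta_sequences <- function(path, numbering_offset = 1) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  offsets <- rep_len(numbering_offset, length(seqs))
  out <- Map(function(s, off)
    protein_sequence(attr(s, "name"), as.character(s), off),
    seqs, offsets)
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write protein sequences to FASTA
#' @param seqs a [protein_sequence()] or list of them.
#' @param path output file.
#' @export
write_fasta_sequences <- function(seqs, path) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  seqinr::write.fasta(lapply(seqs, function(s) s$residues),
                      names = vapply(seqs, `[[`, "", "id"),
                      file.out = path)
  invisible(path)
}

#' Assign heptad registers from coil-block definitions
#'
#' Deterministic cyclic a-g labelling: within each block the register
#' starts at the given phase and cycles with period 7; residues outside
#' all blocks get `-`. Partial heptads at block ends are allowed.
#'
#' @param seq a [protein_sequence()].
#' @param blocks data frame (or list of vectors) with columns/elements
#'   `start`, `end` (full-protein numbering, inclusive) and `phase`
#'   (letter in a..g assigned to the block's first residue).
#' @return object of class `heptad_annotation`: list with `register`
#'   (character vector aligned to residues), `coil_blocks`, `seq_id`,
#'   `numbering_offset` and `score` (`NA` for explicit assignments).
#' @examples
#' s <- protein_sequence("zip", "LEALEGKLEALEGK")
#' assign_register(s, data.frame(start = 1, end = 14, phase = "a"))
#' @export
assign_register <- function(seq, blocks) {
  n <- nchar(seq$residues)
  off <- seq$numbering_offset
  register <- rep("-", n)
  if (is.list(blocks) && !is.data.frame(blocks))
    blocks <- do.call(rbind, lapply(blocks, as.data.frame))
  if (is.null(blocks) || NROW(blocks) == 0) {
    return(new_heptad_annotation(seq, register, blocks = NULL, score = NA))
  }
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  if (NROW(blocks) > 1 &&
      any(blocks$start[-1] <= blocks$end[-NROW(blocks)]))
    stop("scheme error: coil blocks overlap")
  for (k in seq_len(NROW(blocks))) {
    b <- blocks[k, ]
    phase <- match(tolower(b$phase), letters[1:7])
    if (is.na(phase)) stop("phase must be one of a..g, got ", b$phase)
    i0 <- b$start - off + 1L
    i1 <- b$end - off + 1L
    if (b$end < b$start) stop("scheme error: block end before start")
    if (i0 < 1 || i1 > n)
      stop("scheme error: block ", b$start, "-", b$end,
           " outside sequence residues ", off, "-", off + n - 1L)
    idx <- i0:i1
    register[idx] <- letters[1:7][((seq_along(idx) - 1 + phase - 1) %% 7) + 1]
  }
  new_heptad_annotation(seq, register, blocks = blocks, score = NA)
}

new_heptad_annotation <- function(seq, register, blocks, score) {
  structure(list(register = register, coil_blocks = blocks,
                 seq_id = seq$id,
                 numbering_offset = seq$numbering_offset,
                 score = score),
            class = "heptad_annotation")
}

#' @export
print.heptad_annotation <- function(x, ...) {
  n <- length(x$register)
  cat(sprintf("heptad_annotation for %s: %d residues, %d in register\n",
              x$seq_id, n, sum(x$register != "-")))
  if (!is.na(x$score)) cat(sprintf("  scan score %.3f\n", x$score))
  invisible(x)
}

#' Scan a sequence for the best heptad register phase
#'
#' A lightweight hydropathy-based register scanner (an explicitly simpler
#' stand-in for dedicated coiled-coil predictors, and labelled as such in
#' its output): over sliding windows, each of the 7 phase offsets is
#' scored as the mean Kyte-Doolittle hydropathy at the implied a/d
#' positions minus the mean at the other positions; the best offset per
#' window wins, ties break deterministically to the lowest offset and are
#' flagged low-confidence. Adjacent windows agreeing on the phase are
#' merged into blocks.
#'
#' @param seq a [protein_sequence()].
#' @param window window length in residues (>= 14), default 28.
#' @return a `heptad_annotation` whose `score` is the mean winning-margin
#'   per window; attribute `low_confidence` is `TRUE` when any window
#'   tied; attribute `method` records the scanner used.
#' @export
score_register <- function(seq, window = 28) {
  n <- nchar(seq$residues)
  if (window < 14) stop("window must be >= 14")
  if (n < window)
    stop("insufficient length: sequence has ", n,
         " residues, window is ", window)
  letters1 <- strsplit(seq$residues, "")[[1]]
  h <- unname(KD_HYDROPATHY[letters1])

  phase_score <- function(idx, p) {
    ## register letter of position i under phase offset p (0-based):
    ## letter index (i - 1 + p) %% 7; a/d are letter indices 0 and 3.
    reg <- (idx - 1 + p) %% 7
    ad <- reg == 0 | reg == 3
    mean(h[idx][ad]) - mean(h[idx][!ad])
  }

  starts <- seq(1, n - window + 1)
  best <- integer(length(starts)); margin <- numeric(length(starts))
  tied <- logical(length(starts))
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + window - 1)
    sc <- vapply(0:6, function(p) phase_score(idx, p), 0)
    best[w] <- which.max(sc) - 1L
    srt <- sort(sc, decreasing = TRUE)
    margin[w] <- srt[1] - srt[2]
    tied[w] <- margin[w] < 1e-12
  }

  ## per-residue majority vote over covering windows
  votes <- matrix(0, nrow = n, ncol = 7)
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + window - 1)
    votes[idx, best[w] + 1] <- votes[idx, best[w] + 1] + 1
  }
  phase_res <- max.col(votes, ties.method = "first") - 1L
  register <- letters[1:7][((seq_len(n) - 1 + phase_res) %% 7) + 1]

  ## contiguous same-phase runs as blocks
  runs <- rle(phase_res)
  ends <- cumsum(runs$lengths)
  startsr <- ends - runs$lengths + 1
  blocks <- data.frame(
    start = startsr + seq$numbering_offset - 1L,
    end = ends + seq$numbering_offset - 1L,
    phase = register[startsr])

  ann <- new_heptad_annotation(seq, register, blocks = blocks,
                               score = mean(margin))
  attr(ann, "low_confidence") <- any(tied)
  attr(ann, "method") <- "hydropathy_scan"
  ann
}

#' Charged-residue atypicality at heptad a/d positions
#'
#' Counts residues from `charged_set` occupying core (`a` or `d`) heptad
#' positions — the atypical substitutions that weaken the hydrophobic
#' seam of a coiled coil.
#'
#' @param annotation a `heptad_annotation` aligned to `seq`.
#' @param seq the annotated [protein_sequence()].
#' @param charged_set residues counted as charged; default
#'   `c("D","E","K","R")` (histidine excluded at physiological pH).
#' @return list with `n_a_d_positions`, `n_charged_a_d`,
#'   `fraction_charged_a_d` and a `positions` data frame (full-protein
#'   `residue_number`, `letter`, `register`).
#' @export
atypicality_stats <- function(annotation, seq,
                              charged_set = c("D", "E", "K", "R")) {
  letters1 <- strsplit(seq$residues, "")[[1]]
  if (length(letters1) != length(annotation$register))
    stop("alignment error: annotation length ",
         length(annotation$register), " != sequence length ",
         length(letters1))
  ad <- annotation$register %in% c("a", "d")
  hit <- ad & letters1 %in% charged_set
  pos <- data.frame(
    residue_number = which(hit) + seq$numbering_offset - 1L,
    letter = letters1[hit],
    register = annotation$register[hit])
  n_ad <- sum(ad)
  list(n_a_d_positions = n_ad,
       n_charged_a_d = sum(hit),
       fraction_charged_a_d = if (n_ad > 0) sum(hit) / n_ad else 0,
       positions = pos)
}

#' Define a named segment scheme on full-protein coordinates
#'
#' @param ... named intervals, each a length-2 numeric
#'   `c(start, end)` in full-protein numbering (1-based, inclusive).
#' @return object of class `segment_scheme` (named list of intervals).
#' @examples
#' segment_scheme(S = c(425, 589), SN1 = c(425, 506), SC1 = c(517, 589))
#' @export
segment_scheme <- function(...) {
  segs <- list(...)
  if (is.null(names(segs)) || any(names(segs) == ""))
    stop("every segment must be named")
  if (anyDuplicated(names(segs))) stop("segment names must be unique")
  for (nm in names(segs)) {
    iv <- segs[[nm]]
    if (length(iv) != 2 || iv[2] < iv[1])
      stop("scheme error: segment ", nm, " is not a valid interval")
  }
  structure(segs, class = "segment_scheme")
}

#' Stalk segment schemes for the kinesin-II motor subunits
#'
#' The published stalk fragment boundaries, in full-protein numbering:
#' for KLP64D the stalk S = 425-589, its N-terminal half SN1 = 425-506,
#' C-terminal half SC1 = 517-589 and C-terminal third SC2 = 529-589; for
#' KLP68D S = 423-584, SN1 = 423-501, SC1 = 511-587 and the middle region
#' 502-520. Boundaries not published (e.g. SN2) are not included; extend
#' the scheme with [segment_scheme()] as needed.
#'
#' @param subunit `"KLP64D"` or `"KLP68D"`.
#' @return a [segment_scheme()].
#' @export
kinesin2_stalk_scheme <- function(subunit = c("KLP64D", "KLP68D")) {
  subunit <- match.arg(subunit)
  if (subunit == "KLP64D")
    segment_scheme(S = c(425, 589), SN1 = c(425, 506),
                   SC1 = c(517, 589), SC2 = c(529, 589))
  else
    segment_scheme(S = c(423, 584), SN1 = c(423, 501),
                   SC1 = c(511, 587), middle = c(502, 520))
}

#' Slice a named segment out of a sequence
#'
#' Returns the subsequence for a named interval of a [segment_scheme()],
#' preserving full-protein numbering through `numbering_offset`.
#'
#' @param seq a [protein_sequence()] covering the interval.
#' @param scheme a [segment_scheme()].
#' @param name segment name.
#' @return a [protein_sequence()] for the segment.
#' @export
slice_segment <- function(seq, scheme, name) {
  if (!name %in% names(scheme))
    stop("scheme error: unknown segment '", name, "'")
  iv <- scheme[[name]]
  off <- seq$numbering_offset
  n <- nchar(seq$residues)
  i0 <- iv[1] - off + 1L
  i1 <- iv[2] - off + 1L
  if (i0 < 1 || i1 > n)
    stop("scheme error: segment ", name, " (", iv[1], "-", iv[2],
         ") outside sequence residues ", off, "-", off + n - 1L)
  protein_sequence(paste0(seq$id, ":", name),
                   substr(seq$residues, i0, i1),
                   numbering_offset = iv[1])
}

#' Tabulate a heptad annotation per residue
#'
#' @param annotation a `heptad_annotation`.
#' @param seq the annotated [protein_sequence()].
#' @inheritParams atypicality_stats
#' @return data frame with columns `residue_number`, `letter`,
#'   `register`, `charged_at_ad` — the TSV-ready per-residue view.
#' @export
annotation_table <- function(annotation, seq,
                             charged_set = c("D", "E", "K", "R")) {
  letters1 <- strsplit(seq$residues, "")[[1]]
  data.frame(
    residue_number = seq_along(letters1) + seq$numbering_offset - 1L,
    letter = letters1,
    register = annotation$register,
    charged_at_ad = annotation$register %in% c("a", "d") &
      letters1 %in% charged_set)
}
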