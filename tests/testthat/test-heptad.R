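test_that("explicit register assignment cycles a..g from the block phase", {
  s <- protein_sequence("zip", "LEALEGKLEALEGK")
  ann <- assign_register(s, data.frame(start = 1, end = 14, phase = "a"))
  expect_equal(paste(ann$register, collapse = ""), "abcdefgabcdefg")
  # empty block list -> all unassigned
  ann0 <- assign_register(s, NULL)
  expect_true(all(ann0$register == "-"))
  # partial heptad truncates mid-cycle without error
  ann2 <- assign_register(s, data.frame(start = 1, end = 10, phase = "d"))
  expect_equal(paste(ann2$register, collapse = ""), "defgabcdef----")
  # identical inputs give identical annotations (pure function)
  expect_identical(assign_register(s, data.frame(start = 1, end = 14,
                                                 phase = "a")), ann)
})

test_that("register blocks respect numbering offsets and reject overlap", {
  s <- protein_sequence("stalk", strrep("LEALEGK", 10),
                        numbering_offset = 425)
  ann <- assign_register(s, data.frame(start = 425, end = 494,
                                       phase = "a"))
  expect_equal(ann$register[1], "a")
  expect_error(assign_register(s, data.frame(start = c(425, 450),
                                             end = c(460, 470),
                                             phase = c("a", "a"))),
               "overlap")
  expect_error(assign_register(s, data.frame(start = 400, end = 430,
                                             phase = "a")),
               "outside")
  expect_error(assign_register(s, data.frame(start = 430, end = 425,
                                             phase = "a")),
               "end before start")
})

test_that("hydropathy scan recovers a designed leucine-zipper phase", {
  # L at a, V at d, E/K elsewhere, phase a
  rep_unit <- "LEEVKEK"
  s <- protein_sequence("design", strrep(rep_unit, 6))
  ann <- score_register(s, window = 28)
  expect_equal(paste(ann$register[1:7], collapse = ""), "abcdefg")
  expect_false(isTRUE(attr(ann, "low_confidence")))
})

test_that("hydropathy scan flags degenerate sequences and short input", {
  s <- protein_sequence("polyA", strrep("A", 50))
  ann <- score_register(s, window = 28)
  expect_true(attr(ann, "low_confidence"))
  expect_equal(ann$register[1], "a")  # deterministic lowest-offset tie-break
  expect_error(score_register(protein_sequence("tiny", "LEALEGK")),
               "insufficient length")
  expect_error(score_register(s, window = 7), ">= 14")
})

test_that("scan matches the exhaustive 7-offset oracle on each window", {
  g <- gen_heptad_sequence(8, seed = 13)
  letters1 <- strsplit(g$seq$residues, "")[[1]]
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  h <- unname(kd[letters1])
  window <- 28
  oracle_best <- function(start) {
    idx <- start:(start + window - 1)
    sc <- sapply(0:6, function(p) {
      reg <- (idx - 1 + p) %% 7
      ad <- reg == 0 | reg == 3
      mean(h[idx][ad]) - mean(h[idx][!ad])
    })
    which.max(sc) - 1L
  }
  # every window's winning offset must equal the truth phase (a at 1)
  expect_true(all(sapply(seq(1, length(h) - window + 1, by = 3),
                         oracle_best) == 0))
  ann <- score_register(g$seq, window = window)
  expect_equal(ann$register, g$register)
})

test_that("register recovery across 100 seeded generator sequences", {
  hits <- sapply(1:100, function(s) {
    g <- gen_heptad_sequence(6, seed = s)
    ann <- score_register(g$seq, window = 28)
    all(ann$register == g$register)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("charged a/d atypicality counts match constructions", {
  s <- protein_sequence("h", "LEALEGK")
  ann <- assign_register(s, data.frame(start = 1, end = 7, phase = "a"))
  expect_equal(atypicality_stats(ann, s)$n_charged_a_d, 0)
  # substitute K at the d position (position 4)
  s2 <- protein_sequence("h2", "LEAKEGK", numbering_offset = 100)
  ann2 <- assign_register(s2, data.frame(start = 100, end = 106,
                                         phase = "a"))
  st2 <- atypicality_stats(ann2, s2)
  expect_equal(st2$n_charged_a_d, 1)
  expect_equal(st2$positions$residue_number, 103)
  expect_equal(st2$positions$register, "d")
  # histidine excluded by default, countable on request
  s3 <- protein_sequence("h3", "HEALEGK")
  ann3 <- assign_register(s3, data.frame(start = 1, end = 7, phase = "a"))
  expect_equal(atypicality_stats(ann3, s3)$n_charged_a_d, 0)
  expect_equal(atypicality_stats(ann3, s3,
                                 charged_set = c("D", "E", "K", "R",
                                                 "H"))$n_charged_a_d, 1)
})

test_that("planted charged a/d sites are recovered exactly and offset-invariantly", {
  planted <- c(1, 8, 15, 22, 29)
  g <- gen_heptad_sequence(10, charged_ad_positions = planted, seed = 2)
  ann <- assign_register(g$seq, g$blocks)
  st <- atypicality_stats(ann, g$seq)
  expect_equal(st$n_charged_a_d, 5)
  expect_equal(st$fraction_charged_a_d, 5 / st$n_a_d_positions)
  # renumbering does not change the counts
  g2 <- gen_heptad_sequence(10, charged_ad_positions = planted, seed = 2,
                            numbering_offset = 425)
  ann2 <- assign_register(g2$seq, g2$blocks)
  st2 <- atypicality_stats(ann2, g2$seq)
  expect_equal(st2$n_charged_a_d, st$n_charged_a_d)
  expect_equal(st2$fraction_charged_a_d, st$fraction_charged_a_d)
  expect_error(atypicality_stats(ann, g2$seq), NA)
  # mismatched lengths are an alignment error
  short <- protein_sequence("s", "LEALEGK")
  expect_error(atypicality_stats(ann, short), "alignment")
})

test_that("segment slicing reproduces the published stalk interval lengths", {
  # KLP64D numbering: full protein carries the stalk at 425-589
  full <- protein_sequence("KLP64D", strrep("A", 700))
  scheme <- kinesin2_stalk_scheme("KLP64D")
  stalk <- slice_segment(full, scheme, "S")
  expect_equal(nchar(stalk$residues), 165)
  expect_equal(stalk$numbering_offset, 425)
  sn1 <- slice_segment(full, scheme, "SN1")
  expect_equal(nchar(sn1$residues), 82)
  # slicing the stalk out of the stalk-only sequence works via offsets
  sn1b <- slice_segment(stalk, scheme, "SN1")
  expect_equal(sn1b$residues, sn1$residues)
  expect_error(slice_segment(full, scheme, "bogus"), "unknown segment")
  expect_error(segment_scheme(S = c(589, 425)), "not a valid interval")
  short <- protein_sequence("frag", strrep("A", 50),
                            numbering_offset = 500)
  expect_error(slice_segment(short, scheme, "S"), "outside")
})

test_that("FASTA round trip preserves sequences and annotation table aligns", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  g <- gen_heptad_sequence(6, seed = 9, id = "synthetic_stalk")
  write_fasta_sequences(g$seq, tmp)
  back <- read_fasta_sequences(tmp)
  expect_equal(back[[1]]$residues, g$seq$residues)
  ann <- assign_register(g$seq, g$blocks)
  tab <- annotation_table(ann, g$seq)
  expect_equal(nrow(tab), nchar(g$seq$residues))
  expect_true(all(tab$register[tab$charged_at_ad] %in% c("a", "d")))
})
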