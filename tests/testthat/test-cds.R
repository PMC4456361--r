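toy <- coding_sequence("ATGCAAGTGACTTAA", id = "toy")

test_that("cDNA variant labels parse into structured events", {
  v <- parse_cdna_variant("c.79G>A")
  expect_equal(v$kind, "substitution")
  expect_equal(v$start, 79L)
  expect_equal(v$ref_seq, "G")
  expect_equal(v$alt_seq, "A")

  v <- parse_cdna_variant("c.512_513insAACG")
  expect_equal(v$kind, "insertion")
  expect_equal(c(v$start, v$end), c(512L, 513L))
  expect_equal(v$alt_seq, "AACG")

  v <- parse_cdna_variant("c.176_191del16")
  expect_equal(v$kind, "deletion")
  expect_equal(v$end - v$start + 1L, 16L)

  # legacy single-position insertion dialect
  v <- parse_cdna_variant("c.35insG")
  expect_equal(c(v$start, v$end), c(35L, 36L))

  v <- parse_cdna_variant("c.299_300delAT")
  expect_equal(v$ref_seq, "AT")
})

test_that("malformed labels are rejected with the offending token named", {
  expect_error(parse_cdna_variant("c.0G>A"), "position 0")
  expect_error(parse_cdna_variant("79G>A"), "c\\.")
  expect_error(parse_cdna_variant("c.176_191del15"), "15")
  expect_error(parse_cdna_variant("c.299_300delATT"), "ATT")
  expect_error(parse_cdna_variant("c.12N>A"), "N")
  expect_error(parse_cdna_variant("c.10_12insA"), "not adjacent")
  expect_error(parse_cdna_variant("c.30_20del"), "precedes")
  expect_error(parse_cdna_variant("c.garbage"), "garbage")
})

test_that("parse/format round-trips preserve all structured fields", {
  labels <- c(gjb2_table1()$variant, "c.4delC", "c.10_12del3", "c.7A>T",
              "c.5_6insTTT")
  for (lab in labels) {
    v1 <- parse_cdna_variant(lab)
    v2 <- parse_cdna_variant(format_cdna_variant(v1))
    expect_equal(v2[c("kind", "start", "end", "ref_seq", "alt_seq")],
                 v1[c("kind", "start", "end", "ref_seq", "alt_seq")],
                 info = lab)
  }
})

test_that("variants apply to the CDS with reference-base guarding", {
  expect_equal(apply_cdna_variant(toy, "c.4delC"), "ATGAAGTGACTTAA")
  expect_equal(apply_cdna_variant(toy, "c.4C>T"), "ATGTAAGTGACTTAA")
  expect_error(apply_cdna_variant(toy, "c.4G>A"), "expected 'G', found 'C'")
  expect_error(apply_cdna_variant(toy, "c.999A>T"), "beyond")
})

test_that("indels change sequence length by exactly the event size", {
  set.seed(42)
  for (i in 1:50) {
    cds_str <- random_toy_cds()
    cds <- coding_sequence(cds_str)
    v <- random_toy_variant(cds_str)
    mut <- apply_cdna_variant(cds, v$label)
    delta <- switch(v$kind, substitution = 0L, deletion = -(v$end - v$start + 1L),
                    insertion = nchar(v$alt))
    expect_equal(nchar(mut) - nchar(cds_str), delta, info = v$label)
  }
})

test_that("translation stops at the first stop codon and drops partial codons", {
  expect_equal(translate_cds("ATGTGA"), list(protein = "M", stop_reached = TRUE))
  expect_equal(translate_cds("ATGAAGTGA"), list(protein = "MK", stop_reached = TRUE))
  expect_equal(translate_cds("ATGAA"), list(protein = "M", stop_reached = FALSE))
  expect_error(translate_cds("ATGNNN"), "non-ACGT")
})

test_that("coding sequences are validated on construction", {
  expect_error(coding_sequence("ATGAAA"), "stop codon")        # no stop
  expect_error(coding_sequence("AAATGA"), "ATG")               # no start
  expect_error(coding_sequence("ATGTA"), "multiple of 3")
  expect_error(coding_sequence("ATGTAAAAATAA"), "internal")    # internal stop
})

test_that("toy substitutions and frameshifts get the expected labels", {
  p <- predict_consequence(toy, "c.4delC")  # mutant reads ATG AAG TGA
  expect_equal(p$category, "frameshift")
  expect_equal(p$label_paper, "Q2KfsX2")
  expect_equal(p$stop_offset, 2L)

  p <- predict_consequence(coding_sequence("ATGAAATAA"), "c.4A>G")
  expect_equal(p$category, "missense")
  expect_equal(p$label_paper, "p.K2E")

  # frameshift that never meets a new stop codon
  p <- predict_consequence(coding_sequence("ATGAAAAAATAA"), "c.4delA")
  expect_true(p$no_stop)
  expect_match(p$label_paper, "fsX\\?$")

  # in-frame single-codon deletion
  p <- predict_consequence(toy, "c.4_6delCAA")
  expect_equal(p$category, "in_frame")
  expect_equal(p$label_canonical, "p.Q2del")
})

test_that("the GJB2 reference CDS reproduces the published protein labels", {
  cds <- gjb2_cds()
  t1 <- gjb2_table1()
  cons <- predict_consequences(cds, t1$variant)

  # all substitutions (missense, nonsense, silent) match the printed column
  subst <- t1$category %in% c("missense", "nonsense", "silent")
  expect_equal(cons$label_paper[subst], t1$protein_label[subst])

  # standard-notation frameshifts match exactly
  fs_exact <- c("c.35delG" = "G12VfsX2", "c.176_191del16" = "G59AfsX18",
                "c.235delC" = "L79CfsX3", "c.299_300delAT" = "H100RfsX14")
  got <- setNames(cons$label_paper, cons$variant)[names(fs_exact)]
  expect_equal(unname(got), unname(fs_exact))

  # c.512_513insAACG: published as A172EfsX39; the sequence-derived consequence
  # agrees on anchor residue 172 and stop offset 39 (the published ref/alt
  # letters are not derivable from the reference sequence)
  ins <- predict_consequence(cds, "c.512_513insAACG")
  expect_equal(ins$position, 172L)
  expect_equal(ins$stop_offset, 39L)

  # c.35insG: published as G12GfsX36 with an unchanged anchor residue; the
  # first-changed-residue rule anchors one codon later with the same stop
  legacy <- predict_consequence(cds, "c.35insG")
  expect_equal(legacy$category, "frameshift")
  expect_equal(legacy$position + legacy$stop_offset, 12L + 36L)
})

test_that("consequence engine agrees with the brute-force oracle", {
  set.seed(20150604)
  n_pairs <- 1000L
  for (i in seq_len(n_pairs)) {
    cds_str <- random_toy_cds()
    cds <- coding_sequence(cds_str)
    v <- random_toy_variant(cds_str)
    got <- predict_consequence(cds, v$label)
    exp <- oracle_consequence(cds_str, v$kind, v$start, v$end, v$alt)
    if (v$kind == "substitution") {
      idx <- ceiling(v$start / 3)
      if (got$category == "silent") {
        # oracle sees no difference; nothing to compare beyond category
        expect_gt(exp$position, nchar(cds_str) / 3, label = v$label)
      } else {
        expect_equal(got$position, idx, info = v$label)
        expect_equal(exp$position, idx, info = v$label)
        expect_equal(got$alt_aa, chartr("*", "X", exp$alt_aa), info = v$label)
      }
    } else {
      expect_equal(got$position, exp$position, info = paste(cds_str, v$label))
      # an exhausted mutant (edit at the very end, no new stop) has no alt
      exp_alt <- if (is.na(exp$alt_aa)) "" else chartr("*", "X", exp$alt_aa)
      expect_equal(got$alt_aa, exp_alt, info = paste(cds_str, v$label))
      expect_equal(got$stop_offset, exp$stop_offset,
                   info = paste(cds_str, v$label))
    }
  }
})
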