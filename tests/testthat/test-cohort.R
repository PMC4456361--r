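chr_map <- gjb2_characterization()

test_that("bracket genotype labels parse, with markup tolerated", {
  g <- parse_genotype_label("[c.235delC]/[c.299_300delAT]")
  expect_equal(g$allele1, "c.235delC")
  expect_equal(g$allele2, "c.299_300delAT")

  g <- parse_genotype_label("[c.79G>A;c.109G>A;c.341A>G]/[c.109G>A]")
  expect_equal(length(g$allele1), 3L)
  expect_equal(g$allele2, "c.109G>A")

  g <- parse_genotype_label("[c.235delC]/[wt]")
  expect_equal(g$allele2, character(0))

  # bold markup, whitespace and a bare c.-less token as printed in reports
  g <- parse_genotype_label("**[c.235delC**; 79G>A] / [c.439G>A]**")
  expect_equal(sort(g$allele1), c("c.235delC", "c.79G>A"))
})

test_that("malformed genotypes fail with located errors", {
  expect_error(parse_genotype_label("[c.235delC]"), "two allele groups")
  expect_error(parse_genotype_label("[c.235delC/[wt]"), "unbalanced bracket")
  expect_error(parse_genotype_label("[c.bogus]/[wt]"), "unparseable variant")
  expect_error(parse_genotype_label("[c.235delC;c.235delC]/[wt]"), "duplicate")
})

test_that("PTA is the mean of exactly five thresholds", {
  expect_equal(pta_average(c(90, 90, 90, 90, 90)), 90)
  expect_equal(pta_average(c(100, 105, 110, 120, 135)), 114)
  expect_error(pta_average(c(90, 90, 90, 90)), "5 thresholds")
})

test_that("severity grades follow the five clinical bands", {
  expect_equal(as.character(grade_severity(c(25, 26, 40, 41, 70, 71, 90, 90.1, 114))),
               c("normal", "mild", "mild", "moderate", "moderate",
                 "severe", "severe", "profound", "profound"))
  # uncovered gap values land in the band of their rounded integer;
  # values inside a printed band stay put (25.5 is already < 26)
  expect_equal(as.character(grade_severity(c(25.4, 25.5, 40.5, 70.4, 70.5))),
               c("normal", "normal", "moderate", "moderate", "severe"))
  expect_error(grade_severity(-1), "non-negative")
})

test_that("carrier categories follow the pathogenic-allele rules", {
  expect_equal(subject_category("[c.235delC;c.478G>A]/[c.235delC]", chr_map),
               "homozygote")  # cis polymorphism ignored
  expect_equal(subject_category("[c.235delC]/[c.109G>A]", chr_map),
               "compound_heterozygote")
  expect_equal(subject_category("[c.107T>C]/[c.79G>A;c.341A>G]", chr_map),
               "single_heterozygote")  # putative pathogenic counts
  expect_equal(subject_category("[c.79G>A]/[c.79G>A]", chr_map),
               "polymorphisms_only")
  expect_equal(subject_category("[wt]/[wt]", chr_map), "wild_type")
  expect_error(subject_category("[c.999G>A]/[wt]", chr_map), "not present")
})

test_that("carrier category is symmetric in allele order", {
  labels <- c("[c.235delC]/[c.109G>A]", "[c.235delC;c.478G>A]/[c.235delC]",
              "[c.107T>C]/[c.79G>A;c.341A>G]", "[c.79G>A]/[wt]")
  for (lab in labels) {
    parts <- strsplit(lab, "/", fixed = TRUE)[[1L]]
    flipped <- paste(rev(parts), collapse = "/")
    expect_equal(subject_category(flipped, chr_map),
                 subject_category(lab, chr_map), info = lab)
  }
})

test_that("allele frequencies count each occurrence once over 2N alleles", {
  one_het <- data.frame(subject_id = "s1", genotype = "[c.235delC]/[wt]")
  expect_equal(allele_frequencies(one_het)$freq_percent, 50)

  homs <- data.frame(subject_id = c("s1", "s2"),
                     genotype = rep("[c.235delC]/[c.235delC]", 2))
  expect_equal(allele_frequencies(homs)$freq_percent, 100)

  # 1067 subjects carrying 298 c.235delC alleles -> 13.96%
  n_hom <- 149L
  cohort <- data.frame(
    subject_id = sprintf("s%04d", 1:1067),
    genotype = c(rep("[c.235delC]/[c.235delC]", n_hom), rep("[wt]/[wt]", 1067 - n_hom)))
  af <- allele_frequencies(cohort)
  expect_equal(af$count, 298L)
  expect_equal(af$freq_percent, 13.96)
})

test_that("summed allele counts equal total non-reference observations", {
  set.seed(12)
  spec <- cohort_spec(300, haplotypes = c("c.235delC" = 0.2,
                                          "c.79G>A;c.341A>G" = 0.3),
                      pathogenic = "c.235delC", seed = 99)
  subj <- simulate_cohort(spec)
  af <- allele_frequencies(subj)
  gts <- lapply(subj$genotype, parse_genotype_label)
  total_obs <- sum(vapply(gts, function(g) length(g$allele1) + length(g$allele2), 0L))
  expect_equal(sum(af$count), total_obs)
})

test_that("aggregate genotype counts expand to the printed subject totals", {
  subj <- expand_genotype_counts(gjb2_table2())
  expect_equal(nrow(subj), 216L)
  expect_equal(as.integer(table(factor(subj$severity,
                                       c("mild", "moderate", "severe", "profound")))),
               c(8L, 24L, 43L, 141L))
  # assigned PTAs re-derive the assigned severity grade
  expect_equal(as.character(grade_severity(pmin(subj$pta_right, subj$pta_left))),
               subj$severity)
})

test_that("the reconstructed cohort reproduces the published structure", {
  co <- summarize_cohort(gjb2_cohort(), chr_map)
  expect_equal(co$n_subjects, 1067L)
  expect_equal(unname(co$category_counts[c("homozygote", "compound_heterozygote",
                                           "single_heterozygote")]),
               c(153L, 63L, 157L))
  expect_equal(sum(co$category_counts), co$n_subjects)  # partition
  expect_equal(unname(co$crosstab["Total", ]), c(8L, 24L, 43L, 141L))
  expect_equal(rowSums(co$crosstab[1:2, ]),
               c(homozygote = 153, compound_heterozygote = 63))
  h <- co$headline
  expect_equal(h$pct_at_least_one_pathogenic, 34.96)
  expect_equal(h$biallelic_n, 216L)
  expect_equal(h$biallelic_profound_pct, 65.28)
  expect_equal(h$top_homozygote, "[c.235delC]/[c.235delC]")
  expect_equal(h$top_homozygote_pct_of_homozygotes, 70.59)
  expect_equal(h$top_homozygote_pct_of_cohort, 10.12)
  expect_equal(h$top_compound_het, "[c.235delC]/[c.299_300delAT]")
  expect_equal(h$top_compound_het_pct_of_compound_hets, 30.16)
})

test_that("percentages are invariant under duplicating the cohort", {
  co1 <- summarize_cohort(gjb2_cohort()[1:200, ], chr_map)
  doubled <- rbind(gjb2_cohort()[1:200, ], gjb2_cohort()[1:200, ])
  co2 <- summarize_cohort(doubled, chr_map)
  expect_equal(co2$category_percent, co1$category_percent)
  expect_equal(co2$allele_frequencies$freq_percent,
               co1$allele_frequencies$freq_percent)
})

test_that("degenerate cohorts summarize cleanly", {
  one_wt <- data.frame(subject_id = "s1", genotype = "[wt]/[wt]",
                       severity = "severe")
  co <- summarize_cohort(one_wt, chr_map)
  expect_equal(unname(co$category_counts),
               c(0L, 0L, 0L, 0L, 1L))
  empty <- summarize_cohort(one_wt[0, ], chr_map)
  expect_equal(empty$n_subjects, 0L)
})

test_that("subject TSVs with per-frequency thresholds gain per-ear PTAs", {
  t3 <- gjb2_table3()
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(subject_id = t3$proband, genotype = t3$genotype,
                   t3[, grep("^(right|left)_", names(t3))])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  subj <- read_subject_tsv(path)
  expect_equal(subj$pta_right, t3$pta_right)
  expect_equal(subj$pta_left, t3$pta_left)
  expect_equal(as.character(subject_severity_grades <- grade_severity(
    pmin(subj$pta_right, subj$pta_left))), rep("profound", 4))
})
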