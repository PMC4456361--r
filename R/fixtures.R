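#' Bundled reference data from a 1067-subject GJB2 deafness cohort
#'
#' The package ships plain-text transcriptions of the printed variant and
#' genotype tables of a 1067-subject Han Chinese non-syndromic hearing-loss
#' cohort (with 203 regional controls), together with the GJB2 (connexin 26)
#' reference coding sequence. They serve as worked-example inputs and as the
#' ground truth for the package's test suite.
#'
#' * `gjb2_cds()` — the 681-nt GJB2 reference CDS. The shipped sequence was
#'   cross-validated against every sequence-dependent entry of the variant
#'   table (reference bases at all 25 variant sites, all substitution
#'   consequences, frameshift stop offsets) with an independent translator.
#' * `gjb2_table1()` — 25 coding variants with protein labels, conservation
#'   indices, case/control allele frequencies (% of 2134 resp. 406 alleles),
#'   PolyPhen-2/SIFT verdicts, literature evidence flags, and the published
#'   characterization column (kept verbatim for comparison; the rule engine
#'   recomputes its own).
#' * `gjb2_table2()` — the 26 biallelic genotypes (216 subjects) with
#'   per-severity subject counts.
#' * `gjb2_table3()` — the 4 probands carrying putative pathogenic variants.
#'   Only the per-ear PTAs were published; the per-frequency thresholds in
#'   this file are synthetic values constructed to average exactly to the
#'   printed PTAs.
#'
#' @return `gjb2_cds()` a [coding_sequence()]; the others data.frames.
#' @name gjb2_fixtures
NULL

fixture_path <- function(file) {
  system.file("extdata", file, package = "gjb2spectrum", mustWork = TRUE)
}

#' @rdname gjb2_fixtures
#' @export
gjb2_cds <- function() read_cds_fasta(fixture_path("GJB2_NM_004004.5_cds.fa"))

#' @rdname gjb2_fixtures
#' @export
gjb2_table1 <- function() {
  df <- utils::read.delim(fixture_path("table1_variants.tsv"),
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  df$evidence_flag[is.na(df$evidence_flag)] <- "none"
  df
}

#' @rdname gjb2_fixtures
#' @export
gjb2_table2 <- function() {
  utils::read.delim(fixture_path("table2_genotypes.tsv"), stringsAsFactors = FALSE)
}

#' @rdname gjb2_fixtures
#' @export
gjb2_table3 <- function() {
  utils::read.delim(fixture_path("table3_probands.tsv"), stringsAsFactors = FALSE)
}

#' Characterization map for the bundled variant table
#'
#' Runs the rule engine ([classify_table()]) over [gjb2_table1()] and returns
#' the variant -> characterization map used for carrier classification.
#'
#' @return named character vector (values `"Pathogenic"`,
#'   `"Putative pathogenic"`, `"Polymorphism"`).
#' @export
gjb2_characterization <- function() {
  cls <- classify_table(gjb2_table1())
  stats::setNames(cls$table$characterization, cls$table$variant)
}

#' Reconstructed 1067-subject cohort
#'
#' Builds the full study cohort as one row per subject: the 216 biallelic
#' subjects expanded deterministically from [gjb2_table2()], 157 single
#' heterozygotes, and 694 subjects without a pathogenic allele. The published
#' record gives only the single-heterozygote total and names the variants
#' involved, so their per-variant allocation here is synthetic (it includes
#' the reported [c.35delG]/[c.79G>A] carrier and the two single-heterozygous
#' probands of [gjb2_table3()]); likewise the split of the 694 non-carriers
#' between polymorphism-only genotypes and wild type, and all severity grades
#' outside the biallelic group (assigned so cohort-wide severity totals are
#' 34/145/403/485 mild/moderate/severe/profound). Statistics that depend only
#' on the published counts — carrier-category percentages, the biallelic
#' severity cross-tab, top genotype shares — are exact.
#'
#' @return subjects data.frame (`subject_id`, `genotype`, `severity`,
#'   `pta_right`, `pta_left`), 1067 rows.
#' @export
gjb2_cohort <- function() {
  biallelic <- expand_genotype_counts(gjb2_table2(), id_prefix = "B")

  single_hets <- c(
    "[c.235delC]/[wt]" = 32L,
    "[c.35delG]/[c.79G>A]" = 1L,
    "[c.176_191del16]/[wt]" = 2L,
    "[c.299_300delAT]/[wt]" = 6L,
    "[c.512_513insAACG]/[wt]" = 4L,
    "[c.109G>A]/[wt]" = 108L,
    "[c.107T>C]/[c.79G>A;c.341A>G]" = 1L,
    "[c.187G>T]/[c.79G>A;c.341A>G]" = 1L,
    "[c.283G>A]/[wt]" = 1L,
    "[c.427C>T]/[wt]" = 1L)
  stopifnot(sum(single_hets) == 157L)

  non_carriers <- c(
    "[c.79G>A;c.341A>G]/[wt]" = 300L,
    "[c.79G>A]/[wt]" = 150L,
    "[c.341A>G]/[wt]" = 100L,
    "[c.368C>A]/[wt]" = 5L,
    "[c.81C>T]/[wt]" = 1L,
    "[c.444C>T]/[wt]" = 1L,
    "[wt]/[wt]" = 137L)
  stopifnot(sum(non_carriers) == 694L)

  rest_geno <- rep(names(c(single_hets, non_carriers)), c(single_hets, non_carriers))
  # cohort-wide severity totals minus the biallelic group's 8/24/43/141
  rest_sev <- rep(c("mild", "moderate", "severe", "profound"),
                  c(34 - 8, 145 - 24, 403 - 43, 485 - 141))
  stopifnot(length(rest_sev) == length(rest_geno))
  bands <- c(mild = 33, moderate = 55, severe = 80, profound = 110)
  rest <- data.frame(
    subject_id = sprintf("R%04d", seq_along(rest_geno)),
    genotype = rest_geno, severity = rest_sev,
    pta_right = unname(bands[rest_sev]), pta_left = unname(bands[rest_sev]),
    stringsAsFactors = FALSE)
  out <- rbind(biallelic, rest)
  rownames(out) <- NULL
  out
}

#' Case-allele spectrum of the bundled variant table
#'
#' Per-variant case allele frequencies of [gjb2_table1()] as fractions,
#' suitable as the haplotype spectrum of a [cohort_spec()] (each variant as
#' its own haplotype).
#'
#' @return named numeric vector of frequencies in \[0, 1\].
#' @export
gjb2_case_spectrum <- function() {
  t1 <- gjb2_table1()
  stats::setNames(t1$case_freq / 100, t1$variant)
}
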