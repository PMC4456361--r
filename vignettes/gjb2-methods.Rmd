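---
title: "Methods: GJB2 mutation-spectrum analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GJB2 mutation-spectrum analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gjb2spectrum)
```

## The problem

Biallelic loss of GJB2, the gene encoding the gap-junction protein connexin
26 (Cx26), is the most common monogenic cause of non-syndromic sensorineural
hearing loss. A mutation-spectrum study of a deafness cohort proceeds in four
stages, each of which this package implements as a tested, reusable
operation:

1. **Consequence derivation** — each coding-DNA variant (HGVS `c.` notation)
   is applied to the reference coding sequence and translated to its
   protein-level consequence: missense, nonsense, silent, or frameshift with
   an `fsXn` stop offset.
2. **Conservation** — each missense position is scored by a conservation
   index (CI) on an aligned multi-species Cx26 amino-acid panel.
3. **Characterization** — a rule system combines consequence class, CI,
   control-cohort allele frequency, in-silico predictions (PolyPhen-2, SIFT)
   and literature evidence into Pathogenic / Putative pathogenic /
   Polymorphism.
4. **Cohort summarization** — subjects' bracket-notation genotypes are
   classified into carrier categories (homozygote, compound heterozygote,
   single heterozygote, polymorphisms-only, wild type), audiometric severity
   is graded from pure-tone averages, and the genotype–phenotype
   cross-tabulation and headline percentages are computed.

A synthetic-data module generates cohorts, control panels and conservation
panels with the statistical structure these stages assume, so the entire
pipeline is testable without any external download.

## Consequence engine

The reference CDS is validated on construction: length a positive multiple
of 3, initiator ATG, terminal stop, no internal in-frame stop. Coordinates
are 1-based and fully closed on the coding strand; `c.1` is the A of the
ATG. Genomic coordinates, introns and UTRs are out of scope.

Substitutions are resolved by comparing reference and mutant codons at
residue `ceiling(start / 3)`. Indels with net length change not divisible by
3 shift the reading frame; the mutant is translated from the codon
containing the edit and compared residue-by-residue against the reference
protein. Two conventions, chosen to match the clinical labelling dialect,
matter here:

* **Anchoring.** The reported residue is the *first residue whose amino acid
  actually differs* from the reference protein — often one or more codons
  downstream of the edit, because a deletion or insertion can reconstitute
  the reference amino acids for a stretch. Anchoring at the edit codon
  instead would mislabel c.35delG (G12VfsX2, anchored in codon 12 where the
  first difference appears) and c.235delC (L79CfsX3).
* **Stop offset.** `fsXn` counts the new stop codon with the first changed
  residue as 1: `L79CfsX3` means the stop is the third residue of the
  altered run. A frameshift that never meets a stop before the sequence ends
  is reported with offset `?` and a `no_stop` flag.

In-frame indels (net change divisible by 3) fall outside the `fsX` dialect
and are reported as `in_frame` with a prefix/suffix-trimmed deletion or
insertion label.

Two published frameshift labels are *not* derivable from the reference
sequence under any anchoring convention and are retained only as verbatim
data alongside the computed labels: the legacy `c.35insG` label `G12GfsX36`
anchors at an unchanged residue (the first-changed-residue rule gives
`V13CfsX35` — the same stop codon, anchored one residue later), and the
`c.512_513insAACG` label `A172EfsX39` disagrees with the sequence around
codon 172 (A171, W172; the derived consequence `W172TfsX39` shares the
anchor position 172 and stop offset 39 but not the ref/alt letters).

The engine is verified in two independent ways: against the complete
published protein-label column for all 25 cohort variants, and against a
brute-force oracle — string-level mutation plus whole-sequence
`Biostrings::translate`, compared from position 1 — on 1000 random toy CDSs
(3–60 codons) with random single-base substitutions, deletions and
insertions per run.

## Conservation index

CI at a human residue position is the percentage of panel species whose
residue at that alignment column is identical to the human residue, **with
the human row counted in both numerator and denominator**. This convention
is forced by the published values themselves: on a 23-species panel the
attainable values are exactly `100k/23`, and values such as 39.13 (= 9/23)
and 95.65 (= 22/23) only arise when human counts. Residue positions index
the ungapped human sequence (gaps in the human row are skipped); gaps and
`X` in non-human rows never match; comparison is case-insensitive. CI is
invariant under row permutation, and adding a human-identical row strictly
increases it — both held as property tests.

The species composition of the original 23-row panel is not reproduced in
the published record, so real-panel CI values are consumed as annotation
inputs; synthetic panels with prescribed per-position match counts stand in
for structural testing.

## Characterization rules

Rules fire in strict precedence; exactly one fires per variant and its
identifier is recorded:

| rule | condition | result |
|------|-----------|--------|
| R1 | frameshift or nonsense | Pathogenic |
| R2 | silent | Polymorphism |
| R3 | missense, control frequency > 5% **or** CI < 60% | Polymorphism |
| R4 | reported benign in other populations' controls | Polymorphism |
| R5 | established deafness mutation | Pathogenic |
| R6 | CI > 75% **and** control frequency = 0 **and** PolyPhen-2 Damaging **and** SIFT Damaging | Putative pathogenic |
| R7 | otherwise | Polymorphism |

Ordering decisions that the published table forces: **R4 precedes R6**
(p.I203T is doubly Damaging with CI 95.65 and absent from this study's
controls, yet is a polymorphism on external-control evidence), and **R5
precedes R6** (established mutations such as p.V37I — 4.93% in controls,
SIFT Tolerated — are labelled Pathogenic, not Putative pathogenic). All
thresholds are strict inequalities as printed (">5%", "<60%", ">75%"), so
boundary values do not trigger; "absent in controls" means control frequency
exactly 0 in the supplied control set. Pedigree co-segregation is
qualitative in the source and is not a rule input.

## Cohort statistics

Genotypes use bracket notation, `[cis;variants]/[allele2]`, with `wt` or `+`
for a wild-type allele; bold markup and missing `c.` prefixes, as they occur
in printed tables, are tolerated and labels are canonicalized before any
matching. Carrier categories are decided by the per-allele sets of
(putative) pathogenic variants — putative-pathogenic counts as pathogenic
throughout, which is required to place genotypes like
`[c.293G>C]/[c.109G>A]` inside the biallelic group. A shared pathogenic
variant on both alleles makes a homozygote *regardless of additional cis
polymorphisms*: only this rule places `[c.235delC;c.478G>A]/[c.235delC]` in
the homozygote block so that it sums to 153 subjects.

PTA is the mean of the 500/1000/2000/4000/8000 Hz thresholds. Severity
bands: normal (<26 dB), mild (26–40), moderate (41–70), severe (71–90),
profound (>90). The printed bands leave the open intervals (40, 41) and
(70, 71) uncovered for non-integer PTAs; such values are assigned to the
band of their half-up rounded integer. When both ears are given, severity
uses the better (lower) PTA — the audiological convention; the source is
silent on this, and all four of its fully-documented probands grade
identically either way.

Percentages are rounded **half-up** to 2 decimals, which reproduces the
published 14.34, 14.71, 34.96, 65.28, 70.59, 30.16 and 10.12 exactly. Two
published figures (5.91% for 63/1067 and 20.25% for 216/1067) are not
consistent with their own numerator/denominator under any standard rounding
and are not reproduced; likewise the profound share uses the denominator 216
(all biallelic subjects), not the inconsistent 164 printed in one place.

## Synthetic cohorts and panels

`simulate_cohort()` draws each subject's two alleles independently from a
haplotype spectrum — Hardy–Weinberg sampling; no inbreeding or mating
structure, since the source provides none. Recurrent cis combinations (e.g.
`c.79G>A;c.341A>G`) are modeled as explicit haplotypes rather than
independent per-variant draws, matching how they recur in real genotype
tables. Severity is drawn from the subject's carrier category's
distribution, and a PTA is sampled uniformly inside the grade's dB band
(profound: 91–130 dB) — only band membership is consumed downstream. The
default severity model uses the biallelic severity marginal
(8/24/43/141 of 216) for homozygotes and compound heterozygotes; for the
remaining categories, for which the source reports no breakdown, it uses the
cohort-wide marginal (34/145/403/485 of 1067) as this package's own explicit
choice. `simulate_controls()` samples 2n chromosomes with independent
per-variant carriage. `simulate_panel()` builds panels with exact
per-position match counts, so CI values are known by construction.

What the generator does *not* emulate: founder haplotype structure,
linkage between pathogenic variants and polymorphisms beyond the declared
cis haplotypes, age-of-onset distributions, audiogram shapes, and any
genotype–severity correlation beyond the per-category distributions.
Passing tests therefore validate the pipeline's arithmetic and rule logic,
not clinical genotype–phenotype inference on real data.

## Bundled reference data

The package ships transcriptions of the study's printed tables
(`gjb2_table1()`, `gjb2_table2()`, `gjb2_table3()`) and the GJB2 reference
CDS. The CDS was cross-validated against every sequence-dependent entry of
the variant table with an independent translator: all 25 reference bases,
all substitution consequences, and the frameshift anchors and offsets (with
the two verbatim-label exceptions discussed above). In the proband table
only the per-ear PTAs were published; the per-frequency thresholds in the
shipped file are synthetic values constructed to average exactly to the
printed PTAs.

`gjb2_cohort()` reconstructs the full 1067-subject cohort: the 216 biallelic
subjects expand deterministically from the genotype-count table; the 157
single heterozygotes and the 694 subjects without a pathogenic allele are
allocated synthetically (the published record gives only their totals),
which leaves every published count-derived statistic exact while per-variant
allele frequencies outside the biallelic group are illustrative only.

## Problem sizes and numerical choices

The test suite runs at desk scale: 1000 random CDS/variant pairs per oracle
comparison, simulated cohorts of 400–10 000 subjects for recovery checks
(frequency recovery asserted within 3 binomial standard errors; severity
marginals within 0.05), and 23-row panels for CI. Seeds are fixed in every
stochastic test. Rounding is half-up with a 1e-9 guard against binary
representation error. Reference-base mismatches between a variant and the
CDS are errors, never warnings.

## Worked example

```{r, eval = FALSE}
library(gjb2spectrum)
report <- run_full_analysis(gjb2_cds(), gjb2_table1(), gjb2_cohort())
summary(report)
```

## Known limitations

* No genomic-coordinate, multi-exon or `delins` support; the variant
  grammar covers the clinical dialect of single-gene coding reports.
* PolyPhen-2/SIFT verdicts and external evidence flags are inputs; the
  package performs no prediction or literature mining of its own.
* CI requires a pre-aligned panel; alignment construction is out of scope.
* The characterization rules encode one study's published criteria; they
  are not an ACMG/AMP implementation.
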