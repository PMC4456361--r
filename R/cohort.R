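#' Canonicalize a cDNA variant label
#'
#' Parse-and-reformat normalization so that dialect variants of the same
#' event (e.g. `c.35insG` vs `c.35_36insG`, or a bare `79G>A` inside a
#' genotype bracket) compare equal when genotypes are matched against a
#' characterization table.
#'
#' @param label c. label (a missing `c.` prefix before a digit is tolerated).
#' @return canonical label string.
#' @export
canonical_variant_label <- function(label) {
  label <- trimws(label)
  if (grepl("^[0-9]", label)) label <- paste0("c.", label)
  format_cdna_variant(parse_cdna_variant(label))
}

#' Parse a bracket-notation biallelic genotype label
#'
#' Clinical genotype strings write the two alleles separated by `/`, each a
#' bracketed group of cis variants separated by `;`, e.g.
#' `"[c.235delC;c.478G>A]/[c.235delC]"`. `[wt]`, `[+]`, `wt` or `+` denote a
#' wild-type allele. Whitespace and `**` bold markup are tolerated; variant
#' labels are canonicalized via [canonical_variant_label()].
#'
#' @param label genotype string.
#' @return An object of class `genotype`: list with `allele1`, `allele2`
#'   (character vectors of canonical variant labels, possibly empty) and
#'   `raw_label`.
#' @export
#' @examples
#' parse_genotype_label("[c.235delC]/[c.299_300delAT]")
parse_genotype_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label))
    stop_fmt("genotype label must be a single character string")
  raw <- label
  clean <- gsub("\\*\\*", "", label)
  clean <- gsub("[[:space:]]", "", clean)
  parts <- strsplit(clean, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop_fmt("genotype '%s': expected two allele groups separated by '/' (offset %d)",
             raw, regexpr("/", clean)[1L])
  parse_allele <- function(grp, which) {
    offset <- regexpr(grp, clean, fixed = TRUE)[1L]
    if (startsWith(grp, "[")) {
      if (!endsWith(grp, "]"))
        stop_fmt("genotype '%s': unbalanced bracket in allele %d (offset %d)",
                 raw, which, offset)
      grp <- substr(grp, 2L, nchar(grp) - 1L)
    } else if (grepl("[][]", grp)) {
      stop_fmt("genotype '%s': unbalanced bracket in allele %d (offset %d)",
               raw, which, offset)
    }
    if (grp %in% c("", "wt", "WT", "+", "N")) return(character(0))
    toks <- strsplit(grp, ";", fixed = TRUE)[[1L]]
    vars <- vapply(toks, function(tok) {
      tryCatch(canonical_variant_label(tok),
               error = function(e) stop_fmt(
                 "genotype '%s': unparseable variant '%s' in allele %d (offset %d): %s",
                 raw, tok, which, offset, conditionMessage(e)))
    }, "", USE.NAMES = FALSE)
    if (anyDuplicated(vars))
      stop_fmt("genotype '%s': duplicate variant on allele %d", raw, which)
    vars
  }
  structure(list(allele1 = parse_allele(parts[1L], 1L),
                 allele2 = parse_allele(parts[2L], 2L),
                 raw_label = raw),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype>", format_genotype(x), "\n")
  invisible(x)
}

#' Format a genotype back to canonical bracket notation
#'
#' Variants within an allele are ordered by position and the two alleles
#' lexicographically, so the label is invariant under allele order — useful
#' for grouping subjects by genotype.
#'
#' @param g a `genotype`.
#' @return character scalar like `"[c.235delC]/[c.299_300delAT]"`.
#' @export
format_genotype <- function(g) {
  fmt <- function(al) {
    if (!length(al)) return("[wt]")
    starts <- vapply(al, function(v) parse_cdna_variant(v)$start, 0L)
    paste0("[", paste(al[order(starts, al)], collapse = ";"), "]")
  }
  parts <- sort(c(fmt(g$allele1), fmt(g$allele2)))
  paste(parts, collapse = "/")
}

#' Pure-tone average of five audiometric thresholds
#'
#' PTA is the arithmetic mean of the air-conduction thresholds at 500, 1000,
#' 2000, 4000 and 8000 Hz (dB HL).
#'
#' @param thresholds numeric vector of exactly 5 dB values.
#' @return numeric PTA in dB.
#' @export
#' @examples
#' pta_average(c(100, 105, 110, 120, 135)) # 114
pta_average <- function(thresholds) {
  if (length(thresholds) != 5L)
    stop_fmt("pta_average: expected exactly 5 thresholds, got %d", length(thresholds))
  if (anyNA(thresholds) || !is.numeric(thresholds))
    stop_fmt("pta_average: thresholds must be numeric and non-missing")
  mean(thresholds)
}

SEVERITY_LEVELS <- c("normal", "mild", "moderate", "severe", "profound")

#' Grade hearing-loss severity from a pure-tone average
#'
#' Five clinical grades on the PTA in dB HL: normal (<26), mild (26-40),
#' moderate (41-70), severe (71-90), profound (>90). The printed bands leave
#' the open intervals (40, 41) and (70, 71) uncovered for non-integer PTAs;
#' a value there is assigned to the band containing its half-up rounded
#' integer (40.5 -> 41 -> moderate).
#'
#' @param pta numeric vector of PTA values in dB (>= 0).
#' @return factor with levels normal, mild, moderate, severe, profound.
#' @export
#' @examples
#' grade_severity(c(25, 33, 55, 90, 90.1, 114))
grade_severity <- function(pta) {
  if (anyNA(pta) || any(pta < 0))
    stop_fmt("grade_severity: PTA must be non-negative and non-missing")
  in_gap <- (pta > 40 & pta < 41) | (pta > 70 & pta < 71)
  x <- ifelse(in_gap, round_half_up(pta, 0), pta)
  grade <- ifelse(x < 26, "normal",
           ifelse(x <= 40, "mild",
           ifelse(x <= 70, "moderate",
           ifelse(x <= 90, "severe", "profound"))))
  factor(grade, levels = SEVERITY_LEVELS)
}

PATHOGENIC_CLASSES <- c("Pathogenic", "Putative pathogenic")

# canonical-keyed lookup of characterization classes
canonical_characterized <- function(characterized) {
  if (inherits(characterized, "gjb2_classification")) {
    tab <- characterized$table
    characterized <- stats::setNames(tab$characterization, tab$variant)
  }
  stats::setNames(unname(characterized),
                  vapply(names(characterized), canonical_variant_label, ""))
}

#' Carrier category of a subject's genotype
#'
#' Classifies a biallelic genotype against a variant characterization map.
#' Putative-pathogenic variants count as pathogenic. With `P_i` the set of
#' (putative) pathogenic variants on allele `i`: both non-empty sharing a
#' variant -> `homozygote` (additional cis polymorphisms are ignored); both
#' non-empty and disjoint -> `compound_heterozygote`; exactly one non-empty
#' -> `single_heterozygote`; none but some variant present ->
#' `polymorphisms_only`; no variant at all -> `wild_type`.
#'
#' @param g a `genotype` (or a genotype label string).
#' @param characterized named character vector mapping variant labels to
#'   `"Pathogenic"`, `"Putative pathogenic"` or `"Polymorphism"`, or a
#'   [classify_table()] result.
#' @return character scalar, one of the five carrier categories.
#' @export
#' @examples
#' chr <- c("c.235delC" = "Pathogenic", "c.478G>A" = "Polymorphism")
#' subject_category("[c.235delC;c.478G>A]/[c.235delC]", chr) # homozygote
subject_category <- function(g, characterized) {
  if (is.character(g)) g <- parse_genotype_label(g)
  stopifnot(inherits(g, "genotype"))
  map <- canonical_characterized(characterized)
  lookup <- function(vars) {
    cls <- map[vars]
    if (anyNA(cls))
      stop_fmt("genotype '%s': variant(s) %s not present in the characterization map",
               g$raw_label, paste(vars[is.na(cls)], collapse = ", "))
    vars[cls %in% PATHOGENIC_CLASSES]
  }
  p1 <- lookup(g$allele1)
  p2 <- lookup(g$allele2)
  n_var <- length(g$allele1) + length(g$allele2)
  if (length(p1) && length(p2)) {
    if (length(intersect(p1, p2))) "homozygote" else "compound_heterozygote"
  } else if (length(p1) || length(p2)) {
    "single_heterozygote"
  } else if (n_var > 0L) {
    "polymorphisms_only"
  } else {
    "wild_type"
  }
}

CARRIER_CATEGORIES <- c("homozygote", "compound_heterozygote",
                        "single_heterozygote", "polymorphisms_only", "wild_type")

# parse the genotype column once, with informative errors
parse_subject_genotypes <- function(subjects) {
  lapply(seq_len(nrow(subjects)), function(i)
    tryCatch(parse_genotype_label(subjects$genotype[i]),
             error = function(e) stop_fmt("subject '%s' (row %d): %s",
                                          subjects$subject_id[i] %||% i, i,
                                          conditionMessage(e))))
}

#' Per-variant allele frequencies in a cohort
#'
#' Every occurrence of a variant on either allele of any subject counts once;
#' frequencies are percentages of the 2N chromosomes.
#'
#' @param subjects data.frame with a `genotype` column of bracket-notation
#'   labels (see [parse_genotype_label()]).
#' @return data.frame with `variant` (canonical label), `count` and
#'   `freq_percent` (round-half-up, 2 decimals), sorted by decreasing count.
#' @export
allele_frequencies <- function(subjects) {
  stopifnot(is.data.frame(subjects), nrow(subjects) >= 1L)
  gts <- parse_subject_genotypes(subjects)
  all_vars <- unlist(lapply(gts, function(g) c(g$allele1, g$allele2)))
  n_alleles <- 2L * nrow(subjects)
  if (!length(all_vars))
    return(data.frame(variant = character(0), count = integer(0),
                      freq_percent = numeric(0), stringsAsFactors = FALSE))
  counts <- sort(table(all_vars), decreasing = TRUE)
  data.frame(variant = names(counts), count = as.integer(counts),
             freq_percent = round_half_up(100 * as.integer(counts) / n_alleles, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

# severity per subject: explicit column, else better-ear (lower) PTA
subject_severity <- function(subjects) {
  if ("severity" %in% names(subjects)) {
    sev <- as.character(subjects$severity)
    bad <- setdiff(unique(sev[!is.na(sev)]), SEVERITY_LEVELS)
    if (length(bad))
      stop_fmt("unknown severity grade(s): %s", paste(bad, collapse = ", "))
    return(factor(sev, levels = SEVERITY_LEVELS))
  }
  if (all(c("pta_right", "pta_left") %in% names(subjects))) {
    best <- pmin(subjects$pta_right, subjects$pta_left, na.rm = TRUE)
    return(grade_severity(best))
  }
  stop_fmt("subjects need either a 'severity' column or 'pta_right'/'pta_left' columns")
}

#' Summarize a cohort's genotypes and phenotypes
#'
#' Computes the cohort-level statistics of a mutation-spectrum study: carrier
#' category counts and percentages, per-variant allele frequencies, the
#' severity cross-tabulation of the biallelic (two pathogenic alleles)
#' subjects, and headline shares (subjects with at least one pathogenic
#' allele; profound share among biallelic subjects; most frequent homozygous
#' and compound-heterozygous genotypes). All percentages are round-half-up to
#' 2 decimals.
#'
#' @param subjects data.frame with columns `subject_id`, `genotype` and
#'   either `severity` or `pta_right`/`pta_left`.
#' @param characterized characterization map as in [subject_category()].
#' @return An object of class `cohort_summary`; see Details. Fields:
#'   `n_subjects`, `category_counts`, `category_percent`,
#'   `allele_frequencies`, `crosstab` (biallelic severity counts with a Total
#'   row), `headline` (named list of shares) and `subjects` (per-subject
#'   category and severity).
#' @export
summarize_cohort <- function(subjects, characterized) {
  stopifnot(is.data.frame(subjects))
  n <- nrow(subjects)
  if (n == 0L) {
    return(structure(list(
      n_subjects = 0L,
      category_counts = stats::setNames(integer(5), CARRIER_CATEGORIES),
      category_percent = stats::setNames(numeric(5), CARRIER_CATEGORIES),
      allele_frequencies = data.frame(variant = character(0), count = integer(0),
                                      freq_percent = numeric(0)),
      crosstab = matrix(0L, 0, 4, dimnames = list(NULL, SEVERITY_LEVELS[-1])),
      headline = list(), subjects = subjects), class = "cohort_summary"))
  }
  gts <- parse_subject_genotypes(subjects)
  category <- vapply(gts, subject_category, "", characterized = characterized)
  severity <- subject_severity(subjects)
  geno_canon <- vapply(gts, format_genotype, "")

  counts <- vapply(CARRIER_CATEGORIES, function(cl) sum(category == cl), 0L)
  pct <- round_half_up(100 * counts / n, 2)

  biallelic <- category %in% c("homozygote", "compound_heterozygote")
  bands <- SEVERITY_LEVELS[-1]  # hearing-impaired bands
  xt <- rbind(
    homozygote = vapply(bands, function(b)
      sum(biallelic & category == "homozygote" & severity == b), 0L),
    compound_heterozygote = vapply(bands, function(b)
      sum(biallelic & category == "compound_heterozygote" & severity == b), 0L))
  xt <- rbind(xt, Total = colSums(xt))

  top_of <- function(mask) {
    if (!any(mask)) return(list(genotype = NA_character_, count = 0L))
    tb <- sort(table(geno_canon[mask]), decreasing = TRUE)
    list(genotype = names(tb)[1L], count = as.integer(tb[1L]))
  }
  top_hom <- top_of(category == "homozygote")
  top_chet <- top_of(category == "compound_heterozygote")
  n_bi <- sum(biallelic)
  carriers <- sum(counts[c("homozygote", "compound_heterozygote",
                           "single_heterozygote")])
  headline <- list(
    pct_at_least_one_pathogenic = round_half_up(100 * carriers / n, 2),
    biallelic_n = n_bi,
    biallelic_profound_pct = if (n_bi)
      round_half_up(100 * sum(biallelic & severity == "profound") / n_bi, 2) else NA_real_,
    top_homozygote = top_hom$genotype,
    top_homozygote_pct_of_homozygotes = if (counts[["homozygote"]])
      round_half_up(100 * top_hom$count / counts[["homozygote"]], 2) else NA_real_,
    top_homozygote_pct_of_cohort = round_half_up(100 * top_hom$count / n, 2),
    top_compound_het = top_chet$genotype,
    top_compound_het_pct_of_compound_hets = if (counts[["compound_heterozygote"]])
      round_half_up(100 * top_chet$count / counts[["compound_heterozygote"]], 2) else NA_real_)

  per_subject <- data.frame(subject_id = subjects$subject_id %||% seq_len(n),
                            genotype = geno_canon, category = category,
                            severity = severity, stringsAsFactors = FALSE)
  structure(list(n_subjects = n, category_counts = counts,
                 category_percent = pct,
                 allele_frequencies = allele_frequencies(subjects),
                 crosstab = xt, headline = headline, subjects = per_subject),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d subjects\n", x$n_subjects))
  if (x$n_subjects == 0L) return(invisible(x))
  for (cl in names(x$category_counts))
    cat(sprintf("  %-22s %5d (%6.2f%%)\n", cl, x$category_counts[[cl]],
                x$category_percent[[cl]]))
  h <- x$headline
  cat(sprintf("  >=1 pathogenic allele: %.2f%%\n", h$pct_at_least_one_pathogenic))
  if (h$biallelic_n)
    cat(sprintf("  biallelic subjects: %d, profound share %.2f%%\n",
                h$biallelic_n, h$biallelic_profound_pct))
  invisible(x)
}

#' @export
#' @method summary cohort_summary
summary.cohort_summary <- function(object, ...) {
  print(object)
  cat("\nSeverity cross-tab (biallelic subjects):\n")
  print(object$crosstab)
  cat("\nTop allele frequencies:\n")
  print(utils::head(object$allele_frequencies, 10), row.names = FALSE)
  invisible(object)
}

#' Expand an aggregate genotype-count table into subject records
#'
#' Accepts a Table-2-style aggregate (one row per genotype with per-severity
#' subject counts) and expands it deterministically into one row per subject.
#' Each expanded subject is assigned a representative mid-band PTA in both
#' ears (mild 33, moderate 55, severe 80, profound 110 dB) so the severity
#' grade re-derives exactly.
#'
#' @param counts data.frame with columns `genotype`, `mild`, `moderate`,
#'   `severe`, `profound`.
#' @param id_prefix prefix for generated subject ids.
#' @return subjects data.frame (`subject_id`, `genotype`, `severity`,
#'   `pta_right`, `pta_left`).
#' @export
expand_genotype_counts <- function(counts, id_prefix = "S") {
  stopifnot(is.data.frame(counts), "genotype" %in% names(counts))
  bands <- c(mild = 33, moderate = 55, severe = 80, profound = 110)
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (b in names(bands)) {
      k <- if (b %in% names(counts)) counts[[b]][i] else 0L
      if (is.na(k) || k == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = rep(counts$genotype[i], k), severity = b,
        pta_right = bands[[b]], pta_left = bands[[b]],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genotype = character(0), severity = character(0),
               pta_right = numeric(0), pta_left = numeric(0))
  out <- cbind(subject_id = sprintf("%s%04d", id_prefix, seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Read a subject table from TSV
#'
#' Expects `subject_id` and `genotype` columns plus either a `severity`
#' column, `pta_right`/`pta_left` columns, or ten per-frequency threshold
#' columns `right_500 ... right_8000, left_500 ... left_8000` (dB HL), from
#' which per-ear PTAs are computed.
#'
#' @param path TSV file path.
#' @return subjects data.frame ready for [summarize_cohort()].
#' @export
read_subject_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!all(c("subject_id", "genotype") %in% names(df)))
    stop_fmt("subject TSV '%s' needs 'subject_id' and 'genotype' columns", path)
  freqs <- c(500, 1000, 2000, 4000, 8000)
  thr_cols <- c(paste0("right_", freqs), paste0("left_", freqs))
  if (all(thr_cols %in% names(df)) && !all(c("pta_right", "pta_left") %in% names(df))) {
    df$pta_right <- apply(df[, paste0("right_", freqs)], 1, pta_average)
    df$pta_left <- apply(df[, paste0("left_", freqs)], 1, pta_average)
  }
  df
}
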