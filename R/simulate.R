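AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Specify a synthetic case cohort
#'
#' The generator draws each subject's two alleles independently from a
#' haplotype spectrum (Hardy-Weinberg sampling; the residual probability mass
#' is the wild-type allele), classifies the resulting genotype against the
#' supplied pathogenic set, and assigns a severity grade from the carrier
#' category's distribution, with a PTA sampled uniformly inside the grade's
#' dB band (mild 26-40, moderate 41-70, severe 71-90, profound 91-130).
#' Recurrent cis combinations are modeled as explicit multi-variant
#' haplotypes (e.g. `"c.79G>A;c.341A>G"`), not independent per-variant draws.
#'
#' @param n_subjects cohort size (>= 1).
#' @param haplotypes named numeric vector of haplotype frequencies
#'   (fractions summing to <= 1); names are `;`-joined cis variant labels.
#' @param pathogenic character vector of variant labels counted as
#'   (putative) pathogenic for carrier classification.
#' @param severity_model named list mapping each carrier category to a
#'   probability vector over `c(mild, moderate, severe, profound)`
#'   (each summing to 1).
#' @param genotype_counts optional aggregate genotype-count table
#'   (see [expand_genotype_counts()]); when given it overrides sampling and
#'   the cohort is expanded deterministically.
#' @param seed integer seed stored in the spec; `simulate_cohort()` uses it
#'   unless overridden.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, haplotypes = numeric(0),
                        pathogenic = character(0),
                        severity_model = default_severity_model(),
                        genotype_counts = NULL, seed = NULL) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    stop_fmt("cohort_spec: n_subjects must be >= 1")
  if (length(haplotypes)) {
    if (is.null(names(haplotypes)) || any(!nzchar(names(haplotypes))))
      stop_fmt("cohort_spec: haplotypes must be a named frequency vector")
    if (any(haplotypes < 0) || sum(haplotypes) > 1 + 1e-12)
      stop_fmt("cohort_spec: haplotype frequencies must be non-negative and sum to <= 1 (got %.4f)",
               sum(haplotypes))
  }
  bands <- c("mild", "moderate", "severe", "profound")
  for (cl in names(severity_model)) {
    p <- severity_model[[cl]]
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop_fmt("cohort_spec: severity distribution for '%s' must be 4 non-negative values summing to 1", cl)
  }
  missing_cl <- setdiff(CARRIER_CATEGORIES, names(severity_model))
  if (length(missing_cl) && is.null(genotype_counts))
    stop_fmt("cohort_spec: severity_model lacks categories: %s",
             paste(missing_cl, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects), haplotypes = haplotypes,
                 pathogenic = pathogenic, severity_model = severity_model,
                 genotype_counts = genotype_counts, seed = seed,
                 bands = bands),
            class = "cohort_spec")
}

# dB band edges used for uniform within-band PTA sampling
SEVERITY_BANDS <- list(mild = c(26, 40), moderate = c(41, 70),
                       severe = c(71, 90), profound = c(91, 130))

#' Default per-category severity distributions
#'
#' Biallelic carriers (homozygote / compound heterozygote) follow the
#' severity marginal observed among biallelic subjects in the reference
#' cohort (8/24/43/141 of 216 over mild/moderate/severe/profound). The study
#' reports no severity breakdown for single heterozygotes or non-carriers,
#' so those categories default to the overall cohort marginal
#' (34/145/403/485 of 1067) — an explicit modeling choice of this package.
#'
#' @return named list of probability vectors over mild/moderate/severe/profound.
#' @export
default_severity_model <- function() {
  biallelic <- c(8, 24, 43, 141) / 216
  overall <- c(34, 145, 403, 485) / 1067
  list(homozygote = biallelic, compound_heterozygote = biallelic,
       single_heterozygote = overall, polymorphisms_only = overall,
       wild_type = overall)
}

#' Simulate a case cohort
#'
#' Draws subjects according to a [cohort_spec()]; fully reproducible for a
#' fixed seed. When the spec carries a fixed `genotype_counts` table the
#' expansion is deterministic and no sampling occurs.
#'
#' @param spec a `cohort_spec`.
#' @param seed optional integer overriding `spec$seed`.
#' @return subjects data.frame (`subject_id`, `genotype`, `severity`,
#'   `pta_right`, `pta_left`), ready for [summarize_cohort()].
#' @export
#' @examples
#' spec <- cohort_spec(100, haplotypes = c("c.235delC" = 0.14),
#'                     pathogenic = "c.235delC", seed = 1)
#' head(simulate_cohort(spec))
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$genotype_counts))
    return(expand_genotype_counts(spec$genotype_counts))
  seed <- seed %||% spec$seed
  with_seed(seed, {
    n <- spec$n_subjects
    haps <- c(spec$haplotypes, wt = max(0, 1 - sum(spec$haplotypes)))
    draw <- function() sample(names(haps), n, replace = TRUE, prob = haps)
    a1 <- draw(); a2 <- draw()
    fmt <- function(h) if (h == "wt") "[wt]" else paste0("[", h, "]")
    genotype <- paste0(vapply(a1, fmt, ""), "/", vapply(a2, fmt, ""))
    # characterization map: pathogenic set vs everything else
    all_vars <- unique(unlist(strsplit(setdiff(names(haps), "wt"), ";", fixed = TRUE)))
    map <- stats::setNames(
      ifelse(all_vars %in% spec$pathogenic, "Pathogenic", "Polymorphism"),
      all_vars)
    category <- vapply(genotype, subject_category, "", characterized = map,
                       USE.NAMES = FALSE)
    severity <- character(n)
    for (cl in unique(category)) {
      idx <- which(category == cl)
      severity[idx] <- sample(spec$bands, length(idx), replace = TRUE,
                              prob = spec$severity_model[[cl]])
    }
    pta <- function() {
      lo <- vapply(severity, function(s) SEVERITY_BANDS[[s]][1L], 0)
      hi <- vapply(severity, function(s) SEVERITY_BANDS[[s]][2L], 0)
      stats::runif(n, lo, hi)
    }
    data.frame(subject_id = sprintf("SIM%05d", seq_len(n)), genotype = genotype,
               severity = severity, pta_right = pta(), pta_left = pta(),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a control cohort's allele table
#'
#' Samples `2n` control chromosomes; each chromosome carries variant `v`
#' independently with probability `spectrum[v]`. Returns the realized
#' per-variant control allele frequencies.
#'
#' @param n number of control subjects (alleles sampled: 2n).
#' @param spectrum named numeric vector of per-variant allele frequencies
#'   (fractions in \[0, 1\]).
#' @param seed optional integer seed.
#' @return data.frame with `variant`, `count` and `freq_percent`
#'   (round-half-up, 2 decimals, of the 2n alleles).
#' @export
#' @examples
#' simulate_controls(203, c("c.79G>A" = 0.2291), seed = 1)
simulate_controls <- function(n, spectrum, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_fmt("simulate_controls: n must be >= 1")
  if (length(spectrum) && (is.null(names(spectrum)) || any(spectrum < 0) ||
                           any(spectrum > 1)))
    stop_fmt("simulate_controls: spectrum must be named frequencies in [0, 1]")
  with_seed(seed, {
    n_alleles <- 2L * as.integer(n)
    count <- vapply(spectrum, function(f) stats::rbinom(1L, n_alleles, f), 0L)
    data.frame(variant = names(spectrum), count = as.integer(count),
               freq_percent = round_half_up(100 * count / n_alleles, 2),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Specify a synthetic conservation panel
#'
#' @param n_species panel size including the human row (default 23).
#' @param length human sequence length (residues).
#' @param k integer scalar or length-`length` vector: number of rows (human
#'   included) that carry the human residue at each position; `1 <= k <=
#'   n_species`.
#' @param seed optional integer seed.
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(n_species = 23L, length = 30L, k = n_species, seed = NULL) {
  if (n_species < 2L) stop_fmt("panel_spec: n_species must be >= 2")
  if (length < 1L) stop_fmt("panel_spec: length must be >= 1")
  k <- as.integer(rep_len(k, length))
  if (any(k < 1L) || any(k > n_species))
    stop_fmt("panel_spec: k must lie in 1..n_species (human always matches itself)")
  structure(list(n_species = as.integer(n_species), length = as.integer(length),
                 k = k, seed = seed), class = "panel_spec")
}

#' Simulate an aligned conservation panel
#'
#' Generates an ungapped aligned panel in which position `j` has exactly
#' `k[j]` rows (the human row included) carrying the human residue; each
#' mismatching row receives a uniformly drawn different residue. By
#' construction [conservation_index()] at position `j` is
#' `100 * k[j] / n_species`.
#'
#' @param spec a [panel_spec()].
#' @param seed optional integer overriding `spec$seed`.
#' @return an [aligned_panel()] with the human row named `Homo_sapiens`.
#' @export
#' @examples
#' p <- simulate_panel(panel_spec(23, length = 5, k = 9, seed = 1))
#' conservation_index(p, 3)$ci_percent # 39.13
simulate_panel <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  seed <- seed %||% spec$seed
  with_seed(seed, {
    ns <- spec$n_species; L <- spec$length
    mat <- matrix("", nrow = ns, ncol = L)
    human <- sample(AA20, L, replace = TRUE)
    mat[1L, ] <- human
    for (j in seq_len(L)) {
      others <- 2:ns
      matchers <- if (spec$k[j] > 1L)
        sample(others, spec$k[j] - 1L) else integer(0)
      mat[matchers, j] <- human[j]
      mis <- setdiff(others, matchers)
      if (length(mis))
        mat[mis, j] <- sample(setdiff(AA20, human[j]), length(mis), replace = TRUE)
    }
    rows <- apply(mat, 1L, paste, collapse = "")
    names(rows) <- c("Homo_sapiens", sprintf("Species_%02d", seq_len(ns - 1L)))
    aligned_panel(rows)
  })
}
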