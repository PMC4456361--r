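#' Run the full mutation-spectrum analysis
#'
#' End-to-end orchestration: read the reference CDS, the optional aligned
#' conservation panel, the variant annotation table and the subject table;
#' derive protein consequences, conservation indices (when a panel is given),
#' rule-based characterizations and the cohort summary; optionally write a
#' reproducible report bundle. Re-running on identical inputs produces
#' byte-identical outputs (stable ordering, fixed round-half-up formatting).
#'
#' @param cds_fasta path to the reference CDS FASTA (single record), or a
#'   [coding_sequence()].
#' @param annotations path to an annotation TSV (see
#'   [read_annotation_tsv()]), or a data.frame. A `category` column is
#'   optional when a CDS is supplied: consequences are derived from it.
#' @param subjects path to a subject TSV (see [read_subject_tsv()]) or a
#'   subjects data.frame; `NULL` skips the cohort stage.
#' @param panel_fasta optional aligned panel FASTA (or [aligned_panel()]);
#'   when given, conservation indices of missense variants are recomputed
#'   from it and override the annotation column.
#' @param out_dir optional directory for the report bundle:
#'   `characterized.tsv`, `consequences.tsv`, `summary.json`,
#'   `crosstab.tsv`.
#' @return An object of class `gjb2_report`: list with `consequences`
#'   (data.frame), `classification` ([classify_table()] result),
#'   `cohort` ([summarize_cohort()] result or `NULL`) and `out_dir`.
#' @export
#' @examples
#' rep <- run_full_analysis(gjb2_cds(), gjb2_table1(), gjb2_cohort())
#' print(rep)
run_full_analysis <- function(cds_fasta, annotations, subjects = NULL,
                              panel_fasta = NULL, out_dir = NULL) {
  cds <- if (inherits(cds_fasta, "coding_sequence")) cds_fasta
         else read_cds_fasta(cds_fasta)
  ann <- if (is.data.frame(annotations)) annotations
         else read_annotation_tsv(annotations)
  if (!"variant" %in% names(ann))
    stop_fmt("annotation table needs a 'variant' column of c. labels")

  cons <- predict_consequences(cds, ann$variant)
  if (!"category" %in% names(ann))
    ann$category <- cons$category

  if (!is.null(panel_fasta)) {
    panel <- if (inherits(panel_fasta, "aligned_panel")) panel_fasta
             else read_panel_fasta(panel_fasta)
    prof <- ci_profile(panel, cons)
    idx <- match(ann$variant, prof$variant)
    ann$ci_percent <- ifelse(is.na(idx), ann$ci_percent, prof$ci_percent[idx])
  }

  cls <- classify_table(ann)

  cohort <- NULL
  if (!is.null(subjects)) {
    subj <- if (is.data.frame(subjects)) subjects else read_subject_tsv(subjects)
    cohort <- summarize_cohort(subj, cls)
    # annotation rows never observed in the cohort are tolerated, but noted
    known <- vapply(ann$variant, canonical_variant_label, "")
    orphan <- setdiff(known, cohort$allele_frequencies$variant)
    if (length(orphan))
      message(sprintf("annotation variant(s) not observed in the cohort: %s",
                      paste(orphan, collapse = ", ")))
  }

  report <- structure(list(cds = cds, consequences = cons, classification = cls,
                           cohort = cohort, out_dir = out_dir),
                      class = "gjb2_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation_tsv(report$consequences, file.path(out_dir, "consequences.tsv"))
  write_annotation_tsv(report$classification$table,
                       file.path(out_dir, "characterized.tsv"))
  if (!is.null(report$cohort)) {
    co <- report$cohort
    summary_list <- list(
      n_subjects = co$n_subjects,
      category_counts = as.list(co$category_counts),
      category_percent = as.list(co$category_percent),
      pathogenic_case_freq = report$classification$pathogenic_case_freq,
      headline = co$headline)
    jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    xt <- data.frame(category = rownames(co$crosstab), co$crosstab,
                     check.names = FALSE)
    write_annotation_tsv(xt, file.path(out_dir, "crosstab.tsv"))
  }
  invisible(out_dir)
}

#' @export
print.gjb2_report <- function(x, ...) {
  cat("<gjb2_report>\n")
  cat(sprintf("  reference CDS: %s (%d nt)\n", x$cds$id, nchar(x$cds$bases)))
  cat(sprintf("  %d variants annotated\n", nrow(x$consequences)))
  print(x$classification)
  if (!is.null(x$cohort)) print(x$cohort)
  invisible(x)
}

#' @export
#' @method summary gjb2_report
summary.gjb2_report <- function(object, ...) {
  print(object)
  if (!is.null(object$cohort)) {
    cat("\nSeverity cross-tab (biallelic subjects):\n")
    print(object$cohort$crosstab)
  }
  invisible(object)
}
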