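#' Characterize a single annotated variant
#'
#' Applies the rule system used to characterize coding GJB2 variants in a
#' case/control cohort. Rules fire in strict precedence; the first match
#' decides and its identifier is recorded for auditability:
#'
#' * **R1** frameshift or nonsense consequence -> `Pathogenic` (truncating).
#' * **R2** silent consequence -> `Polymorphism`.
#' * **R3** missense with control allele frequency > 5% OR conservation
#'   index < 60% -> `Polymorphism` (common or poorly conserved).
#' * **R4** reported as benign in other populations' controls ->
#'   `Polymorphism` (external-control evidence overrides in-silico damage).
#' * **R5** established deafness mutation -> `Pathogenic`.
#' * **R6** CI > 75% AND control frequency exactly 0 AND PolyPhen-2 Damaging
#'   AND SIFT Damaging -> `Putative pathogenic`.
#' * **R7** default -> `Polymorphism`.
#'
#' All thresholds are strict inequalities; boundary values (CI exactly 60 or
#' 75, control frequency exactly 5) do not trigger R3/R6.
#'
#' @param a a named list or one-row data.frame with `category` (consequence
#'   category), `ci_percent` (required for missense), `control_freq`
#'   (% of control alleles), `polyphen` (`"Damaging"`, `"Benign"` or `NA`),
#'   `sift` (`"Damaging"`, `"Tolerated"` or `NA`), `evidence_flag` (`"none"`,
#'   `"benign_in_other_controls"` or `"known_pathogenic"`).
#' @return list with `value` (one of `"Pathogenic"`, `"Putative pathogenic"`,
#'   `"Polymorphism"`) and `fired_rule` (`"R1"`..`"R7"`).
#' @export
#' @examples
#' classify_variant(list(category = "frameshift", ci_percent = NA,
#'   control_freq = 0, polyphen = NA, sift = NA, evidence_flag = "none"))
classify_variant <- function(a) {
  if (is.data.frame(a)) a <- as.list(a[1L, ])
  need <- function(field) {
    val <- a[[field]]
    if (is.null(val) || (length(val) == 1L && is.na(val)))
      stop_fmt("classify_variant: required field '%s' is missing for a %s variant",
               field, a$category %||% "?")
    val
  }
  category <- need("category")
  flag <- a$evidence_flag %||% "none"
  if (is.na(flag)) flag <- "none"
  ok_flags <- c("none", "benign_in_other_controls", "known_pathogenic")
  if (!flag %in% ok_flags)
    stop_fmt("classify_variant: unknown evidence_flag '%s'", flag)

  out <- function(value, rule) list(value = value, fired_rule = rule)

  if (category %in% c("frameshift", "nonsense")) return(out("Pathogenic", "R1"))
  if (category == "silent") return(out("Polymorphism", "R2"))
  if (category != "missense")
    return(out("Polymorphism", "R7"))
  ci <- need("ci_percent")
  ctrl <- need("control_freq")
  if (ctrl > 5 || ci < 60) return(out("Polymorphism", "R3"))
  if (flag == "benign_in_other_controls") return(out("Polymorphism", "R4"))
  if (flag == "known_pathogenic") return(out("Pathogenic", "R5"))
  polyphen <- need("polyphen")
  sift <- need("sift")
  if (ci > 75 && ctrl == 0 && polyphen == "Damaging" && sift == "Damaging")
    return(out("Putative pathogenic", "R6"))
  out("Polymorphism", "R7")
}

#' Characterize a variant annotation table
#'
#' Row-wise [classify_variant()] plus cohort-level summary: class counts and
#' the summed case-allele frequency of all variants characterized Pathogenic
#' or Putative pathogenic — the headline "allelic frequency of pathogenic
#' mutations" of a cohort.
#'
#' @param annotations data.frame with one row per variant; columns as in
#'   [classify_variant()] plus `variant` (c. label) and `case_freq`
#'   (% of case alleles).
#' @return An object of class `gjb2_classification`: list with `table` (the
#'   input plus `characterization` and `fired_rule` columns), `counts`
#'   (named class counts) and `pathogenic_case_freq` (summed case frequency
#'   of Pathogenic + Putative pathogenic rows, in %).
#' @export
classify_table <- function(annotations) {
  stopifnot(is.data.frame(annotations))
  if (nrow(annotations) == 0L) {
    tab <- cbind(annotations, characterization = character(0),
                 fired_rule = character(0))
    return(structure(list(table = tab,
                          counts = c(Pathogenic = 0L, `Putative pathogenic` = 0L,
                                     Polymorphism = 0L),
                          pathogenic_case_freq = 0),
                     class = "gjb2_classification"))
  }
  res <- lapply(seq_len(nrow(annotations)), function(i)
    classify_variant(as.list(annotations[i, ])))
  tab <- annotations
  tab$characterization <- vapply(res, `[[`, "", "value")
  tab$fired_rule <- vapply(res, `[[`, "", "fired_rule")
  classes <- c("Pathogenic", "Putative pathogenic", "Polymorphism")
  counts <- vapply(classes, function(cl) sum(tab$characterization == cl), 0L)
  patho <- tab$characterization %in% c("Pathogenic", "Putative pathogenic")
  freq_sum <- if ("case_freq" %in% names(tab))
    round_half_up(sum(tab$case_freq[patho]), 2) else NA_real_
  structure(list(table = tab, counts = counts, pathogenic_case_freq = freq_sum),
            class = "gjb2_classification")
}

#' @export
print.gjb2_classification <- function(x, ...) {
  cat("<gjb2_classification>\n")
  cat(sprintf("  %d variants: %s\n", nrow(x$table),
              paste(sprintf("%s %d", names(x$counts), x$counts), collapse = ", ")))
  if (!is.na(x$pathogenic_case_freq))
    cat(sprintf("  summed case allele frequency of (putative) pathogenic variants: %.2f%%\n",
                x$pathogenic_case_freq))
  invisible(x)
}

#' @export
#' @method summary gjb2_classification
summary.gjb2_classification <- function(object, ...) {
  print(object)
  tab <- object$table
  cols <- intersect(c("variant", "protein_label", "characterization", "fired_rule"),
                    names(tab))
  print(tab[, cols], row.names = FALSE)
  invisible(object)
}

#' Read / write a variant annotation TSV
#'
#' The annotation table mirrors a clinical variant-report layout: one row per
#' variant with its consequence category, conservation index, case and
#' control allele frequencies (percent), in-silico verdicts and evidence
#' flag. Missing values are encoded as `NA` (or empty fields).
#'
#' @param path TSV file path.
#' @return data.frame (for `read_annotation_tsv`).
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  needed <- c("variant", "category", "ci_percent", "case_freq", "control_freq",
              "polyphen", "sift", "evidence_flag")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_fmt("annotation TSV '%s' lacks column(s): %s", path,
             paste(missing, collapse = ", "))
  df$evidence_flag[is.na(df$evidence_flag)] <- "none"
  df
}

#' @rdname read_annotation_tsv
#' @param x data.frame to write.
#' @export
write_annotation_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
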