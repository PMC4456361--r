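#' Construct an aligned multi-species amino-acid panel
#'
#' The panel holds one aligned row per species ('-' marks gaps), with exactly
#' one row flagged as the human reference. Residue positions are indexed on
#' the ungapped human sequence, since conservation is reported at human
#' residue coordinates.
#'
#' @param rows named character vector of equal-length aligned amino-acid
#'   strings; names are species identifiers.
#' @param human index or name of the human row, or `NULL` to select the row
#'   whose name matches `human_pattern`.
#' @param human_pattern regular expression used when `human` is `NULL`
#'   (default `"Homo_sapiens"`, case-insensitive).
#' @return An object of class `aligned_panel`: list with `species`, `rows`,
#'   `human` (row index) and `n_species`.
#' @export
aligned_panel <- function(rows, human = NULL, human_pattern = "Homo_sapiens") {
  if (length(rows) < 2L) stop_fmt("panel needs at least 2 species, got %d", length(rows))
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop_fmt("all panel rows must be named with a species identifier")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop_fmt("aligned rows have unequal lengths (%s)",
             paste(unique(widths), collapse = ", "))
  if (is.null(human)) {
    hit <- grep(human_pattern, names(rows), ignore.case = TRUE)
    if (length(hit) != 1L)
      stop_fmt("expected exactly one row matching '%s', found %d",
               human_pattern, length(hit))
    human <- hit
  } else if (is.character(human)) {
    human <- match(human, names(rows))
    if (is.na(human)) stop_fmt("human row not found in panel")
  }
  structure(list(species = names(rows), rows = toupper(unname(rows)),
                 human = as.integer(human), n_species = length(rows)),
            class = "aligned_panel")
}

#' @export
print.aligned_panel <- function(x, ...) {
  cat(sprintf("<aligned_panel> %d species, alignment width %d, human = %s\n",
              x$n_species, nchar(x$rows[1L]), x$species[x$human]))
  invisible(x)
}

#' Read an aligned panel from a multi-FASTA file
#'
#' @param path aligned FASTA (equal-length rows, '-' gaps).
#' @inheritParams aligned_panel
#' @return An [aligned_panel()].
#' @export
read_panel_fasta <- function(path, human = NULL, human_pattern = "Homo_sapiens") {
  set <- Biostrings::readBStringSet(path)
  rows <- as.character(set)
  names(rows) <- names(set)
  aligned_panel(rows, human = human, human_pattern = human_pattern)
}

# map an ungapped human residue index to its alignment column
human_column <- function(panel, position) {
  hrow <- strsplit(panel$rows[panel$human], "")[[1L]]
  resi <- cumsum(hrow != "-")
  col <- which(resi == position & hrow != "-")
  if (length(col) != 1L)
    stop_fmt("human residue position %d is beyond the human sequence (length %d)",
             position, max(resi))
  col
}

#' Conservation index at a human residue position
#'
#' The conservation index (CI) is the percentage of panel species — the human
#' row included in both numerator and denominator — whose residue at the
#' alignment column of the given human position is identical to the human
#' residue. Comparison is case-insensitive; gaps and 'X'/ambiguous residues
#' in non-human rows never match. On a 23-species panel the attainable values
#' are exactly 100k/23 for k = 1..23 (39.13, 56.52, ..., 95.65, 100).
#'
#' @param panel an [aligned_panel()].
#' @param position 1-based residue index on the ungapped human sequence; must
#'   map to a non-gap human column.
#' @return list with `position`, `human_aa`, `matches` (count of identical
#'   rows, human included) and `ci_percent` (rounded to 2 decimals).
#' @export
#' @examples
#' p <- aligned_panel(c(Homo_sapiens = "MKV", chimp = "MKV", mouse = "MAV"))
#' conservation_index(p, 2)$ci_percent # 66.67
conservation_index <- function(panel, position) {
  stopifnot(inherits(panel, "aligned_panel"))
  if (!is.numeric(position) || length(position) != 1L || position < 1L)
    stop_fmt("position must be a single positive residue index")
  col <- human_column(panel, position)
  col_res <- toupper(substr(panel$rows, col, col))
  human_aa <- col_res[panel$human]
  matches <- sum(col_res == human_aa & col_res != "-" & col_res != "X")
  list(position = as.integer(position), human_aa = human_aa,
       matches = as.integer(matches),
       ci_percent = round_half_up(100 * matches / panel$n_species, 2))
}

#' Conservation-index profile for a set of missense consequences
#'
#' Computes one CI per missense variant at its residue position. Non-missense
#' consequences (silent, frameshift, nonsense, ...) have no single substituted
#' residue to score and are skipped with a message.
#'
#' @param panel an [aligned_panel()].
#' @param consequences a list of `protein_consequence` objects, or a
#'   data.frame from [predict_consequences()].
#' @return data.frame with `variant`, `label`, `position`, `human_aa`,
#'   `matches`, `ci_percent`, one row per missense variant.
#' @export
ci_profile <- function(panel, consequences) {
  if (is.data.frame(consequences)) {
    df <- consequences
  } else {
    df <- do.call(rbind, lapply(consequences, function(p)
      data.frame(variant = p$variant, category = p$category,
                 position = p$position, label_paper = p$label_paper,
                 stringsAsFactors = FALSE)))
  }
  empty <- data.frame(variant = character(0), label = character(0),
                      position = integer(0), human_aa = character(0),
                      matches = integer(0), ci_percent = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(df) || nrow(df) == 0L) return(empty)
  keep <- df$category == "missense"
  skipped <- df[!keep, , drop = FALSE]
  if (nrow(skipped))
    message(sprintf("ci_profile: skipping %d non-missense variant(s): %s",
                    nrow(skipped), paste(skipped$variant, collapse = ", ")))
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    ci <- conservation_index(panel, df$position[i])
    data.frame(variant = df$variant[i], label = df$label_paper[i],
               position = ci$position, human_aa = ci$human_aa,
               matches = ci$matches, ci_percent = ci$ci_percent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
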