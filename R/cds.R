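#' Construct a validated coding sequence
#'
#' A coding sequence (CDS) runs from the A of the initiator ATG (position c.1)
#' to the final base of the stop codon, on the coding strand, 1-based and
#' fully closed. Validation enforces the biological invariants a CDS used for
#' consequence prediction must satisfy.
#'
#' @param bases character scalar over {A,C,G,T} (case-insensitive; U is
#'   normalized to T).
#' @param id accession or name for the sequence.
#' @return An object of class `coding_sequence`: a list with `id` and `bases`.
#' @export
#' @examples
#' coding_sequence("ATGCAAGTGACTTAA", id = "toy")
coding_sequence <- function(bases, id = "cds") {
  if (!is.character(bases) || length(bases) != 1L)
    stop_fmt("bases must be a single character string")
  bases <- chartr("u", "t", toupper(bases))
  bases <- chartr("U", "T", bases)
  bad <- regmatches(bases, regexpr("[^ACGT]", bases))
  if (length(bad) && nzchar(bad))
    stop_fmt("coding sequence '%s' contains non-ACGT character '%s'", id, bad)
  n <- nchar(bases)
  if (n == 0L || n %% 3L != 0L)
    stop_fmt("coding sequence '%s' length (%d) is not a positive multiple of 3", id, n)
  if (substr(bases, 1L, 3L) != "ATG")
    stop_fmt("coding sequence '%s' does not begin with ATG", id)
  codons <- codon_split(bases)
  aas <- GENETIC_CODE_1[codons]
  if (aas[length(aas)] != "*")
    stop_fmt("coding sequence '%s' does not end with a stop codon", id)
  if (any(aas[-length(aas)] == "*"))
    stop_fmt("coding sequence '%s' contains an internal in-frame stop codon", id)
  structure(list(id = id, bases = bases), class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt (%d codons incl. stop)\n",
              x$id, nchar(x$bases), nchar(x$bases) / 3L))
  invisible(x)
}

#' Read a coding sequence from a FASTA file
#'
#' Reads a single-record FASTA, uppercases it and normalizes U to T.
#'
#' @param path path to a FASTA file with exactly one record.
#' @param id optional id override; defaults to the FASTA header.
#' @return A [coding_sequence()].
#' @export
read_cds_fasta <- function(path, id = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L)
    stop_fmt("expected exactly 1 FASTA record in '%s', found %d", path, length(set))
  coding_sequence(as.character(set[[1L]]), id = id %||% names(set)[1L])
}

# standard genetic code, codon -> one-letter amino acid ('*' = stop)
GENETIC_CODE_1 <- Biostrings::GENETIC_CODE

codon_split <- function(bases) {
  n <- nchar(bases) %/% 3L
  if (n == 0L) return(character(0))
  substring(bases, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a base string codon-by-codon
#'
#' Translates from position 1 under the standard genetic code until the first
#' stop codon, or until fewer than 3 bases remain (a trailing partial codon is
#' dropped). This deliberately accepts sequences whose length is not a
#' multiple of 3, as produced by frameshifting indels.
#'
#' @param seq base string over {A,C,G,T}.
#' @return list with `protein` (one-letter residues before the stop) and
#'   `stop_reached` (logical).
#' @export
#' @examples
#' translate_cds("ATGAAGTGA") # MK, stop reached
translate_cds <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L)
    stop_fmt("seq must be a single character string")
  seq <- toupper(seq)
  bad <- regmatches(seq, regexpr("[^ACGT]", seq))
  if (length(bad) && nzchar(bad))
    stop_fmt("sequence contains non-ACGT character '%s'", bad)
  codons <- codon_split(seq)
  if (length(codons) == 0L)
    return(list(protein = "", stop_reached = FALSE))
  aas <- unname(GENETIC_CODE_1[codons])
  stop_at <- which(aas == "*")
  if (length(stop_at)) {
    list(protein = paste(aas[seq_len(stop_at[1L] - 1L)], collapse = ""),
         stop_reached = TRUE)
  } else {
    list(protein = paste(aas, collapse = ""), stop_reached = FALSE)
  }
}

#' Parse an HGVS-style cDNA variant label
#'
#' Accepts the coding-sequence dialect used in clinical GJB2 reports:
#' substitutions (`c.79G>A`), deletions with stated bases (`c.235delC`,
#' `c.299_300delAT`) or a stated count (`c.176_191del16`), insertions between
#' two adjacent positions (`c.512_513insAACG`), and the legacy single-position
#' insertion (`c.35insG`, normalized to an insertion between c.35 and c.36).
#'
#' @param label character scalar beginning with `"c."`.
#' @return An object of class `cdna_variant`: list with `kind` (one of
#'   `"substitution"`, `"deletion"`, `"insertion"`), `start`, `end` (1-based,
#'   closed; for insertions the flanking positions), `ref_seq` (stated
#'   reference base(s), possibly `""`), `alt_seq` (replacement / inserted
#'   bases, `""` for deletions) and `raw_label`.
#' @export
#' @examples
#' parse_cdna_variant("c.79G>A")
#' parse_cdna_variant("c.176_191del16")
parse_cdna_variant <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label))
    stop_fmt("variant label must be a single character string")
  raw <- trimws(label)
  if (!startsWith(raw, "c."))
    stop_fmt("variant label '%s' does not begin with 'c.'", raw)
  body <- substr(raw, 3L, nchar(raw))

  mk <- function(kind, start, end, ref_seq, alt_seq) {
    if (start < 1L)
      stop_fmt("variant '%s': position %d is below the coding region (c.1)", raw, start)
    if (end < start)
      stop_fmt("variant '%s': end position %d precedes start %d", raw, end, start)
    structure(list(kind = kind, start = as.integer(start), end = as.integer(end),
                   ref_seq = ref_seq, alt_seq = alt_seq, raw_label = raw),
              class = "cdna_variant")
  }
  chk_bases <- function(tok) {
    if (grepl("[^ACGTacgt]", tok))
      stop_fmt("variant '%s': non-ACGT characters in token '%s'", raw, tok)
    toupper(tok)
  }

  m <- regmatches(body, regexec("^([0-9]+)([A-Za-z])>([A-Za-z])$", body))[[1L]]
  if (length(m)) {
    pos <- as.integer(m[2L])
    if (pos == 0L) stop_fmt("variant '%s': position 0 is invalid (c. positions are 1-based)", raw)
    return(mk("substitution", pos, pos, chk_bases(m[3L]), chk_bases(m[4L])))
  }

  m <- regmatches(body, regexec("^([0-9]+)(?:_([0-9]+))?del([A-Za-z0-9]*)$", body))[[1L]]
  if (length(m)) {
    start <- as.integer(m[2L])
    end <- if (nzchar(m[3L])) as.integer(m[3L]) else start
    if (start == 0L || end == 0L)
      stop_fmt("variant '%s': position 0 is invalid (c. positions are 1-based)", raw)
    span <- end - start + 1L
    tok <- m[4L]
    ref_seq <- ""
    if (nzchar(tok)) {
      if (grepl("^[0-9]+$", tok)) {
        if (as.integer(tok) != span)
          stop_fmt("variant '%s': stated deletion length %s does not match span %d_%d (%d bases)",
                   raw, tok, start, end, span)
      } else {
        ref_seq <- chk_bases(tok)
        if (nchar(ref_seq) != span)
          stop_fmt("variant '%s': stated deleted bases '%s' (%d) do not match span %d_%d (%d bases)",
                   raw, ref_seq, nchar(ref_seq), start, end, span)
      }
    }
    return(mk("deletion", start, end, ref_seq, ""))
  }

  m <- regmatches(body, regexec("^([0-9]+)(?:_([0-9]+))?ins([A-Za-z0-9]+)$", body))[[1L]]
  if (length(m)) {
    start <- as.integer(m[2L])
    if (start == 0L) stop_fmt("variant '%s': position 0 is invalid (c. positions are 1-based)", raw)
    if (nzchar(m[3L])) {
      end <- as.integer(m[3L])
      if (end != start + 1L)
        stop_fmt("variant '%s': insertion flanks %d_%d are not adjacent", raw, start, end)
    } else {
      # legacy single-position dialect: inserted between P and P+1
      end <- start + 1L
    }
    return(mk("insertion", start, end, "", chk_bases(m[4L])))
  }

  stop_fmt("cannot parse variant label '%s': unrecognized token '%s'", raw, body)
}

#' Format a structured cDNA variant back to a canonical label
#'
#' Inverse of [parse_cdna_variant()] on the structured fields: re-parsing the
#' formatted label recovers `kind`, `start`, `end`, `ref_seq` and `alt_seq`.
#'
#' @param v a `cdna_variant`.
#' @return character scalar, e.g. `"c.299_300delAT"`.
#' @export
format_cdna_variant <- function(v) {
  stopifnot(inherits(v, "cdna_variant"))
  switch(v$kind,
    substitution = sprintf("c.%d%s>%s", v$start, v$ref_seq, v$alt_seq),
    deletion = {
      span <- v$end - v$start + 1L
      pos <- if (span == 1L) sprintf("c.%d", v$start) else sprintf("c.%d_%d", v$start, v$end)
      suffix <- if (nzchar(v$ref_seq)) v$ref_seq else if (span > 1L) as.character(span) else ""
      paste0(pos, "del", suffix)
    },
    insertion = sprintf("c.%d_%dins%s", v$start, v$end, v$alt_seq)
  )
}

#' @export
print.cdna_variant <- function(x, ...) {
  cat(sprintf("<cdna_variant> %s (%s %d..%d)\n", x$raw_label, x$kind, x$start, x$end))
  invisible(x)
}

#' Apply a cDNA variant to a coding sequence
#'
#' Returns the mutated base string (its length need not be a multiple of 3).
#' A stated reference base that disagrees with the sequence is an error, never
#' a warning: a mismatch means the variant and the reference are from
#' different sequences.
#'
#' @param cds a [coding_sequence()].
#' @param v a `cdna_variant` (or a label, parsed on the fly).
#' @return character scalar, the mutated sequence.
#' @export
#' @examples
#' cds <- coding_sequence("ATGCAAGTGACTTAA")
#' apply_cdna_variant(cds, "c.4C>T")
apply_cdna_variant <- function(cds, v) {
  stopifnot(inherits(cds, "coding_sequence"))
  if (is.character(v)) v <- parse_cdna_variant(v)
  stopifnot(inherits(v, "cdna_variant"))
  n <- nchar(cds$bases)
  if (v$end > n)
    stop_fmt("variant '%s': position %d beyond CDS '%s' length %d",
             v$raw_label, v$end, cds$id, n)
  found <- substr(cds$bases, v$start, v$end)
  if (v$kind %in% c("substitution", "deletion") && nzchar(v$ref_seq) &&
      found != v$ref_seq)
    stop_fmt("variant '%s': reference mismatch at c.%d: expected '%s', found '%s'",
             v$raw_label, v$start, v$ref_seq, found)
  switch(v$kind,
    substitution = paste0(substr(cds$bases, 1L, v$start - 1L), v$alt_seq,
                          substr(cds$bases, v$start + 1L, n)),
    deletion = paste0(substr(cds$bases, 1L, v$start - 1L),
                      substr(cds$bases, v$end + 1L, n)),
    insertion = paste0(substr(cds$bases, 1L, v$start), v$alt_seq,
                       substr(cds$bases, v$start + 1L, n))
  )
}

#' Predict the protein-level consequence of a cDNA variant
#'
#' Substitutions are resolved by comparing the reference and mutant codons at
#' residue `ceiling(start/3)` (silent / missense / nonsense). Indels whose net
#' length change is not a multiple of 3 are frameshifts: the anchor is the
#' first residue whose translated amino acid actually differs from the
#' reference protein (scanning from the codon containing the edit — frequently
#' one or more codons downstream of the edit itself), and the fsX offset
#' counts the new stop codon with that first changed residue as 1 (`fsX3`
#' means the stop is the 3rd residue of the altered run). In-frame indels are
#' reported as `in_frame` with a descriptive label; they fall outside the
#' clinical fsX dialect.
#'
#' @param cds a [coding_sequence()].
#' @param v a `cdna_variant` or a c. label.
#' @return An object of class `protein_consequence`: list with `category`
#'   (`missense`, `nonsense`, `silent`, `frameshift`, `in_frame` or
#'   `no_change`), `position` (1-based residue index of the first affected
#'   codon), `ref_aa`, `alt_aa` (one-letter, `"X"` for stop), `stop_offset`
#'   (integer for frameshifts, `NA` with `no_stop = TRUE` when no new stop is
#'   reached before the sequence ends, `NA` otherwise), `no_stop`,
#'   `label_canonical` (e.g. `"p.L79CfsX3"`) and `label_paper` (the clinical
#'   table dialect: `"L79CfsX3"`, `"p.E47X"`, `"p.V27I"`, silent `"p.V27"`).
#' @export
#' @examples
#' cds <- coding_sequence("ATGCAAGTGACTTAA")
#' predict_consequence(cds, "c.4delC") # frameshift Q2KfsX2
predict_consequence <- function(cds, v) {
  stopifnot(inherits(cds, "coding_sequence"))
  if (is.character(v)) v <- parse_cdna_variant(v)
  mutant <- apply_cdna_variant(cds, v)  # validates positions and ref bases

  ref_tr <- translate_cds(cds$bases)
  # residues plus the terminal stop as an extra comparable position
  ref_ext <- c(strsplit(ref_tr$protein, "")[[1L]], "*")

  res <- function(category, position, ref_aa, alt_aa, stop_offset, no_stop,
                  label_canonical, label_paper) {
    structure(list(category = category, position = position, ref_aa = ref_aa,
                   alt_aa = alt_aa, stop_offset = stop_offset, no_stop = no_stop,
                   label_canonical = label_canonical, label_paper = label_paper,
                   variant = v$raw_label),
              class = "protein_consequence")
  }
  aa1 <- function(a) if (a == "*") "X" else a

  if (v$kind == "substitution") {
    idx <- ceiling(v$start / 3)
    ref_codon <- substr(cds$bases, 3L * idx - 2L, 3L * idx)
    alt_codon <- substr(mutant, 3L * idx - 2L, 3L * idx)
    ref_aa <- unname(GENETIC_CODE_1[ref_codon])
    alt_aa <- unname(GENETIC_CODE_1[alt_codon])
    if (ref_aa == alt_aa) {
      lab <- sprintf("p.%s%d", aa1(ref_aa), idx)
      return(res("silent", idx, aa1(ref_aa), aa1(alt_aa), NA_integer_, FALSE,
                 paste0(lab, "="), lab))
    }
    cat_ <- if (alt_aa == "*") "nonsense" else "missense"
    lab <- sprintf("p.%s%d%s", aa1(ref_aa), idx, aa1(alt_aa))
    return(res(cat_, idx, aa1(ref_aa), aa1(alt_aa), NA_integer_, FALSE, lab, lab))
  }

  # indel
  shift <- if (v$kind == "insertion") nchar(v$alt_seq) else -(v$end - v$start + 1L)
  mut_tr <- translate_cds(mutant)
  mut_ext <- c(strsplit(mut_tr$protein, "")[[1L]],
               if (mut_tr$stop_reached) "*")

  if (shift %% 3L == 0L) {
    if (mut_tr$stop_reached && identical(mut_tr$protein, ref_tr$protein))
      return(res("no_change", NA_integer_, "", "", NA_integer_, FALSE,
                 "p.(=)", "p.(=)"))
    return(in_frame_consequence(v, ref_ext, mut_ext, res, aa1))
  }

  # frameshift: scan from the codon containing the edit for the first residue
  # that differs from the reference protein
  from <- ceiling(v$start / 3)
  i <- from
  repeat {
    ref_i <- if (i <= length(ref_ext)) ref_ext[i] else NA_character_
    mut_i <- if (i <= length(mut_ext)) mut_ext[i] else NA_character_
    if (is.na(mut_i)) {
      # mutant ran out with no stop and no difference: edit at the very end
      ref_aa <- aa1(ref_i %||% "")
      return(res("frameshift", i, ref_aa, "", NA_integer_, TRUE,
                 sprintf("p.%s%dfsX?", ref_aa, i), sprintf("%s%dfsX?", ref_aa, i)))
    }
    if (is.na(ref_i) || ref_i != mut_i) break
    i <- i + 1L
  }
  ref_aa <- aa1(if (i <= length(ref_ext)) ref_ext[i] else "")
  alt_aa <- aa1(mut_ext[i])
  if (mut_tr$stop_reached) {
    stop_pos <- length(mut_ext)  # index of '*' in mut_ext
    off <- stop_pos - i + 1L
    lab <- sprintf("%s%d%sfsX%d", ref_aa, i, alt_aa, off)
    if (alt_aa == "X") lab <- sprintf("%s%dXfsX1", ref_aa, i)
    res("frameshift", i, ref_aa, alt_aa, off, FALSE, paste0("p.", lab), lab)
  } else {
    lab <- sprintf("%s%d%sfsX?", ref_aa, i, alt_aa)
    res("frameshift", i, ref_aa, alt_aa, NA_integer_, TRUE, paste0("p.", lab), lab)
  }
}

# in-frame indel labelling via common prefix/suffix trimming
in_frame_consequence <- function(v, ref_ext, mut_ext, res, aa1) {
  ref_aa_v <- ref_ext[-length(ref_ext)]
  mut_has_stop <- length(mut_ext) && mut_ext[length(mut_ext)] == "*"
  mut_aa_v <- if (mut_has_stop) mut_ext[-length(mut_ext)] else mut_ext
  nr <- length(ref_aa_v); nm <- length(mut_aa_v)
  a <- 0L
  while (a < min(nr, nm) && ref_aa_v[a + 1L] == mut_aa_v[a + 1L]) a <- a + 1L
  b <- 0L
  while (b < min(nr, nm) - a && ref_aa_v[nr - b] == mut_aa_v[nm - b]) b <- b + 1L
  if (nm < nr) {        # net deletion of residues
    del <- (a + 1L):(nr - b)
    lab <- if (length(del) == 1L)
      sprintf("p.%s%ddel", aa1(ref_aa_v[del]), del)
    else
      sprintf("p.%s%d_%s%ddel", aa1(ref_aa_v[del[1L]]), del[1L],
              aa1(ref_aa_v[del[length(del)]]), del[length(del)])
    first <- del[1L]
    res("in_frame", first, aa1(ref_aa_v[first]), "", NA_integer_, FALSE, lab, lab)
  } else {              # net insertion of residues
    ins <- vapply((a + 1L):(nm - b), function(i) aa1(mut_aa_v[i]), "")
    left <- max(a, 1L)
    lab <- sprintf("p.%s%d_%s%dins%s", aa1(ref_aa_v[left]), left,
                   aa1(ref_aa_v[min(left + 1L, nr)]), min(left + 1L, nr),
                   paste(ins, collapse = ""))
    res("in_frame", a + 1L, aa1(ref_aa_v[min(a + 1L, nr)]),
        paste(ins, collapse = ""), NA_integer_, FALSE, lab, lab)
  }
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("<protein_consequence> %s -> %s (%s)\n",
              x$variant, x$label_paper, x$category))
  invisible(x)
}

#' Predict consequences for a table of variant labels
#'
#' Vectorized wrapper around [predict_consequence()].
#'
#' @param cds a [coding_sequence()].
#' @param labels character vector of c. labels.
#' @return data.frame with one row per label: `variant`, `category`,
#'   `position`, `ref_aa`, `alt_aa`, `stop_offset`, `label_canonical`,
#'   `label_paper`.
#' @export
predict_consequences <- function(cds, labels) {
  rows <- lapply(labels, function(lab) {
    p <- predict_consequence(cds, lab)
    data.frame(variant = lab, category = p$category, position = p$position,
               ref_aa = p$ref_aa, alt_aa = p$alt_aa,
               stop_offset = if (is.na(p$stop_offset)) NA_integer_ else p$stop_offset,
               label_canonical = p$label_canonical, label_paper = p$label_paper,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
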