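# Independent brute-force consequence oracle.
#
# Deliberately shares no code with the package internals: mutation is done by
# plain string surgery here, translation goes through Biostrings::translate on
# the whole sequence, and the consequence is read off by comparing the two
# full protein strings from position 1. predict_consequence() instead works
# at codon level and scans from the edit codon, so agreement is a genuine
# cross-check.

oracle_translate <- function(seq) {
  n <- (nchar(seq) %/% 3L) * 3L
  if (n == 0L) return(list(protein = "", stop = FALSE))
  # no.init.codon: translate codon 1 with the plain code (otherwise CTG/TTG
  # would be read as initiator Met)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1L, n)),
                                           no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) list(protein = substr(aa, 1L, stop_at - 1L), stop = TRUE)
  else list(protein = aa, stop = FALSE)
}

oracle_mutate <- function(bases, kind, start, end, alt) {
  switch(kind,
    substitution = paste0(substr(bases, 1L, start - 1L), alt,
                          substr(bases, start + 1L, nchar(bases))),
    deletion = paste0(substr(bases, 1L, start - 1L),
                      substr(bases, end + 1L, nchar(bases))),
    insertion = paste0(substr(bases, 1L, start), alt,
                       substr(bases, start + 1L, nchar(bases))))
}

# returns list(position, alt_aa, stop_offset) for a frameshifting indel, or
# list(position, ref_aa, alt_aa) for a substitution, by exhaustive comparison
oracle_consequence <- function(bases, kind, start, end, alt) {
  mut <- oracle_mutate(bases, kind, start, end, alt)
  ref <- oracle_translate(bases)
  mtr <- oracle_translate(mut)
  refv <- c(strsplit(ref$protein, "")[[1L]], "*")
  mutv <- c(strsplit(mtr$protein, "")[[1L]], if (mtr$stop) "*")
  i <- 1L
  while (i <= min(length(refv), length(mutv)) && refv[i] == mutv[i]) i <- i + 1L
  alt_aa <- if (i <= length(mutv)) mutv[i] else NA_character_
  stop_offset <- if (mtr$stop) length(mutv) - i + 1L else NA_integer_
  list(position = i,
       ref_aa = if (i <= length(refv)) refv[i] else NA_character_,
       alt_aa = alt_aa, stop_offset = stop_offset)
}

# random toy CDS of n_codons (incl. stop), no internal in-frame stop
random_toy_cds <- function(n_codons = sample(3:60, 1)) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  stops <- names(code)[code == "*"]
  paste0("ATG",
         paste(sample(sense, n_codons - 2L, replace = TRUE), collapse = ""),
         sample(stops, 1L))
}

# random single-base indel or substitution inside the coding part
random_toy_variant <- function(cds_str) {
  n <- nchar(cds_str)
  kind <- sample(c("substitution", "deletion", "insertion"), 1L)
  pos <- sample(seq_len(n - 3L), 1L)  # keep the terminal stop codon intact
  ref <- substr(cds_str, pos, pos)
  if (kind == "substitution") {
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    list(label = sprintf("c.%d%s>%s", pos, ref, alt),
         kind = kind, start = pos, end = pos, alt = alt)
  } else if (kind == "deletion") {
    list(label = sprintf("c.%ddel%s", pos, ref),
         kind = kind, start = pos, end = pos, alt = "")
  } else {
    alt <- sample(c("A", "C", "G", "T"), 1L)
    list(label = sprintf("c.%d_%dins%s", pos, pos + 1L, alt),
         kind = kind, start = pos, end = pos + 1L, alt = alt)
  }
}
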