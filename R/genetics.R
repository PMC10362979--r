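# Small genetic-code helpers shared across modules.  Translation uses the
# standard code as tabulated by Biostrings.

translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L) stop("codon must be 3 nt, got '", codon, "'")
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("cannot translate codon '", codon, "'")
  aa
}

# Translate a codon that may contain IUPAC ambiguity codes.  Returns the
# single amino acid shared by all expansions, otherwise "X".
translate_codon_iupac <- function(codon) {
  codon <- toupper(codon)
  if (grepl("[^ACGTRYSWKMBDHVN]", codon)) return("X")
  sets <- lapply(strsplit(codon, "")[[1]], function(ch) .IUPAC[[ch]])
  combos <- expand.grid(sets[[1]], sets[[2]], sets[[3]],
                        stringsAsFactors = FALSE)
  aas <- unique(apply(combos, 1L, function(b)
    Biostrings::GENETIC_CODE[[paste(b, collapse = "")]]))
  if (length(aas) == 1L) aas else "X"
}

# Translate a spliced coding sequence (frame_offset 0); trailing partial
# codon dropped; ambiguous or N-containing codons become "X".
translate_coding <- function(seq) {
  seq <- toupper(seq)
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(seq, seq(1L, by = 3L, length.out = n_codon),
                      seq(3L, by = 3L, length.out = n_codon))
  paste(vapply(codons, translate_codon_iupac, ""), collapse = "")
}

.PURINES <- c("A", "G")

#' Classify a base substitution as transition or transversion
#'
#' @param ref,alt Single unambiguous bases.
#' @return `"transition"` (purine<->purine or pyrimidine<->pyrimidine) or
#'   `"transversion"`.
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(ref %in% c("A", "C", "G", "T"), alt %in% c("A", "C", "G", "T"))
  if (ref == alt) stop("ref and alt are identical")
  if ((ref %in% .PURINES) == (alt %in% .PURINES)) "transition"
  else "transversion"
}
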