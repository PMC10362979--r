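# IUPAC nucleotide ambiguity codes.  A Sanger "double peak" (heterozygous
# position in a diploid consensus) is encoded as the two-base code.

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Expand an IUPAC nucleotide code to its base set
#'
#' @param code A single IUPAC nucleotide character (case-insensitive).
#' @return Character vector of the bases the code denotes, in A < C < G < T
#'   order (e.g. `"W"` gives `c("A", "T")`).
#' @examples
#' expand_iupac("W")
#' expand_iupac("K")
#' @export
expand_iupac <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L)
    stop("`code` must be a single character")
  out <- .IUPAC[[toupper(code)]]
  if (is.null(out))
    stop("invalid IUPAC nucleotide code: '", code, "'")
  out
}

# Base set -> IUPAC code (inverse of expand_iupac).
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  key <- paste(bases, collapse = "")
  codes <- vapply(.IUPAC, paste, "", collapse = "")
  hit <- names(codes)[codes == key]
  if (length(hit) != 1L)
    stop("no IUPAC code for base set {", key, "}")
  hit
}

# Vectorised base-set expansion for a sequence string; returns list of sets.
expand_seq <- function(seq) {
  lapply(strsplit(toupper(seq), "")[[1]], function(ch) {
    if (ch %in% c("-", ".")) return(character(0))
    out <- .IUPAC[[ch]]
    if (is.null(out)) stop("invalid IUPAC character '", ch, "'")
    out
  })
}

# TRUE when two IUPAC codes share at least one base.
iupac_compatible <- function(a, b) {
  length(intersect(expand_iupac(a), expand_iupac(b))) > 0L
}
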