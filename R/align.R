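# Reference-anchored pairwise processing: global alignment of a specimen
# consensus to the genomic reference fragment, trimming of non-homologous
# flanks, and intron excision to obtain the spliced coding sequence.

#' Default alignment scoring scheme
#'
#' Match +1 (including any pair of IUPAC codes whose base sets intersect),
#' mismatch -1, gap opening -5 plus -1 per gapped base (a length-L gap
#' scores `-5 - L`).
#'
#' @return Named list of scoring parameters.
#' @export
default_scoring <- function() {
  list(match = 1, mismatch = -1, gap_open = -5, gap_extend = -1)
}

#' Global (Needleman-Wunsch) alignment with affine gaps
#'
#' Computes the optimal global alignment of a specimen against the
#' reference under an affine gap scheme.  IUPAC ambiguity codes score as a
#' match whenever their base sets intersect, so a heterozygous double-peak
#' position aligns cleanly to either underlying allele.  Tie-breaking in
#' the traceback is deterministic: diagonal, then gap-in-reference, then
#' gap-in-specimen.
#'
#' @param reference,specimen Nucleotide strings over the IUPAC alphabet.
#' @param scoring List as returned by [default_scoring()].
#' @return An `ace_alignment`: aligned `ref` and `spec` strings (gap `"-"`),
#'   `score`, and `ref_pos`, the reference-local coordinate of each column
#'   (`NA` for insertion columns).
#' @export
global_align <- function(reference, specimen, scoring = default_scoring()) {
  if (!nzchar(reference) || !nzchar(specimen)) stop("empty sequence")
  res <- nw_align_cpp(toupper(reference), toupper(specimen),
                      scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  ref_chars <- strsplit(res$ref, "")[[1]]
  ref_pos <- ifelse(ref_chars == "-", NA_integer_, cumsum(ref_chars != "-"))
  structure(list(ref = res$ref, spec = res$spec, score = res$score,
                 ref_pos = as.integer(ref_pos)),
            class = "ace_alignment")
}

#' @export
print.ace_alignment <- function(x, ...) {
  cat("Global alignment:", nchar(x$ref), "columns, score", x$score, "\n")
  invisible(x)
}

#' Trim non-homologous specimen flanks from an alignment
#'
#' Removes the alignment columns holding the first `lead` and last `tail`
#' specimen bases that fall outside the reference span (i.e. overhang
#' columns where the reference is gapped).  Columns within the reference
#' span are never removed.
#'
#' @param alignment An `ace_alignment`.
#' @param lead,tail Numbers of flanking specimen bases to remove (defaults
#'   148 and 74, the analysis' synchronisation convention).
#' @return A trimmed `ace_alignment`.
#' @export
trim_flanks <- function(alignment, lead = 148L, tail = 74L) {
  spec_chars <- strsplit(alignment$spec, "")[[1]]
  n_spec <- sum(spec_chars != "-")
  if (n_spec <= lead + tail)
    stop("over-trimming: specimen has ", n_spec,
         " bases but lead + tail = ", lead + tail)
  ncol_ <- length(spec_chars)
  covered <- !is.na(alignment$ref_pos)
  first_ref <- if (any(covered)) which(covered)[1] else ncol_ + 1L
  last_ref <- if (any(covered)) max(which(covered)) else 0L

  drop <- rep(FALSE, ncol_)
  # leading overhang: specimen-base columns before the reference span
  lead_cols <- which(seq_len(ncol_) < first_ref & spec_chars != "-")
  if (lead > 0L && length(lead_cols))
    drop[lead_cols[seq_len(min(lead, length(lead_cols)))]] <- TRUE
  tail_cols <- which(seq_len(ncol_) > last_ref & spec_chars != "-")
  if (tail > 0L && length(tail_cols))
    drop[rev(tail_cols)[seq_len(min(tail, length(tail_cols)))]] <- TRUE
  if (!any(drop)) return(alignment)

  keep <- !drop
  structure(list(
    ref = paste(strsplit(alignment$ref, "")[[1]][keep], collapse = ""),
    spec = paste(spec_chars[keep], collapse = ""),
    score = alignment$score,
    ref_pos = alignment$ref_pos[keep]
  ), class = "ace_alignment")
}

#' Excise the intron: project a specimen onto the spliced coding axis
#'
#' Concatenates the specimen bases aligned to exon columns of the
#' reference.  Specimen deletions within exons become `"N"` placeholders
#' (with a warning) so affected codons are no-called downstream; specimen
#' insertions inside an exon are rejected, since coding indels would break
#' the reading frame and none are expected in this gene fragment.
#'
#' @param alignment An `ace_alignment` (typically after [trim_flanks()]).
#' @param model An `ace_reference`.
#' @param id Specimen identifier carried through to reports.
#' @return An `ace_spliced`: `id`, `seq` (spliced coding string, IUPAC and
#'   `N` allowed) and `coverage` (range of spliced positions covered).
#' @export
splice <- function(alignment, model, id = "specimen") {
  ref_pos <- alignment$ref_pos
  spec_chars <- strsplit(alignment$spec, "")[[1]]
  ncol_ <- length(spec_chars)

  # fragment-local position of every spliced coding position
  n_coding <- coding_length(model)
  frag_of <- spliced_to_fragment(model, seq_len(n_coding))
  exon_col <- match(ref_pos, frag_of)        # spliced index per column, or NA

  # insertions: columns with no reference base flanked by consecutive
  # coding positions within one exon
  ins <- which(is.na(ref_pos) & spec_chars != "-")
  for (col in ins) {
    left <- ref_pos[seq_len(col - 1L)]
    right <- ref_pos[seq(col + 1L, length.out = ncol_ - col)]
    pl <- if (any(!is.na(left))) max(left, na.rm = TRUE) else NA_integer_
    pr <- if (any(!is.na(right))) min(right, na.rm = TRUE) else NA_integer_
    if (is.na(pl) || is.na(pr)) next                      # flank insertion
    sl <- match(pl, frag_of); sr <- match(pr, frag_of)
    if (!is.na(sl) && !is.na(sr) && sr == sl + 1L &&
        exon_of(model, sl) == exon_of(model, sr))
      stop("specimen insertion inside exon ", exon_of(model, sl),
           " (after spliced position ", sl, ")")
  }

  out <- rep(NA_character_, n_coding)
  hit <- which(!is.na(exon_col))
  out[exon_col[hit]] <- spec_chars[hit]
  covered <- which(!is.na(out))
  if (!length(covered)) stop("alignment covers no exon bases")
  n_del <- sum(out[covered] == "-")
  if (n_del > 0L)
    warning("specimen deletion spanning ", n_del,
            " coding base(s); emitted as N (no-call)")
  out[out == "-"] <- "N"
  span <- range(covered)
  out[is.na(out)] <- "N"
  seq <- paste(out[span[1]:span[2]], collapse = "")
  if (span[1] > 1L) seq <- paste0(strrep("N", span[1] - 1L), seq)
  if (span[2] < n_coding) seq <- paste0(seq, strrep("N", n_coding - span[2]))
  structure(list(id = id, seq = seq, coverage = span), class = "ace_spliced")
}

#' Pairwise percent identity among spliced sequences
#'
#' Identity is computed over positions determined (non-N) in both
#' sequences; IUPAC codes sharing a base count as identical.  Pairs with no
#' comparable positions are `NA`.
#'
#' @param spliced List of `ace_spliced` objects (or named character vector
#'   of equal-length sequences).
#' @return Symmetric numeric matrix of percent identities (diagonal 100).
#' @export
identity_matrix <- function(spliced) {
  seqs <- if (is.character(spliced)) spliced
          else setNames(vapply(spliced, `[[`, "", "seq"),
                        vapply(spliced, `[[`, "", "id"))
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must have equal length")
  mats <- lapply(seqs, expand_seq)
  n <- length(seqs)
  out <- matrix(NA_real_, n, n, dimnames = list(names(seqs), names(seqs)))
  diag(out) <- 100
  det <- lapply(mats, function(m) vapply(m, length, 0L) < 4L &
                  vapply(m, length, 0L) > 0L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- det[[i]] & det[[j]]
      if (!any(ok)) next
      same <- mapply(function(a, b) length(intersect(a, b)) > 0L,
                     mats[[i]][ok], mats[[j]][ok])
      out[i, j] <- out[j, i] <- 100 * sum(same) / sum(ok)
    }
  }
  out
}
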