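# End-to-end orchestration: FASTA in -> alignment -> trimming -> splicing
# -> genotypes -> SNP catalog -> allele assignments -> frequency report.

#' Run the full resistance-genotyping pipeline
#'
#' @param specimens A named `DNAStringSet` or path to a multi-record FASTA
#'   of specimen consensus sequences (IUPAC heterozygote codes allowed).
#' @param model An `ace_reference`.
#' @param scoring Alignment scoring, see [default_scoring()].
#' @param lead,tail Numbers of non-homologous nucleotides deleted from the
#'   start and end of every specimen before alignment (defaults 148 and
#'   74).  Pass 0 for sequences already synchronised with the reference.
#' @param catalog Allele catalog (defaults to the model's).
#' @return An `ace_results` list: `spliced` (list of `ace_spliced`),
#'   `genotypes`, `snps`, `alleles`, `frequencies`, `identity` (percent
#'   identity matrix, `NULL` for a single specimen).
#' @examples
#' model <- generate_reference(seed = 1)
#' cohort <- generate_cohort(model, load_fixture("iran20"))
#' res <- run_pipeline(cohort$sequences, model)
#' res$frequencies
#' @export
run_pipeline <- function(specimens, model, scoring = default_scoring(),
                         lead = 148L, tail = 74L, catalog = model$catalog) {
  if (is.character(specimens))
    specimens <- Biostrings::readDNAStringSet(specimens)
  if (length(specimens) == 0L) stop("no specimen sequences supplied")
  ids <- names(specimens)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("specimen sequences must be named")

  # The flanks are non-homologous to the reference: deleting them from the
  # raw sequences before alignment (the synchronisation convention) avoids
  # spurious terminal matches between random flank bases and the reference.
  spliced <- lapply(seq_along(specimens), function(k) {
    seq <- as.character(specimens[[k]])
    if (lead + tail > 0L) {
      if (nchar(seq) <= lead + tail)
        stop("specimen ", ids[k], " is shorter (", nchar(seq),
             " nt) than lead + tail = ", lead + tail)
      seq <- substr(seq, lead + 1L, nchar(seq) - tail)
    }
    aln <- global_align(model$sequence, seq, scoring = scoring)
    splice(aln, model, id = ids[k])
  })
  names(spliced) <- ids

  genotypes <- call_genotypes(spliced, model)
  snps <- catalog_snps(spliced, model)
  alleles <- assign_alleles(genotypes, model, catalog = catalog)
  freqs <- summarize_frequencies(alleles, genotypes, model)
  identity <- if (length(spliced) >= 2L) identity_matrix(spliced) else NULL

  structure(list(spliced = spliced, genotypes = genotypes, snps = snps,
                 alleles = alleles, frequencies = freqs,
                 identity = identity),
            class = "ace_results")
}

#' @export
print.ace_results <- function(x, ...) {
  cat("ACE resistance-genotyping results for", length(x$spliced),
      "specimen(s)\n")
  cat(nrow(x$snps), "SNP record(s);",
      length(unique(x$alleles$allele)), "distinct allele(s)\n\n")
  print(x$frequencies)
  invisible(x)
}
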