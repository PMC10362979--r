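# Allele nomenclature: named combinations of residues at positions
# 260/316/342/407, with sensitivity class.  The packaged default holds the
# six field combinations (alleles I-VI) and their laboratory-allele
# synonyms (V1-V15 naming).

.CATALOG_COLS <- c("res260", "res316", "res342", "res407",
                   "allele", "lab_alleles", "class")
.CLASSES <- c("sensitive", "insensitive", "putative_insensitive")

#' Load an allele catalog from TSV
#'
#' Columns: `res260`, `res316`, `res342`, `res407` (single amino-acid
#' letters), `allele` (name), `lab_alleles` (comma-separated synonyms or
#' `-`), `class` (one of `sensitive`, `insensitive`,
#' `putative_insensitive`).
#'
#' @param path TSV file path.
#' @return A `data.frame` of class `ace_catalog`.
#' @export
load_allele_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(.CATALOG_COLS, names(df))
  if (length(missing))
    stop("allele catalog is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, .CATALOG_COLS]
  bad <- setdiff(df$class, .CLASSES)
  if (length(bad))
    stop("unknown sensitivity class(es): ", paste(bad, collapse = ", "))
  combo <- apply(df[, 1:4], 1L, paste, collapse = "")
  if (anyDuplicated(combo))
    stop("duplicate residue combination(s) in catalog: ",
         paste(unique(combo[duplicated(combo)]), collapse = ", "))
  class(df) <- c("ace_catalog", "data.frame")
  df
}

#' The packaged default allele catalog
#'
#' Six combinations: allele I (V-A-V-Y, lab V14, insensitive), II
#' (L-A-G-Y, putative insensitive), III (L-A-A-Y, lab V15, insensitive),
#' IV (L-A-G-F, putative insensitive), V (V-A-A-Y, lab V10, insensitive)
#' and VI (V-A-G-F, lab V1-V9/V12/V13, the sensitive wild type).
#'
#' @return An `ace_catalog` data frame.
#' @export
default_allele_catalog <- function() {
  load_allele_catalog(system.file("extdata", "allele_catalog.tsv",
                                  package = "mdace", mustWork = TRUE))
}
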