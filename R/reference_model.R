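# Annotated ACE reference fragment: exon I + intron + exon II spanning the
# diagnostic resistance codons (residues 260, 316, 342, 407).  Everything
# downstream (alignment, splicing, genotyping, nomenclature) consults this
# model.
#
# Coordinate systems:
#   * fragment-local: 1-based position in the genomic fragment (with intron);
#   * spliced-local:  1-based position in the intron-free coding sequence;
#   * label:          "absolute" reporting coordinate = spliced-local +
#                     coordinate_offset (default 1040, so local 433 <-> 1473).
# Published per-site coordinates are frame-inconsistent with any single
# reading frame across the fragment, so each diagnostic site additionally
# carries its conventional reporting label (`variable_position_label`) as
# annotation metadata; arithmetic labels are used for all other positions.

#' Load an annotated ACE reference fragment
#'
#' Reads a YAML annotation document (sections: `fragment`, `exons`, `sites`,
#' optional `catalog`) together with a single-record reference FASTA, checks
#' every structural invariant, and returns the reference model used by all
#' downstream stages.
#'
#' @param annotation_path Path to the YAML annotation document.
#' @param fasta_path Path to a single-record FASTA with the unambiguous
#'   reference fragment (exon I + intron + exon II).
#' @return An object of class `ace_reference`: the fragment sequence, exon
#'   intervals, coordinate/frame offsets, diagnostic-site definitions and
#'   (when annotated) the allele catalog.
#' @seealso [generate_reference()], [default_annotation_path()]
#' @export
load_reference <- function(annotation_path, fasta_path) {
  ann <- yaml::read_yaml(annotation_path)
  for (field in c("fragment", "exons", "sites")) {
    if (is.null(ann[[field]]))
      stop("annotation is missing required section '", field, "'")
  }
  fa <- Biostrings::readDNAStringSet(fasta_path)
  if (length(fa) != 1L)
    stop("reference FASTA must contain exactly one record, found ", length(fa))
  seq <- toupper(as.character(fa[[1]]))

  exons <- do.call(rbind, lapply(ann$exons, function(e)
    data.frame(start = as.integer(e$start), end = as.integer(e$end))))
  sites <- lapply(ann$sites, function(s) {
    res_map <- unlist(s$resistant)
    list(label = s$label,
         residue = as.integer(s$residue),
         codon_local_start = as.integer(s$codon_local_start),
         variable_offset = as.integer(s$variable_offset),
         variable_position_label = as.integer(s$variable_position_label),
         wildtype_codon = toupper(s$wildtype_codon),
         wildtype_aa = toupper(s$wildtype_aa),
         resistant = setNames(toupper(unname(res_map)), toupper(names(res_map))))
  })
  names(sites) <- vapply(sites, `[[`, "", "label")

  catalog <- NULL
  if (!is.null(ann$catalog)) {
    cat_path <- ann$catalog
    if (!file.exists(cat_path))
      cat_path <- file.path(dirname(annotation_path), ann$catalog)
    catalog <- load_allele_catalog(cat_path)
  }

  model <- structure(list(
    sequence = seq,
    exons = exons,
    coordinate_offset = as.integer(ann$fragment$coordinate_offset),
    frame_offset = as.integer(ann$fragment$frame_offset %||% 0L),
    sites = sites,
    catalog = catalog
  ), class = "ace_reference")
  validate_reference(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an `ace_reference` model
#'
#' Checks every structural invariant: ordered disjoint exon intervals inside
#' the sequence, a single intervening intron, GT..AG intron ends (warning
#' only, as a dialect tolerance), diagnostic codons inside one exon, and full
#' consistency of each site's wild-type codon and resistant base map with the
#' standard genetic code.  Violations are errors naming the failed invariant.
#'
#' @param model An `ace_reference`.
#' @return The model, invisibly.
#' @export
validate_reference <- function(model) {
  seq <- model$sequence
  if (grepl("[^ACGT]", seq))
    stop("invariant 'reference unambiguous': sequence contains non-ACGT characters")
  ex <- model$exons
  if (nrow(ex) < 2L)
    stop("invariant 'two exons': need at least 2 exon intervals")
  if (any(ex$start > ex$end))
    stop("invariant 'valid intervals': exon start > end")
  if (is.unsorted(ex$start, strictly = TRUE) ||
      any(ex$start[-1] <= ex$end[-nrow(ex)]))
    stop("invariant 'exons ordered and disjoint' violated")
  if (ex$start[1] < 1L || ex$end[nrow(ex)] > nchar(seq))
    stop("invariant 'exons within sequence': interval outside the ",
         nchar(seq), "-nt sequence")

  intron <- substr(seq, ex$end[1] + 1L, ex$start[2] - 1L)
  if (nchar(intron) > 0L &&
      !(startsWith(intron, "GT") && endsWith(intron, "AG")))
    warning("intron does not follow the GT..AG rule (tolerated)")

  coding_len <- coding_length(model)
  for (s in model$sites) {
    if (translate_codon(s$wildtype_codon) != s$wildtype_aa)
      stop("invariant 'wildtype codon translates to wildtype aa' failed for ",
           "site '", s$label, "'")
    for (base in names(s$resistant)) {
      mut <- s$wildtype_codon
      substr(mut, s$variable_offset + 1L, s$variable_offset + 1L) <- base
      if (translate_codon(mut) != s$resistant[[base]])
        stop("invariant 'resistant base map consistent with genetic code' ",
             "failed for site '", s$label, "' (", base, " -> ",
             s$resistant[[base]], " but codon ", mut, " is ",
             translate_codon(mut), ")")
    }
    codon_end <- s$codon_local_start + 2L
    if (codon_end > coding_len)
      stop("invariant 'codon within coding sequence' failed for site '",
           s$label, "'")
    exon_idx <- exon_of(model, s$codon_local_start)
    if (exon_of(model, codon_end) != exon_idx)
      stop("invariant 'codon wholly inside one exon' failed for site '",
           s$label, "'")
    # the annotated wild-type codon must match the reference itself
    ref_codon <- substr(spliced_reference(model), s$codon_local_start, codon_end)
    if (ref_codon != s$wildtype_codon)
      stop("invariant 'reference carries wildtype codon' failed for site '",
           s$label, "': reference has ", ref_codon, ", annotation says ",
           s$wildtype_codon)
  }
  invisible(model)
}

# Total spliced (coding) length.
coding_length <- function(model) {
  sum(model$exons$end - model$exons$start + 1L)
}

# Intron-free coding sequence of the reference.
spliced_reference <- function(model) {
  paste(substring(model$sequence, model$exons$start, model$exons$end),
        collapse = "")
}

# 1-based exon index containing a spliced-local position.
exon_of <- function(model, spliced_pos) {
  lens <- model$exons$end - model$exons$start + 1L
  cum <- cumsum(lens)
  idx <- findInterval(spliced_pos - 1L, c(0L, cum), rightmost.closed = FALSE)
  if (any(spliced_pos < 1L | spliced_pos > cum[length(cum)]))
    stop("spliced position out of range")
  idx
}

# Map spliced-local -> fragment-local coordinates.
spliced_to_fragment <- function(model, spliced_pos) {
  lens <- model$exons$end - model$exons$start + 1L
  cum <- c(0L, cumsum(lens))
  idx <- exon_of(model, spliced_pos)
  model$exons$start[idx] + (spliced_pos - cum[idx] - 1L)
}

#' Convert spliced-local coordinates to reporting labels (and back)
#'
#' The reporting ("absolute") label of a spliced coding position is the
#' position plus the model's `coordinate_offset` (default 1040, anchoring the
#' fragment at label 1041), so local 433 maps to label 1473.
#'
#' @param model An `ace_reference`.
#' @param spliced_pos Integer vector of 1-based spliced coding positions.
#' @return Integer vector of labels.
#' @export
local_to_label <- function(model, spliced_pos) {
  n <- coding_length(model)
  if (any(spliced_pos < 1L | spliced_pos > n))
    stop("spliced position out of range [1, ", n, "]")
  as.integer(spliced_pos + model$coordinate_offset)
}

#' @rdname local_to_label
#' @param label Integer vector of reporting labels.
#' @export
label_to_local <- function(model, label) {
  pos <- as.integer(label - model$coordinate_offset)
  n <- coding_length(model)
  if (any(pos < 1L | pos > n))
    stop("label out of range [", 1L + model$coordinate_offset, ", ",
         n + model$coordinate_offset, "]")
  pos
}

#' Extract the codon of a diagnostic site from a spliced coding sequence
#'
#' @param model An `ace_reference`.
#' @param site A diagnostic-site entry of `model$sites` (or its label).
#' @param spliced_seq Spliced coding nucleotide string (IUPAC allowed).
#' @return The 3-character codon at the site.
#' @export
codon_at <- function(model, site, spliced_seq) {
  if (is.character(site)) site <- get_site(model, site)
  start <- site$codon_local_start
  if (nchar(spliced_seq) < start + 2L)
    stop("spliced sequence too short (", nchar(spliced_seq),
         " nt) for codon at ", start)
  substr(spliced_seq, start, start + 2L)
}

get_site <- function(model, label) {
  s <- model$sites[[label]]
  if (is.null(s)) stop("unknown diagnostic site '", label, "'")
  s
}

# Spliced-local coordinate of a site's variable (polymorphic) base.
site_variable_local <- function(site) {
  site$codon_local_start + site$variable_offset
}

# Reference base at a site's variable position.
site_ref_base <- function(site) {
  substr(site$wildtype_codon, site$variable_offset + 1L, site$variable_offset + 1L)
}

#' Serialize an `ace_reference` back to its annotation document
#'
#' Writing then reloading (with the same FASTA) reproduces an identical
#' model.
#'
#' @param model An `ace_reference`.
#' @param path Output YAML path.
#' @param catalog_path Optional path (written into the document) of the
#'   allele-catalog TSV.
#' @return `path`, invisibly.
#' @export
write_reference_annotation <- function(model, path, catalog_path = NULL) {
  doc <- list(
    schema = "mdace-annotation/1",
    fragment = list(coordinate_offset = model$coordinate_offset,
                    frame_offset = model$frame_offset),
    exons = lapply(seq_len(nrow(model$exons)), function(i)
      list(start = model$exons$start[i], end = model$exons$end[i])),
    sites = lapply(unname(model$sites), function(s)
      list(label = s$label, residue = s$residue,
           codon_local_start = s$codon_local_start,
           variable_offset = s$variable_offset,
           variable_position_label = s$variable_position_label,
           wildtype_codon = s$wildtype_codon,
           wildtype_aa = s$wildtype_aa,
           resistant = as.list(s$resistant)))
  )
  if (!is.null(catalog_path)) doc$catalog <- catalog_path
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Path to the packaged default annotation document
#'
#' The packaged annotation describes the synthetic reference produced by
#' [generate_reference()]: exon I of 534 nt, an 86-nt intron, exon II of
#' 205 nt, coordinate offset 1040, and the four diagnostic sites V260L,
#' A316S, G342A/V and F407Y with their conventional reporting labels.
#'
#' @return File path of the YAML annotation shipped with the package.
#' @export
default_annotation_path <- function() {
  system.file("extdata", "ace_annotation.yaml", package = "mdace",
              mustWork = TRUE)
}

#' @export
print.ace_reference <- function(x, ...) {
  lens <- x$exons$end - x$exons$start + 1L
  cat("ACE reference fragment:", nchar(x$sequence), "nt\n")
  cat("  exons:", paste(lens, collapse = " + "), "nt; intron:",
      nchar(x$sequence) - sum(lens), "nt\n")
  cat("  coordinate offset:", x$coordinate_offset,
      "(labels", 1L + x$coordinate_offset, "-",
      coding_length(x) + x$coordinate_offset, ")\n")
  cat("  diagnostic sites:", paste(names(x$sites), collapse = ", "), "\n")
  invisible(x)
}
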