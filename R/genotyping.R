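# Genotype calling at the diagnostic resistance codons and cohort-wide SNP
# cataloguing.  Heterozygotes are read from IUPAC ambiguity codes, the
# in-silico equivalent of the Sanger double-peak signal.

.GENOTYPES <- c("SS", "RS", "RR", "RR_mixed", "no_call")

#' Call the RR/RS/SS genotype at one diagnostic site
#'
#' Expands the IUPAC code at the site's variable position and classifies:
#' reference base only = SS; reference plus one resistant base = RS; a
#' single resistant base = RR; two resistant bases = RR_mixed.  Any N in
#' the codon, ambiguity away from the variable position, or a base not in
#' the site's resistant map yields `no_call`.
#'
#' @param spliced An `ace_spliced` (or plain spliced coding string).
#' @param site A diagnostic-site entry of the model (or its label, with
#'   `model` supplied).
#' @param model The `ace_reference` (required when `site` is a label).
#' @return One-row `data.frame`: specimen, site, genotype, observed bases
#'   (`/`-separated), observed amino acids.
#' @export
call_genotype <- function(spliced, site, model = NULL) {
  if (is.character(site)) site <- get_site(model, site)
  seq <- if (inherits(spliced, "ace_spliced")) spliced$seq else spliced
  id <- if (inherits(spliced, "ace_spliced")) spliced$id else "specimen"
  start <- site$codon_local_start

  res <- function(genotype, bases, aas) data.frame(
    specimen = id, site = site$label, genotype = genotype,
    bases = paste(bases, collapse = "/"), aa = paste(aas, collapse = "/"),
    stringsAsFactors = FALSE)

  if (nchar(seq) < start + 2L) return(res("no_call", character(0), character(0)))
  codon <- substr(seq, start, start + 2L)
  chars <- strsplit(codon, "")[[1]]
  if (any(chars == "N")) return(res("no_call", character(0), character(0)))

  vi <- site$variable_offset + 1L
  other <- chars[-vi]
  if (any(vapply(other, function(ch) length(expand_iupac(ch)) > 1L, TRUE))) {
    warning("specimen ", id, ", site ", site$label,
            ": ambiguity outside the variable position; no-call")
    return(res("no_call", character(0), character(0)))
  }
  wt_other <- strsplit(site$wildtype_codon, "")[[1]][-vi]
  if (!all(other == wt_other)) {
    warning("specimen ", id, ", site ", site$label,
            ": unexpected substitution at a non-variable codon position; no-call")
    return(res("no_call", character(0), character(0)))
  }

  bases <- expand_iupac(chars[vi])
  ref <- site_ref_base(site)
  resistant <- names(site$resistant)
  aa_of <- function(b) if (b == ref) site$wildtype_aa else site$resistant[[b]]

  unknown <- setdiff(bases, c(ref, resistant))
  if (length(unknown)) {
    warning("specimen ", id, ", site ", site$label, ": base(s) ",
            paste(unknown, collapse = ","),
            " outside the annotated allele set; no-call")
    return(res("no_call", bases, character(0)))
  }
  aas <- vapply(bases, aa_of, "")
  genotype <-
    if (identical(bases, ref)) "SS"
    else if (length(bases) == 2L && ref %in% bases) "RS"
    else if (length(bases) == 1L) "RR"
    else if (length(bases) == 2L) "RR_mixed"
    else "no_call"
  res(genotype, bases, unique(aas))
}

#' Call genotypes for a cohort at every diagnostic site
#'
#' @param spliced List of `ace_spliced` objects.
#' @param model An `ace_reference`.
#' @return Long `data.frame` of [call_genotype()] rows (specimen x site).
#' @export
call_genotypes <- function(spliced, model) {
  rows <- lapply(spliced, function(sp)
    do.call(rbind, lapply(model$sites, function(site)
      call_genotype(sp, site))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Catalog all SNPs in a cohort of spliced sequences
#'
#' Every spliced position where any specimen's base set differs from the
#' reference base yields one record with: position, reporting label (the
#' annotated site label for diagnostic positions, arithmetic label
#' otherwise), reference and alternate bases, exon of origin,
#' transition/transversion class (a multi-allelic site counts once when all
#' alternates share a class, otherwise one record per alternate), coding
#' effect under the standard genetic code, carrier count and zygosity
#' summary.
#'
#' @param spliced List of `ace_spliced` objects.
#' @param model An `ace_reference`.
#' @return `data.frame`, one row per SNP (ordered by position), columns
#'   `pos`, `label`, `ref`, `alt` (comma-separated), `exon`, `class`,
#'   `effect`, `carriers`, `het`, `hom`.
#' @export
catalog_snps <- function(spliced, model) {
  if (!length(spliced)) stop("need at least one specimen")
  ref <- strsplit(spliced_reference(model), "")[[1]]
  n <- length(ref)
  sets <- lapply(spliced, function(sp) expand_seq(sp$seq))

  site_vpos <- vapply(model$sites, site_variable_local, 0L)
  site_label <- vapply(model$sites, function(s) s$variable_position_label, 0L)

  recs <- list()
  for (p in seq_len(n)) {
    per_spec <- lapply(sets, `[[`, p)
    informative <- vapply(per_spec, function(b)
      length(b) > 0L && length(b) < 4L, TRUE)
    alt_bases <- sort(setdiff(unique(unlist(per_spec[informative])), ref[p]))
    if (!length(alt_bases)) next

    carrier <- vapply(per_spec, function(b)
      length(b) < 4L && length(intersect(b, alt_bases)) > 0L, TRUE)
    het <- vapply(per_spec, function(b)
      length(b) > 1L && length(b) < 4L && ref[p] %in% b &&
        length(intersect(b, alt_bases)) > 0L, TRUE)
    hom <- carrier & !het

    classes <- vapply(alt_bases, function(a) substitution_class(ref[p], a), "")
    effects <- vapply(alt_bases, function(a)
      .coding_effect(model, p, ref, a), "")

    make_rec <- function(alts, cls, eff) data.frame(
      pos = p,
      label = if (p %in% site_vpos) site_label[[match(p, site_vpos)]]
              else local_to_label(model, p),
      ref = ref[p], alt = paste(alts, collapse = ","),
      exon = exon_of(model, p), class = cls, effect = eff,
      carriers = sum(carrier), het = sum(het), hom = sum(hom),
      stringsAsFactors = FALSE)

    if (length(unique(classes)) == 1L && length(unique(effects)) == 1L) {
      recs[[length(recs) + 1L]] <- make_rec(alt_bases, classes[1], effects[1])
    } else {
      for (k in seq_along(alt_bases))
        recs[[length(recs) + 1L]] <-
          make_rec(alt_bases[k], classes[k], effects[k])
    }
  }
  if (!length(recs))
    return(data.frame(pos = integer(), label = integer(), ref = character(),
                      alt = character(), exon = integer(), class = character(),
                      effect = character(), carriers = integer(),
                      het = integer(), hom = integer()))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# Synonymous/nonsynonymous status of a single-base change at spliced
# position p (frame_offset 0); trailing partial codon is "incomplete".
.coding_effect <- function(model, p, ref_chars, alt) {
  frame_pos <- p - 1L + model$frame_offset
  codon_start <- p - (frame_pos %% 3L)
  if (codon_start < 1L || codon_start + 2L > length(ref_chars))
    return("incomplete")
  codon <- paste(ref_chars[codon_start:(codon_start + 2L)], collapse = "")
  mut <- codon
  substr(mut, p - codon_start + 1L, p - codon_start + 1L) <- alt
  if (translate_codon(codon) == translate_codon(mut)) "synonymous"
  else "nonsynonymous"
}
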