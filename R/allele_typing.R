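# Resistance-allele nomenclature.  Phase cannot be resolved from a single
# diploid Sanger consensus, so each specimen is summarised by its
# maximal-resistance haplotype: the resistant residue is reported at every
# site carrying at least one resistant allele (RS or RR).  Assignments with
# a heterozygous supporting call are flagged phase-unresolved.

#' Reconstruct a specimen's resistance haplotype from genotype calls
#'
#' @param calls `data.frame` of [call_genotype()] rows for one specimen,
#'   covering all annotated sites.
#' @param model An `ace_reference`.
#' @return Named list: `residues` (named character vector keyed by residue
#'   number, e.g. `c("260" = "L", ...)`), `ambiguous` (TRUE when an
#'   RR_mixed call leaves two resistant residues, reported as e.g.
#'   `"A/V"`), `phase_unresolved` (TRUE when any supporting call is
#'   heterozygous), `unknown` (residue positions with no_call).
#' @export
resistance_haplotype <- function(calls, model) {
  residues <- character(0)
  unknown <- character(0)
  ambiguous <- FALSE
  phase_unresolved <- FALSE
  for (s in model$sites) {
    key <- as.character(s$residue)
    row <- calls[calls$site == s$label, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("calls must contain exactly one row for site ", s$label)
    g <- row$genotype
    if (g == "no_call") {
      residues[key] <- "?"
      unknown <- c(unknown, key)
      next
    }
    if (g == "SS") {
      residues[key] <- s$wildtype_aa
      next
    }
    if (g %in% c("RS", "RR_mixed")) phase_unresolved <- TRUE
    obs <- setdiff(strsplit(row$aa, "/")[[1]], s$wildtype_aa)
    if (g == "RR_mixed" && length(obs) == 2L) {
      residues[key] <- paste(sort(obs), collapse = "/")
      ambiguous <- TRUE
    } else {
      residues[key] <- obs[1]
    }
  }
  residues <- residues[order(as.integer(names(residues)))]
  list(residues = residues, ambiguous = ambiguous,
       phase_unresolved = phase_unresolved, unknown = unknown)
}

#' Assign allele nomenclature to a resistance haplotype
#'
#' An exact catalog match returns the catalog name and sensitivity class;
#' otherwise the allele is reported as `novel-<residues>` with class
#' `putative_insensitive` when at least one residue is resistant, or
#' `sensitive` for an uncatalogued wild type.  Haplotypes with unknown
#' positions are `unclassified`.
#'
#' @param haplotype Result of [resistance_haplotype()] (or a plain named
#'   residue vector).
#' @param catalog An `ace_catalog`.
#' @param model An `ace_reference` (supplies the wild-type residues).
#' @return One-row `data.frame`: haplotype string, residues, allele name,
#'   lab-allele synonyms, class, flags.
#' @export
assign_allele <- function(haplotype, catalog, model) {
  if (is.list(haplotype)) {
    residues <- haplotype$residues
    ambiguous <- isTRUE(haplotype$ambiguous)
    phase <- isTRUE(haplotype$phase_unresolved)
    unknown <- length(haplotype$unknown) > 0L
  } else {
    residues <- haplotype
    ambiguous <- any(grepl("/", residues))
    phase <- NA
    unknown <- any(residues == "?")
  }
  combo <- paste(residues, collapse = "")
  out <- data.frame(
    haplotype = combo,
    res260 = residues[["260"]], res316 = residues[["316"]],
    res342 = residues[["342"]], res407 = residues[["407"]],
    allele = NA_character_, lab_alleles = NA_character_,
    class = NA_character_, ambiguous = ambiguous,
    phase_unresolved = phase, stringsAsFactors = FALSE)

  if (unknown || ambiguous) {
    out$allele <- paste0("unresolved-", combo)
    out$class <- "unclassified"
    return(out)
  }
  hit <- which(catalog$res260 == residues[["260"]] &
               catalog$res316 == residues[["316"]] &
               catalog$res342 == residues[["342"]] &
               catalog$res407 == residues[["407"]])
  if (length(hit) == 1L) {
    out$allele <- catalog$allele[hit]
    out$lab_alleles <- catalog$lab_alleles[hit]
    out$class <- catalog$class[hit]
  } else {
    wt <- vapply(model$sites, `[[`, "", "wildtype_aa")
    names(wt) <- vapply(model$sites, function(s) as.character(s$residue), "")
    is_wt <- all(residues == wt[names(residues)])
    out$allele <- paste0("novel-", combo)
    out$class <- if (is_wt) "sensitive" else "putative_insensitive"
  }
  out
}

#' Assign alleles for a whole cohort
#'
#' @param calls Long genotype `data.frame` from [call_genotypes()].
#' @param model An `ace_reference`.
#' @param catalog Allele catalog (defaults to the one attached to `model`).
#' @return `data.frame` with one row per specimen.
#' @export
assign_alleles <- function(calls, model, catalog = model$catalog) {
  if (is.null(catalog)) stop("no allele catalog supplied or attached")
  specs <- unique(calls$specimen)
  rows <- lapply(specs, function(sp) {
    hap <- resistance_haplotype(calls[calls$specimen == sp, , drop = FALSE],
                                model)
    cbind(data.frame(specimen = sp, stringsAsFactors = FALSE),
          assign_allele(hap, catalog, model))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
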