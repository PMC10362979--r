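# Synthetic cohort generator.  Builds a reference fragment with the study's
# gene structure (534-nt exon I, 85-88-nt intron, 205-nt exon II) and
# specimen consensus sequences carrying chosen genotypes at the diagnostic
# codons plus background synonymous SNPs, heterozygotes encoded as IUPAC
# ambiguity codes.  The packaged "iran20" fixture reproduces the published
# 20-specimen genotype structure so that every frequency the pipeline
# reports is checkable against printed values.

.EXON1_LEN <- 534L
.EXON2_LEN <- 205L
.CODING_LEN <- .EXON1_LEN + .EXON2_LEN   # 739 nt, frame_offset 0
.DEFAULT_INTRON <- 86L
.DEFAULT_OFFSET <- 1040L
.FLANK_LEAD <- 148L
.FLANK_TAIL <- 74L

# Codons pinned in every generated reference: the four diagnostic codons
# (wild type) and the eight third-position sites catalogued as polymorphic
# in the packaged fixture.  Pinning them makes the fixture's SNP plan valid
# under any seed.
.PINNED_CODONS <- c(
  "94"  = "GGC",  # Gly; fixture SNP C>T at 96 (synonymous transition)
  "133" = "GTG",  # V260 wild type; variable base = codon position 1
  "208" = "CCA",  # Pro; fixture SNP A>G at 210
  "301" = "GCC",  # A316 wild type
  "328" = "GTT",  # Val; fixture SNP T>C at 330
  "433" = "GGA",  # G342 wild type; variable base = codon position 2
  "445" = "GCA",  # Ala; fixture SNP A>G at 447 (the reported local-447 A/G)
  "505" = "CTG",  # Leu; fixture SNP G>A at 507
  "568" = "GAC",  # Asp; fixture SNP C>T at 570
  "628" = "TTT",  # F407 wild type; variable base = codon position 2
  "661" = "ACT",  # Thr; fixture SNP T>C at 663
  "718" = "GGA"   # Gly; fixture SNP A>C at 720 (synonymous transversion)
)

.default_sites <- function() {
  sites <- list(
    list(label = "V260L", residue = 260L, codon_local_start = 133L,
         variable_offset = 0L, variable_position_label = 1174L,
         wildtype_codon = "GTG", wildtype_aa = "V",
         resistant = c(T = "L", C = "L")),
    list(label = "A316S", residue = 316L, codon_local_start = 301L,
         variable_offset = 0L, variable_position_label = 1341L,
         wildtype_codon = "GCC", wildtype_aa = "A",
         resistant = c(T = "S")),
    list(label = "G342A/V", residue = 342L, codon_local_start = 433L,
         variable_offset = 1L, variable_position_label = 1473L,
         wildtype_codon = "GGA", wildtype_aa = "G",
         resistant = c(T = "V", C = "A")),
    list(label = "F407Y", residue = 407L, codon_local_start = 628L,
         variable_offset = 1L, variable_position_label = 1668L,
         wildtype_codon = "TTT", wildtype_aa = "F",
         resistant = c(A = "Y"))
  )
  names(sites) <- vapply(sites, `[[`, "", "label")
  sites
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG.
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.NONSTOP_CODONS <- local({
  all3 <- expand.grid(b1 = c("A", "C", "G", "T"), b2 = c("A", "C", "G", "T"),
                      b3 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  codons <- apply(all3, 1L, paste, collapse = "")
  codons[!codons %in% c("TAA", "TAG", "TGA")]
})

#' Generate a synthetic annotated ACE reference fragment
#'
#' Produces a random coding sequence of 739 nt (534-nt exon I + 205-nt exon
#' II) with the wild-type diagnostic codons pinned at their default spliced
#' positions, joined by a GT..AG intron, and returns the fully annotated
#' reference model.  Deterministic for a given seed.
#'
#' @param seed Integer seed.
#' @param intron_length Intron length in nt, between 85 and 88.
#' @param catalog Allele catalog to attach (default: packaged catalog).
#' @return An `ace_reference`.
#' @export
generate_reference <- function(seed = 1L, intron_length = .DEFAULT_INTRON,
                               catalog = default_allele_catalog()) {
  stopifnot(intron_length >= 85L, intron_length <= 88L)
  with_rng(seed, {
    codons <- sample(.NONSTOP_CODONS, .CODING_LEN %/% 3L, replace = TRUE)
    coding <- strsplit(paste(codons, collapse = ""), "")[[1]]
    coding <- c(coding, sample(c("A", "C", "G", "T"), 1L))
    for (start in names(.PINNED_CODONS)) {
      i <- as.integer(start)
      coding[i:(i + 2L)] <- strsplit(.PINNED_CODONS[[start]], "")[[1]]
    }
    intron <- c("G", "T",
                sample(c("A", "C", "G", "T"), intron_length - 4L, replace = TRUE),
                "A", "G")
    fragment <- paste(c(coding[1:.EXON1_LEN], intron,
                        coding[(.EXON1_LEN + 1L):.CODING_LEN]), collapse = "")
    exon2_start <- .EXON1_LEN + intron_length + 1L
    model <- structure(list(
      sequence = fragment,
      exons = data.frame(start = c(1L, exon2_start),
                         end = c(.EXON1_LEN, exon2_start + .EXON2_LEN - 1L)),
      coordinate_offset = .DEFAULT_OFFSET,
      frame_offset = 0L,
      sites = .default_sites(),
      catalog = catalog
    ), class = "ace_reference")
    validate_reference(model)
    model
  })
}

#' Construct a cohort configuration
#'
#' @param specimens Character vector of specimen identifiers (the full
#'   roster; specimens absent from `genotypes` are wild type everywhere).
#' @param genotypes `data.frame` with columns `specimen`, `site`, `genotype`
#'   (`"RS"` or `"RR"`; SS is the default and need not be listed) and
#'   `alt_base` (the resistant base; may be `NA` for sites with a single
#'   resistant base).
#' @param syn_snps Optional `data.frame` of background synonymous SNPs with
#'   columns `pos` (spliced-local), `ref`, `alt`, `zygosity` (`"het"` or
#'   `"hom"`) and `specimen` (one row per carrier).
#' @param intron_length Scalar in 85..88, or named integer vector keyed by
#'   specimen for per-specimen intron-length variation.
#' @param flank_lead,flank_tail Lengths of random non-homologous flanking
#'   sequence added to each specimen (defaults 148 and 74 nt, the trimming
#'   convention of the analysis).
#' @param seed Integer seed for randomized parts (flanks, intron edits).
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(specimens, genotypes = NULL, syn_snps = NULL,
                          intron_length = .DEFAULT_INTRON,
                          flank_lead = .FLANK_LEAD, flank_tail = .FLANK_TAIL,
                          seed = 1L) {
  specimens <- as.character(specimens)
  if (anyDuplicated(specimens)) stop("duplicate specimen ids")
  if (is.null(genotypes))
    genotypes <- data.frame(specimen = character(), site = character(),
                            genotype = character(), alt_base = character(),
                            stringsAsFactors = FALSE)
  if (is.null(genotypes$alt_base)) genotypes$alt_base <- NA_character_
  stopifnot(all(c("specimen", "site", "genotype") %in% names(genotypes)))
  if (!all(genotypes$genotype %in% c("RS", "RR")))
    stop("config genotypes must be RS or RR (SS is implicit)")
  if (!all(genotypes$specimen %in% specimens))
    stop("genotype table references unknown specimen(s)")
  if (!is.null(syn_snps)) {
    stopifnot(all(c("pos", "ref", "alt", "zygosity", "specimen") %in%
                    names(syn_snps)))
    if (any(toupper(syn_snps$ref) == toupper(syn_snps$alt)))
      stop("synonymous SNP with alt equal to ref")
    if (!all(syn_snps$specimen %in% specimens))
      stop("SNP table references unknown specimen(s)")
  }
  stopifnot(all(intron_length >= 85L & intron_length <= 88L))
  structure(list(specimens = specimens, genotypes = genotypes,
                 syn_snps = syn_snps, intron_length = intron_length,
                 flank_lead = as.integer(flank_lead),
                 flank_tail = as.integer(flank_tail),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Residue combination and allele name implied by a config row set; this is
# the generator's own (pipeline-independent) bookkeeping for the truth table.
.truth_haplotype <- function(model, geno_rows) {
  residues <- vapply(model$sites, function(s) {
    rows <- geno_rows[geno_rows$site == s$label, , drop = FALSE]
    if (nrow(rows) == 0L) return(s$wildtype_aa)
    alt <- rows$alt_base[1]
    if (is.na(alt)) {
      if (length(s$resistant) != 1L)
        stop("alt_base required for multi-allelic site ", s$label)
      alt <- names(s$resistant)
    }
    aa <- s$resistant[[toupper(alt)]]
    if (is.null(aa)) stop("base ", alt, " is not a resistant base of ", s$label)
    aa
  }, "")
  names(residues) <- vapply(model$sites, function(s) as.character(s$residue), "")
  residues[order(as.integer(names(residues)))]
}

.truth_allele <- function(catalog, residues) {
  hit <- which(catalog$res260 == residues[["260"]] &
               catalog$res316 == residues[["316"]] &
               catalog$res342 == residues[["342"]] &
               catalog$res407 == residues[["407"]])
  if (length(hit) == 1L)
    return(list(allele = catalog$allele[hit], class = catalog$class[hit]))
  wt <- c("260" = "V", "316" = "A", "342" = "G", "407" = "F")
  combo <- paste(residues, collapse = "")
  list(allele = paste0("novel-", combo),
       class = if (all(residues == wt[names(residues)])) "sensitive"
               else "putative_insensitive")
}

#' Generate a synthetic specimen cohort
#'
#' Builds one consensus sequence per specimen: random leading flank +
#' exon I + intron + exon II + random trailing flank, with configured
#' genotypes applied at the diagnostic codons (RS as the two-base IUPAC
#' code, RR as the homozygous resistant base) and background SNPs applied
#' at their carriers.  Also returns the truth table used only by tests.
#'
#' @param model An `ace_reference` (see [generate_reference()]).
#' @param config A [cohort_config()].
#' @return A list with `sequences` (named `DNAStringSet`) and `truth`
#'   (list of data frames: `genotypes`, `haplotypes`, `syn_snps`).
#' @export
generate_cohort <- function(model, config) {
  stopifnot(inherits(model, "ace_reference"), inherits(config, "cohort_config"))
  site_labels <- names(model$sites)
  unknown <- setdiff(config$genotypes$site, site_labels)
  if (length(unknown))
    stop("config references unknown site label(s): ",
         paste(unknown, collapse = ", "))

  diag_codon_pos <- unlist(lapply(model$sites, function(s)
    s$codon_local_start + 0:2))
  if (!is.null(config$syn_snps)) {
    clash <- intersect(config$syn_snps$pos, diag_codon_pos)
    if (length(clash))
      stop("background SNP collides with a diagnostic codon at spliced ",
           "position(s) ", paste(clash, collapse = ", "))
    ref_coding <- strsplit(spliced_reference(model), "")[[1]]
    bad <- toupper(config$syn_snps$ref) != ref_coding[config$syn_snps$pos]
    if (any(bad))
      stop("SNP ref base disagrees with reference at spliced position(s) ",
           paste(unique(config$syn_snps$pos[bad]), collapse = ", "))
  }

  ref_coding <- strsplit(spliced_reference(model), "")[[1]]
  ref_intron <- substr(model$sequence, model$exons$end[1] + 1L,
                       model$exons$start[2] - 1L)
  n <- length(config$specimens)

  truth_geno <- truth_hap <- truth_syn <- list()
  seqs <- character(n)

  with_rng(config$seed, {
    for (k in seq_len(n)) {
      sp <- config$specimens[k]
      coding <- ref_coding
      rows <- config$genotypes[config$genotypes$specimen == sp, , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        site <- model$sites[[rows$site[r]]]
        alt <- rows$alt_base[r]
        if (is.na(alt)) {
          if (length(site$resistant) != 1L)
            stop("alt_base required for multi-allelic site ", site$label)
          alt <- names(site$resistant)
        }
        alt <- toupper(alt)
        if (!alt %in% names(site$resistant))
          stop("base ", alt, " is not a resistant base of ", site$label)
        vpos <- site_variable_local(site)
        coding[vpos] <- if (rows$genotype[r] == "RS")
          iupac_code(c(site_ref_base(site), alt)) else alt
      }
      if (!is.null(config$syn_snps)) {
        srows <- config$syn_snps[config$syn_snps$specimen == sp, , drop = FALSE]
        for (r in seq_len(nrow(srows))) {
          p <- srows$pos[r]
          coding[p] <- if (srows$zygosity[r] == "het")
            iupac_code(c(srows$ref[r], srows$alt[r]))
          else toupper(srows$alt[r])
        }
        truth_syn[[k]] <- srows
      }

      ilen <- if (length(config$intron_length) == 1L) config$intron_length
              else config$intron_length[[sp]]
      intron <- .resize_intron(ref_intron, as.integer(ilen))
      lead <- paste(sample(c("A", "C", "G", "T"), config$flank_lead,
                           replace = TRUE), collapse = "")
      tail <- paste(sample(c("A", "C", "G", "T"), config$flank_tail,
                           replace = TRUE), collapse = "")
      seqs[k] <- paste0(lead,
                        paste(coding[1:.EXON1_LEN], collapse = ""),
                        intron,
                        paste(coding[(.EXON1_LEN + 1L):length(coding)],
                              collapse = ""),
                        tail)

      residues <- .truth_haplotype(model, rows)
      al <- .truth_allele(model$catalog, residues)
      truth_hap[[k]] <- data.frame(
        specimen = sp,
        res260 = residues[["260"]], res316 = residues[["316"]],
        res342 = residues[["342"]], res407 = residues[["407"]],
        allele = al$allele, class = al$class, stringsAsFactors = FALSE)
      all_sites <- data.frame(specimen = sp, site = site_labels,
                              genotype = "SS", alt_base = NA_character_,
                              stringsAsFactors = FALSE)
      for (r in seq_len(nrow(rows))) {
        i <- match(rows$site[r], all_sites$site)
        all_sites$genotype[i] <- rows$genotype[r]
        all_sites$alt_base[i] <- rows$alt_base[r]
      }
      truth_geno[[k]] <- all_sites
    }
  })

  sequences <- Biostrings::DNAStringSet(setNames(seqs, config$specimens))
  truth <- list(
    genotypes = if (n) do.call(rbind, truth_geno) else
      data.frame(specimen = character(), site = character(),
                 genotype = character(), alt_base = character()),
    haplotypes = if (n) do.call(rbind, truth_hap) else
      data.frame(specimen = character(), res260 = character(),
                 res316 = character(), res342 = character(),
                 res407 = character(), allele = character(),
                 class = character()),
    syn_snps = if (length(truth_syn)) do.call(rbind, truth_syn) else NULL
  )
  list(sequences = sequences, truth = truth)
}

# Shrink or grow an intron to a target length by editing its middle,
# preserving the GT..AG ends.  Inserted bases are drawn from the RNG.
.resize_intron <- function(intron, target_len) {
  cur <- nchar(intron)
  if (target_len == cur) return(intron)
  if (target_len < cur) {
    drop <- cur - target_len
    mid <- cur %/% 2L
    return(paste0(substr(intron, 1L, mid - drop), substr(intron, mid + 1L, cur)))
  }
  add <- target_len - cur
  mid <- cur %/% 2L
  paste0(substr(intron, 1L, mid),
         paste(sample(c("A", "C", "G", "T"), add, replace = TRUE), collapse = ""),
         substr(intron, mid + 1L, cur))
}

#' Load a packaged cohort fixture
#'
#' `"iran20"` is the packaged 20-specimen field cohort: specimen labels
#' MK257685-MK257704 with the published per-specimen genotypes at V260L,
#' G342A/V and F407Y, three all-wild-type (sensitive) specimens, and eight
#' background synonymous SNPs placed so the cohort-wide catalog totals 7
#' transitions and 4 transversions across 7 exon-I and 4 exon-II sites
#' (including the homozygous A>G change at spliced position 447 carried by
#' MK257686).
#'
#' @param name Fixture name; currently only `"iran20"`.
#' @return A [cohort_config()].
#' @export
load_fixture <- function(name) {
  if (!identical(name, "iran20"))
    stop("unknown fixture '", name, "'; available: iran20")
  specimens <- sprintf("MK%d", 257685:257704)
  mk <- function(i) sprintf("MK%d", 257684 + i)

  g <- list()
  add <- function(site, genotype, alt, ids)
    data.frame(specimen = vapply(ids, mk, ""), site = site,
               genotype = genotype, alt_base = alt, stringsAsFactors = FALSE)
  g[[1]] <- add("V260L", "RR", "T", 6L)                      # MK257690
  g[[2]] <- add("V260L", "RS", "T", c(8L, 9L, 11L, 16L, 20L))
  g[[3]] <- add("G342A/V", "RR", "C", 6L)                    # G342A homozygote
  g[[4]] <- add("G342A/V", "RS", "C", c(8L, 9L, 17L, 18L, 19L))
  g[[5]] <- add("G342A/V", "RS", "T", c(1L, 3L, 4L, 5L, 7L, 12L, 13L, 14L))
  g[[6]] <- add("F407Y", "RS", "A",
                c(1L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 11L, 12L, 13L, 14L,
                  16L, 17L, 18L, 19L))
  genotypes <- do.call(rbind, g)

  s <- list()
  snp <- function(pos, ref, alt, zygosity, ids)
    data.frame(pos = pos, ref = ref, alt = alt, zygosity = zygosity,
               specimen = vapply(ids, mk, ""), stringsAsFactors = FALSE)
  s[[1]] <- snp(96L,  "C", "T", "hom", c(1L, 3L, 4L, 5L, 12L, 13L, 14L))
  s[[2]] <- snp(210L, "A", "G", "het", 7L)
  s[[3]] <- snp(330L, "T", "C", "hom", c(17L, 18L, 19L))
  s[[4]] <- snp(447L, "A", "G", "hom", 2L)          # MK257686
  s[[5]] <- snp(507L, "G", "A", "hom", c(8L, 9L))
  s[[6]] <- snp(570L, "C", "T", "hom", c(11L, 16L))
  s[[7]] <- snp(663L, "T", "C", "hom", 6L)
  s[[8]] <- snp(720L, "A", "C", "het", 20L)
  syn_snps <- do.call(rbind, s)

  intron <- setNames(rep(86L, 20L), specimens)
  intron[["MK257694"]] <- 85L
  intron[["MK257699"]] <- 87L
  intron[["MK257704"]] <- 88L

  cohort_config(specimens = specimens, genotypes = genotypes,
                syn_snps = syn_snps, intron_length = intron, seed = 20L)
}

#' Write a reference or cohort to FASTA
#'
#' @param model An `ace_reference`.
#' @param path Output FASTA path.
#' @param name Record name for the reference.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(model, path, name = "ACE_reference") {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(model$sequence, name)), path)
  invisible(path)
}
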