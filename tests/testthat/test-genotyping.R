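test_that("IUPAC expansion follows the standard definitions", {
  expect_identical(expand_iupac("W"), c("A", "T"))
  expect_identical(expand_iupac("K"), c("G", "T"))
  expect_identical(expand_iupac("N"), c("A", "C", "G", "T"))
  expect_identical(expand_iupac("a"), "A")
  expect_error(expand_iupac("Z"), "invalid IUPAC")
  # every two-base code round-trips through its base set
  for (code in c("R", "Y", "S", "W", "K", "M"))
    expect_identical(mdace:::iupac_code(expand_iupac(code)), code)
})

test_that("genotypes are called from the double-peak code at each site", {
  model <- ref_model()
  ref_spliced <- paste(substring(model$sequence, model$exons$start,
                                 model$exons$end), collapse = "")
  # the reference itself is SS everywhere
  for (s in model$sites) {
    call <- call_genotype(ref_spliced, s)
    expect_identical(call$genotype, "SS")
    expect_identical(call$aa, s$wildtype_aa)
  }

  vpos <- function(lbl) {
    s <- model$sites[[lbl]]
    s$codon_local_start + s$variable_offset
  }
  sub1 <- function(seq, pos, ch) { substr(seq, pos, pos) <- ch; seq }

  # heterozygous W (A/T) at F407Y -> RS with amino acids {F, Y}
  seq <- sub1(ref_spliced, vpos("F407Y"), "W")
  call <- call_genotype(seq, model$sites[["F407Y"]])
  expect_identical(call$genotype, "RS")
  expect_setequal(strsplit(call$aa, "/")[[1]], c("F", "Y"))

  # homozygous resistant at V260L and G342 -> RR at both
  seq <- sub1(sub1(ref_spliced, vpos("V260L"), "T"), vpos("G342A/V"), "C")
  expect_identical(call_genotype(seq, model$sites[["V260L"]])$genotype, "RR")
  g342 <- call_genotype(seq, model$sites[["G342A/V"]])
  expect_identical(g342$genotype, "RR")
  expect_identical(g342$aa, "A")

  # two resistant bases, no wild type -> RR_mixed with both residues
  seq <- sub1(ref_spliced, vpos("G342A/V"), "Y")   # C/T
  mixed <- call_genotype(seq, model$sites[["G342A/V"]])
  expect_identical(mixed$genotype, "RR_mixed")
  expect_setequal(strsplit(mixed$aa, "/")[[1]], c("A", "V"))

  # N in the codon or a truncated sequence -> no_call
  seq <- sub1(ref_spliced, model$sites[["V260L"]]$codon_local_start + 2L, "N")
  expect_identical(call_genotype(seq, model$sites[["V260L"]])$genotype,
                   "no_call")
  expect_identical(call_genotype(substr(ref_spliced, 1, 100),
                                 model$sites[["F407Y"]])$genotype, "no_call")

  # ambiguity away from the variable position -> no_call with warning
  seq <- sub1(ref_spliced, vpos("V260L") + 1L, "R")
  expect_warning(call <- call_genotype(seq, model$sites[["V260L"]]),
                 "outside the variable position")
  expect_identical(call$genotype, "no_call")
})

test_that("transition/transversion agrees with the exhaustive lookup", {
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  for (ref in c("A", "C", "G", "T")) for (alt in c("A", "C", "G", "T")) {
    if (ref == alt) next
    expected <- if (purine[[ref]] == purine[[alt]]) "transition"
                else "transversion"
    expect_identical(substitution_class(ref, alt), expected)
  }
})

test_that("coding effect agrees with whole-sequence translation", {
  model <- ref_model()
  ref_spliced <- paste(substring(model$sequence, model$exons$start,
                                 model$exons$end), collapse = "")
  ref_chars <- strsplit(ref_spliced, "")[[1]]
  set.seed(21)
  checked <- 0L
  while (checked < 200L) {
    p <- sample(737L, 1L)     # keep inside complete codons
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref_chars[p]), 1L)
    got <- mdace:::.coding_effect(model, p, ref_chars, alt)
    # oracle: translate the full mutated sequence with Biostrings
    mut <- ref_spliced
    substr(mut, p, p) <- alt
    n <- 738L   # complete codons only
    aa_ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(ref_spliced, 1, n)), no.init.codon = TRUE))
    aa_mut <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(mut, 1, n)), no.init.codon = TRUE))
    expect_identical(got,
                     if (aa_ref == aa_mut) "synonymous" else "nonsynonymous")
    checked <- checked + 1L
  }
})

test_that("the fixture SNP catalog matches the published aggregate counts", {
  res <- iran20_results()$res
  snps <- res$snps
  expect_identical(nrow(snps), 11L)
  expect_identical(sum(snps$class == "transition"), 7L)
  expect_identical(sum(snps$class == "transversion"), 4L)
  expect_identical(sum(snps$exon == 1L), 7L)
  expect_identical(sum(snps$exon == 2L), 4L)

  r1473 <- snps[snps$label == 1473L, ]
  expect_identical(r1473$alt, "C,T")
  expect_identical(r1473$effect, "nonsynonymous")

  r447 <- snps[snps$pos == 447L, ]
  expect_identical(r447$alt, "G")
  expect_identical(r447$effect, "synonymous")
  expect_identical(r447$carriers, 1L)
})

test_that("a cohort of reference clones yields an empty catalog", {
  model <- ref_model()
  cfg <- cohort_config(c("c1", "c2"), flank_lead = 0L, flank_tail = 0L,
                       seed = 2L)
  out <- generate_cohort(model, cfg)
  res <- run_pipeline(out$sequences, model, lead = 0L, tail = 0L)
  expect_identical(nrow(res$snps), 0L)
  expect_true(all(res$genotypes$genotype == "SS"))
})
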