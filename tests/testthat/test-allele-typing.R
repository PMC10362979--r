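make_calls <- function(model, genos) {
  do.call(rbind, lapply(names(model$sites), function(lbl) {
    s <- model$sites[[lbl]]
    g <- genos[[lbl]] %||% "SS"
    if (is.list(g)) { aa <- g$aa; g <- g$genotype } else aa <- NULL
    if (is.null(aa)) {
      aa <- switch(g,
        SS = s$wildtype_aa,
        RS = paste(c(s$wildtype_aa, s$resistant[[1]]), collapse = "/"),
        RR = s$resistant[[1]],
        no_call = "")
    }
    data.frame(specimen = "S", site = lbl, genotype = g, bases = "",
               aa = aa, stringsAsFactors = FALSE)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the maximal-resistance haplotype follows the genotype calls", {
  model <- ref_model()
  # V260L RS + F407Y RS, G342 SS -> (L, A, G, Y)
  hap <- resistance_haplotype(
    make_calls(model, list(V260L = "RS", F407Y = list(genotype = "RS", aa = "F/Y"))),
    model)
  expect_identical(unname(hap$residues), c("L", "A", "G", "Y"))
  expect_true(hap$phase_unresolved)

  # all SS -> wild type (V, A, G, F), phase resolved
  hap <- resistance_haplotype(make_calls(model, list()), model)
  expect_identical(unname(hap$residues), c("V", "A", "G", "F"))
  expect_false(hap$phase_unresolved)

  # V260L RR + G342A RR + F407Y RS -> (L, A, A, Y)
  hap <- resistance_haplotype(
    make_calls(model, list(
      V260L = "RR",
      `G342A/V` = list(genotype = "RR", aa = "A"),
      F407Y = list(genotype = "RS", aa = "F/Y"))), model)
  expect_identical(unname(hap$residues), c("L", "A", "A", "Y"))

  # RR_mixed at 342 -> "A/V", flagged ambiguous
  hap <- resistance_haplotype(
    make_calls(model, list(`G342A/V` = list(genotype = "RR_mixed", aa = "A/V"))),
    model)
  expect_identical(hap$residues[["342"]], "A/V")
  expect_true(hap$ambiguous)

  # no_call leaves the position unknown
  hap <- resistance_haplotype(
    make_calls(model, list(F407Y = list(genotype = "no_call", aa = ""))), model)
  expect_identical(hap$residues[["407"]], "?")
  expect_identical(hap$unknown, "407")
})

test_that("catalog matching, novel alleles and sensitivity classes", {
  model <- ref_model()
  catalog <- default_allele_catalog()
  hap <- function(r) setNames(r, c("260", "316", "342", "407"))

  a <- assign_allele(hap(c("V", "A", "V", "Y")), catalog, model)
  expect_identical(a$allele, "I")
  expect_identical(a$class, "insensitive")
  expect_identical(a$lab_alleles, "V14")

  expect_identical(assign_allele(hap(c("V", "A", "G", "F")), catalog,
                                 model)$class, "sensitive")

  # removing allele IV from the catalog forces the novel path
  stripped <- catalog[catalog$allele != "IV", ]
  a <- assign_allele(hap(c("L", "A", "G", "F")), stripped, model)
  expect_identical(a$allele, "novel-LAGF")
  expect_identical(a$class, "putative_insensitive")

  # an uncatalogued wild type is still sensitive
  a <- assign_allele(hap(c("V", "A", "G", "F")),
                     catalog[catalog$allele != "VI", ], model)
  expect_identical(a$allele, "novel-VAGF")
  expect_identical(a$class, "sensitive")

  # unknown positions are unclassified
  a <- assign_allele(hap(c("?", "A", "G", "F")), catalog, model)
  expect_identical(a$class, "unclassified")
})

test_that("assignment is pure and monotone under catalog growth", {
  model <- ref_model()
  catalog <- default_allele_catalog()
  hap <- setNames(c("L", "A", "A", "Y"), c("260", "316", "342", "407"))
  expect_identical(assign_allele(hap, catalog, model),
                   assign_allele(hap, catalog, model))
  grown <- rbind(catalog, data.frame(
    res260 = "L", res316 = "S", res342 = "V", res407 = "Y",
    allele = "VII", lab_alleles = "-", class = "insensitive"))
  for (i in seq_len(nrow(catalog))) {
    h <- setNames(unlist(catalog[i, 1:4]), c("260", "316", "342", "407"))
    expect_identical(assign_allele(h, grown, model)$allele,
                     assign_allele(h, catalog, model)$allele)
  }
})

test_that("the fixture cohort reproduces the published allele assignments", {
  fix <- iran20_results()
  got <- fix$res$alleles
  want <- fix$cohort$truth$haplotypes
  expect_identical(nrow(got), 20L)
  m <- match(want$specimen, got$specimen)
  expect_identical(got$allele[m], want$allele)
  expect_identical(got$class[m], want$class)
})
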