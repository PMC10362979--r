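test_that("TrN distance is zero for identical pairs and matches ape", {
  set.seed(31)
  s <- random_dna(500)
  expect_identical(trn_distance(s, s), 0)
  for (rep in 1:8) {
    a <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE,
                      prob = c(0.3, 0.2, 0.3, 0.2)), collapse = "")
    b <- strsplit(a, "")[[1]]
    idx <- sample(1000, 60)
    b[idx] <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
    b <- paste(b, collapse = "")
    expect_equal(trn_distance(a, b), oracle_trn_ape(a, b), tolerance = 1e-10)
    expect_equal(trn_distance(a, b), trn_distance(b, a))
  }
})

test_that("TrN excludes ambiguous sites pairwise", {
  a <- "ACGTACGTACGTACGTACGT"
  b <- a
  substr(b, 1, 1) <- "N"
  substr(b, 2, 2) <- "W"   # heterozygote code: excluded, not a difference
  expect_identical(trn_distance(a, b), 0)
  expect_error(trn_distance("NNNN", "ACGT"), "no comparable sites")
})

test_that("TrN reduces to K2P with only transversions, and to JC when
           substitution types are balanced", {
  # transversion-only pair with equal base frequencies
  base <- rep(c("A", "C", "G", "T"), each = 50)
  b <- base
  b[c(1, 2)] <- "C"     # A->C
  b[c(51, 52)] <- "A"   # C->A
  b[c(101, 102)] <- "T" # G->T
  b[c(151, 152)] <- "G" # T->G
  a <- paste(base, collapse = ""); bb <- paste(b, collapse = "")
  expect_equal(trn_distance(a, bb), oracle_k80_ape(a, bb), tolerance = 1e-9)

  # balanced construction: TN93 == Jukes-Cantor closed form
  pair <- balanced_jc_pair(k = 2L, ident_per_base = 24L)
  jc <- -0.75 * log(1 - 4 * pair$p / 3)
  expect_equal(trn_distance(pair$a, pair$b), jc, tolerance = 1e-9)
})

test_that("saturated pairs are capped with a warning", {
  a <- paste(rep(c("A", "C", "G", "T"), each = 10), collapse = "")
  b <- paste(rep(c("G", "T", "A", "C"), each = 10), collapse = "")
  expect_warning(d <- trn_distance(a, b), "saturated")
  expect_identical(d, 5.0)
})

test_that("amino-acid p-distance counts determined differing positions", {
  a <- strrep("ACDEFGHIKL", 10)
  expect_identical(aa_p_distance(a, a), 0)
  b <- a
  substr(b, 1, 1) <- "W"; substr(b, 50, 50) <- "Y"
  expect_equal(aa_p_distance(a, b), 0.02)
  expect_equal(aa_p_distance(a, b), aa_p_distance(b, a))
  # X positions drop out of the denominator
  c_ <- a
  substr(c_, 1, 1) <- "X"
  expect_identical(aa_p_distance(a, c_), 0)
})

test_that("NJ recovers additive trees exactly", {
  set.seed(32)
  for (rep in 1:10) {
    true <- ape::rtree(8, br = function(n) runif(n, 0.05, 0.5))
    d <- ape::cophenetic.phylo(true)
    got <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), got)), 0)
    dd <- ape::cophenetic.phylo(got)[rownames(d), colnames(d)]
    expect_equal(dd, d, tolerance = 1e-10)
  }
})

test_that("three taxa follow the closed-form branch lengths", {
  d <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- nj_tree(d)
  bl <- setNames(tree$edge.length,
                 tree$tip.label[tree$edge[, 2]])
  expect_equal(bl[["a"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(bl[["b"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(bl[["c"]], (0.4 + 0.5 - 0.3) / 2)
})

test_that("tied distance matrices give the same tree on repeated runs", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- nj_tree(d); t2 <- nj_tree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("bootstrap is deterministic under seed and bounded in {0,100}", {
  set.seed(33)
  base <- strsplit(random_dna(200), "")[[1]]
  flip <- c(A = "G", C = "T", G = "A", T = "C")
  mk <- function(idx) { s <- base; s[idx] <- flip[s[idx]]
                        paste(s, collapse = "") }
  seqs <- c(t1 = mk(integer(0)), t2 = mk(1:5), t3 = mk(11:20),
            t4 = mk(31:45))
  t1 <- bootstrap_nj(seqs, "trn", replicates = 25L, seed = 9L)
  t2 <- bootstrap_nj(seqs, "trn", replicates = 25L, seed = 9L)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  one <- bootstrap_nj(seqs, "trn", replicates = 1L, seed = 9L)
  expect_true(all(one$node.label %in% c(0L, 100L)))
})

test_that("the synonymous 447 change separates nucleotide but not
           amino-acid distances in the fixture", {
  fix <- iran20_results()
  nt <- setNames(vapply(fix$res$spliced, `[[`, "", "seq"),
                 names(fix$res$spliced))
  aa <- translate_cohort(fix$res$spliced)
  # MK257686 vs the other sensitive specimens MK257694 / MK257699
  expect_identical(aa_p_distance(aa[["MK257686"]], aa[["MK257694"]]), 0)
  expect_identical(aa_p_distance(aa[["MK257686"]], aa[["MK257699"]]), 0)
  expect_gt(trn_distance(nt[["MK257686"]], nt[["MK257694"]]), 0)
  expect_gt(trn_distance(nt[["MK257686"]], nt[["MK257699"]]), 0)
  expect_identical(trn_distance(nt[["MK257694"]], nt[["MK257699"]]), 0)
})
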