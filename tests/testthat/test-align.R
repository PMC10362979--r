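test_that("identical sequences align gaplessly with score = length", {
  set.seed(11)
  s <- random_dna(50)
  aln <- global_align(s, s)
  expect_equal(aln$score, 50)
  expect_identical(aln$ref, s)
  expect_identical(aln$spec, s)
})

test_that("IUPAC codes sharing a base score as matches", {
  set.seed(12)
  s <- random_dna(40)
  sp <- s
  substr(sp, 20, 20) <- "W"   # overlaps A or T only
  substr(s, 20, 20) <- "A"
  aln <- global_align(s, sp)
  expect_equal(aln$score, 40)
  expect_false(grepl("-", aln$spec))
})

test_that("alignment score equals the exhaustive enumeration oracle", {
  set.seed(13)
  for (rep in 1:60) {
    a <- random_dna(sample(1:6, 1))
    b <- random_dna(sample(1:6, 1))
    aln <- global_align(a, b)
    expect_equal(aln$score, oracle_nw_score(a, b),
                 info = paste(a, "vs", b))
  }
})

test_that("score is symmetric under input swap (symmetric scheme)", {
  set.seed(14)
  for (rep in 1:25) {
    a <- random_dna(sample(3:9, 1))
    b <- random_dna(sample(3:9, 1))
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  }
})

test_that("alignment rejects empty or non-IUPAC input", {
  expect_error(global_align("", "ACGT"), "empty")
  expect_error(global_align("ACGT", "ACZT"), "non-IUPAC")
})

test_that("flank trimming removes only overhang specimen bases", {
  ref <- "ACGTACGTAA"
  spec <- paste0("TTT", ref, "GG")   # flanks mismatching the reference ends
  aln <- global_align(ref, spec)
  trimmed <- trim_flanks(aln, lead = 3L, tail = 2L)
  # trimmed alignment spans the reference bases only
  spec_chars <- strsplit(trimmed$spec, "")[[1]]
  expect_identical(sum(spec_chars != "-" & is.na(trimmed$ref_pos)), 0L)
  expect_identical(sum(!is.na(trimmed$ref_pos)), nchar(ref))
  expect_identical(trimmed$spec, ref)

  # lead = tail = 0 is the identity
  expect_identical(trim_flanks(aln, 0L, 0L), aln)
  expect_error(trim_flanks(global_align("ACGTACGT", "ACGTACGT"), 5L, 5L),
               "over-trimming")
})

test_that("splicing excises the intron and tolerates its length variation", {
  model <- ref_model()
  spliced_ref <- paste(substring(model$sequence, model$exons$start,
                                 model$exons$end), collapse = "")
  aln <- global_align(model$sequence, model$sequence)
  sp <- splice(aln, model, id = "ref")
  expect_identical(nchar(sp$seq), 739L)
  expect_identical(sp$seq, spliced_ref)

  # a specimen with a different intron length splices identically
  for (ilen in c(85L, 87L, 88L)) {
    cfg <- cohort_config("S1", intron_length = ilen,
                         flank_lead = 0L, flank_tail = 0L, seed = 5L)
    seq <- as.character(generate_cohort(model, cfg)$sequences[[1]])
    sp2 <- splice(global_align(model$sequence, seq), model, id = "S1")
    expect_identical(sp2$seq, spliced_ref)
  }
})

test_that("coding insertions are rejected and deletions become N", {
  model <- ref_model()
  seq <- model$sequence
  with_ins <- paste0(substr(seq, 1, 100), "A", substr(seq, 101, nchar(seq)))
  expect_error(splice(global_align(seq, with_ins), model), "insertion inside exon")

  with_del <- paste0(substr(seq, 1, 99), substr(seq, 101, nchar(seq)))
  expect_warning(sp <- splice(global_align(seq, with_del), model), "deletion")
  expect_identical(substr(sp$seq, 100, 100), "N")
})

test_that("percent identity counts IUPAC overlap and excludes N", {
  a <- "ACGTACGTAC"
  expect_equal(identity_matrix(c(x = a, y = a))["x", "y"], 100)
  b <- a; substr(b, 3, 3) <- "A"
  expect_equal(identity_matrix(c(x = a, y = b))["x", "y"], 100 * 9 / 10)
  w <- a; substr(w, 5, 5) <- "W"   # W covers the A at position 5
  expect_equal(identity_matrix(c(x = a, y = w))["x", "y"], 100)
  nn <- a; substr(nn, 1, 1) <- "N"
  expect_equal(identity_matrix(c(x = a, y = nn))["x", "y"], 100)

  set.seed(16)
  seqs <- setNames(vapply(1:4, function(i) random_dna(30), ""),
                   paste0("s", 1:4))
  m <- identity_matrix(seqs)
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(100, 4))
})

test_that("one substituted position in a 739-nt pair gives 100*738/739", {
  model <- ref_model()
  a <- paste(substring(model$sequence, model$exons$start, model$exons$end),
             collapse = "")
  b <- a
  substr(b, 400, 400) <- setdiff(c("A", "C", "G", "T"),
                                 substr(a, 400, 400))[1]
  expect_equal(identity_matrix(c(a = a, b = b))["a", "b"], 100 * 738 / 739)
})
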