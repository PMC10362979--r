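# Independent oracles used by the tests.  These deliberately avoid the
# package's own code paths.

# Exhaustive enumeration of all global alignments of two short sequences
# under the affine scheme (gap of length L costs open + L * ext), taking
# the maximum score.  Exponential; only for sequences of a few bases.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1,
                            open = -5, ext = -1) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A)
  m <- length(B)
  if (n == 0L) return(if (m == 0L) 0 else open + m * ext)
  if (m == 0L) return(open + n * ext)
  compat <- function(x, y)
    length(intersect(expand_iupac(x), expand_iupac(y))) > 0L
  smat <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    smat[i, j] <- if (compat(A[i], B[j])) match else mismatch
  rec <- function(i, j, prev) {
    if (i == n && j == m) return(0)
    best <- -Inf
    if (i < n && j < m) {
      v <- smat[i + 1L, j + 1L] + rec(i + 1L, j + 1L, 0L)
      if (v > best) best <- v
    }
    if (j < m) {
      v <- ext + (if (prev == 1L) 0 else open) + rec(i, j + 1L, 1L)
      if (v > best) best <- v
    }
    if (i < n) {
      v <- ext + (if (prev == 2L) 0 else open) + rec(i + 1L, j, 2L)
      if (v > best) best <- v
    }
    best
  }
  rec(0L, 0L, 0L)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# TN93 distance of exactly two sequences via ape (its pooled base
# frequencies then equal the pooled-pair frequencies the package uses).
oracle_trn_ape <- function(a, b) {
  m <- ape::as.DNAbin(rbind(a = strsplit(tolower(a), "")[[1]],
                            b = strsplit(tolower(b), "")[[1]]))
  as.numeric(ape::dist.dna(m, model = "TN93", pairwise.deletion = TRUE))
}

oracle_k80_ape <- function(a, b) {
  m <- ape::as.DNAbin(rbind(a = strsplit(tolower(a), "")[[1]],
                            b = strsplit(tolower(b), "")[[1]]))
  as.numeric(ape::dist.dna(m, model = "K80", pairwise.deletion = TRUE))
}

# A pair of sequences with exactly balanced substitution-type counts and
# equal pooled base frequencies, for which TN93 collapses to the
# Jukes-Cantor closed form.  `k` sites per unordered substitution type.
balanced_jc_pair <- function(k = 2L, ident_per_base = 24L) {
  ident <- rep(c("A", "C", "G", "T"), each = ident_per_base)
  types <- list(c("A", "G"), c("C", "T"), c("A", "C"),
                c("A", "T"), c("C", "G"), c("G", "T"))
  a <- b <- character(0)
  for (t in types) {
    a <- c(a, rep(t, each = k %/% 2L))
    b <- c(b, rep(rev(t), each = k %/% 2L))
  }
  list(a = c(ident, a), b = c(ident, b),
       p = length(a) / (length(ident) + length(a)))
}

# Random cohort configuration over the annotated sites, for round-trip
# property tests.  Uses only fixture-pinned background-SNP positions so the
# plan is valid for any generated reference.
random_config <- function(seed) {
  set.seed(seed)
  n <- sample(3:6, 1L)
  ids <- sprintf("SP%02d", seq_len(n))
  sites <- c("V260L", "A316S", "G342A/V", "F407Y")
  alt_pool <- list("V260L" = c("T", "C"), "A316S" = "T",
                   "G342A/V" = c("T", "C"), "F407Y" = "A")
  rows <- list()
  for (id in ids) for (s in sites) {
    g <- sample(c("SS", "RS", "RR"), 1L, prob = c(0.6, 0.3, 0.1))
    if (g == "SS") next
    rows[[length(rows) + 1L]] <- data.frame(
      specimen = id, site = s, genotype = g,
      alt_base = sample(alt_pool[[s]], 1L), stringsAsFactors = FALSE)
  }
  syn_pool <- data.frame(
    pos = c(96L, 210L, 330L, 447L, 507L, 570L, 663L, 720L),
    ref = c("C", "A", "T", "A", "G", "C", "T", "A"),
    alt = c("T", "G", "C", "G", "A", "T", "C", "C"))
  syn <- NULL
  if (runif(1) < 0.5) {
    pick <- sample(nrow(syn_pool), sample(1:3, 1L))
    syn <- do.call(rbind, lapply(pick, function(i) data.frame(
      pos = syn_pool$pos[i], ref = syn_pool$ref[i], alt = syn_pool$alt[i],
      zygosity = sample(c("het", "hom"), 1L),
      specimen = sample(ids, 1L), stringsAsFactors = FALSE)))
  }
  cohort_config(ids,
                genotypes = if (length(rows)) do.call(rbind, rows) else NULL,
                syn_snps = syn,
                intron_length = sample(85:88, 1L),
                seed = seed)
}
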