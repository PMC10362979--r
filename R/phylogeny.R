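# Distance phylogenetics: Tamura-Nei (TN93) nucleotide distances with
# empirical base frequencies from each pooled pair, amino-acid p-distances,
# neighbor-joining (via ape) and column bootstrap.  Trees are unrooted and
# serialized as Newick with integer bootstrap supports as node labels.

.SATURATION_CAP <- 5.0

# Split a sequence string into an uppercase character vector.
.chars <- function(x) if (length(x) == 1L && nchar(x) > 1L)
  strsplit(toupper(x), "")[[1]] else toupper(x)

#' Tamura-Nei (TN93) pairwise distance
#'
#' Closed-form TN93 distance with separate purine and pyrimidine transition
#' terms and empirical base frequencies estimated from the two sequences
#' pooled.  Sites where either sequence is not an unambiguous A/C/G/T
#' (gaps, N, IUPAC heterozygote codes) are excluded pairwise.  Saturated
#' pairs (a logarithm argument <= 0) are capped at 5 substitutions/site
#' with a warning.
#'
#' @param a,b Equal-length nucleotide strings (or character vectors).
#' @return Non-negative distance in substitutions per site.
#' @export
trn_distance <- function(a, b) {
  a <- .chars(a); b <- .chars(b)
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites (all excluded)")
  a <- a[ok]; b <- b[ok]
  L <- length(a)
  if (all(a == b)) return(0)

  counts <- table(factor(c(a, b), levels = c("A", "C", "G", "T")))
  pi <- counts / (2 * L)
  pA <- pi[["A"]]; pC <- pi[["C"]]; pG <- pi[["G"]]; pT <- pi[["T"]]
  pR <- pA + pG; pY <- pC + pT

  diff <- a != b
  p1 <- sum(diff & ((a == "A" & b == "G") | (a == "G" & b == "A"))) / L
  p2 <- sum(diff & ((a == "C" & b == "T") | (a == "T" & b == "C"))) / L
  q <- sum(diff) / L - p1 - p2

  if (pR == 0 || pY == 0) stop("degenerate base composition")
  saturated <- FALSE
  d <- 0
  if (pA * pG > 0) {
    w1 <- 1 - pR * p1 / (2 * pA * pG) - q / (2 * pR)
    if (w1 <= 0) saturated <- TRUE
    else d <- d - (2 * pA * pG / pR) * log(w1)
  } else if (p1 > 0) saturated <- TRUE
  if (pC * pT > 0) {
    w2 <- 1 - pY * p2 / (2 * pC * pT) - q / (2 * pY)
    if (w2 <= 0) saturated <- TRUE
    else d <- d - (2 * pC * pT / pY) * log(w2)
  } else if (p2 > 0) saturated <- TRUE
  w3 <- 1 - q / (2 * pR * pY)
  if (w3 <= 0) saturated <- TRUE
  else d <- d - 2 * (pR * pY - pA * pG * pY / pR - pC * pT * pR / pY) * log(w3)

  if (saturated) {
    warning("saturated pair: TN93 log argument <= 0; distance capped at ",
            .SATURATION_CAP)
    return(.SATURATION_CAP)
  }
  d
}

#' Amino-acid p-distance
#'
#' Fraction of differing positions among mutually determined positions
#' (both not `X`, `-` or `*`).
#'
#' @param a,b Equal-length amino-acid strings (or character vectors).
#' @return Distance in `[0, 1]`.
#' @export
aa_p_distance <- function(a, b) {
  a <- .chars(a); b <- .chars(b)
  if (length(a) != length(b)) stop("sequences must have equal length")
  undet <- c("X", "-", ".", "*")
  ok <- !(a %in% undet) & !(b %in% undet)
  if (!any(ok)) stop("no comparable positions")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Pairwise distance matrix for a set of sequences
#'
#' @param seqs Named character vector of equal-length sequences.
#' @param type `"trn"` (nucleotide TN93) or `"aa"` (amino-acid p-distance).
#' @return Symmetric numeric matrix with a `model` attribute.
#' @export
distance_matrix <- function(seqs, type = c("trn", "aa")) {
  type <- match.arg(type)
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  fun <- if (type == "trn") trn_distance else aa_p_distance
  mats <- lapply(seqs, .chars)
  out <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      out[i, j] <- out[j, i] <- fun(mats[[i]], mats[[j]])
  attr(out, "model") <- if (type == "trn") "TrN" else "p-distance"
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`); an additive input
#' matrix is recovered exactly.  Negative branch-length estimates are
#' clamped to zero with a warning.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) or `dist`.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Neighbor-joining tree with column bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and labels each internal node of the full-data tree with
#' the percentage of replicates containing its bipartition.  Deterministic
#' under `seed`.
#'
#' @param seqs Named character vector of equal-length sequences.
#' @param type `"trn"` or `"aa"` (see [distance_matrix()]).
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @return A `phylo` tree with integer `node.label` supports (0-100).
#' @export
bootstrap_nj <- function(seqs, type = c("trn", "aa"), replicates = 1000L,
                         seed = NULL) {
  type <- match.arg(type)
  if (replicates < 1L) stop("replicates must be >= 1")
  mat <- do.call(rbind, lapply(seqs, .chars))
  rownames(mat) <- names(seqs)
  build <- function(m) {
    v <- setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
    nj_tree(distance_matrix(v, type = type))
  }
  run <- function() {
    tree <- build(mat)
    counts <- suppressWarnings(
      ape::boot.phylo(tree, mat, build, B = replicates, rooted = FALSE,
                      quiet = TRUE))
    # the root's trivial bipartition is in every replicate; other NAs mean
    # the bipartition was never observed
    if (is.na(counts[1])) counts[1] <- replicates
    counts[is.na(counts)] <- 0L
    tree$node.label <- as.integer(round(100 * counts / replicates))
    tree
  }
  if (is.null(seed)) run() else with_rng(seed, run())
}

#' Translate spliced coding sequences to amino acids
#'
#' Codons containing IUPAC heterozygote codes translate to the shared amino
#' acid when all expansions agree, otherwise `X`; codons with N are `X`.
#'
#' @param spliced List of `ace_spliced` objects (or named character vector).
#' @return Named character vector of amino-acid sequences.
#' @export
translate_cohort <- function(spliced) {
  seqs <- if (is.character(spliced)) spliced
          else setNames(vapply(spliced, `[[`, "", "seq"),
                        vapply(spliced, `[[`, "", "id"))
  vapply(seqs, translate_coding, "")
}

#' Write a distance matrix as a PHYLIP square matrix
#'
#' @param d Symmetric labelled distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.8f", d[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}
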