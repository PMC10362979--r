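# Cohort summary frequencies: per-allele frequencies (per specimen, as in
# field surveys of this gene), per-substitution carrier prevalences
# (RS + RR + RR_mixed), per-site genotype-class counts, and the fraction of
# specimens carrying at least one resistance substitution.

#' Summarise cohort frequencies
#'
#' All counts are exact integer counts over the analysed specimens;
#' percentages are `100 * count / denominator`.  Specimens with `no_call`
#' at a site are excluded from that site's denominator.  Carrier prevalence
#' counts RS, RR and RR_mixed together.  Allele frequency is per specimen;
#' `per_chromosome = TRUE` instead weights RR as 2 and RS as 1 over `2n`
#' chromosomes (for the substitution table).
#'
#' @param assignments `data.frame` from [assign_alleles()].
#' @param calls `data.frame` from [call_genotypes()].
#' @param model An `ace_reference`.
#' @param per_chromosome Report substitution frequencies per chromosome
#'   instead of per specimen (default `FALSE`).
#' @return An `ace_freq_report` list: `n`, `alleles`, `substitutions`,
#'   `genotype_classes`, `n_with_substitution`, `pct_with_substitution`,
#'   `n_sensitive`.
#' @export
summarize_frequencies <- function(assignments, calls, model,
                                  per_chromosome = FALSE) {
  n <- length(unique(assignments$specimen))
  if (n == 0L) stop("empty cohort")

  tab <- table(assignments$allele)
  alleles <- data.frame(
    allele = names(tab), count = as.integer(tab),
    pct = round(100 * as.integer(tab) / n, 2),
    class = assignments$class[match(names(tab), assignments$allele)],
    stringsAsFactors = FALSE)
  alleles <- alleles[order(-alleles$count, alleles$allele), ]
  rownames(alleles) <- NULL

  # substitution-level carriers: one row per (site, resistant residue)
  sub_rows <- list()
  for (s in model$sites) {
    site_calls <- calls[calls$site == s$label, , drop = FALSE]
    called <- site_calls[site_calls$genotype != "no_call", , drop = FALSE]
    denom <- nrow(called)
    for (res in unique(unname(s$resistant))) {
      sub_name <- paste0(s$wildtype_aa, s$residue, res)
      has_res <- vapply(seq_len(nrow(called)), function(i) {
        called$genotype[i] %in% c("RS", "RR", "RR_mixed") &&
          res %in% strsplit(called$aa[i], "/")[[1]]
      }, TRUE)
      count <- sum(has_res)
      if (per_chromosome) {
        copies <- vapply(seq_len(nrow(called)), function(i) {
          if (!has_res[i]) return(0L)
          if (called$genotype[i] == "RR") 2L else 1L
        }, 0L)
        sub_rows[[length(sub_rows) + 1L]] <- data.frame(
          substitution = sub_name, site = s$label, carriers = count,
          denominator = denom, copies = sum(copies),
          pct = round(100 * sum(copies) / (2L * denom), 2),
          stringsAsFactors = FALSE)
      } else {
        sub_rows[[length(sub_rows) + 1L]] <- data.frame(
          substitution = sub_name, site = s$label, carriers = count,
          denominator = denom, pct = round(100 * count / denom, 2),
          stringsAsFactors = FALSE)
      }
    }
  }
  substitutions <- do.call(rbind, sub_rows)
  rownames(substitutions) <- NULL

  geno_tab <- as.data.frame.matrix(table(calls$site, calls$genotype))
  for (g in setdiff(.GENOTYPES, names(geno_tab))) geno_tab[[g]] <- 0L
  geno_tab <- geno_tab[, .GENOTYPES]

  # at least one resistance substitution, judged on the assigned haplotype
  wt <- vapply(model$sites, `[[`, "", "wildtype_aa")
  names(wt) <- vapply(model$sites, function(s) as.character(s$residue), "")
  res_cols <- paste0("res", names(wt))
  has_sub <- vapply(seq_len(nrow(assignments)), function(i) {
    resid <- unlist(assignments[i, res_cols])
    any(resid != wt & resid != "?")
  }, TRUE)
  sens <- assignments$class == "sensitive"

  structure(list(
    n = n,
    alleles = alleles,
    substitutions = substitutions,
    genotype_classes = geno_tab,
    n_with_substitution = sum(has_sub),
    pct_with_substitution = round(100 * sum(has_sub) / n, 2),
    n_sensitive = sum(sens)
  ), class = "ace_freq_report")
}

#' @export
print.ace_freq_report <- function(x, ...) {
  cat("Cohort of", x$n, "specimens\n\n")
  cat("Allele frequencies (per specimen):\n")
  print(x$alleles, row.names = FALSE)
  cat("\nSubstitution carrier prevalence (RS + RR):\n")
  print(x$substitutions, row.names = FALSE)
  cat("\nGenotype classes by site:\n")
  print(x$genotype_classes)
  cat("\nSpecimens with >= 1 substitution:", x$n_with_substitution,
      sprintf("(%.2f%%)", x$pct_with_substitution), "\n")
  cat("Sensitive specimens:", x$n_sensitive, "\n")
  invisible(x)
}
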