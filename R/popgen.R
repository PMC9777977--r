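#' Per-locus allele frequencies
#'
#' For a biallelic locus with genotype counts (N_AA, N_Aa, N_aa),
#' p_A = (2 N_AA + N_Aa) / (2 n) where n is the number of genotyped animals.
#' Genotype frequencies (counts / n) are returned alongside.
#'
#' @param g A `geno_tbl`, or a genotype-count tibble with columns `locus`,
#'   `genotype`, `count` (as [smad_genotype_counts]).
#' @param locus Optional locus name to restrict to.
#' @return Tibble with one row per (locus, allele): `locus`, `allele`, `freq`,
#'   `n_typed`.
#' @examples
#' allele_freqs(smad_genotype_counts, locus = "g.45975G>A")
#' @export
allele_freqs <- function(g, locus = NULL) {
  counts <- as_genotype_counts(g)
  if (!is.null(locus)) {
    if (!locus %in% counts$locus) abort(paste0("Unknown locus: ", locus))
    counts <- counts[counts$locus %in% locus, ]
  }
  counts %>%
    group_by(.data$locus) %>%
    dplyr::group_modify(function(d, key) {
      n_typed <- sum(d$count)
      if (n_typed == 0) abort(paste0("All calls missing at locus ", key$locus))
      alleles <- unlist(strsplit(d$genotype, ""))
      tallies <- tapply(rep(d$count, each = 2) / (2 * n_typed), alleles, sum)
      # keep allele order as in the genotype classes (reference allele first)
      ord <- unique(alleles)
      tibble(allele = ord, freq = as.numeric(tallies[ord]), n_typed = n_typed)
    }) %>%
    ungroup()
}

as_genotype_counts <- function(g) {
  if (inherits(g, "geno_tbl")) return(genotype_counts(g))
  req <- c("locus", "genotype", "count")
  if (!all(req %in% names(g))) {
    abort("Expected a geno_tbl or a count table with columns locus, genotype, count")
  }
  as_tibble(g)
}

pic_from_freqs <- function(p) {
  # Botstein's polymorphism information content
  sum_p2 <- sum(p^2)
  pairs <- if (length(p) > 1) combn(p, 2, function(x) 2 * x[1]^2 * x[2]^2) else 0
  1 - sum_p2 - sum(pairs)
}

classify_pic <- function(pic) {
  # boundary 0.25 assigned to "moderate", 0.5 and above to "high"
  dplyr::case_when(pic < 0.25 ~ "low", pic < 0.5 ~ "moderate", TRUE ~ "high")
}

#' Per-locus diversity indices
#'
#' Expected homozygosity Ho = sum p_i^2, heterozygosity He = 1 - Ho, effective
#' allele number Ne = 1 / Ho, and Botstein's polymorphism information content
#' PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2, all from allele frequencies
#' (Ho is the expected homozygosity under random mating, not the observed
#' homozygote fraction). PIC below 0.25 is classed `low`, 0.25 to below 0.5
#' `moderate`, 0.5 and above `high`.
#'
#' @inheritParams allele_freqs
#' @return Tibble with columns `locus`, `n_typed`, `ho`, `he`, `ne`, `pic`,
#'   `pic_class`.
#' @examples
#' diversity_stats(smad_genotype_counts)
#' @export
diversity_stats <- function(g, locus = NULL) {
  allele_freqs(g, locus) %>%
    group_by(.data$locus) %>%
    summarise(
      n_typed = .data$n_typed[1],
      ho = sum(.data$freq^2),
      he = 1 - ho,
      ne = 1 / ho,
      pic = pic_from_freqs(.data$freq),
      .groups = "drop"
    ) %>%
    mutate(pic_class = classify_pic(.data$pic)) %>%
    # keep input locus order rather than alphabetical
    arrange(match(.data$locus, unique(as_genotype_counts(g)$locus)))
}

#' Hardy-Weinberg equilibrium tests for biallelic loci
#'
#' The chi-square test compares observed genotype counts with expectations
#' p^2 n, 2pq n, q^2 n from the observed allele frequencies (df = number of
#' genotype classes with positive expectation minus number of segregating
#' alleles; 1 for a segregating biallelic locus). The exact test is the
#' conditional test on the observed allele counts: the probability of each
#' possible heterozygote count is enumerated and the p-value sums the
#' probabilities of all configurations no more probable than the observed one.
#'
#' @inheritParams allele_freqs
#' @return Tibble with one row per locus: `locus`, `n_typed`, `chi2`, `df`,
#'   `p_chi2`, `p_exact`, plus expected counts in `expected` (list column).
#'   Monomorphic loci return NA statistics.
#' @examples
#' hwe_test(smad_genotype_counts, locus = "g.45975G>A")
#' @export
hwe_test <- function(g, locus = NULL) {
  counts <- as_genotype_counts(g)
  if (!is.null(locus)) counts <- counts[counts$locus %in% locus, ]
  purrr::map_dfr(unique(counts$locus), function(lc) {
    d <- counts[counts$locus == lc, ]
    if (nrow(d) != 3) abort(paste0("Locus ", lc, ": expected 3 biallelic genotype classes"))
    obs <- d$count
    n <- sum(obs)
    n_het <- obs[2]
    n_a <- 2 * obs[1] + n_het
    p <- n_a / (2 * n)
    q <- 1 - p
    if (p == 0 || q == 0) {
      return(tibble(locus = lc, n_typed = n, chi2 = NA_real_, df = NA_integer_,
                    p_chi2 = NA_real_, p_exact = NA_real_,
                    expected = list(setNames(c(p^2, 2 * p * q, q^2) * n, d$genotype))))
    }
    expected <- c(p^2, 2 * p * q, q^2) * n
    if (any(expected == 0 & obs > 0)) {
      abort(paste0("Locus ", lc, ": observed genotypes in a class with zero expectation"))
    }
    keep <- expected > 0
    chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep])
    df <- as.integer(sum(keep) - 2L)
    p_chi2 <- pchisq(chi2, df = df, lower.tail = FALSE)
    tibble(locus = lc, n_typed = n, chi2 = chi2, df = df, p_chi2 = p_chi2,
           p_exact = hwe_exact_p(n_het, n_a, n),
           expected = list(setNames(expected, d$genotype)))
  })
}

# Exact conditional HWE p-value: full enumeration over heterozygote counts
# compatible with the minor-allele count, probabilities via log factorials.
hwe_exact_p <- function(n_het, n_a, n) {
  n_minor <- min(n_a, 2 * n - n_a)
  het_values <- seq(n_minor %% 2, n_minor, by = 2)
  log_prob <- vapply(het_values, function(h) {
    n_hom_minor <- (n_minor - h) / 2
    n_hom_major <- n - h - n_hom_minor
    lgamma(n + 1) - lgamma(n_hom_minor + 1) - lgamma(h + 1) - lgamma(n_hom_major + 1) +
      h * log(2) +
      lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(log_prob - max(log_prob))
  prob <- prob / sum(prob)
  p_obs <- prob[het_values == n_het]
  sum(prob[prob <= p_obs + 1e-12])
}

#' One-stop per-locus population-genetic summary
#'
#' Combines genotype counts, allele frequencies, diversity indices and both
#' Hardy-Weinberg tests into one row per locus, full precision. Use
#' [write_popgen_report()] for the rounded, publication-style table.
#'
#' @inheritParams allele_freqs
#' @return Tibble with one row per locus.
#' @examples
#' popgen_summary(smad_genotype_counts)
#' @export
popgen_summary <- function(g, locus = NULL) {
  counts <- as_genotype_counts(g)
  if (!is.null(locus)) counts <- counts[counts$locus %in% locus, ]
  freqs <- allele_freqs(counts)
  wide_counts <- counts %>%
    group_by(.data$locus) %>%
    summarise(genotype_counts = paste0(.data$genotype, "=", .data$count, collapse = ", "),
              .groups = "drop")
  freq_wide <- freqs %>%
    group_by(.data$locus) %>%
    summarise(p_ref = .data$freq[1],
              p_alt = if (dplyr::n() > 1) .data$freq[2] else 0,
              .groups = "drop")
  div <- diversity_stats(counts)
  hwe <- hwe_test(counts) %>% select(-"expected", -"n_typed")
  out <- div %>%
    left_join(wide_counts, by = "locus") %>%
    left_join(freq_wide, by = "locus") %>%
    left_join(hwe, by = "locus")
  if ("gene" %in% names(counts)) {
    out <- dplyr::relocate(
      mutate(out, gene = counts$gene[match(out$locus, counts$locus)]), "gene")
  }
  out
}
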