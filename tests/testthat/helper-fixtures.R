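# Fixture builders and independent oracles shared across the suite.

make_geno <- function(..., loci = NULL) {
  # make_geno(`g.10729C>T` = c("CC","CT",NA), ...)
  cols <- list(...)
  n <- length(cols[[1]])
  df <- tibble::tibble(sample = sprintf("e%02d", seq_len(n)), !!!cols)
  genotype_table(df, loci)
}

# Exact conditional HWE p-value by direct enumeration with plain factorials
# (independent of the package's log-gamma implementation; n <= 50).
oracle_hwe_exact <- function(n_aa, n_het, n_bb) {
  n <- n_aa + n_het + n_bb
  n_a <- 2 * n_aa + n_het
  n_minor <- min(n_a, 2 * n - n_a)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- sapply(hets, function(h) {
    hom_minor <- (n_minor - h) / 2
    hom_major <- n - h - hom_minor
    (factorial(n) / (factorial(hom_minor) * factorial(h) * factorial(hom_major))) *
      2^h * factorial(n_minor) * factorial(2 * n - n_minor) / factorial(2 * n)
  })
  probs <- probs / sum(probs)
  p_obs <- probs[hets == n_het]
  sum(probs[probs <= p_obs + 1e-12])
}

# Brute-force MLE of 2-locus haplotype frequencies on a 1-D grid.
# At any stationary point of the phase-ambiguous likelihood the haplotype
# margins equal the observed allele frequencies (only double heterozygotes
# are phase-ambiguous and both phasings share the same margins), so the
# likelihood is maximised over the single free parameter p_AB.
oracle_ld_grid <- function(g, loci, step = 1e-5) {
  info <- loci_info(g)
  calls <- as.data.frame(g)[, loci]
  complete <- stats::complete.cases(calls)
  calls <- calls[complete, ]
  ref <- info$ref_allele[match(loci, info$locus)]
  n_ref <- sapply(1:2, function(k) {
    sum(sapply(strsplit(calls[[k]], ""), function(a) sum(a == ref[k])))
  })
  n <- nrow(calls)
  p_a <- n_ref[1] / (2 * n)
  p_b <- n_ref[2] / (2 * n)
  lo <- max(0, p_a + p_b - 1)
  hi <- min(p_a, p_b)
  grid <- seq(lo, hi, by = step)
  # tabulate samples by (ref-allele dose at locus 1, dose at locus 2)
  dose <- sapply(1:2, function(k) {
    sapply(strsplit(calls[[k]], ""), function(a) sum(a == ref[k]))
  })
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[dose[i, 1] + 1, dose[i, 2] + 1] <- tab[dose[i, 1] + 1, dose[i, 2] + 1] + 1
  f_AB <- grid
  f_Ab <- p_a - grid
  f_aB <- p_b - grid
  f_ab <- 1 - p_a - p_b + grid
  lik_class <- function(da, db) {
    # genotype-class likelihood given ref-allele doses (0,1,2) at each locus
    if (da == 1 && db == 1) return(2 * f_AB * f_ab + 2 * f_Ab * f_aB)
    h_a1 <- if (da >= 1) "A" else "a"; h_a2 <- if (da == 2) "A" else "a"
    h_b1 <- if (db >= 1) "B" else "b"; h_b2 <- if (db == 2) "B" else "b"
    f <- list(AB = f_AB, Ab = f_Ab, aB = f_aB, ab = f_ab)
    h1 <- paste0(h_a1, h_b1); h2 <- paste0(h_a2, h_b2)
    (if (h1 == h2) 1 else 2) * f[[h1]] * f[[h2]]
  }
  loglik <- numeric(length(grid))
  for (da in 0:2) for (db in 0:2) {
    if (tab[da + 1, db + 1] == 0) next
    loglik <- loglik + tab[da + 1, db + 1] * log(pmax(lik_class(da, db), 1e-300))
  }
  best <- grid[which.max(loglik)]
  c(AB = best, Ab = p_a - best, aB = p_b - best, ab = 1 - p_a - p_b + best)
}

# Balanced minimum-evolution (Pauplin) tree length of each of the three
# unrooted 4-taxon topologies; NJ provably picks the topology minimising it.
oracle_bme_split <- function(d) {
  stopifnot(nrow(d) == 4)
  score <- function(i, j) {
    # topology pairing taxa (i,j) | rest
    rest <- setdiff(1:4, c(i, j))
    (d[i, j] + d[rest[1], rest[2]]) / 2 +
      (d[i, rest[1]] + d[i, rest[2]] + d[j, rest[1]] + d[j, rest[2]]) / 4
  }
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  scores <- sapply(splits, function(s) score(s[1], s[2]))
  splits[[which.min(scores)]]
}

# the cherry containing taxon 1 in an unrooted 4-taxon phylo tree
tree_split_with_taxon1 <- function(tr, labels) {
  stopifnot(inherits(tr, "phylo"))
  tr <- ape::unroot(tr)
  # the internal edge partitions the taxa 2|2; find taxon 1's partner
  for (other in 2:4) {
    cand <- labels[c(1, other)]
    rest <- setdiff(labels, cand)
    if (ape::is.monophyletic(tr, cand) || ape::is.monophyletic(tr, rest)) {
      return(c(1, other))
    }
  }
  stop("no 2|2 split found")
}

expect_no_shared_letter <- function(l1, l2) {
  expect_length(intersect(strsplit(l1, "")[[1]], strsplit(l2, "")[[1]]), 0)
}

expect_shared_letter <- function(l1, l2) {
  expect_gt(length(intersect(strsplit(l1, "")[[1]], strsplit(l2, "")[[1]])), 0)
}
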