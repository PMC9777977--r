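#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Standard gene-counting EM for 2-4 linked biallelic loci. Each sample's
#' unphased multi-locus genotype is compatible with a set of haplotype pairs
#' (2^(h-1) unordered pairs for h heterozygous loci). The E-step distributes
#' each sample over its compatible pairs in proportion to the current
#' frequency products (a double heterozygote whose two phasings are equally
#' likely contributes weight 0.5 to each); the M-step re-estimates haplotype
#' frequencies from the expected gamete counts. Initialisation is the uniform
#' distribution over compatible haplotypes, so the algorithm is deterministic.
#' The log-likelihood is non-decreasing across iterations by construction and
#' is checked at every step.
#'
#' Samples missing a call at any requested locus are dropped (listwise
#' deletion, reported via a message).
#'
#' @param g A `geno_tbl`.
#' @param loci Character vector of 2-4 locus names, in map order.
#' @param tol Convergence tolerance on the maximum absolute change in any
#'   haplotype frequency (default 1e-8).
#' @param max_iter Iteration cap (default 1000); hitting it returns
#'   `converged = FALSE` rather than raising.
#' @return An object of class `hap_em`: list with `loci`, `haplotypes`
#'   (tibble `haplotype`, `freq`), `log_likelihood`, `n_iter`, `converged`,
#'   `n_used`, `n_dropped`, and the per-iteration `log_lik_trace`.
#' @export
em_haplotypes <- function(g, loci, tol = 1e-8, max_iter = 1000) {
  if (length(loci) < 2 || length(loci) > 4) {
    abort("em_haplotypes() supports 2 to 4 loci")
  }
  info <- loci_info(g)
  missing_loci <- setdiff(loci, info$locus)
  if (length(missing_loci) > 0) {
    abort(paste0("Loci not in genotype table: ", paste(missing_loci, collapse = ", ")))
  }
  calls <- as.matrix(as_tibble(g)[, loci, drop = FALSE])
  complete <- stats::complete.cases(calls)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) inform(paste0(n_dropped, " sample(s) dropped for missing calls"))
  calls <- calls[complete, , drop = FALSE]
  n <- nrow(calls)
  if (n == 0) abort("No samples with complete calls at the requested loci")

  pairs_by_sample <- lapply(seq_len(n), function(i) compatible_pairs(calls[i, ]))
  # collapse identical genotype patterns to unique patterns with multiplicities
  keys <- vapply(pairs_by_sample, function(p) paste(p$h1, p$h2, collapse = ";"),
                 character(1))
  uk <- !duplicated(keys)
  patterns <- pairs_by_sample[uk]
  weights <- as.numeric(table(keys)[keys[uk]])

  haps <- sort(unique(unlist(lapply(patterns, function(p) c(p$h1, p$h2)))))
  freq <- setNames(rep(1 / length(haps), length(haps)), haps)

  log_lik <- function(f) {
    sum(weights * vapply(patterns, function(p) {
      log(sum(p$mult * f[p$h1] * f[p$h2]))
    }, numeric(1)))
  }

  ll_trace <- log_lik(freq)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    counts <- setNames(numeric(length(haps)), haps)
    for (j in seq_along(patterns)) {
      p <- patterns[[j]]
      w <- p$mult * freq[p$h1] * freq[p$h2]
      tw <- sum(w)
      if (tw == 0) next
      w <- weights[j] * w / tw
      for (k in seq_along(w)) {
        counts[p$h1[k]] <- counts[p$h1[k]] + w[k]
        counts[p$h2[k]] <- counts[p$h2[k]] + w[k]
      }
    }
    new_freq <- counts / (2 * n)
    delta <- max(abs(new_freq - freq))
    freq <- new_freq
    ll <- log_lik(freq)
    if (ll < ll_trace[length(ll_trace)] - 1e-9) {
      abort("EM log-likelihood decreased; this indicates a bug")
    }
    ll_trace <- c(ll_trace, ll)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  structure(list(
    loci = loci,
    haplotypes = tibble(haplotype = names(freq), freq = as.numeric(freq)) %>%
      arrange(dplyr::desc(.data$freq)),
    log_likelihood = ll_trace[length(ll_trace)],
    n_iter = iter,
    converged = converged,
    n_used = n,
    n_dropped = n_dropped,
    log_lik_trace = ll_trace
  ), class = "hap_em")
}

# all unordered haplotype pairs compatible with one sample's unphased calls;
# mult = 2 for heterozygous (distinguishable-order) pairs, 1 for homozygous
compatible_pairs <- function(calls) {
  alleles <- strsplit(calls, "")
  het <- vapply(alleles, function(a) a[1] != a[2], logical(1))
  n_het <- sum(het)
  if (n_het <= 1) {
    h1 <- vapply(alleles, `[`, character(1), 1)
    h2 <- vapply(alleles, `[`, character(1), 2)
    return(list(h1 = paste(h1, collapse = ""), h2 = paste(h2, collapse = ""),
                mult = if (n_het == 1) 2 else 1))
  }
  # fix the first het locus's assignment to enumerate unordered pairs once
  choice_loci <- which(het)[-1]
  grid <- expand.grid(rep(list(c(1L, 2L)), length(choice_loci)))
  h1 <- character(nrow(grid)); h2 <- character(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    pick <- rep(1L, length(calls))
    pick[choice_loci] <- as.integer(grid[r, ])
    a1 <- mapply(function(a, k) a[k], alleles, pick)
    a2 <- mapply(function(a, k) a[3 - k], alleles, pick)
    h1[r] <- paste(a1, collapse = "")
    h2[r] <- paste(a2, collapse = "")
  }
  list(h1 = h1, h2 = h2, mult = rep(2, length(h1)))
}

#' @export
print.hap_em <- function(x, ...) {
  cat("<hap_em> ", length(x$loci), " loci (", paste(x$loci, collapse = ", "), "), ",
      x$n_used, " samples\n", sep = "")
  cat("logLik ", format(x$log_likelihood), "; ", x$n_iter, " iterations; converged: ",
      x$converged, "\n", sep = "")
  print(x$haplotypes, ...)
  invisible(x)
}

#' @rdname em_haplotypes
#' @param x A `hap_em` object.
#' @param ... Unused.
#' @export
tidy.hap_em <- function(x, ...) x$haplotypes

#' @rdname em_haplotypes
#' @export
glance.hap_em <- function(x, ...) {
  tibble(n_loci = length(x$loci), n_haplotypes = nrow(x$haplotypes),
         log_likelihood = x$log_likelihood, n_iter = x$n_iter,
         converged = x$converged, n_used = x$n_used, n_dropped = x$n_dropped)
}

ld_from_hap_freqs <- function(freq, ref1, ref2) {
  # freq: named vector over 2-character haplotypes; alleles coded by letters
  a1 <- substr(names(freq), 1, 1)
  a2 <- substr(names(freq), 2, 2)
  p_a <- sum(freq[a1 == ref1])
  p_b <- sum(freq[a2 == ref2])
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    return(tibble(D = NA_real_, dprime = NA_real_, r2 = NA_real_, monomorphic = TRUE))
  }
  p_ab <- sum(freq[a1 == ref1 & a2 == ref2])
  D <- p_ab - p_a * p_b
  d_max <- if (D >= 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
           else        min(p_a * p_b, (1 - p_a) * (1 - p_b))
  dprime <- if (D == 0) 0 else abs(D) / d_max
  r2 <- D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  tibble(D = D, dprime = dprime, r2 = r2, monomorphic = FALSE)
}

#' Pairwise linkage disequilibrium
#'
#' Estimates two-locus haplotype frequencies by [em_haplotypes()] and derives
#' D = p_AB - p_A p_B, the normalised D' = |D| / Dmax (1 whenever at most
#' three of the four gametes occur), and r^2. Alleles are coded with the
#' reference allele of each locus as "A"/"B". Pairs involving a monomorphic
#' locus are returned flagged with NA statistics rather than raising.
#'
#' @param g A `geno_tbl`.
#' @param loci Loci to include (default: all loci in `g`); all unordered pairs
#'   are evaluated in input order.
#' @param ... Passed to [em_haplotypes()].
#' @return Tibble with columns `locus1`, `locus2`, `D`, `dprime`,
#'   `dprime_pct` (integer percent, as LD heatmaps display it), `r2`,
#'   `monomorphic`.
#' @export
pairwise_ld <- function(g, loci = NULL, ...) {
  info <- loci_info(g)
  loci <- loci %||% info$locus
  if (length(loci) < 2) abort("Need at least 2 loci")
  pairs <- combn(loci, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    l1 <- pairs[1, k]; l2 <- pairs[2, k]
    em <- em_haplotypes(g, c(l1, l2), ...)
    freq <- setNames(em$haplotypes$freq, em$haplotypes$haplotype)
    ref1 <- info$ref_allele[info$locus == l1]
    ref2 <- info$ref_allele[info$locus == l2]
    stats <- ld_from_hap_freqs(freq, ref1, ref2)
    bind_cols(tibble(locus1 = l1, locus2 = l2), stats) %>%
      mutate(dprime_pct = ifelse(is.na(.data$dprime), NA_integer_,
                                 as.integer(round_half_up(100 * .data$dprime, 0))))
  })
}

#' Linkage-disequilibrium blocks by a D' threshold rule
#'
#' Groups contiguous loci of one gene into blocks: adjacent locus pairs with
#' D' at or above the threshold are chained greedily (the published blocks are
#' "completely linked", so the default threshold of 0.98 tolerates only
#' sampling noise). This intentionally replaces confidence-interval block
#' definitions: with complete linkage the two rules agree and the threshold
#' rule is transparent. Each block's haplotype frequencies are re-estimated by
#' EM over all member loci and filtered at a reporting threshold.
#'
#' @param g A `geno_tbl` whose locus annotation carries a `gene` column.
#' @param gene Gene symbol to scan.
#' @param dprime_threshold Minimum adjacent-pair D' (fraction; values > 1 are
#'   read as percent). Default 0.98.
#' @param report_threshold Haplotypes below this frequency are dropped from
#'   the report (default 0.01).
#' @param ... Passed to [em_haplotypes()].
#' @return Tibble with one row per block: `gene`, `block`, `loci` (list
#'   column), `n_loci`, `haplotypes` (list column of tibbles), `converged`.
#'   Zero rows when no adjacent pair qualifies.
#' @export
find_blocks <- function(g, gene, dprime_threshold = 0.98, report_threshold = 0.01, ...) {
  if (dprime_threshold > 1) dprime_threshold <- dprime_threshold / 100
  info <- loci_info(g)
  gene_loci <- info$locus[!is.na(info$gene) & info$gene == gene]
  if (length(gene_loci) < 2) abort(paste0("Need >= 2 annotated loci for gene ", gene))
  adj <- purrr::map_dfr(seq_len(length(gene_loci) - 1), function(i) {
    pairwise_ld(g, gene_loci[i:(i + 1)], ...)
  })
  qualifies <- !is.na(adj$dprime) & adj$dprime >= dprime_threshold
  runs <- rle(qualifies)
  blocks <- list()
  pos <- 1L
  for (r in seq_along(runs$lengths)) {
    if (runs$values[r]) {
      members <- gene_loci[pos:(pos + runs$lengths[r])]
      blocks[[length(blocks) + 1]] <- members
    }
    pos <- pos + runs$lengths[r]
  }
  if (length(blocks) == 0) {
    return(tibble(gene = character(), block = integer(), loci = list(),
                  n_loci = integer(), haplotypes = list(), converged = logical()))
  }
  purrr::map_dfr(seq_along(blocks), function(b) {
    members <- blocks[[b]]
    # EM caps at 4 loci; longer runs are split into consecutive 4-locus chunks
    chunks <- split(members, ceiling(seq_along(members) / 4))
    purrr::map_dfr(seq_along(chunks), function(ci) {
      em <- em_haplotypes(g, chunks[[ci]], ...)
      tibble(gene = gene, block = b,
             loci = list(chunks[[ci]]), n_loci = length(chunks[[ci]]),
             haplotypes = list(dplyr::filter(em$haplotypes, .data$freq >= report_threshold)),
             converged = em$converged)
    })
  }) %>% mutate(block = dplyr::dense_rank(.data$block))
}

#' D' heatmap of all locus pairs
#'
#' @param g A `geno_tbl`.
#' @param loci Optional subset/order of loci.
#' @return A ggplot: lower-triangle tile plot annotated with D' in percent.
#' @export
plot_ld_matrix <- function(g, loci = NULL) {
  ld <- pairwise_ld(g, loci)
  ord <- loci %||% loci_info(g)$locus
  ld$locus1 <- factor(ld$locus1, levels = ord)
  ld$locus2 <- factor(ld$locus2, levels = ord)
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$locus1, y = .data$locus2,
                                   fill = .data$dprime)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$dprime_pct), "-",
                                                   .data$dprime_pct)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "grey85",
                                 name = "D'") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
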