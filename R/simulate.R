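#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generator. Defaults emulate
#' the study flock: 433 ewes, allele frequencies from the bundled genotype
#' counts, Hardy-Weinberg proportions (F = 0), parities uniform over 1-3, a
#' baseline twin probability of 0.07 (litter sizes concentrated at 1 with
#' occasional twins, matching per-genotype means of about 1.07), and a
#' 13-tissue x 3-animal x 3-replicate Ct design with a flat reference gene.
#'
#' Every stochastic operation derives its own stream seed from the master
#' `seed` by a fixed offset (genotypes +1, phenotypes +2, Ct +3, sequences
#' +4), so adding a later stage never perturbs earlier draws.
#'
#' @param n_samples Number of ewes.
#' @param loci Tibble with columns `locus` and `p_ref` (reference-allele
#'   frequency), plus optionally `gene`; default: frequencies computed from
#'   [smad_genotype_counts].
#' @param haplotype_pools Optional named list: each element a named numeric
#'   vector of haplotype frequencies over a block of loci (names of the list
#'   element's `loci` attribute give the member loci); block loci are drawn as
#'   two haplotypes per ewe and collapsed to unphased genotypes.
#' @param inbreeding_f Inbreeding-like departure from Hardy-Weinberg
#'   proportions: P(AA) = p^2 + Fpq, P(Aa) = 2pq(1-F) (default 0).
#' @param parity_probs Probabilities of parities 1-3.
#' @param twin_prob Baseline twin probability (litter size = 1 + Bernoulli).
#' @param genotype_effects Named list per locus: named numeric vector of
#'   additive twin-probability offsets per genotype.
#' @param parity_effects Numeric length-3 twin-probability offsets per parity.
#' @param interaction_effects Optional function(genotype, parity) -> offset.
#' @param tissues,n_animals,n_replicates Ct design.
#' @param ct_reference_mean Reference-gene Ct, flat across tissues.
#' @param ct_target_means Named list per target gene: named numeric vector of
#'   per-tissue mean Ct (lower = more expressed); a scalar is recycled.
#' @param animal_sd,replicate_sd Between-animal and technical-replicate SDs
#'   on the Ct scale.
#' @param seed Master seed (mandatory for any stochastic call).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 433,
                       loci = NULL,
                       haplotype_pools = NULL,
                       inbreeding_f = 0,
                       parity_probs = c(1 / 3, 1 / 3, 1 / 3),
                       twin_prob = 0.07,
                       genotype_effects = list(),
                       parity_effects = c(0, 0, 0),
                       interaction_effects = NULL,
                       tissues = c("hypothalamus", "pituitary", "heart", "liver",
                                   "spleen", "lung", "kidney", "ovary", "uterus",
                                   "oviduct", "rumen", "duodenum", "longissimus dorsi"),
                       n_animals = 3,
                       n_replicates = 3,
                       ct_reference_mean = 18,
                       ct_target_means = NULL,
                       animal_sd = 0.2,
                       replicate_sd = 0.15,
                       seed = 1L) {
  if (is.null(loci)) {
    af <- allele_freqs(smad_genotype_counts)
    loci <- af %>%
      group_by(.data$locus) %>%
      summarise(p_ref = .data$freq[1], .groups = "drop") %>%
      mutate(gene = smad_loci$gene[match(.data$locus, smad_loci$locus)]) %>%
      arrange(match(.data$locus, smad_loci$locus))
  }
  stopifnot(abs(sum(parity_probs) - 1) < 1e-9)
  cfg <- list(n_samples = n_samples, loci = loci, haplotype_pools = haplotype_pools,
              inbreeding_f = inbreeding_f, parity_probs = parity_probs,
              twin_prob = twin_prob, genotype_effects = genotype_effects,
              parity_effects = parity_effects, interaction_effects = interaction_effects,
              tissues = tissues, n_animals = n_animals, n_replicates = n_replicates,
              ct_reference_mean = ct_reference_mean, ct_target_means = ct_target_means,
              animal_sd = animal_sd, replicate_sd = replicate_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

stream_seed <- function(cfg, offset) cfg$seed + offset

#' Simulate unphased genotypes
#'
#' Independent loci are drawn genotype-wise with P(AA) = p^2 + Fpq,
#' P(Aa) = 2pq(1 - F), P(aa) = q^2 + Fpq. Loci belonging to a haplotype pool
#' are drawn as two haplotypes per ewe from the pool and collapsed to
#' unphased genotypes, giving the blocks the linkage structure the pool
#' implies.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_table()] with samples `ewe001`, ...
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  f <- cfg$inbreeding_f
  withr::with_seed(stream_seed(cfg, 1L), {
    n <- cfg$n_samples
    samples <- sprintf("ewe%03d", seq_len(n))
    cols <- list()
    pool_loci <- unlist(lapply(cfg$haplotype_pools, function(p) attr(p, "loci")))
    for (i in seq_len(nrow(cfg$loci))) {
      lc <- cfg$loci$locus[i]
      if (lc %in% pool_loci) next
      p <- cfg$loci$p_ref[i]
      q <- 1 - p
      if (f < -min(p, q) / max(p, q) - 1e-12 || f > 1) {
        abort(paste0("Infeasible inbreeding coefficient for p = ", p))
      }
      al <- parse_locus_alleles(lc)
      probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
      gclass <- c(paste0(al["ref"], al["ref"]), paste0(al["ref"], al["alt"]),
                  paste0(al["alt"], al["alt"]))
      cols[[lc]] <- sample(gclass, n, replace = TRUE, prob = probs)
    }
    for (pool in cfg$haplotype_pools) {
      members <- attr(pool, "loci")
      stopifnot(!is.null(members), abs(sum(pool) - 1) < 1e-9)
      h1 <- sample(names(pool), n, replace = TRUE, prob = pool)
      h2 <- sample(names(pool), n, replace = TRUE, prob = pool)
      for (k in seq_along(members)) {
        a1 <- substr(h1, k, k)
        a2 <- substr(h2, k, k)
        cols[[members[k]]] <- paste0(a1, a2)  # canonicalised by genotype_table()
      }
    }
    df <- bind_cols(tibble(sample = samples), as_tibble(cols))
    loci_meta <- infer_loci_info(df)
    if ("gene" %in% names(cfg$loci)) {
      loci_meta$gene <- cfg$loci$gene[match(loci_meta$locus, cfg$loci$locus)]
    }
    genotype_table(df, loci_meta)
  })
}

#' Simulate litter-size phenotypes
#'
#' Litter size = 1 + Bernoulli(pi) per ewe, where pi is the baseline twin
#' probability plus additive genotype, parity and interaction offsets on the
#' probability scale (values in the flock are almost always 1 or 2, so a
#' binary twin indicator is the natural generative model even though the
#' association model fits litter size by least squares, mirroring the
#' analysis it emulates). Parities are drawn from the configured
#' distribution.
#'
#' @param g A `geno_tbl` (as from [simulate_genotypes()]).
#' @param cfg A [sim_config()].
#' @return Phenotype tibble (`sample`, `parity`, `litter_size`).
#' @export
simulate_litter <- function(g, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(stream_seed(cfg, 2L), {
    n <- nrow(g)
    parity <- sample(1:3, n, replace = TRUE, prob = cfg$parity_probs)
    pi_twin <- rep(cfg$twin_prob, n) + cfg$parity_effects[parity]
    for (lc in names(cfg$genotype_effects)) {
      if (!lc %in% names(g)) abort(paste0("Effect references unknown locus: ", lc))
      eff <- cfg$genotype_effects[[lc]]
      calls <- g[[lc]]
      known <- calls %in% names(eff)
      pi_twin[known] <- pi_twin[known] + eff[calls[known]]
      if (!is.null(cfg$interaction_effects)) {
        pi_twin <- pi_twin + mapply(cfg$interaction_effects, calls, parity)
      }
    }
    if (any(pi_twin < 0 | pi_twin > 1)) {
      abort("Twin probability outside [0, 1] after applying offsets")
    }
    tibble(sample = g$sample, parity = as.integer(parity),
           litter_size = 1L + stats::rbinom(n, 1, pi_twin))
  })
}

#' Simulate a qPCR Ct table
#'
#' Ct = per-(tissue, gene) mean + animal effect + N(0, replicate SD). The
#' reference gene is flat across tissues by default; target-gene tissue
#' profiles come from `cfg$ct_target_means` (default: one target gene
#' "TARGET" at Ct 24 everywhere).
#'
#' @param cfg A [sim_config()].
#' @param reference Name of the reference gene (default "GAPDH").
#' @return Ct tibble (`animal`, `tissue`, `gene`, `replicate`, `ct`).
#' @export
simulate_ct <- function(cfg, reference = "GAPDH") {
  stopifnot(inherits(cfg, "sim_config"))
  target_means <- cfg$ct_target_means %||% list(TARGET = 24)
  withr::with_seed(stream_seed(cfg, 3L), {
    genes <- c(names(target_means), reference)
    design <- tidyr::expand_grid(
      animal = sprintf("a%d", seq_len(cfg$n_animals)),
      tissue = cfg$tissues,
      gene = genes,
      replicate = seq_len(cfg$n_replicates)
    )
    animal_effect <- setNames(stats::rnorm(cfg$n_animals, 0, cfg$animal_sd),
                              unique(design$animal))
    mean_ct <- function(gene, tissue) {
      if (gene == reference) return(cfg$ct_reference_mean)
      m <- target_means[[gene]]
      if (length(m) == 1 && is.null(names(m))) return(m)
      if (!tissue %in% names(m)) abort(paste0("No Ct mean for tissue ", tissue,
                                              " of gene ", gene))
      m[[tissue]]
    }
    design %>%
      mutate(ct = mapply(mean_ct, .data$gene, .data$tissue) +
               animal_effect[.data$animal] +
               stats::rnorm(dplyr::n(), 0, cfg$replicate_sd))
  })
}

#' Simulate a coding sequence embedded in random flanks
#'
#' Generates an ATG-initiated ORF of the requested length (stop codon
#' included; internal stops excluded) flanked by random sequence, e.g. to
#' exercise ORF discovery on transcripts the size of the SMAD coding regions
#' (1398, 1404, 1278 nt).
#'
#' @param orf_len ORF length in nucleotides, a multiple of 3, >= 6.
#' @param flank Length of each random flank (default 150).
#' @param seed Seed for the sequence stream.
#' @return List with `sequence` (character), `orf_start` (0-based),
#'   `orf_len`, and the encoded `protein`.
#' @export
simulate_cds <- function(orf_len, flank = 150, seed = 1L) {
  if (orf_len %% 3 != 0 || orf_len < 6) abort("orf_len must be a multiple of 3, >= 6")
  withr::with_seed(as.integer(seed) + 4L, {
    stops <- c("TAA", "TAG", "TGA")
    bases <- c("A", "C", "G", "T")
    codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
    sense <- setdiff(codons, stops)
    n_codons <- orf_len / 3 - 2
    body <- sample(sense, n_codons, replace = TRUE)
    orf <- paste0("ATG", paste(body, collapse = ""), sample(stops, 1))
    left <- paste(sample(bases, flank, replace = TRUE), collapse = "")
    right <- paste(sample(bases, flank, replace = TRUE), collapse = "")
    seqn <- paste0(left, orf, right)
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(orf, 1, orf_len - 3))))
    list(sequence = seqn, orf_start = flank, orf_len = orf_len, protein = prot)
  })
}

#' Write a full synthetic study to disk
#'
#' Convenience wrapper: simulates genotypes, phenotypes and a Ct table under
#' one config and writes them as TSV plus a FASTA of synthetic coding
#' sequences, so every analysis stage can be exercised from files.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param orf_lens ORF lengths for the FASTA (default the three SMAD ORF
#'   sizes).
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_study <- function(cfg, dir, orf_lens = c(SMAD1 = 1398, SMAD2 = 1404, SMAD3 = 1278)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- simulate_genotypes(cfg)
  pheno <- simulate_litter(g, cfg)
  ct <- simulate_ct(cfg)
  paths <- list(
    genotypes = file.path(dir, "genotypes.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    ct = file.path(dir, "ct.tsv"),
    fasta = file.path(dir, "synthetic_cds.fasta")
  )
  write_genotype_tsv(g, paths$genotypes)
  readr::write_tsv(pheno, paths$phenotypes, progress = FALSE)
  readr::write_tsv(ct, paths$ct, progress = FALSE)
  fasta_lines <- unlist(purrr::imap(as.list(orf_lens), function(len, nm) {
    cds <- simulate_cds(len, seed = cfg$seed)
    c(paste0(">", nm, "_synthetic orf_start=", cds$orf_start + 1,
             " orf_len=", cds$orf_len), cds$sequence)
  }))
  writeLines(fasta_lines, paths$fasta)
  invisible(paths)
}
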