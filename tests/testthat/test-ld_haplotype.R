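test_that("EM equals direct gamete counting when phase is unambiguous", {
  # nobody heterozygous at more than one locus -> phase known for everyone
  g <- make_geno(
    `g.440G>A`   = c("GG", "GA", "GG", "GG", "AA"),
    `g.10729C>T` = c("CC", "CC", "CT", "TT", "CC")
  )
  em <- em_haplotypes(g, c("g.440G>A", "g.10729C>T"))
  counted <- c(GC = 4, AC = 3, GT = 3) / 10  # reading gametes off the calls
  est <- setNames(em$haplotypes$freq, em$haplotypes$haplotype)
  expect_equal(est[names(counted)], counted, tolerance = 1e-9)
  expect_true(em$converged)
})

test_that("EM matches brute-force likelihood maximisation on small samples", {
  for (seed in c(101, 202, 303)) {
    cfg <- sim_config(
      n_samples = 20,
      loci = tibble::tibble(locus = c("g.5133C>T", "g.18905T>C"),
                            p_ref = c(0.6, 0.7), gene = "SMAD3"),
      seed = seed
    )
    g <- simulate_genotypes(cfg)
    em <- em_haplotypes(g, c("g.5133C>T", "g.18905T>C"), tol = 1e-10)
    grid_mle <- oracle_ld_grid(g, c("g.5133C>T", "g.18905T>C"), step = 1e-5)
    # map allele letters to the oracle's A/B coding (ref = uppercase first)
    est <- setNames(em$haplotypes$freq, em$haplotypes$haplotype)
    key <- c(AB = "CT", Ab = "CC", aB = "TT", ab = "TC")
    for (h in names(key)) {
      got <- if (key[h] %in% names(est)) est[[key[h]]] else 0
      expect_equal(got, unname(grid_mle[h]), tolerance = 1e-4)
    }
  }
})

test_that("EM log-likelihood is monotone and the fit is deterministic", {
  cfg <- sim_config(n_samples = 100,
                    loci = tibble::tibble(locus = c("g.1A>G", "g.2C>T"),
                                          p_ref = c(0.5, 0.5)),
                    seed = 7)
  g <- simulate_genotypes(cfg)
  em1 <- em_haplotypes(g, c("g.1A>G", "g.2C>T"))
  em2 <- em_haplotypes(g, c("g.1A>G", "g.2C>T"))
  expect_true(all(diff(em1$log_lik_trace) >= -1e-9))
  expect_identical(em1$haplotypes, em2$haplotypes)
})

test_that("EM recovers a 4-SNP haplotype pool at flock scale", {
  loci4 <- c("g.18905T>C", "g.18965C>T", "g.21447C>T", "g.21551A>G")
  pool <- c(CCCG = 0.59, CCTG = 0.23, CTCG = 0.20)
  pool <- pool / sum(pool)
  attr(pool, "loci") <- loci4
  cfg <- sim_config(n_samples = 433,
                    loci = tibble::tibble(locus = loci4, p_ref = NA, gene = "SMAD3"),
                    haplotype_pools = list(pool), seed = 19)
  g <- simulate_genotypes(cfg)
  em <- em_haplotypes(g, loci4)
  est <- setNames(em$haplotypes$freq, em$haplotypes$haplotype)
  for (h in names(pool)) {
    expect_lt(abs(unname(est[h]) - unname(pool[h])), 0.03)
  }
})

test_that("EM estimates converge to the generating pool as n grows", {
  loci2 <- c("g.1A>G", "g.2C>T")
  pool <- c(AC = 0.55, AT = 0.15, GC = 0.05, GT = 0.25)
  attr(pool, "loci") <- loci2
  err <- sapply(c(100, 1000), function(n) {
    cfg <- sim_config(n_samples = n,
                      loci = tibble::tibble(locus = loci2, p_ref = NA),
                      haplotype_pools = list(pool), seed = 23)
    em <- em_haplotypes(simulate_genotypes(cfg), loci2)
    est <- setNames(em$haplotypes$freq, em$haplotypes$haplotype)
    max(abs(est[names(pool)] - pool))
  })
  expect_lt(err[1], 0.10)
  expect_lt(err[2], 0.04)
  expect_lt(err[2], err[1])
})

test_that("more than 4 loci or no complete samples are rejected", {
  g <- make_geno(
    `g.1A>G` = c("AA", NA), `g.2C>T` = c(NA, "CC"), `g.3G>A` = c("GG", "GG"),
    `g.4T>C` = c("TT", "TT"), `g.5A>C` = c("AA", "AA")
  )
  expect_error(em_haplotypes(g, loci_info(g)$locus), "2 to 4")
  expect_error(suppressMessages(em_haplotypes(g, c("g.1A>G", "g.2C>T"))),
               "No samples")
})

test_that("D, D' and r2 follow their closed forms", {
  # two complementary haplotypes only
  two <- ovisnp:::ld_from_hap_freqs(c(AB = 0.5, ab = 0.5), "A", "B")
  expect_equal(two$D, 0.25)
  expect_equal(two$dprime, 1)
  expect_equal(two$r2, 1)

  # independence: p_AB = p_A p_B
  ind <- ovisnp:::ld_from_hap_freqs(
    c(AB = 0.35, Ab = 0.35, aB = 0.15, ab = 0.15), "A", "B")
  expect_equal(ind$D, 0, tolerance = 1e-12)
  expect_equal(ind$dprime, 0)
  expect_equal(ind$r2, 0, tolerance = 1e-12)

  # arithmetic case: D = 0.6 - 0.8 * 0.75 = 0
  ar <- ovisnp:::ld_from_hap_freqs(
    c(AB = 0.6, Ab = 0.2, aB = 0.15, ab = 0.05), "A", "B")
  expect_equal(ar$D, 0, tolerance = 1e-12)
  expect_equal(ar$dprime, 0)

  # monomorphic locus: flagged, not an error
  mono <- ovisnp:::ld_from_hap_freqs(c(AB = 0.7, Ab = 0.3), "A", "B")
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$dprime))
})

test_that("D' is 1 whenever a gamete class is absent, and both stats stay in [0,1]", {
  withr::with_seed(99, {
    for (i in 1:25) {
      f3 <- stats::runif(3)
      f3 <- f3 / sum(f3)
      haps <- sample(c("AB", "Ab", "aB", "ab"), 3)
      res <- ovisnp:::ld_from_hap_freqs(setNames(f3, haps), "A", "B")
      expect_equal(res$dprime, 1, tolerance = 1e-9)
      f4 <- stats::runif(4)
      f4 <- f4 / sum(f4)
      res4 <- ovisnp:::ld_from_hap_freqs(
        setNames(f4, c("AB", "Ab", "aB", "ab")), "A", "B")
      expect_true(res4$dprime >= 0 && res4$dprime <= 1 + 1e-9)
      expect_true(res4$r2 >= 0 && res4$r2 <= 1 + 1e-9)
    }
  })
})

test_that("pairwise_ld on data from a two-gamete pool reports complete linkage", {
  loci2 <- c("g.1A>G", "g.2C>T")
  pool <- c(AC = 0.5, GT = 0.5)
  attr(pool, "loci") <- loci2
  cfg <- sim_config(n_samples = 433, loci = tibble::tibble(locus = loci2, p_ref = NA),
                    haplotype_pools = list(pool), seed = 5)
  ld <- pairwise_ld(simulate_genotypes(cfg))
  expect_equal(ld$dprime, 1, tolerance = 1e-6)
  expect_equal(ld$dprime_pct, 100L)
})

test_that("block finding splits at weak adjacent linkage", {
  # two completely linked pairs, independent of each other (the SMAD1 pattern)
  p1 <- c(GC = 0.94, AT = 0.06); attr(p1, "loci") <- c("g.440G>A", "g.10729C>T")
  p2 <- c(TG = 0.29, CA = 0.71); attr(p2, "loci") <- c("g.45823T>C", "g.45975G>A")
  loci <- tibble::tibble(
    locus = c("g.440G>A", "g.10729C>T", "g.45823T>C", "g.45975G>A"),
    p_ref = NA, gene = "SMAD1")
  cfg <- sim_config(n_samples = 433, loci = loci,
                    haplotype_pools = list(p1, p2), seed = 13)
  g <- simulate_genotypes(cfg)
  blocks <- find_blocks(g, "SMAD1")
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$n_loci, c(2L, 2L))
  expect_identical(blocks$loci[[1]], c("g.440G>A", "g.10729C>T"))
  expect_identical(blocks$loci[[2]], c("g.45823T>C", "g.45975G>A"))
  # reported haplotypes: two per block at the pool frequencies
  h1 <- blocks$haplotypes[[1]]
  expect_setequal(h1$haplotype, c("GC", "AT"))
  expect_equal(h1$freq[h1$haplotype == "GC"], 0.94, tolerance = 0.03)

  # independent loci -> no blocks
  cfg_ind <- sim_config(n_samples = 433,
                        loci = dplyr::mutate(loci, p_ref = c(0.6, 0.7, 0.35, 0.55)),
                        seed = 17)
  expect_equal(nrow(find_blocks(simulate_genotypes(cfg_ind), "SMAD1")), 0)

  # threshold 0 is degenerate: one block over all contiguous loci
  all_block <- find_blocks(simulate_genotypes(cfg_ind), "SMAD1",
                           dprime_threshold = 0)
  expect_equal(nrow(all_block), 1)
  expect_equal(all_block$n_loci, 4L)
})

test_that("hap_em tidiers expose frequencies and fit metadata", {
  g <- make_geno(`g.1A>G` = c("AA", "AG", "GG"), `g.2C>T` = c("CC", "CT", "TT"))
  em <- em_haplotypes(g, c("g.1A>G", "g.2C>T"))
  td <- tidy(em)
  expect_named(td, c("haplotype", "freq"))
  expect_equal(sum(td$freq), 1, tolerance = 1e-9)
  gl <- glance(em)
  expect_equal(gl$n_loci, 2L)
  expect_true(gl$converged)
})
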