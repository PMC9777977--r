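make_assoc <- function(genotype, parity, litter) {
  tibble::tibble(sample = sprintf("e%03d", seq_along(genotype)),
                 genotype = genotype, parity = as.integer(parity),
                 litter_size = as.integer(litter))
}

test_that("Type III tests agree with car::Anova on a complete design", {
  cfg <- sim_config(seed = 31, genotype_effects = list("g.14946G>A" = c(GA = 0.1)))
  g <- simulate_genotypes(cfg)
  ph <- simulate_litter(g, cfg)
  assoc <- join_genotypes_phenotypes(g, ph, "g.14946G>A")
  fit <- fit_litter_model(assoc)

  d <- data.frame(genotype = factor(assoc$genotype), parity = factor(assoc$parity),
                  litter_size = assoc$litter_size)
  ref <- car::Anova(lm(litter_size ~ parity * genotype, data = d,
                       contrasts = list(parity = "contr.sum", genotype = "contr.sum")),
                    type = 3)
  td <- tidy(fit)
  expect_equal(td$statistic[td$term == "genotype"], ref["genotype", "F value"],
               tolerance = 1e-10)
  expect_equal(td$statistic[td$term == "parity"], ref["parity", "F value"],
               tolerance = 1e-10)
  expect_equal(td$statistic[td$term == "parity:genotype"],
               ref["parity:genotype", "F value"], tolerance = 1e-10)
  expect_equal(td$df[td$term == "Residuals"],
               as.integer(ref["Residuals", "Df"]))
})

test_that("degenerate and underdetermined designs are handled explicitly", {
  # all litter sizes equal: every F is 0 with p = 1
  flat <- make_assoc(rep(c("CC", "CT"), each = 10), rep(1:2, 10), rep(1, 20))
  fit <- fit_litter_model(flat)
  td <- tidy(fit)
  expect_equal(td$statistic[td$term != "Residuals"], c(0, 0, 0))
  expect_equal(td$p.value[td$term != "Residuals"], c(1, 1, 1))

  # single genotype level is not an association design
  expect_error(fit_litter_model(make_assoc(rep("CC", 10), rep(1:2, 5),
                                           rep(1:2, 5))),
               "genotype_means")

  # an empty parity-by-genotype cell drops interaction columns with a message
  holey <- make_assoc(c(rep("CC", 12), rep("TT", 6)),
                      c(rep(1:3, 4), rep(1, 6)),
                      withr::with_seed(3, rbinom(18, 1, 0.3) + 1))
  expect_message(fit2 <- fit_litter_model(holey), "unestimable")
  expect_gt(length(fit2$dropped), 0)
  expect_true(all(is.finite(tidy(fit2)$statistic[1:2])))
})

test_that("a planted genotype effect is detected at flock scale", {
  # twin-probability offset of 0.2 on the heterozygote; 200 simulations
  n_reject <- 0
  for (seed in 1:200) {
    cfg <- sim_config(seed = seed,
                      genotype_effects = list("g.14946G>A" = c(GA = 0.2)))
    g <- simulate_genotypes(cfg)
    ph <- simulate_litter(g, cfg)
    assoc <- join_genotypes_phenotypes(g, ph, "g.14946G>A")
    p <- tidy(fit_litter_model(assoc)) %>%
      dplyr::filter(term == "genotype") %>% dplyr::pull(p.value)
    if (p < 0.05) n_reject <- n_reject + 1
  }
  expect_gte(n_reject / 200, 0.8)
})

test_that("genotype summaries report n, mean, SD, SEM and zero-rows", {
  a <- make_assoc(rep("CC", 4), rep(1, 4), c(1, 1, 1, 2))
  m <- genotype_means(a, all_genotypes = c("CC", "CT", "TT"))
  cc <- m[m$genotype == "CC", ]
  expect_equal(cc$mean, 1.25)
  expect_equal(cc$sd, 0.5)
  expect_equal(cc$sem, 0.25)
  # absent classes get the report convention 0.00 +/- 0.00
  expect_equal(m$n[m$genotype == "TT"], 0L)
  expect_equal(m$display[m$genotype == "TT"], "0.00 ± 0.00")

  # binomial expectation: twin rate 0.07 in a 417-ewe genotype class
  cfg <- sim_config(n_samples = 417, twin_prob = 0.07, seed = 8,
                    loci = tibble::tibble(locus = "g.10729C>T", p_ref = 1))
  g <- simulate_genotypes(cfg)
  ph <- simulate_litter(g, cfg)
  assoc <- join_genotypes_phenotypes(g, ph, "g.10729C>T")
  m2 <- genotype_means(assoc)
  expect_equal(m2$mean[m2$genotype == "CC"], 1.07, tolerance = 0.03)
})

test_that("compact letter displays separate exactly the significant pairs", {
  # identical groups share a letter
  same <- pairwise_letters(list(g1 = c(1, 1, 2, 2), g2 = c(1, 2, 1, 2)))
  expect_equal(same$letters, c("a", "a"))

  # one clearly separated group gets its own letter
  three <- pairwise_letters(list(
    lo1 = c(10.0, 10.1, 9.9), lo2 = c(10.1, 10.0, 10.2),
    hi = c(50.0, 50.1, 49.9)))
  expect_equal(three$letters[three$group == "hi"], "a")
  expect_shared_letter(three$letters[three$group == "lo1"],
                       three$letters[three$group == "lo2"])
  expect_no_shared_letter(three$letters[three$group == "hi"],
                          three$letters[three$group == "lo1"])

  # the display depends only on the p matrix: permuting input order permutes
  # group rows but yields the same letter partition
  withr::with_seed(12, {
    vals <- list(a = rnorm(8, 0), b = rnorm(8, 0.1), c = rnorm(8, 3), d = rnorm(8, 3.1))
    l1 <- pairwise_letters(vals)
    l2 <- pairwise_letters(vals[c(3, 1, 4, 2)])
    expect_identical(l1[order(l1$group), c("group", "letters")],
                     l2[order(l2$group), c("group", "letters")])
  })
})

test_that("the elevated-TT pattern earns TT a distinct letter", {
  cfg <- sim_config(seed = 41,
                    genotype_effects = list("g.21447C>T" = c(TT = 0.3)))
  g <- simulate_genotypes(cfg)
  ph <- simulate_litter(g, cfg)
  assoc <- join_genotypes_phenotypes(g, ph, "g.21447C>T")
  m <- genotype_means(assoc, all_genotypes = c("CC", "CT", "TT"))
  expect_equal(m$letters[m$genotype == "TT"], "a")
  expect_no_shared_letter(m$letters[m$genotype == "TT"],
                          m$letters[m$genotype == "CC"])
  expect_shared_letter(m$letters[m$genotype == "CC"],
                       m$letters[m$genotype == "CT"])
})

test_that("Welch letters fall back to pooled variance for singleton groups", {
  expect_warning(
    pairwise_letters(list(g1 = c(1, 2, 1), g2 = 5), var = "welch"),
    "falling back"
  )
})

test_that("fit tidiers expose the ANOVA table and fit summary", {
  a <- make_assoc(rep(c("CC", "CT", "TT"), each = 12),
                  rep(1:3, 12), withr::with_seed(4, rbinom(36, 1, 0.2) + 1))
  fit <- fit_litter_model(a)
  expect_named(tidy(fit), c("term", "sumsq", "df", "meansq", "statistic", "p.value"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 36L)
  expect_equal(gl$df.residual + sum(tidy(fit)$df[tidy(fit)$term != "Residuals"]),
               35L)  # n - 1
})
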