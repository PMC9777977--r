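# ovisnp

Tidy candidate-gene SNP analysis for livestock reproductive traits, built
around a litter-size study of the *SMAD1*, *SMAD2* and *SMAD3* genes in a
flock of 433 Tibetan ewes genotyped at ten exonic biallelic SNPs.

Candidate-gene studies of this shape recur across animal breeding: a handful
of SNPs in genes of a known pathway (here TGF-β/SMAD, which regulates
follicle development and ovulation), a lowly heritable count phenotype
(litter size, almost always 1 or 2 lambs), and a qPCR panel of tissue
expression. ovisnp packages every statistical stage of that workflow as
tibble-in/tibble-out functions, so each published table becomes a function
call, and bundles a seeded synthetic-data generator so the whole pipeline is
testable without any external data.

## What it computes

**Per-locus population genetics.** From genotype counts `(N_AA, N_Aa, N_aa)`
with allele frequencies `p, q`: expected homozygosity `Ho = Σpᵢ²`,
heterozygosity `He = 1 − Ho`, effective allele number `Ne = 1/Ho`, and
Botstein's polymorphism information content
`PIC = 1 − Σpᵢ² − Σᵢ<ⱼ 2pᵢ²pⱼ²` (classed low < 0.25 ≤ moderate < 0.5 ≤ high),
plus chi-square and exact conditional Hardy–Weinberg tests.

**Haplotypes and LD.** Gene-counting EM over 2–4 loci for haplotype
frequencies from unphased genotypes; `D = p_AB − p_A p_B`, `D′ = |D|/D_max`,
`r²`; block reports under a documented D′-threshold rule for "completely
linked" loci.

**Litter-size association.** The fixed-effects model
`Y = μ + parity + genotype + parity:genotype + e` by least squares with
Type III F tests, per-genotype means ± SD/SEM, and compact letter displays
from pairwise t tests (`p < 0.05` ⇒ no shared letter).

**Relative expression.** `2^−ΔΔCt` with reference-gene normalisation,
calibrator-tissue rescaling, per-animal folds summarised as mean ± SEM, and
one-way ANOVA tissue comparisons with letters.

**Sequence utilities.** ORF discovery and translation, ProtParam-style
protein parameters (MW, pI, GRAVY, instability, aliphatic index), percent
identity of aligned proteins, and Saitou–Nei neighbor-joining trees.

**Synthetic data.** `sim_config()` defaults encode the study conditions
(433 ewes, the published allele frequencies, twin probability 0.07,
13 tissues × 3 animals × triplicate Ct); all draws are seeded and
bit-reproducible.

## Worked example

The bundled `smad_genotype_counts` table holds the published genotype counts;
one call reproduces the population-genetics table:

```r
library(ovisnp)
library(dplyr)

popgen_summary(smad_genotype_counts) |>
  mutate(across(c(ho, he, ne, pic, chi2, p_chi2, p_exact),
                ~ round_half_up(.x, 2))) |>
  select(gene, locus, ho, he, ne, pic, pic_class, p_chi2, p_exact)
#> # A tibble: 10 × 9
#>    gene  locus         ho    he    ne   pic pic_class p_chi2 p_exact
#>    <chr> <chr>      <dbl> <dbl> <dbl> <dbl> <chr>      <dbl>   <dbl>
#>  1 SMAD1 g.45975G>A  0.75  0.25  1.34  0.22 low         0.1     0.13
#>  2 SMAD1 g.440G>A    0.92  0.08  1.09  0.08 low         0.37    1
#>  3 SMAD1 g.45823T>C  0.63  0.37  1.59  0.3  moderate    0.33    0.36
#>  4 SMAD1 g.10729C>T  0.96  0.04  1.04  0.04 low         0.7     1
#>  5 SMAD2 g.14946G>A  0.58  0.42  1.73  0.33 moderate    0.26    0.31
#>  6 SMAD3 g.21447C>T  0.69  0.31  1.45  0.26 moderate    0.82    1
#>  7 SMAD3 g.5133C>T   0.54  0.46  1.85  0.35 moderate    0.69    0.68
#>  8 SMAD3 g.18965C>T  0.75  0.25  1.34  0.22 low         0.84    0.85
#>  9 SMAD3 g.18905T>C  0.56  0.44  1.79  0.34 moderate    0.45    0.45
#> 10 SMAD3 g.21551A>G  0.56  0.44  1.79  0.34 moderate    0.55    0.59
```

Reading the first row: at g.45975G>A the expected homozygosity is 0.75, so
the locus behaves like 1.34 equifrequent alleles; a PIC of 0.22 makes it a
lowly informative marker; and both Hardy–Weinberg p-values exceed 0.05, so
the genotype distribution is consistent with random mating. Six of the ten
loci are moderately polymorphic, and every locus is in equilibrium — the
qualitative conclusions of the source study.

The association stage runs on individual records. With no phenotypes
deposited, the synthetic generator stands in — here with a planted
twin-probability increase of 0.2 for the rare TT genotype at g.21447C>T,
the pattern reported for that locus:

```r
cfg <- sim_config(seed = 42,
                  genotype_effects = list("g.21447C>T" = c(TT = 0.2)))
g     <- simulate_genotypes(cfg)
ph    <- simulate_litter(g, cfg)
assoc <- join_genotypes_phenotypes(g, ph, "g.21447C>T")

genotype_means(assoc, all_genotypes = c("CC", "CT", "TT"))
#> # A tibble: 3 × 7
#>   genotype     n  mean    sd    sem letters display
#>   <chr>    <int> <dbl> <dbl>  <dbl> <chr>   <chr>
#> 1 CC         278  1.05 0.226 0.0136 b       1.05 ± 0.23
#> 2 CT         139  1.05 0.219 0.0186 b       1.05 ± 0.22
#> 3 TT          16  1.31 0.479 0.120  a       1.31 ± 0.48

tidy(fit_litter_model(assoc))
#> # A tibble: 4 × 6
#>   term             sumsq    df meansq statistic    p.value
#>   <chr>            <dbl> <int>  <dbl>     <dbl>      <dbl>
#> 1 parity           0.130     2 0.0649      1.15  0.319
#> 2 genotype         1.11      2 0.554       9.77  0.0000709
#> 3 parity:genotype  0.250     4 0.0625      1.10  0.355
#> 4 Residuals       24.0     424 0.0566     NA    NA
```

The TT ewes average 1.31 lambs against 1.05 for the carriers of C, the
letter display gives TT its own letter, and the genotype F test rejects —
the planted effect is recovered. `em_haplotypes()`, `pairwise_ld()`,
`find_blocks()`, `relative_expression()`, `tissue_comparison()`,
`find_orfs()`, `protein_params()` and `nj_tree()` cover the remaining stages;
each fitted object has `tidy()`/`glance()` methods and the result types have
`autoplot()`/`plot_*()` figures.

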