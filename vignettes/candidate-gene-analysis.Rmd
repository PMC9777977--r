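---
title: "Candidate-gene SNP analysis of litter size: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene SNP analysis of litter size: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ovisnp implements the complete statistical workflow of a candidate-gene SNP
study of litter size in Tibetan sheep: ten exonic biallelic SNPs in the
*SMAD1*, *SMAD2* and *SMAD3* genes genotyped in 433 ewes, qPCR expression of
the three genes across thirteen tissues, and the sequence-level
characterisation of the cloned coding regions. This vignette explains the
models, the tunable parameters and the design decisions; the README shows the
worked example.

```{r setup}
library(ovisnp)
library(dplyr)
```

## Data model

All user-facing functions take and return tibbles. Genotypes live in a wide
`geno_tbl` (one `sample` column plus one column of diploid calls per locus,
reference allele written first, `NA`/`"NN"` for missing) with locus
annotation carried as an attribute. Calls are unphased and stay unphased
through I/O; phase is only ever *estimated*, inside the EM haplotype module.
Loci are identified by labels such as `g.21447C>T` — no genomic coordinates
are modelled, because the study identifies loci by label only.

The published genotype counts ship as `smad_genotype_counts`;
`counts_to_genotypes()` expands them into individual calls so that published
count tables flow through the same pipeline as raw data. Two loci are
internally inconsistent between the study's own tables (g.45823T>C: 149 vs
159 heterozygotes, totals 423 vs 433; g.5133C>T: 200 vs 190, totals 443 vs
433). Both count sets are bundled and `flag_count_inconsistencies()` surfaces
the disagreement; the package deliberately does not resolve it.

## Per-locus population genetics

With allele frequencies $p_i$ estimated by allele counting, the per-locus
indices are expected homozygosity $Ho = \sum p_i^2$, heterozygosity
$He = 1 - Ho$, effective allele number $Ne = 1/Ho$, and Botstein's
polymorphism information content

$$PIC = 1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2 ,$$

classed low below 0.25, moderate from 0.25 to below 0.5, high at 0.5 and
above (the source text uses strict inequalities on both sides of 0.25, so a
tie rule is required; the boundary is assigned to "moderate"). $Ho$ is the
*expected* homozygosity, not the observed homozygote fraction — the choice is
verifiable from the published numbers, since the observed fraction 318/433 =
0.734 at g.45975G>A does not round to the printed 0.75 while
$\sum p_i^2 = 0.746$ does.

Hardy–Weinberg equilibrium is tested two ways: the classical chi-square
against expectations $(p^2, 2pq, q^2)\,n$ (df = genotype classes with
positive expectation minus segregating alleles; 1 for a biallelic locus), and
the exact conditional test, which enumerates every heterozygote count
compatible with the observed allele counts and sums the probabilities of all
configurations no more probable than the observed one. The published
chi-square column prints values (e.g. 1.00 at a locus whose expected
minor-homozygote count is 0.75) that cannot be reproduced as either a df=1
statistic or its p-value under any reading we tried; both of our p-values are
reported and only the qualitative claim p > 0.05 is asserted in tests.

Report output is rounded to 2 decimals, half away from zero, to mirror the
publication style (`round_half_up()`); full precision is always retained
internally and written to a sidecar by `write_popgen_report()`.

One reproduction caveat found while validating: the printed $Ne$ and $PIC$ at
g.440G>A (1.08 and 0.07) are inconsistent with that locus's own printed
counts — exact computation from 397/36/0 gives 1.0866 and 0.0765, which round
to 1.09 and 0.08. Recomputing from allele frequencies pre-rounded to 2
decimals reproduces those two cells but breaks others (g.45975G>A He,
g.14946G>A Ne), so no single rounding pipeline reproduces the whole printed
table; the package computes from exact frequencies, which reproduces 30 of
the 32 cells for the internally consistent loci. The corresponding acceptance
test intentionally asserts all 32 printed cells and fails on those two.

## Haplotypes and linkage disequilibrium

`em_haplotypes()` is standard gene-counting EM for 2–4 loci: each sample's
unphased genotype is compatible with $2^{h-1}$ unordered haplotype pairs ($h$
= heterozygous loci); the E-step distributes the sample over those pairs in
proportion to current frequency products, the M-step re-estimates frequencies
from expected gamete counts. Initialisation is the uniform distribution over
compatible haplotypes, which makes the fit deterministic; a double
heterozygote whose two phasings are equally likely contributes exactly 0.5 to
each, with no arbitrary assignment. Convergence is declared when no frequency
moves by more than `tol` (default 1e-8, `max_iter` 1000; hitting the cap
returns `converged = FALSE` rather than raising). The log-likelihood is
asserted non-decreasing at every iteration. The 4-locus cap matches the
largest published haplotype span.

Pairwise LD uses the conventional parameterisation: $D = p_{AB} - p_A p_B$,
$D' = |D|/D_{max}$ (1 whenever at most three of the four gametes occur),
$r^2 = D^2 / (p_A p_a p_B p_b)$. Pairs involving a monomorphic locus return a
flagged row with `NA` statistics rather than an error, because simulated and
subset data hit that case routinely.

`find_blocks()` intentionally does **not** reproduce confidence-interval
block definitions from LD software. The published blocks are all "completely
linked", so a transparent rule — chain contiguous loci whose adjacent-pair
$D'$ is at least a threshold — identifies the same structure. The default
threshold of 0.98 (rather than 1.0) tolerates the sampling noise that EM
introduces at finite n even under textbook complete linkage. Missing data are
handled by listwise deletion per block, with a message reporting the count.
The published haplotype tables also print odds-ratio and p-value columns
against an unstated outcome, and block frequencies that do not sum to one;
those cells are not computable from any documented input and are not
reproduction targets.

## The litter-size model

Association uses the study's fixed-effects linear model

$$Y_{ijn} = \mu + P_i + G_j + I_{PG} + e_{ijn}$$

with parity ($i = 1,2,3$), genotype, their interaction, and
$e \sim N(0, \sigma^2)$, fit by ordinary least squares with sum-to-zero
contrasts and Type III F tests (the convention of the GLM software named in
the source). Litter size in this flock is almost always 1 or 2, i.e. a
shifted binary variable; the package nevertheless follows the published
method and fits it by least squares — reproducing the stated analysis is the
point — and the type-I-error simulation in the acceptance suite confirms the
F test holds its nominal size under the null at this n.

Type III sums of squares are computed by estimable-column model comparison:
the full design matrix is built with sum contrasts, columns made unestimable
by empty parity-by-genotype cells are dropped (with a message), and each
term's F compares the retained columns against the model without that term's
columns. On complete designs this equals the classical Type III table, which
the test suite verifies against an independent implementation.

`pairwise_letters()` builds compact letter displays from all pairwise t tests
on a pooled (by default, model-residual) variance, by insert-and-absorb on
groups sorted by descending mean: groups that differ at $\alpha$ share no
letter. Whether the published letters came from interaction-adjusted means or
raw group tests is unstated; both routes are exposed
(`use_model_variance`, `var = "welch"`). Dispersion is reported both as SD
and SEM: the published table's "mean ± x" values are numerically consistent
with SD even though the text says SEM, so `genotype_means()` carries both and
labels which one the display shows. Following the source, p-values across the
ten loci are not multiplicity-corrected.

## Relative expression

`relative_expression()` is the textbook $2^{-\Delta\Delta Ct}$ method:
technical replicates averaged first, $\Delta Ct$ = target − reference per
animal and tissue, $\Delta\Delta Ct$ against the mean $\Delta Ct$ of a
calibrator tissue, fold $= 2^{-\Delta\Delta Ct}$ per animal, summarised as
mean ± SEM over animals (n = 3 in the study design). Amplification efficiency
is fixed at 2; no efficiency correction is described in the source and none
is applied. The source does not name its calibrator, and the choice only
rescales all folds by a common factor, so the default is the
lowest-expression tissue (highest mean $\Delta Ct$), making folds ≥ 1-ish;
any tissue can be set explicitly. Two exact invariances pin the arithmetic
down and are tested to machine precision: adding a constant to every Ct of
both genes changes nothing, and shifting the reference gene alone shifts all
$\Delta Ct$ equally, leaving fold ratios unchanged. The published expression
figure prints no numbers, so only ordering and letter patterns are testable,
never bar heights.

## Sequence utilities

`find_orfs()` scans ATG-to-stop frames under the standard genetic code
(forward strand by default — cDNA input is assumed sense; the reverse
complement sits behind a flag). Coordinates are 0-based half-open; the ORF
length includes the stop codon, so protein length = nt/3 − 1.
`protein_params()` reimplements the ProtParam battery: average-mass molecular
weight, Bjellqvist-pKa isoelectric point by bisection of the net-charge
curve (including the N/C-terminal residue-specific pKa overrides), charged
residue counts, Kyte–Doolittle GRAVY, Guruprasad instability index from the
published dipeptide weight table, and the aliphatic index. The constant
tables are embedded as code with their provenance noted. The actual cloned
sheep sequences are not printed in the source, so its specific protein values
are not desk-reproducible; tests instead freeze reference values computed
once with an independent ProtParam implementation, and the qualitative
classifications (GRAVY < 0 → hydrophilic, instability > 40 → unstable) are
asserted on sequences in that regime.

`nj_tree()` is Saitou–Nei neighbor joining written here because the study's
tree is a method deliverable: Q-criterion ties break on the smallest
(row, column) pair, and negative branch lengths are clamped to zero with the
deficit moved to the sister branch. Tests verify exact recovery on additive
matrices, agreement with an independent NJ implementation, and — on random
4-taxon instances — agreement with exhaustive minimum-evolution topology
scoring.

## The synthetic-data generator

No genotype, phenotype or Ct data were deposited, so the generator is the
package's study stand-in, and its defaults *are* the study conditions: 433
ewes; per-locus allele frequencies taken from the bundled counts;
Hardy–Weinberg proportions (an inbreeding-like `F` is available and defaults
to 0); parities uniform over 1–3 (the source gives no parity distribution;
uniform is the neutral choice); litter size = 1 + Bernoulli($\pi$) with
baseline twin probability 0.07, matching the typical published per-genotype
mean of 1.07; and a 13-tissue × 3-animal × 3-replicate Ct design with a flat
reference gene, replicate SD 0.15 and animal SD 0.2 cycles — values typical
of well-run qPCR. Genotype, parity and interaction effects are additive
offsets on the twin *probability* scale, validated to [0, 1]; this makes a
planted effect equal the group-mean contrast exactly, which is what the
recovery tests measure. Blocked loci are drawn as two haplotypes per ewe from
a stated pool and collapsed to unphased calls.

Each stage derives its own seed from the master seed by a fixed offset
(genotypes +1, phenotypes +2, Ct +3, sequences +4), so adding a stage never
perturbs earlier draws, and identical config + seed is bit-identical.

What the generator does *not* emulate: family structure and relatedness
(ewes are independent draws, whereas a real flock has half-sib structure that
inflates association test sizes), genotyping error and allelic dropout,
repeated records per ewe across parities, and qPCR efficiency differences
between genes. Passing tests therefore demonstrate correctness of the
*methods* under the stated sampling model, not robustness of the study's
conclusions to those real-data features.

## Problem sizes and numerical choices

The simulation-based checks run at the study's own scale where that is cheap
(n = 433 per replicate) and use 500 replicates for the bias check, 1000 for
the type-I-error check, 100 seeds for the expression-ordering check, and 100
random instances for the NJ-vs-exhaustive check — sizes chosen so each
estimate's Monte-Carlo error is comfortably inside the asserted band while
the whole suite stays fast. EM convergence is 1e-8 on frequencies; the
brute-force likelihood oracle uses a 1e-5 grid against a 1e-4 assertion; the
exact HWE enumeration works in log-space to survive flock-scale factorials.
Degenerate inputs are given defined behaviour rather than errors where a
pipeline can plausibly hit them: monomorphic loci (flagged LD, NA HWE),
all-equal litter sizes (F = 0, p = 1), absent genotype classes (zero-rows in
reports), and non-converged EM (`converged = FALSE`).

## Limitations

Published cells that are not functions of any published input — the
association table's means (raw phenotypes undeposited), the haplotype
frequency/OR columns (frequencies don't sum to 1, outcome unstated), the
expression bar heights, and the two inconsistent cells noted above — are
recorded as bundled metadata or flagged, never "reproduced". Identity
percentages depend on alignment parameters the source does not state, so
identity is validated only on self-comparisons and synthetic cases.
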