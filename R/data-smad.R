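#' SMAD candidate-SNP locus annotation
#'
#' The ten exonic biallelic SNPs screened in the SMAD1, SMAD2 and SMAD3 genes
#' of a Tibetan sheep flock of 433 ewes. Locus labels follow the `g.<pos><ref>><alt>`
#' convention; `ref_allele`/`alt_allele` are parsed from the label. Coordinates are
#' not modelled: loci are identified by label only.
#'
#' @format A tibble with one row per locus and columns `gene`, `locus`, `exon`,
#'   `mutation_type`, `ref_allele`, `alt_allele`.
#' @export
smad_loci <- tibble::tribble(
  ~gene,   ~locus,        ~exon, ~mutation_type,
  "SMAD1", "g.45975G>A",  2L,    "synonymous",
  "SMAD1", "g.440G>A",    7L,    "synonymous",
  "SMAD1", "g.45823T>C",  2L,    "synonymous",
  "SMAD1", "g.10729C>T",  5L,    "synonymous",
  "SMAD2", "g.14946G>A",  8L,    "synonymous",
  "SMAD3", "g.21447C>T",  7L,    "synonymous",
  "SMAD3", "g.5133C>T",   4L,    "synonymous",
  "SMAD3", "g.18965C>T",  6L,    "synonymous",
  "SMAD3", "g.18905T>C",  6L,    "missense",
  "SMAD3", "g.21551A>G",  7L,    "synonymous"
)
smad_loci$ref_allele <- sub("^g\\.\\d+([ACGT])>([ACGT])$", "\\1", smad_loci$locus)
smad_loci$alt_allele <- sub("^g\\.\\d+([ACGT])>([ACGT])$", "\\2", smad_loci$locus)

#' Published genotype counts at the SMAD candidate SNPs
#'
#' Genotype counts for the 433-ewe flock as printed in the population-genetics
#' table of the source study. Two loci are internally inconsistent between the
#' published tables: at g.45823T>C the counts sum to 423 here while the
#' association table gives 29/159/245 (sum 433), and at g.5133C>T they sum to
#' 443 versus 184/190/59 (sum 433). The alternate count set is bundled as
#' [smad_genotype_counts_alt]; neither is privileged, and
#' [flag_count_inconsistencies()] reports loci whose counts disagree.
#'
#' @format A tibble with columns `gene`, `locus`, `genotype` (two-letter call,
#'   reference allele first) and `count`.
#' @seealso [smad_genotype_counts_alt], [counts_to_genotypes()]
#' @export
smad_genotype_counts <- tibble::tribble(
  ~gene,   ~locus,        ~genotype, ~count,
  "SMAD1", "g.45975G>A",  "GG", 318L, "SMAD1", "g.45975G>A", "GA", 101L, "SMAD1", "g.45975G>A", "AA", 14L,
  "SMAD1", "g.440G>A",    "GG", 397L, "SMAD1", "g.440G>A",   "GA",  36L, "SMAD1", "g.440G>A",   "AA",  0L,
  "SMAD1", "g.45823T>C",  "TT",  29L, "SMAD1", "g.45823T>C", "TC", 149L, "SMAD1", "g.45823T>C", "CC", 245L,
  "SMAD1", "g.10729C>T",  "CC", 417L, "SMAD1", "g.10729C>T", "CT",  16L, "SMAD1", "g.10729C>T", "TT",  0L,
  "SMAD2", "g.14946G>A",  "GG", 205L, "SMAD2", "g.14946G>A", "GA", 193L, "SMAD2", "g.14946G>A", "AA", 35L,
  "SMAD3", "g.21447C>T",  "CC", 283L, "SMAD3", "g.21447C>T", "CT", 135L, "SMAD3", "g.21447C>T", "TT", 15L,
  "SMAD3", "g.5133C>T",   "CC", 184L, "SMAD3", "g.5133C>T",  "CT", 200L, "SMAD3", "g.5133C>T",  "TT", 59L,
  "SMAD3", "g.18965C>T",  "CC", 315L, "SMAD3", "g.18965C>T", "CT", 108L, "SMAD3", "g.18965C>T", "TT", 10L,
  "SMAD3", "g.18905T>C",  "TT",  50L, "SMAD3", "g.18905T>C", "TC", 184L, "SMAD3", "g.18905T>C", "CC", 199L,
  "SMAD3", "g.21551A>G",  "AA",  50L, "SMAD3", "g.21551A>G", "AG", 186L, "SMAD3", "g.21551A>G", "GG", 197L
)

#' Alternate genotype counts from the association table
#'
#' Genotype counts as printed alongside the per-genotype litter-size means.
#' They agree with [smad_genotype_counts] except at g.45823T>C and g.5133C>T,
#' where the two published tables disagree; both sets are kept so the
#' inconsistency can be surfaced rather than silently resolved.
#'
#' @format Same shape as [smad_genotype_counts].
#' @export
smad_genotype_counts_alt <- {
  x <- smad_genotype_counts
  x$count[x$locus == "g.45823T>C" & x$genotype == "TC"] <- 159L
  x$count[x$locus == "g.5133C>T" & x$genotype == "CT"] <- 190L
  x
}

#' Per-genotype litter-size summaries from the source flock
#'
#' Published per-genotype sample sizes, mean litter sizes and dispersions for
#' the 433 ewes. The raw phenotypes were not deposited, so these summaries are
#' used only to parameterise the synthetic-data generator (typical twin rate
#' about 0.07) and are not a numeric reproduction surface.
#'
#' @format A tibble with columns `gene`, `locus`, `genotype`, `n`, `mean`, `sd`.
#' @export
smad_litter_means <- tibble::tribble(
  ~gene,   ~locus,       ~genotype, ~n,   ~mean, ~sd,
  "SMAD1", "g.45975G>A", "GG", 318L, 1.07, 0.25,
  "SMAD1", "g.45975G>A", "GA", 101L, 1.06, 0.24,
  "SMAD1", "g.45975G>A", "AA",  14L, 1.14, 0.36,
  "SMAD1", "g.440G>A",   "GG", 397L, 1.07, 0.25,
  "SMAD1", "g.440G>A",   "GA",  36L, 1.11, 0.32,
  "SMAD1", "g.440G>A",   "AA",   0L, 0.00, 0.00,
  "SMAD1", "g.45823T>C", "TT",  29L, 1.07, 0.26,
  "SMAD1", "g.45823T>C", "TC", 159L, 1.05, 0.22,
  "SMAD1", "g.45823T>C", "CC", 245L, 1.08, 0.27,
  "SMAD1", "g.10729C>T", "CC", 417L, 1.07, 0.26,
  "SMAD1", "g.10729C>T", "CT",  16L, 1.00, 0.00,
  "SMAD1", "g.10729C>T", "TT",   0L, 0.00, 0.00,
  "SMAD2", "g.14946G>A", "GG", 205L, 1.07, 0.25,
  "SMAD2", "g.14946G>A", "GA", 193L, 1.08, 0.28,
  "SMAD2", "g.14946G>A", "AA",  35L, 1.00, 0.00,
  "SMAD3", "g.21447C>T", "CC", 283L, 1.06, 0.24,
  "SMAD3", "g.21447C>T", "CT", 135L, 1.06, 0.24,
  "SMAD3", "g.21447C>T", "TT",  15L, 1.27, 0.46,
  "SMAD3", "g.5133C>T",  "CC", 184L, 1.09, 0.28,
  "SMAD3", "g.5133C>T",  "CT", 190L, 1.04, 0.20,
  "SMAD3", "g.5133C>T",  "TT",  59L, 1.10, 0.30,
  "SMAD3", "g.18965C>T", "CC", 315L, 1.07, 0.26,
  "SMAD3", "g.18965C>T", "CT", 108L, 1.07, 0.26,
  "SMAD3", "g.18965C>T", "TT",  10L, 1.00, 0.00,
  "SMAD3", "g.18905T>C", "TT",  50L, 1.12, 0.33,
  "SMAD3", "g.18905T>C", "TC", 184L, 1.05, 0.23,
  "SMAD3", "g.18905T>C", "CC", 199L, 1.07, 0.26,
  "SMAD3", "g.21551A>G", "AA",  50L, 1.12, 0.33,
  "SMAD3", "g.21551A>G", "AG", 186L, 1.05, 0.23,
  "SMAD3", "g.21551A>G", "GG", 197L, 1.07, 0.26
)

#' Flag loci whose published genotype counts are inconsistent
#'
#' Compares two genotype-count tables (by default the two published count sets)
#' and returns the loci where any genotype count differs or where counts do not
#' sum to the stated flock size.
#'
#' @param counts,alt Genotype-count tibbles with columns `locus`, `genotype`, `count`.
#' @param n_expected Expected number of genotyped animals per locus (default 433).
#' @return A tibble with one row per flagged locus and columns `locus`,
#'   `n_counts`, `n_alt`, `mismatch` (any per-genotype disagreement) and
#'   `bad_total` (either table's counts do not sum to `n_expected`).
#' @examples
#' flag_count_inconsistencies()
#' @export
flag_count_inconsistencies <- function(counts = smad_genotype_counts,
                                       alt = smad_genotype_counts_alt,
                                       n_expected = 433L) {
  merged <- dplyr::full_join(
    counts[, c("locus", "genotype", "count")],
    alt[, c("locus", "genotype", "count")],
    by = c("locus", "genotype"), suffix = c("", "_alt")
  )
  per_locus <- merged %>%
    group_by(.data$locus) %>%
    summarise(
      n_counts = sum(.data$count),
      n_alt = sum(.data$count_alt),
      mismatch = any(.data$count != .data$count_alt),
      .groups = "drop"
    ) %>%
    mutate(bad_total = .data$n_counts != n_expected | .data$n_alt != n_expected)
  per_locus[per_locus$mismatch | per_locus$bad_total, ]
}
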