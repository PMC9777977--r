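#' Write a publication-style population-genetics report
#'
#' Emits two files: `<stem>.tsv`, the rounded report (2 decimals, half away
#' from zero, mirroring how such tables are printed), and
#' `<stem>_full.tsv`, a full-precision sidecar. All rounding happens at
#' serialisation only: re-reading the sidecar reproduces the internal values
#' exactly (up to the 15 significant digits written).
#'
#' @param g A `geno_tbl` or genotype-count tibble (see [popgen_summary()]).
#' @param stem Output path stem (without extension).
#' @param digits Decimals for the rounded report (default 2).
#' @return Invisibly, the two paths written.
#' @export
write_popgen_report <- function(g, stem, digits = 2) {
  full <- popgen_summary(g)
  rounded <- full %>%
    mutate(across(dplyr::where(is.numeric), ~ round_half_up(.x, digits)))
  paths <- c(report = paste0(stem, ".tsv"), sidecar = paste0(stem, "_full.tsv"))
  readr::write_tsv(rounded, paths["report"], progress = FALSE)
  readr::write_tsv(
    mutate(full, across(dplyr::where(is.numeric), ~ signif(.x, 15))),
    paths["sidecar"], progress = FALSE)
  invisible(paths)
}

#' Write a publication-style association report
#'
#' One block of rows per locus: genotype, n, mean litter size with dispersion
#' and significance letters, shaped like the published association table.
#'
#' @param g A `geno_tbl`.
#' @param pheno Phenotype tibble.
#' @param path Output TSV path.
#' @param loci Loci to report (default all).
#' @param alpha Significance level for letters.
#' @return Invisibly, the combined tibble written.
#' @export
write_assoc_report <- function(g, pheno, path, loci = NULL, alpha = 0.05) {
  info <- loci_info(g)
  loci <- loci %||% info$locus
  out <- purrr::map_dfr(loci, function(lc) {
    row <- info[info$locus == lc, ]
    classes <- c(paste0(row$ref_allele, row$ref_allele),
                 paste0(row$ref_allele, row$alt_allele),
                 paste0(row$alt_allele, row$alt_allele))
    assoc <- suppressMessages(join_genotypes_phenotypes(g, pheno, lc))
    means <- genotype_means(assoc, alpha = alpha, all_genotypes = classes)
    bind_cols(tibble(gene = row$gene, locus = lc), means)
  })
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' Run manifest for reproducible outputs
#'
#' Records what produced an output directory: command label, package version,
#' seed, input-file digests and a timestamp. Reruns with identical inputs and
#' seed produce identical outputs, so equal manifests (timestamp aside) imply
#' equal results.
#'
#' @param command Free-text label of the operation.
#' @param inputs Character vector of input file paths (digested if they
#'   exist).
#' @param seed Seed used, if any.
#' @param dir Directory to write `manifest.tsv` into (NULL = don't write).
#' @return The manifest as a one-row tibble.
#' @export
run_manifest <- function(command, inputs = character(), seed = NA_integer_, dir = NULL) {
  digest_file <- function(p) {
    if (!file.exists(p)) return(NA_character_)
    # small stable content digest without extra dependencies
    x <- readBin(p, "raw", file.info(p)$size)
    sprintf("size%d-sum%.0f", length(x), sum(as.integer(x)) %% 1e9)
  }
  digests <- paste(vapply(inputs, digest_file, character(1)), collapse = ";")
  m <- tibble(
    command = command,
    package_version = as.character(utils::packageVersion("ovisnp")),
    seed = as.integer(seed),
    inputs = paste(basename(inputs), collapse = ";"),
    input_digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(m, file.path(dir, "manifest.tsv"), progress = FALSE)
  }
  m
}
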