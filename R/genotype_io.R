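#' @section Genotype data model:
#' Genotypes are held in a wide tibble of class `geno_tbl`: a `sample` column
#' followed by one column per locus, each cell an unordered diploid call such
#' as `"CT"` (stored reference-allele first) or `NA` for missing. The token
#' `"NN"` denotes missing in TSV files. Locus annotation (gene, reference and
#' alternate allele, exon, mutation type) travels in the `"loci"` attribute,
#' accessible via [loci_info()]. Phase is never inferred at I/O time.
#' @name genotype-data
NULL

MISSING_TOKEN <- "NN"

parse_locus_alleles <- function(locus) {
  m <- regmatches(locus, regexec("([ACGT])>([ACGT])$", locus))[[1]]
  if (length(m) == 3 && m[2] != m[3]) c(ref = m[2], alt = m[3]) else c(ref = NA, alt = NA)
}

infer_loci_info <- function(df, loci = NULL) {
  locus_names <- setdiff(names(df), "sample")
  if (!is.null(loci)) {
    missing_meta <- setdiff(locus_names, loci$locus)
    if (length(missing_meta) > 0) {
      abort(paste0("No locus metadata for: ", paste(missing_meta, collapse = ", ")))
    }
    return(loci[match(locus_names, loci$locus), , drop = FALSE])
  }
  info <- purrr::map(locus_names, function(lc) {
    al <- parse_locus_alleles(lc)
    if (is.na(al["ref"])) {
      # fall back to observed alleles, major allele as reference
      chars <- unlist(strsplit(stats::na.omit(as.character(df[[lc]])), ""))
      chars <- chars[chars != "N"]
      tab <- sort(table(chars), decreasing = TRUE)
      if (length(tab) == 0) abort(paste0("Locus ", lc, ": all calls missing and alleles not parseable from name"))
      al <- c(ref = names(tab)[1], alt = if (length(tab) > 1) names(tab)[2] else NA)
    }
    tibble(locus = lc, gene = NA_character_, exon = NA_integer_,
           mutation_type = NA_character_, ref_allele = unname(al["ref"]),
           alt_allele = unname(al["alt"]))
  })
  bind_rows(info)
}

canonicalize_call <- function(call, ref, alt, locus, sample) {
  out <- call
  out[!is.na(out) & out == MISSING_TOKEN] <- NA
  ok <- is.na(out)
  chars <- strsplit(out[!ok], "")
  valid <- vapply(chars, function(ch) {
    length(ch) == 2 && all(ch %in% c(ref, alt))
  }, logical(1))
  if (any(!valid)) {
    bad <- which(!ok)[!valid]
    abort(paste0(
      "Invalid genotype call(s) at locus ", locus, ": ",
      paste0("sample ", sample[bad], " = '", call[bad], "'", collapse = "; "),
      " (alleles must be in {", ref, ",", alt, "} or '", MISSING_TOKEN, "')"
    ))
  }
  # unordered diploid call: store reference allele first
  out[!ok] <- vapply(chars, function(ch) {
    paste(ch[order(match(ch, c(ref, alt)))], collapse = "")
  }, character(1))
  out
}

#' Construct and validate a genotype table
#'
#' @param df Data frame with a `sample` column and one column of diploid calls
#'   per locus (e.g. `"CT"`, `"NN"` for missing).
#' @param loci Optional locus-annotation tibble (as [smad_loci]); when absent,
#'   reference/alternate alleles are parsed from locus names of the form
#'   `g.<pos><ref>><alt>`, falling back to observed major/minor alleles.
#' @return A `geno_tbl`: the validated tibble with calls canonicalised
#'   (reference allele written first) and locus metadata attached.
#' @examples
#' genotype_table(tibble::tibble(sample = c("e1", "e2", "e3"),
#'                               `g.10729C>T` = c("CC", "CT", "TC")))
#' @export
genotype_table <- function(df, loci = NULL) {
  df <- as_tibble(df)
  if (!"sample" %in% names(df)) abort("Genotype table must have a 'sample' column")
  if (anyDuplicated(df$sample)) {
    abort(paste0("Duplicate sample id(s): ",
                 paste(unique(df$sample[duplicated(df$sample)]), collapse = ", ")))
  }
  df$sample <- as.character(df$sample)
  info <- infer_loci_info(df, loci)
  if (anyDuplicated(info$locus)) abort("Locus names must be unique")
  for (i in seq_len(nrow(info))) {
    lc <- info$locus[i]
    df[[lc]] <- canonicalize_call(as.character(df[[lc]]), info$ref_allele[i],
                                  info$alt_allele[i], lc, df$sample)
  }
  structure(df, loci = info, class = c("geno_tbl", class(df)))
}

#' Locus annotation of a genotype table
#' @param g A `geno_tbl`.
#' @return The locus-annotation tibble attached to `g`.
#' @export
loci_info <- function(g) attr(g, "loci")

#' @export
print.geno_tbl <- function(x, ...) {
  info <- loci_info(x)
  cat("<geno_tbl> ", nrow(x), " samples x ", nrow(info), " loci\n", sep = "")
  NextMethod()
}

#' Read a genotype TSV
#'
#' Expected layout: header `sample<TAB><locus1><TAB>...`, one row per sample,
#' calls as two-letter strings with `"NN"` for missing.
#'
#' @inheritParams genotype_table
#' @param path Path to a tab-separated genotype file.
#' @return A validated [genotype_table()].
#' @export
read_genotype_tsv <- function(path, loci = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0) abort(paste0("Empty genotype file: ", path))
  genotype_table(df, loci)
}

#' Write a genotype table as TSV
#' @param g A `geno_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(g, path) {
  out <- as_tibble(g)
  out[is.na(out)] <- MISSING_TOKEN
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Keeps only biallelic SNP records and uses the GT field; `./.` maps to
#' missing. Requires the vcfR package.
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped).
#' @return A [genotype_table()] whose loci are named `CHROM:POS` unless an ID
#'   is present.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_genotype_vcf() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (!any(biallelic)) abort("VCF contains no biallelic SNP records")
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  locus_names <- ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste0(fix$CHROM, ":", fix$POS), fix$ID)
  calls <- matrix(NA_character_, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), locus_names))
  for (i in seq_len(nrow(gt))) {
    alleles <- c(fix$REF[i], fix$ALT[i])
    g <- gt[i, ]
    parsed <- strsplit(g, "[/|]")
    calls[, i] <- vapply(parsed, function(p) {
      if (length(p) != 2 || any(is.na(p)) || any(p == ".")) return(NA_character_)
      paste(alleles[as.integer(p) + 1], collapse = "")
    }, character(1))
  }
  df <- bind_cols(tibble(sample = rownames(calls)), as_tibble(calls))
  loci <- tibble(locus = locus_names, gene = NA_character_, exon = NA_integer_,
                 mutation_type = NA_character_,
                 ref_allele = fix$REF, alt_allele = fix$ALT)
  genotype_table(df, loci)
}

#' Genotype calls in long (tidy) form
#' @param g A `geno_tbl`.
#' @return Tibble with columns `sample`, `locus`, `genotype` (NA = missing).
#' @export
genotype_calls <- function(g) {
  info <- loci_info(g)
  tidyr::pivot_longer(as_tibble(g), cols = dplyr::all_of(info$locus),
                      names_to = "locus", values_to = "genotype")
}

#' Per-locus genotype counts
#'
#' Counts every canonical genotype class (ref/ref, ref/alt, alt/alt) at each
#' locus, including classes with zero observations; missing calls are excluded.
#'
#' @param g A `geno_tbl`.
#' @return Tibble with columns `gene`, `locus`, `genotype`, `count`.
#' @export
genotype_counts <- function(g) {
  info <- loci_info(g)
  long <- genotype_calls(g)
  purrr::pmap_dfr(info, function(locus, gene, ref_allele, alt_allele, ...) {
    classes <- c(paste0(ref_allele, ref_allele),
                 paste0(ref_allele, alt_allele),
                 paste0(alt_allele, alt_allele))
    calls <- long$genotype[long$locus == locus]
    tibble(gene = gene, locus = locus, genotype = classes,
           count = vapply(classes, function(cl) sum(calls == cl, na.rm = TRUE),
                          integer(1), USE.NAMES = FALSE))
  })
}

#' Expand a genotype-count table into individual calls
#'
#' Inverse of [genotype_counts()]: builds a `geno_tbl` with the stated number
#' of animals per genotype class, so analyses that start from published count
#' tables can run through the same pipeline as raw data. Loci with differing
#' totals are padded with missing calls up to the largest total.
#'
#' @param counts Tibble with columns `locus`, `genotype`, `count` (and
#'   optionally `gene`).
#' @param loci Optional locus annotation; parsed from locus names otherwise.
#' @return A [genotype_table()] with samples `s0001`, `s0002`, ...
#' @examples
#' g <- counts_to_genotypes(smad_genotype_counts)
#' @export
counts_to_genotypes <- function(counts, loci = NULL) {
  locus_names <- unique(counts$locus)
  n_max <- max(vapply(locus_names, function(lc) sum(counts$count[counts$locus == lc]),
                      numeric(1)))
  samples <- sprintf("s%04d", seq_len(n_max))
  cols <- lapply(locus_names, function(lc) {
    sub <- counts[counts$locus == lc, ]
    calls <- rep(sub$genotype, sub$count)
    c(calls, rep(NA_character_, n_max - length(calls)))
  })
  names(cols) <- locus_names
  df <- bind_cols(tibble(sample = samples), as_tibble(cols))
  if (is.null(loci) && "gene" %in% names(counts)) {
    loci <- infer_loci_info(df)
    loci$gene <- counts$gene[match(loci$locus, counts$locus)]
  }
  genotype_table(df, loci)
}

#' Read a phenotype TSV
#'
#' Expected columns `sample`, `parity`, `litter_size`. Parity must be 1-3 and
#' litter size a positive integer (lambs per parturition).
#'
#' @param path Path to a tab-separated phenotype file.
#' @return A validated tibble.
#' @export
read_phenotype_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- readr::read_tsv(path, col_types = "cdd", progress = FALSE)
  validate_phenotypes(df)
}

validate_phenotypes <- function(df) {
  req <- c("sample", "parity", "litter_size")
  if (!all(req %in% names(df))) {
    abort(paste0("Phenotype table needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(df$parity %% 1 != 0) || any(!df$parity %in% 1:3)) {
    abort("parity must be an integer in 1..3")
  }
  if (any(df$litter_size %% 1 != 0) || any(df$litter_size < 1)) {
    abort("litter_size must be a positive integer")
  }
  df$sample <- as.character(df$sample)
  df$parity <- as.integer(df$parity)
  df$litter_size <- as.integer(df$litter_size)
  as_tibble(df)
}

#' Read a Ct TSV
#'
#' Expected columns `animal`, `tissue`, `gene`, `replicate`, `ct`; Ct values
#' must be finite and positive. Triplicate technical replicates are the usual
#' design but any number >= 1 is accepted.
#'
#' @param path Path to a tab-separated Ct file.
#' @return A validated tibble.
#' @export
read_ct_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- readr::read_tsv(path, col_types = "cccid", progress = FALSE)
  validate_ct(df)
}

validate_ct <- function(df) {
  req <- c("animal", "tissue", "gene", "replicate", "ct")
  if (!all(req %in% names(df))) {
    abort(paste0("Ct table needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) abort("Ct values must be finite and > 0")
  as_tibble(df)
}

#' Join genotypes at one locus with litter-size phenotypes
#'
#' Inner join on sample id; samples with a missing call at the locus are
#' dropped (a message reports how many).
#'
#' @param g A `geno_tbl`.
#' @param pheno Phenotype tibble (`sample`, `parity`, `litter_size`).
#' @param locus Locus name present in `g`.
#' @return Tibble with columns `sample`, `genotype`, `parity`, `litter_size`.
#' @export
join_genotypes_phenotypes <- function(g, pheno, locus) {
  info <- loci_info(g)
  if (!locus %in% info$locus) abort(paste0("Locus not in genotype table: ", locus))
  geno <- tibble(sample = g$sample, genotype = g[[locus]])
  joined <- inner_join(geno, validate_phenotypes(pheno), by = "sample")
  if (nrow(joined) == 0) abort("No overlapping sample ids between genotypes and phenotypes")
  n_missing <- sum(is.na(joined$genotype))
  if (n_missing > 0) {
    inform(paste0(n_missing, " sample(s) missing a call at ", locus, " were excluded"))
  }
  out <- joined[!is.na(joined$genotype), c("sample", "genotype", "parity", "litter_size")]
  attr(out, "locus") <- locus
  out
}
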