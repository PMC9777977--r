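# Physicochemical constant tables (published reference data, embedded as code).
# Kyte & Doolittle (1982) hydropathy scores.
.kd_hydropathy <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2, I = 4.5,
  K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5, S = -0.8,
  T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

# Free amino-acid average isotopic masses (Da); peptide MW = sum - (len-1) * water.
.aa_avg_mass <- c(
  A = 89.0932, C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G = 75.0666, H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885)
.water_mass <- 18.0153

# Guruprasad et al. (1990) dipeptide instability weight values (DIWV);
# rows = first residue of the dipeptide, columns = second.
.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.diwv <- matrix(c(
  1.0, 44.94, -7.49, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0,
  1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 33.6, 1.0, 1.0, 20.26, 33.6, 1.0, 20.26, -6.54, 1.0, 1.0, 33.6, -6.54, 24.68, 1.0,
  1.0, 1.0, 1.0, 1.0, -6.54, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, -6.54, 20.26, -14.03, 1.0, 1.0, 1.0,
  1.0, 44.94, 20.26, 33.6, 1.0, 1.0, -6.54, 20.26, 1.0, 1.0, 1.0, 1.0, 20.26, 20.26, 1.0, 20.26, 1.0, 1.0, -14.03, 1.0,
  1.0, 1.0, 13.34, 1.0, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 33.601,
  -7.49, 1.0, 1.0, -6.54, 1.0, 13.34, 1.0, -7.49, -7.49, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 13.34, -7.49,
  1.0, 1.0, 1.0, 1.0, -9.37, -9.37, 1.0, 44.94, 24.68, 1.0, 1.0, 24.68, -1.88, 1.0, 1.0, 1.0, -6.54, 1.0, -1.88, 44.94,
  1.0, 1.0, 1.0, 44.94, 1.0, 1.0, 13.34, 1.0, -7.49, 20.26, 1.0, 1.0, -1.88, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0,
  1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, -7.49, 1.0, -7.49, 33.6, 1.0, -6.54, 24.64, 33.6, 1.0, 1.0, -7.49, 1.0, 1.0,
  1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 20.26, 33.6, 20.26, 1.0, 1.0, 1.0, 24.68, 1.0,
  13.34, 1.0, 1.0, 1.0, 1.0, 1.0, 58.28, 1.0, 1.0, 1.0, -1.88, 1.0, 44.94, -6.54, -6.54, 44.94, -1.88, 1.0, 1.0, 24.68,
  1.0, -1.88, 1.0, 1.0, -14.03, -14.03, 1.0, 44.94, 24.68, 1.0, 1.0, 1.0, -1.88, -6.54, 1.0, 1.0, -7.49, 1.0, -9.37, 1.0,
  20.26, -6.54, -6.54, 18.38, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, -6.54, 1.0, 20.26, 20.26, -6.54, 20.26, 1.0, 20.26, -1.88, 1.0,
  1.0, -6.54, 20.26, 20.26, -6.54, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 20.26, 20.26, 1.0, 44.94, 1.0, -6.54, 1.0, -6.54,
  1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 20.26, 1.0, 1.0, 1.0, 1.0, 13.34, 20.26, 20.26, 58.28, 44.94, 1.0, 1.0, 58.28, -6.54,
  1.0, 33.6, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 44.94, 20.26, 20.26, 20.26, 1.0, 1.0, 1.0, 1.0,
  1.0, 1.0, 1.0, 20.26, 13.34, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0, -6.54, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0,
  1.0, 1.0, -14.03, 1.0, 1.0, -7.49, 1.0, 1.0, -1.88, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, -6.54,
  -14.03, 1.0, 1.0, 1.0, 1.0, -9.37, 24.68, 1.0, 1.0, 13.34, 24.68, 13.34, 1.0, 1.0, 1.0, 1.0, -14.03, -7.49, 1.0, 1.0,
  24.68, 1.0, 24.68, -6.54, 1.0, -7.49, 13.34, 1.0, 1.0, 1.0, 44.94, 1.0, 13.34, 1.0, -15.91, 1.0, -7.49, 1.0, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(.aa20, .aa20))

# Bjellqvist pKa set (the one ProtParam uses), incl. terminal-residue overrides.
.pka_positive <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
.pka_negative <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
.pka_nterm_override <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7)
.pka_cterm_override <- c(D = 4.55, E = 4.75)

validate_dna <- function(seq) {
  seq <- toupper(as.character(seq))
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0) {
    abort(paste0("Non-IUPAC nucleotide character(s): ",
                 paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")))
  }
  seq
}

#' Find open reading frames
#'
#' Scans the given strand (and optionally the reverse complement) for
#' ATG-to-stop frames of at least `min_len` nucleotides under the standard
#' genetic code. Coordinates are 0-based half-open on the reported strand;
#' the nucleotide length includes the stop codon, so the protein length is
#' nt/3 - 1.
#'
#' @param seq Nucleotide sequence: a character scalar or
#'   [Biostrings::DNAString] over A/C/G/T/N.
#' @param min_len Minimum ORF length in nucleotides, stop included
#'   (default 6 = one codon + stop).
#' @param both_strands Also scan the reverse complement (default FALSE:
#'   cDNA input is assumed to be in sense orientation).
#' @return Tibble sorted by decreasing length: `start`, `end`, `frame` (0-2),
#'   `strand`, `nt_len`, `protein` (stop not translated).
#' @examples
#' find_orfs("ATGAAATAA")
#' @export
find_orfs <- function(seq, min_len = 6, both_strands = FALSE) {
  if (min_len < 6) abort("min_len must be at least 6 (one codon plus stop)")
  seq <- validate_dna(seq)
  scan_strand <- function(s, strand) {
    n <- nchar(s)
    out <- list()
    for (frame in 0:2) {
      starts <- seq.int(frame + 1, n - 2, by = 3)
      if (length(starts) == 0) next
      codons <- substring(s, starts, starts + 2)
      is_atg <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      stop_idx <- which(is_stop)
      for (ai in which(is_atg)) {
        nxt <- stop_idx[stop_idx > ai]
        if (length(nxt) == 0) next
        si <- nxt[1]
        nt_len <- (si - ai + 1) * 3
        if (nt_len < min_len) next
        orf_seq <- substring(s, starts[ai], starts[si] - 1)
        prot <- as.character(Biostrings::translate(Biostrings::DNAString(orf_seq)))
        out[[length(out) + 1]] <- tibble(
          start = starts[ai] - 1L, end = starts[si] + 2L, frame = frame,
          strand = strand, nt_len = nt_len, protein = prot)
      }
    }
    bind_rows(out)
  }
  res <- scan_strand(seq, "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    res <- bind_rows(res, scan_strand(rc, "-"))
  }
  if (nrow(res) == 0) {
    return(tibble(start = integer(), end = integer(), frame = integer(),
                  strand = character(), nt_len = integer(), protein = character()))
  }
  arrange(res, dplyr::desc(.data$nt_len))
}

validate_protein <- function(p) {
  p <- toupper(as.character(p))
  chars <- strsplit(p, "")[[1]]
  bad <- which(!chars %in% .aa20)
  if (length(bad) > 0) {
    abort(paste0("Non-standard residue '", chars[bad[1]], "' at position ", bad[1]))
  }
  p
}

net_charge_at_ph <- function(counts, first, last, ph) {
  pos_pk <- .pka_positive
  if (first %in% names(.pka_nterm_override)) pos_pk["Nterm"] <- .pka_nterm_override[first]
  neg_pk <- .pka_negative
  if (last %in% names(.pka_cterm_override)) neg_pk["Cterm"] <- .pka_cterm_override[last]
  pos_n <- c(Nterm = 1, counts[c("K", "R", "H")])
  neg_n <- c(Cterm = 1, counts[c("D", "E", "C", "Y")])
  names(pos_n) <- names(pos_pk); names(neg_n) <- names(neg_pk)
  sum(pos_n / (1 + 10^(ph - pos_pk))) - sum(neg_n / (1 + 10^(neg_pk - ph)))
}

#' Protein physicochemical parameters
#'
#' ProtParam-style summary of a protein sequence over the 20 standard
#' residues: molecular weight from average residue masses; isoelectric point
#' by bisection of the Henderson-Hasselbalch net charge with the Bjellqvist
#' pKa set (including its terminal-residue overrides); charged-residue counts
#' (Asp+Glu, Arg+Lys); GRAVY (mean Kyte-Doolittle hydropathy; negative means
#' hydrophilic); Guruprasad instability index (10/L times the sum of DIWV
#' dipeptide weights; above 40 predicts an unstable protein); and the
#' aliphatic index X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu) in mole percent.
#'
#' @param p Protein sequence (character scalar, standard one-letter codes).
#' @return A one-row tibble: `length`, `mw`, `pi`, `n_negative` (Asp+Glu),
#'   `n_positive` (Arg+Lys), `gravy`, `instability`, `aliphatic`,
#'   `stability_class` ("stable"/"unstable"), `hydropathy_class`
#'   ("hydrophilic"/"hydrophobic").
#' @examples
#' protein_params("MKWVT")
#' @export
protein_params <- function(p) {
  p <- validate_protein(p)
  chars <- strsplit(p, "")[[1]]
  len <- length(chars)
  counts <- setNames(vapply(.aa20, function(a) sum(chars == a), numeric(1)), .aa20)

  mw <- sum(.aa_avg_mass[chars]) - (len - 1) * .water_mass
  gravy <- mean(.kd_hydropathy[chars])
  instability <- if (len >= 2) {
    10 / len * sum(.diwv[cbind(chars[-len], chars[-1])])
  } else 0
  aliphatic <- 100 * (counts["A"] + 2.9 * counts["V"] + 3.9 * (counts["I"] + counts["L"])) / len
  pi_val <- stats::uniroot(function(ph) net_charge_at_ph(counts, chars[1], chars[len], ph),
                           interval = c(0, 14), tol = 1e-6)$root

  tibble(length = len, mw = mw, pi = pi_val,
         n_negative = as.integer(counts["D"] + counts["E"]),
         n_positive = as.integer(counts["R"] + counts["K"]),
         gravy = gravy, instability = unname(instability),
         aliphatic = unname(aliphatic),
         stability_class = ifelse(instability > 40, "unstable", "stable"),
         hydropathy_class = ifelse(gravy < 0, "hydrophilic", "hydrophobic"))
}

#' Pairwise percent identity of aligned protein sequences
#'
#' Identity = matching columns / columns where neither sequence has a gap,
#' times 100. Inputs must be pre-aligned (equal length); set `align = TRUE`
#' to run a convenience global alignment (BLOSUM62, gap open 10, extend 0.5)
#' on each pair first.
#'
#' @param seqs Named character vector of protein sequences (gaps as "-").
#' @param align Globally align each pair before scoring (default FALSE).
#' @return Symmetric numeric matrix of percent identities.
#' @export
identity_matrix <- function(seqs, align = FALSE) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  lens <- nchar(seqs)
  if (!align && length(unique(lens)) > 1) {
    abort("Sequences differ in length; align them first or set align = TRUE")
  }
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  pct <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    use <- ca != "-" & cb != "-"
    if (!any(use)) return(NA_real_)
    100 * sum(ca[use] == cb[use]) / sum(use)
  }
  if (n < 2) return(m)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (align) {
        data("BLOSUM62", package = "Biostrings", envir = environment())
        al <- Biostrings::pairwiseAlignment(
          gsub("-", "", seqs[i]), gsub("-", "", seqs[j]), type = "global",
          substitutionMatrix = get("BLOSUM62", envir = environment()),
          gapOpening = 10, gapExtension = 0.5)
        a <- as.character(Biostrings::alignedPattern(al))
        b <- as.character(Biostrings::alignedSubject(al))
      } else {
        a <- seqs[i]; b <- seqs[j]
      }
      m[i, j] <- m[j, i] <- pct(a, b)
    }
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomerative neighbor joining. Ties in the Q criterion are
#' broken by the smallest (row, column) index pair; negative branch lengths
#' are clamped to zero with the deficit moved to the sister branch. The
#' result is an unrooted [ape::phylo] tree (write it with [ape::write.tree]).
#'
#' @param d Symmetric non-negative distance matrix with labelled rows/columns,
#'   zero diagonal, at least 3 taxa. Asymmetry beyond 1e-9 is an error.
#' @return An `ape::phylo` object with branch lengths.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) abort("Need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-9) abort("Distance matrix is not symmetric")
  if (any(d < 0)) abort("Distances must be non-negative")
  diag(d) <- 0

  # each active node carries a growing newick fragment
  labels <- rownames(d)
  frags <- labels
  repeat {
    n_active <- nrow(d)
    if (n_active == 3) break
    r <- rowSums(d)
    q <- (n_active - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # smallest (row, col) pair among the minima, row < col
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]

    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n_active - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj - bi; bi <- 0 }
    if (bj < 0) { bi <- bi - bj; bj <- 0 }

    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frags[i], bi, frags[j], bj)
    keep <- setdiff(seq_len(n_active), c(i, j))
    new_d <- (d[i, keep] + d[j, keep] - d[i, j]) / 2
    new_d[new_d < 0] <- 0
    d <- rbind(cbind(d[keep, keep, drop = FALSE], new_d),
               c(new_d, 0))
    frags <- c(frags[keep], new_frag)
    rownames(d) <- colnames(d) <- paste0("n", seq_len(nrow(d)))
  }
  # terminal trifurcation: three-point formulas
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  bs <- c(b1, b2, b3)
  for (k in 1:3) {
    if (bs[k] < 0) {
      others <- setdiff(1:3, k)
      bs[others] <- bs[others] + bs[k] / 2
      bs[k] <- 0
    }
  }
  newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                    frags[1], bs[1], frags[2], bs[2], frags[3], bs[3])
  ape::read.tree(text = newick)
}
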