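test_that("ORF discovery follows the ATG-to-stop rule", {
  one <- find_orfs("ATGAAATAA")
  expect_equal(nrow(one), 1)
  expect_equal(one$nt_len, 9)
  expect_equal(one$protein, "MK")
  expect_equal(one$start, 0)
  expect_equal(one$end, 9)

  expect_equal(nrow(find_orfs("CCCAAATTTGGG")), 0)   # no ATG
  expect_equal(nrow(find_orfs("ATGAAACCC")), 0)      # no stop
  expect_error(find_orfs("ATGXXXTAA"), "Non-IUPAC")
  expect_error(find_orfs("ATGTAA", min_len = 3), "at least 6")

  # reverse-strand ORF only found when asked
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("ATGAAATAA")))
  expect_equal(nrow(find_orfs(rc)), 0)
  both <- find_orfs(rc, both_strands = TRUE)
  expect_equal(both$strand, "-")
  expect_equal(both$protein, "MK")
})

test_that("embedded coding sequences are recovered with the expected protein length", {
  # every reported ORF obeys protein length = nt/3 - 1 (stop untranslated)
  for (len in c(300, 1398)) {
    cds <- simulate_cds(len, seed = len)
    orfs <- find_orfs(cds$sequence, min_len = 60)
    expect_true(any(orfs$nt_len == len))
    hit <- orfs[orfs$nt_len == len, ][1, ]
    expect_equal(nchar(hit$protein), len / 3 - 1)
    expect_equal(hit$protein, cds$protein)
    expect_true(all(nchar(orfs$protein) == orfs$nt_len / 3 - 1))
    expect_true(all(substr(orfs$protein, 1, 1) == "M"))
  }
})

test_that("protein parameters match their defining formulas", {
  # Kyte-Doolittle extremes and the aliphatic-index anchor
  expect_equal(protein_params(strrep("I", 12))$gravy, 4.5)
  expect_equal(protein_params(strrep("A", 7))$aliphatic, 100)

  # instability of MKWVT: hand-summed dipeptide weights
  # DIWV: MK = 1.0, KW = 1.0, WV = -7.49, VT = -7.49 -> sum = -12.98
  mk <- protein_params("MKWVT")
  expect_equal(mk$instability, 10 / 5 * (1.0 + 1.0 - 7.49 - 7.49))
  expect_equal(mk$n_positive, 1L)
  expect_equal(mk$n_negative, 0L)

  expect_error(protein_params("MKXVT"), "position 3")
})

test_that("protein parameters agree with frozen reference-tool values", {
  # expected values computed once with an independent ProtParam
  # implementation and frozen
  p1 <- protein_params("MKWVT")
  expect_equal(p1$mw, 663.8284, tolerance = 1e-3)
  expect_equal(p1$gravy, 0.12, tolerance = 1e-6)
  expect_equal(p1$instability, -25.96, tolerance = 1e-6)
  expect_equal(p1$pi, 8.5001, tolerance = 1e-3)

  p2 <- protein_params("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  expect_equal(p2$mw, 3935.5547, tolerance = 1e-3)
  expect_equal(p2$gravy, -0.40303, tolerance = 1e-5)
  expect_equal(p2$instability, 53.548485, tolerance = 1e-5)
  expect_equal(p2$pi, 9.98797, tolerance = 1e-3)
  expect_equal(p2$n_negative, 3L)
  expect_equal(p2$n_positive, 6L)
  expect_equal(p2$aliphatic, 94.545455, tolerance = 1e-5)
  # GRAVY < 0 and instability > 40: an "unstable hydrophilic" protein
  expect_equal(p2$stability_class, "unstable")
  expect_equal(p2$hydropathy_class, "hydrophilic")

  p3 <- protein_params("ACDEFGHIKLMNPQRSTVWY")
  expect_equal(p3$mw, 2395.7134, tolerance = 1e-3)
  expect_equal(p3$pi, 6.78455, tolerance = 1e-3)
})

test_that("percent identity counts matching non-gap columns", {
  expect_equal(identity_matrix(c(a = "MKWVT", b = "MKWVT"))["a", "b"], 100)
  expect_equal(identity_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"], 75)
  # gapped columns are excluded from the denominator
  expect_equal(identity_matrix(c(a = "MK-VT", b = "MKWVA"))["a", "b"], 75)
  expect_error(identity_matrix(c(a = "MK", b = "MKW")), "length")

  # random pairs against a direct column-count oracle
  withr::with_seed(77, {
    for (i in 1:10) {
      s1 <- paste(sample(c("A", "C", "D", "-"), 30, replace = TRUE), collapse = "")
      s2 <- paste(sample(c("A", "C", "D", "-"), 30, replace = TRUE), collapse = "")
      c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
      use <- c1 != "-" & c2 != "-"
      expected <- 100 * sum(c1[use] == c2[use]) / sum(use)
      expect_equal(identity_matrix(c(x = s1, y = s2))["x", "y"], expected)
    }
  })
})

test_that("neighbor joining solves the three-taxon tree in closed form", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["x"]], (3 + 5 - 6) / 2)
  expect_equal(bl[["y"]], (3 + 6 - 5) / 2)
  expect_equal(bl[["z"]], (5 + 6 - 3) / 2)
})

test_that("an additive five-taxon matrix is recovered exactly", {
  true <- ape::read.tree(text = "((a:2,b:3):1,(c:1.5,d:2.5):2,e:4);")
  d <- ape::cophenetic.phylo(true)
  labs <- c("a", "b", "c", "d", "e")
  d <- d[labs, labs]
  tr <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  # branch lengths reproduce the generating tree (additivity)
  expect_equal(sort(tr$edge.length), sort(true$edge.length), tolerance = 1e-9)
  # round-trip through Newick
  txt <- ape::write.tree(tr)
  expect_equal(ape::dist.topo(ape::read.tree(text = txt), ape::unroot(true)), 0,
               ignore_attr = TRUE)
})

test_that("NJ recovers generating topologies on ultrametric trees", {
  withr::with_seed(55, {
    for (i in 1:30) {
      n_taxa <- sample(4:8, 1)
      true <- ape::rcoal(n_taxa)
      d <- ape::cophenetic.phylo(true)
      tr <- nj_tree(d)
      expect_equal(ape::dist.topo(ape::unroot(true), tr), 0, ignore_attr = TRUE)
      # cross-check against the reference NJ implementation
      ref <- ape::nj(d)
      expect_equal(ape::dist.topo(ref, tr), 0, ignore_attr = TRUE)
    }
  })
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 1.1, 0, 3, 2, 3, 0), 3, 3)
  expect_error(nj_tree(d), "symmetric")
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
  dn <- matrix(c(0, -1, 2, -1, 0, 3, 2, 3, 0), 3, 3)
  expect_error(nj_tree(dn), "non-negative")
})
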