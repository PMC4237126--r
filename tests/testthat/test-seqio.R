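test_that("FASTA alignments are parsed, normalized and validated", {
  fa <- write_fasta(c(a = "ACGTA", b = "ACG-A"))
  aln <- read_alignment(fa)
  expect_s3_class(aln, "cp_alignment")
  expect_equal(aln$L, 5)
  expect_equal(aln$ids, c("a", "b"))

  # lowercase input is stored uppercase; header ids end at whitespace
  fa2 <- write_fasta(c("x1 some description" = "acgta"))
  aln2 <- read_alignment(fa2)
  expect_equal(aln2$ids, "x1")
  expect_equal(paste(aln2$mat[1, ], collapse = ""), "ACGTA")

  fa3 <- write_fasta(c(a = "ACGTA", b = "ACGTAA"))
  expect_error(read_alignment(fa3), "unequal")
  fa4 <- tempfile(); writeLines(character(0), fa4)
  expect_error(read_alignment(fa4), "FASTA")
  expect_error(alignment(c(a = "ACGTA", a = "ACGTA")), "duplicated")
})

test_that("sample tables are validated", {
  tsv <- tempfile()
  writeLines(c("id\tspecies\tlat\tlon", "s1\tspA\t0.5\t9.25"), tsv)
  st <- read_sample_table(tsv)
  expect_equal(st$lat, 0.5)
  expect_equal(st$lon, 9.25)

  expect_error(sample_table(data.frame(id = "s1", species = "x",
                                       lat = 91, lon = 0)), "latitude")
  expect_error(sample_table(data.frame(id = c("s1", "s1"), species = "x",
                                       lat = 0, lon = 0)), "duplicated")
  expect_error(sample_table(data.frame(id = "s1", species = "x", lat = 0)),
               "missing column")
})

test_that("simple indel coding produces one character per maximal gap run", {
  cd <- code_indels(alignment(c(a = "ACGTA", b = "AC--A", c = "ACGTA")))
  expect_equal(ncol(cd$indel), 1)
  expect_equal(ncol(cd$sub), 0)
  expect_equal(unname(cd$indel[, 1]), c(0L, 1L, 0L))
  expect_equal(cd$indel_spans$start, 3)
  expect_equal(cd$indel_spans$end, 4)

  cd2 <- code_indels(alignment(c(a = "ACGTA", b = "ACGTT")))
  expect_equal(ncol(cd2$indel), 0)
  expect_equal(ncol(cd2$sub), 1)

  # overlapping but non-identical runs are distinct characters
  cd3 <- code_indels(alignment(c(a = "A--TA", b = "A-GTA")))
  expect_equal(ncol(cd3$indel), 2)
  expect_equal(cd3$indel_spans, data.frame(start = c(2, 2), end = c(2, 3)))
  expect_equal(unname(cd3$indel), rbind(c(0L, 1L), c(1L, 0L)))
})

test_that("haplotype collapsing merges identical coded vectors", {
  hs <- collapse_haplotypes(code_indels(alignment(
    c(a = "ACGTA", b = "ACGTA", c = "ACGTA"))))
  expect_equal(unname(hs$counts), 3L)
  expect_equal(hs$id, "H1")

  hs2 <- collapse_haplotypes(code_indels(alignment(
    c(a = "ACGTA", b = "ACGTT", c = "ACGTA"))))
  expect_equal(unname(hs2$counts), c(2L, 1L))
  expect_equal(hs2$carriers$H1, c("a", "c"))

  # ambiguous sample at a varying character is dropped with a warning
  expect_warning(
    hs3 <- collapse_haplotypes(code_indels(alignment(
      c(a = "ACGTA", b = "ACGTT", c = "ACGTN")))),
    "dropping 1")
  expect_equal(hs3$n, 2)
  expect_equal(hs3$dropped, "c")

  # gap states are not ambiguity: the indel character carries them
  hs4 <- collapse_haplotypes(code_indels(alignment(
    c(a = "ACGTA", b = "AC--A", c = "AC--A"))))
  expect_equal(unname(hs4$counts), c(2L, 1L))
})

test_that("multi-locus haplotypes are defined on the concatenation", {
  cd1 <- code_indels(alignment(c(a = "ACGTA", b = "ACGTA", c = "ACGTT")))
  cd2 <- code_indels(alignment(c(a = "GGGG", b = "GGGA", c = "GGGG")))
  cc <- concat_coded(cd1, cd2)
  expect_equal(cc$L, 9)
  hs <- collapse_haplotypes(cc)
  # a and b identical at locus 1 but split by locus 2; c distinct at locus 1
  expect_equal(length(hs$id), 3)
  hs1 <- collapse_haplotypes(cd1)
  expect_equal(length(hs1$id), 2)
})

test_that("collapse/expand round trip restores per-sample coded vectors", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 12; L <- 40
    m <- matrix(sample(c("A", "C", "G", "T"), n * L, TRUE), n, L)
    m[sample(length(m), 8)] <- "-"
    seqs <- apply(m, 1, paste, collapse = "")
    names(seqs) <- paste0("s", seq_len(n))
    cd <- code_indels(alignment(seqs))
    hs <- collapse_haplotypes(cd)
    ex <- expand_haplotypes(hs)
    ord <- rownames(ex$sub)
    expect_equal(ex$sub, cd$sub[ord, , drop = FALSE])
    expect_equal(ex$indel, cd$indel[ord, , drop = FALSE])
  }
})

test_that("nucleotide diversity matches its definition and brute force", {
  # two sequences differing at 3 of 600 sites -> pi = 0.005
  s1 <- paste(rep("A", 600), collapse = "")
  s2 <- paste(c(rep("A", 597), "C", "C", "C"), collapse = "")
  hs <- collapse_haplotypes(code_indels(alignment(c(x = s1, y = s2))))
  pol <- summarize_polymorphism(hs)
  expect_equal(pol$pi, 0.005)
  expect_equal(pol$snps, 3)

  # monomorphic sample
  hsm <- collapse_haplotypes(code_indels(alignment(
    c(a = "ACGTA", b = "ACGTA"))))
  polm <- summarize_polymorphism(hsm)
  expect_equal(polm$pi, 0)
  expect_equal(polm$snps, 0)
  expect_equal(polm$pi_sd, 0)

  # an indel counts as a single mutation
  hsg <- collapse_haplotypes(code_indels(alignment(
    c(a = "ACGTA", b = "AC--A"))))
  polg <- summarize_polymorphism(hsg)
  expect_equal(polg$snps, 1)
  expect_equal(mutation_distance_matrix(hsg)["H1", "H2"], 1L)

  expect_error(summarize_polymorphism(
    collapse_haplotypes(code_indels(alignment(c(a = "ACGTA"))))),
    "at least 2")

  # pi equals the brute-force average over ordered pairs of individuals
  set.seed(21)
  for (rep in 1:5) {
    n <- 10; L <- 60
    base <- sample(c("A", "C", "G", "T"), L, TRUE)
    m <- matrix(rep(base, each = n), n, L)
    for (k in 1:8) {
      j <- sample(L, 1)
      rows <- sample(n, sample(1:4, 1))
      m[rows, j] <- sample(setdiff(c("A", "C", "G", "T"), base[j]), 1)
    }
    seqs <- apply(m, 1, paste, collapse = "")
    names(seqs) <- paste0("s", seq_len(n))
    hs <- collapse_haplotypes(code_indels(alignment(seqs)))
    D <- mutation_distance_matrix(hs)
    hap <- hs$assignment[names(seqs)]
    tot <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j) tot <- tot + D[hap[i], hap[j]]
    }
    expect_equal(summarize_polymorphism(hs)$pi, tot / (n * (n - 1)) / L)
  }
})

test_that("SNP count equals per-column brute force on random alignments", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 20; L <- 50
    base <- sample(c("A", "C", "G", "T"), L, TRUE)
    m <- matrix(rep(base, each = n), n, L)
    for (k in 1:12) {
      j <- sample(L, 1)
      m[sample(n, sample(1:6, 1)), j] <-
        sample(setdiff(c("A", "C", "G", "T"), base[j]), 1)
    }
    seqs <- apply(m, 1, paste, collapse = "")
    names(seqs) <- paste0("s", seq_len(n))
    bf <- sum(vapply(seq_len(L), function(j) {
      length(unique(m[, j])) >= 2
    }, logical(1)))
    cd <- code_indels(alignment(seqs))
    expect_equal(ncol(cd$sub) + ncol(cd$indel), bf)
  }
})

test_that("masked columns are excluded from substitution characters", {
  aln <- alignment(c(a = "ACGTA", b = "TCGTT"))
  expect_equal(ncol(code_indels(aln)$sub), 2)
  expect_equal(ncol(code_indels(aln, mask_cols = c(1))$sub), 1)
})

test_that("haplotype outputs are written", {
  aln <- alignment(c(a = "ACGTA", b = "ACGTT", c = "ACGTA"))
  hs <- collapse_haplotypes(code_indels(aln))
  mem <- tempfile(); fa <- tempfile()
  write_haplotypes(hs, aln, membership_path = mem, fasta_path = fa)
  tab <- read.delim(mem)
  expect_equal(tab$haplotype[tab$id == "b"], "H2")
  rt <- read_alignment(fa)
  expect_equal(rt$ids, c("H1", "H2"))
  expect_equal(paste(rt$mat["H2", ], collapse = ""), "ACGTT")
})
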