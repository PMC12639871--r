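# Haplotype construction and read simulation.

test_that("error-free reads are exact amplicon copies with deterministic allocation", {
  locus <- test_locus()
  em0 <- errorModel(0, 0, 0)
  hA <- haplotypeSpec("A", structure = "DEL_CHIMERA", bin = "CH-1")
  hB <- haplotypeSpec("B", structure = "DEL_CHIMERA", bin = "CH-8")
  rs <- simulateReads(hA, hB, locus, depth = 60, error_model = em0, seed = 3)
  expect_equal(length(rs), 60L)
  expect_equal(as.integer(table(truthTags(rs))), c(30L, 30L))
  # same seed, same bytes
  rs2 <- simulateReads(hA, hB, locus, depth = 60, error_model = em0, seed = 3)
  expect_identical(as.character(readSequences(rs)),
                   as.character(readSequences(rs2)))

  hN <- haplotypeSpec("A")
  rsn <- simulateReads(hN, hN, locus, depth = 10, error_model = em0, seed = 5)
  gene <- as.character(geneRef(locus)); pseudo <- as.character(pseudoRef(locus))
  tags <- truthTags(rsn)
  sq <- as.character(readSequences(rsn))
  expect_true(all(sq[grepl(":gene", tags)] == gene))
  expect_true(all(sq[grepl(":pseudo", tags)] == pseudo))
})

test_that("injected substitutions follow the binomial expectation", {
  locus <- test_locus()
  em <- errorModel(substitution = 0.01, ins = 0, del = 0)
  hN <- haplotypeSpec("A")
  rs <- simulateReads(hN, hN, locus, depth = 8, error_model = em, seed = 11)
  gene <- strsplit(as.character(geneRef(locus)), "")[[1L]]
  pseudo <- strsplit(as.character(pseudoRef(locus)), "")[[1L]]
  nMis <- 0L; nBases <- 0L
  for (i in seq_along(rs)) {
    tmpl <- if (grepl(":gene", truthTags(rs)[i])) gene else pseudo
    rd <- strsplit(as.character(readSequences(rs)[[i]]), "")[[1L]]
    nMis <- nMis + sum(rd != tmpl)
    nBases <- nBases + length(tmpl)
  }
  expect_gt(nBases, 10000L)
  expected <- nBases * 0.01
  sigma <- sqrt(nBases * 0.01 * 0.99)
  expect_lt(abs(nMis - expected), 3 * sigma)
})

test_that("haplotype variants are applied exactly (edit-script oracle)", {
  locus <- test_locus()
  # homozygous intron-2 splice diplotype: both gene amplicons identical,
  # one base different from the reference
  h6 <- haplotypeSpec("A", variants = "c.293-13C>G")
  amp <- buildHaplotype(h6, locus)
  gene <- strsplit(as.character(geneRef(locus)), "")[[1L]]
  g6 <- strsplit(as.character(amp$seqs[[which(amp$types == "gene")]]), "")[[1L]]
  expect_equal(length(g6), length(gene))
  d <- which(g6 != gene)
  expect_equal(d - 1L, parseCodingName("c.293-13C>G", locus)$gene_pos)
  expect_equal(g6[d], "G")

  # four SNVs + one duplication: rebuild independently from parsed events
  hB <- haplotypeSpec("B", variants = c("c.844G>T", "c.923dup", "c.955C>T",
                                        "c.1069C>T"))
  built <- as.character(buildHaplotype(hB, locus)$seqs[[1L]])
  ch <- gene
  evs <- do.call(rbind, lapply(hB@variants, parseCodingName, locus = locus))
  evs <- evs[order(evs$gene_pos, decreasing = TRUE), ]
  for (i in seq_len(nrow(evs))) {
    e <- evs[i, ]
    if (e$kind == "SNV") ch[e$gene_pos + 1L] <- e$alt
    else if (e$kind == "dup") ch <- append(ch, e$alt, after = e$gene_pos)
  }
  expect_identical(built, paste(ch, collapse = ""))
  expect_equal(nchar(built), nchar(paste(gene, collapse = "")) + 1L)
})

test_that("deletion chimeras carry pseudo alleles before and gene alleles after the breakpoint", {
  locus <- test_locus()
  p <- psvTable(locus)
  bins <- junctionBins(locus)
  row <- which(bins$label == "CH-3")
  bp <- p$gene_pos[bins$psv_lo[row]] + 5L
  h <- haplotypeSpec("A", structure = "DEL_CHIMERA", bin = "CH-3")
  amp <- buildHaplotype(h, locus, breakpoint = bp)
  expect_equal(amp$types, "fused")
  fused <- strsplit(as.character(amp$seqs[[1L]]), "")[[1L]]
  pre <- CAHscreen:::.pseudoPrefixLen(locus, bp)
  snv <- p[p$kind == "SNV", ]
  for (i in seq_len(nrow(snv))) {
    pos <- snv$gene_pos[i]
    if (pos < bp) {
      expect_identical(fused[snv$pseudo_pos[i] + 1L], snv$pseudo_allele[i])
    } else {
      expect_identical(fused[pre + (pos - bp) + 1L], snv$gene_allele[i])
    }
  }
  # a variant upstream of the breakpoint no longer exists on the fused allele
  hBad <- haplotypeSpec("A", structure = "DEL_CHIMERA", bin = "CH-9",
                        variants = "c.92C>T")
  expect_error(buildHaplotype(hBad, locus), "deleted by the structure")
})

test_that("cohort fixtures are reproducible files", {
  locus <- test_locus()
  specs <- table1Specs()[1:3]
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- writeCohortFixture(specs, locus, d1, depth = 12, seed = 42)
  m2 <- writeCohortFixture(specs, locus, d2, depth = 12, seed = 42)
  expect_equal(nrow(m1), 3L)
  for (f in m1$fastq)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  expect_error(writeCohortFixture(specs, locus, d1, depth = 12, seed = 42),
               "not empty")
  d3 <- withr::local_tempdir()
  m3 <- writeCohortFixture(specs, locus, d3, depth = 12, seed = 43)
  expect_false(identical(unname(tools::md5sum(file.path(d1, m1$fastq[1L]))),
                         unname(tools::md5sum(file.path(d3, m3$fastq[1L])))))
  expect_identical(m1$truth_status, m3$truth_status)
  # empty spec list -> empty manifest
  d4 <- withr::local_tempdir()
  m4 <- writeCohortFixture(list(), locus, d4, depth = 12, seed = 1)
  expect_equal(nrow(m4), 0L)
  # FASTQ round-trip preserves sequences and truth tags
  rt <- readFastqReads(file.path(d1, m1$fastq[1L]))
  expect_equal(length(rt), m1$n_reads[1L])
  expect_false(any(is.na(truthTags(rt))))
  # the packaged fixture is the full 12-case set
  expect_equal(length(table1Specs()), 12L)
})
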