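# Fitting alignment and pileup variant calling.

test_that("exact and single-substitution reads align as expected", {
  locus <- test_locus()
  rf <- as.character(geneRef(locus))
  a <- alignRead(rf, rf)
  expect_equal(a$ref_start, 0L)
  expect_equal(a$ref_end, nchar(rf))
  expect_equal(nrow(a$events), 0L)
  expect_equal(a$identity, 1)
  expect_equal(a$score, 2 * nchar(rf))

  ch <- strsplit(rf, "")[[1L]]
  ch[1001L] <- setdiff(c("A", "C", "G", "T"), ch[1001L])[1L]
  a2 <- alignRead(paste(ch, collapse = ""), rf)
  expect_equal(nrow(a2$events), 1L)
  expect_equal(a2$events$type, "X")
  expect_equal(a2$events$ref_pos, 1000L)
})

test_that("alignment scores equal an independent full-matrix dynamic program", {
  # oracle: Biostrings' global-local (pattern end-to-end, subject ends free)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  set.seed(314)
  for (i in 1:500) {
    ref <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    if (i %% 2 == 0) {
      rd <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    } else {
      s <- sample(1:20, 1)
      ch <- strsplit(substr(ref, s, s + 99), "")[[1L]]
      ch[sample(100, 5)] <- sample(c("A", "C", "G", "T"), 5, TRUE)
      if (i %% 3 == 0) ch <- ch[-sample(length(ch), 2)]
      if (i %% 5 == 0) ch <- append(ch, sample(c("A", "C", "G", "T"), 1),
                                    after = sample(length(ch), 1))
      rd <- paste(ch, collapse = "")
    }
    mine <- alignRead(rd, ref, band = 200)$score
    oracle <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(rd), Biostrings::DNAString(ref),
      type = "global-local", substitutionMatrix = mat,
      gapOpening = 6, gapExtension = 1))
    expect_equal(mine, oracle)
  }
})

test_that("low-identity reads are excluded from the pileup", {
  locus <- test_locus()
  set.seed(2)
  junk <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  rs <- new("ReadSet",
            sequences = Biostrings::DNAStringSet(c(ok = as.character(geneRef(locus)),
                                                   junk = junk)),
            qualities = Biostrings::BStringSet(c(ok = strrep("I", 3120),
                                                 junk = strrep("I", 3000))),
            truth = c(NA_character_, NA_character_), sample = NA_character_)
  out <- alignReads(rs, geneRef(locus))
  expect_equal(length(out$alignments), 1L)
  expect_equal(out$excluded, "junk")
})

test_that("pileup calling honours zygosity bands and the 30x coverage floor", {
  locus <- test_locus()
  em0 <- errorModel(0, 0, 0)
  h6 <- haplotypeSpec("A", variants = "c.293-13C>G")

  # 40 error-free reads from a homozygote: one HOM call with the right name
  rs <- simulateReads(h6, h6, locus, depth = 40, error_model = em0, seed = 6)
  cl <- classifyReads(rs, locus)
  fun <- cl$reads[cl$classes == "FUNCTIONAL"]
  alns <- alignReads(fun, geneRef(locus))$alignments
  out <- callSmallVariants(alns, locus)
  expect_equal(nrow(out$calls), 1L)
  expect_equal(out$calls$name, "c.293-13C>G")
  expect_equal(out$calls$zygosity, "HOM")

  # 29 reads: zero calls, the whole locus is in the no-call mask
  out29 <- callSmallVariants(alns[1:29], locus)
  expect_equal(nrow(out29$calls), 0L)
  expect_equal(out29$mask$start, 0L)
  expect_equal(out29$mask$end, length(geneRef(locus)))

  # 50/50 reference/variant mixture: one HET call at fraction 0.5
  hRef <- haplotypeSpec("B")
  h518 <- haplotypeSpec("A", variants = "c.518T>A")
  rs2 <- simulateReads(h518, hRef, locus, depth = 40, error_model = em0, seed = 7)
  cl2 <- classifyReads(rs2, locus)
  fun2 <- cl2$reads[cl2$classes == "FUNCTIONAL"]
  out2 <- callSmallVariants(alignReads(fun2, geneRef(locus))$alignments, locus)
  expect_equal(out2$calls$name, "c.518T>A")
  expect_equal(out2$calls$zygosity, "HET")
  expect_equal(out2$calls$frac, 0.5)

  # raising min_depth never adds a call
  rs3 <- simulateReads(h518, h6, locus, depth = 80, seed = 9)
  cl3 <- classifyReads(rs3, locus)
  alns3 <- alignReads(cl3$reads[cl3$classes == "FUNCTIONAL"],
                      geneRef(locus))$alignments
  prev <- NULL
  for (md in c(30L, 50L, 70L, 81L)) {
    cc <- callSmallVariants(alns3, locus, min_depth = md)$calls
    if (!is.null(prev)) expect_true(all(cc$name %in% prev$name))
    prev <- cc
  }
})

test_that("indel events are left-normalised", {
  # build a toy reference with a homopolymer run and delete its last base:
  # the event must shift to the run start
  ref <- "ACGTACGTAAAAACGTACGTACGTACGTACGTACGTACGT"
  ch <- strsplit(ref, "")[[1L]]
  rd <- paste(ch[-13L], collapse = "")  # removes the last A of AAAAA (0-based 12)
  a <- alignRead(rd, ref, band = 40)
  expect_equal(nrow(a$events), 1L)
  expect_equal(a$events$type, "D")
  expect_equal(a$events$ref_pos, 8L)  # run starts at 0-based 8
  expect_equal(a$events$ref, "A")
  # same for an inserted copy inside the run
  rd2 <- paste(append(ch, "A", after = 13L), collapse = "")
  a2 <- alignRead(rd2, ref, band = 40)
  expect_equal(a2$events$type, "I")
  expect_equal(a2$events$ref_pos, 8L)
  expect_equal(a2$events$alt, "A")
})

test_that("calls render to VCF and the mask to BED", {
  locus <- test_locus()
  em0 <- errorModel(0, 0, 0)
  h <- haplotypeSpec("A", variants = c("c.518T>A", "c.923dup", "c.740del"))
  rs <- simulateReads(h, h, locus, depth = 40, error_model = em0, seed = 10)
  cl <- classifyReads(rs, locus)
  alns <- alignReads(cl$reads[cl$classes == "FUNCTIONAL"],
                     geneRef(locus))$alignments
  out <- callSmallVariants(alns, locus)
  expect_setequal(out$calls$name, c("c.518T>A", "c.923dup", "c.740del"))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeCallsVcf(out$calls, locus, vcf, sample = "s1")
  skip_if_not_installed("vcfR")
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  expect_equal(nrow(v@fix), 3L)
  expect_setequal(v@fix[, "ID"], c("c.518T>A", "c.923dup", "c.740del"))
  # anchored indel rows: REF/ALT share the anchor base
  dup <- v@fix[v@fix[, "ID"] == "c.923dup", ]
  expect_equal(nchar(dup[["ALT"]]), nchar(dup[["REF"]]) + 1L)
  bed <- withr::local_tempfile(fileext = ".bed")
  writeMaskBed(data.frame(start = 0L, end = 10L), bed)
  expect_match(readLines(bed), "^toy_gene\t0\t10")
})
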