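# Toy locus construction, PSV derivation and coding-name mapping.

test_that("locus build is deterministic and matches its configuration", {
  l1 <- test_locus()
  l2 <- buildToyLocus()
  expect_identical(as.character(geneRef(l1)), as.character(geneRef(l2)))
  expect_identical(as.character(pseudoRef(l1)), as.character(pseudoRef(l2)))
  expect_identical(psvTable(l1), psvTable(l2))
  expect_identical(primerSet(l1), primerSet(l2))

  cfg <- l1@config
  expect_equal(nrow(psvTable(l1)),
               cfg$psv_snvs + cfg$psv_indels + cfg$flank_psvs)
  expect_equal(sum(psvTable(l1)$kind != "SNV"), cfg$psv_indels)
  # junction bins tile the PSV span without gaps or overlap
  b <- junctionBins(l1)
  expect_true(all(b$start[-1L] == b$end[-nrow(b)]))
  p <- psvTable(l1)
  expect_equal(b$start[1L], p$gene_pos[1L])
  expect_equal(b$end[nrow(b)], p$gene_pos[nrow(p)] + 1L)
  # references align end-to-end at high identity
  pid <- Biostrings::pid(Biostrings::pairwiseAlignment(
    geneRef(l1), pseudoRef(l1), type = "global"))
  expect_gt(pid, 90)
})

test_that("undiverged configuration yields no signature variants", {
  l0 <- buildToyLocus(toyLocusConfig(divergence = 0))
  expect_equal(nrow(psvTable(l0)), 0L)
  s <- as.character(geneRef(test_locus()))
  expect_equal(nrow(deriveSignatureVariants(s, s)), 0L)
})

test_that("signature derivation recovers a known planted edit script", {
  set.seed(7)
  base <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  ch <- strsplit(base, "")[[1L]]
  # one substitution at 0-based position 100
  ch2 <- ch
  ch2[101L] <- setdiff(c("A", "C", "G", "T"), ch[101L])[1L]
  one <- deriveSignatureVariants(paste(ch, collapse = ""),
                                 paste(ch2, collapse = ""))
  expect_equal(nrow(one), 1L)
  expect_equal(one$gene_pos, 100L)
  expect_equal(one$kind, "SNV")

  # a 12-edit script with pinned indel contexts (oracle: the script itself)
  ch[300:304] <- c("A", "C", "G", "T", "A")   # deletion context
  ch[450:451] <- c("G", "T")                  # insertion context
  subPos <- c(20L, 60L, 120L, 160L, 200L, 240L, 360L, 400L, 500L, 550L)
  mut <- ch
  for (p in subPos) mut[p + 1L] <- setdiff(c("A", "C", "G", "T"), ch[p + 1L])[1L]
  mut <- append(mut, c("C", "A"), after = 450L)   # ins before 0-based 450
  mut <- mut[-(302:303)]                           # del of 0-based 301..302
  psv <- deriveSignatureVariants(paste(ch, collapse = ""),
                                 paste(mut, collapse = ""))
  expect_equal(nrow(psv), 12L)
  expect_setequal(psv$gene_pos[psv$kind == "SNV"], subPos)
  expect_equal(psv$gene_pos[psv$kind == "del"], 301L)
  expect_equal(psv$gene_allele[psv$kind == "del"], "GT")
  expect_equal(psv$gene_pos[psv$kind == "ins"], 450L)
  expect_equal(psv$pseudo_allele[psv$kind == "ins"], "CA")

  # symmetry: swapping the references exchanges alleles and coordinates
  rev_ <- deriveSignatureVariants(paste(mut, collapse = ""),
                                  paste(ch, collapse = ""))
  expect_equal(nrow(rev_), 12L)
  expect_setequal(rev_$gene_pos[rev_$kind == "SNV"], psv$pseudo_pos[psv$kind == "SNV"])
  expect_equal(sum(rev_$kind == "ins"), 1L)  # the planted del, seen mirrored
  expect_equal(rev_$pseudo_allele[rev_$kind == "ins"], "GT")
  expect_equal(sum(rev_$kind == "del"), 1L)
  expect_equal(rev_$gene_allele[rev_$kind == "del"], "CA")
})

test_that("non-homologous sequences are rejected", {
  set.seed(9)
  a <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_error(deriveSignatureVariants(a, b), "not homologous")
  expect_error(deriveSignatureVariants("", a), "empty")
  expect_error(deriveSignatureVariants("ACGN", "ACGT"), "alphabet")
})

test_that("coding names map to the coordinates implied by the exon table", {
  locus <- test_locus()
  cm <- cdsMap(locus)
  # independent oracle: offset arithmetic straight off the packaged table
  v <- parseCodingName("c.518T>A", locus)
  expect_equal(v$gene_pos, cm$ref_start[3L] + (518L - cm$coding_start[3L]))
  expect_equal(v$ref, "T"); expect_equal(v$alt, "A")
  v2 <- parseCodingName("c.293-13C>G", locus)
  expect_equal(v2$gene_pos, cm$ref_start[3L] - 13L)
  v3 <- parseCodingName("c.*1215C>T", locus)
  expect_equal(v3$gene_pos, locus@utr3Start + 1214L)
  v4 <- parseCodingName("c.92C>T", locus)
  expect_equal(v4$gene_pos, cm$ref_start[1L] + 91L)

  expect_error(parseCodingName("c.518G>A", locus), class = "cah_ref_mismatch")
  expect_error(parseCodingName("c.nonsense", locus), class = "cah_parse_error")
  expect_error(parseCodingName("c.10712G>A", locus), class = "cah_parse_error")
  expect_error(parseCodingName("c.293-99C>G", locus), class = "cah_parse_error")
})

test_that("parse and format round-trip on every mappable knowledge-base name", {
  locus <- test_locus()
  kb <- test_kb()
  nms <- kbEntries(kb)$name
  mappable <- nms[!grepl("_CH-|^STAR:", nms) & nms != "c.10712G>A"]
  expect_length(mappable, 11L)
  for (nm in mappable) {
    v <- parseCodingName(nm, locus)
    kind <- if (v$kind == "dup") "ins" else v$kind
    back <- formatCodingName(v$gene_pos, v$ref, v$alt, kind, locus)
    expect_identical(back, nm)
  }
})

test_that("the packaged knowledge base matches the study tables", {
  kb <- test_kb()
  e <- kbEntries(kb)
  patho <- e[e$classification == "P", ]
  expect_equal(nrow(patho), 11L)
  expect_equal(sum(grepl("_CH-?", patho$name)), 3L)   # structural classes
  expect_equal(sum(!grepl("_CH-?", patho$name)), 8L)  # SNVs/indels
  expect_equal(sort(patho$name[patho$allele_tally == 7L]),
               c("c.293-13C>G", "c.518T>A"))
  expect_equal(e$phenotype[e$name == "c.92C>T"], "unknown")
})

test_that("knowledge-base loading validates its input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tclassification\tphenotype",
               "c.518T>A\tP\tSV", "c.518T>A\tP\tSV"), tmp)
  expect_error(loadVariantKB(tmp), "duplicate")
  writeLines(c("name\tclassification\tphenotype", "c.1A>G\t\tSW"), tmp)
  expect_error(loadVariantKB(tmp), "missing classification")
  writeLines("name\tclassification\tphenotype", tmp)
  expect_equal(nrow(kbEntries(loadVariantKB(tmp))), 0L)
  writeLines(c("name,classification,phenotype", "c.1A>G,VUS,odd"), tmp)
  expect_equal(kbEntries(loadVariantKB(tmp))$phenotype, "unknown")
})

test_that("locus files round-trip through FASTA + JSON", {
  locus <- test_locus()
  dir <- withr::local_tempdir()
  writeLocusFiles(locus, dir)
  back <- loadLocusFiles(dir)
  expect_identical(as.character(geneRef(back)), as.character(geneRef(locus)))
  expect_identical(as.character(pseudoRef(back)), as.character(pseudoRef(locus)))
  expect_equal(psvTable(back)$gene_pos, psvTable(locus)$gene_pos)
  expect_identical(primerSet(back), primerSet(locus))
  expect_equal(junctionBins(back)$label, junctionBins(locus)$label)
})
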