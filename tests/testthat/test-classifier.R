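# Demultiplexing and primer-pair classification.

test_that("demultiplexing assigns by leading barcode with one-mismatch tolerance", {
  locus <- test_locus()
  bcs <- defaultBarcodes(3)
  h <- haplotypeSpec("A")
  pool <- list()
  for (i in 1:3) {
    rs <- simulateReads(h, h, locus, depth = 10, error_model = errorModel(0, 0, 0),
                        barcode = bcs[[i]], seed = i, case_id = names(bcs)[i])
    pool[[i]] <- rs
  }
  seqs <- do.call(c, lapply(pool, readSequences))
  names(seqs) <- paste0("r", seq_along(seqs))
  quals <- do.call(c, lapply(pool, readQualities))
  names(quals) <- names(seqs)
  truth <- unlist(lapply(pool, truthTags))
  merged <- new("ReadSet", sequences = seqs, qualities = quals,
                truth = rep(names(bcs), each = 20L), sample = NA_character_)
  dm <- demultiplexReads(merged, bcs)
  expect_equal(sum(vapply(dm, length, integer(1L))), length(merged))
  for (nm in names(bcs)) {
    expect_equal(length(dm[[nm]]), 20L)
    expect_true(all(truthTags(dm[[nm]]) == nm))
    # barcode stripped: reads now start at the amplicon
    expect_equal(unique(Biostrings::width(readSequences(dm[[nm]]))),
                 unique(Biostrings::width(readSequences(pool[[1L]]))) -
                   nchar(bcs[[1L]]))
  }

  # one mismatch is tolerated, two are not
  one <- readSequences(merged)[1L]
  s <- as.character(one[[1L]])
  substr(s, 1, 1) <- if (substr(s, 1, 1) == "A") "C" else "A"
  twoMm <- s
  substr(twoMm, 2, 2) <- if (substr(twoMm, 2, 2) == "A") "C" else "A"
  mk <- function(x) new("ReadSet",
                        sequences = Biostrings::DNAStringSet(c(r = x)),
                        qualities = Biostrings::BStringSet(c(r = strrep("I", nchar(x)))),
                        truth = NA_character_, sample = NA_character_)
  expect_equal(length(demultiplexReads(mk(s), bcs)[[1L]]), 1L)
  expect_equal(length(demultiplexReads(mk(twoMm), bcs)[["undetermined"]]), 1L)

  # close barcodes are rejected up front
  bad <- c(s1 = "ACGTACGTACGTACGT", s2 = "ACGTACGTACGTACGA")
  expect_error(demultiplexReads(merged, bad), "Hamming")
})

test_that("classification recovers the simulated amplicon category", {
  locus <- test_locus()
  em0 <- errorModel(0, 0, 0)
  mkrs <- function(hA, hB, seed) simulateReads(hA, hB, locus, depth = 20,
                                               error_model = em0, seed = seed)
  rs <- mkrs(haplotypeSpec("A", variants = "c.518T>A"),
             haplotypeSpec("B", structure = "DEL_CHIMERA", bin = "CH-1"), 2)
  cl <- classifyReads(rs, locus)
  tags <- truthTags(rs)
  expect_true(all(cl$classes[grepl(":gene", tags)] == "FUNCTIONAL"))
  expect_true(all(cl$classes[grepl(":pseudo", tags)] == "PSEUDO"))
  expect_true(all(cl$classes[grepl(":fused", tags)] == "DEL_CHIMERA"))

  # conversion haplotypes keep gene primers, so they classify FUNCTIONAL
  rsc <- mkrs(haplotypeSpec("A", structure = "CONV_CHIMERA", bin = "CH-2"),
              haplotypeSpec("B"), 4)
  clc <- classifyReads(rsc, locus)
  expect_true(all(clc$classes[grepl(":conv", truthTags(rsc))] == "FUNCTIONAL"))

  # random sequence is never silently dropped, just UNASSIGNED
  expect_equal(classifyRead(paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                                  collapse = ""), locus), "UNASSIGNED")
})

test_that("classification is orientation-insensitive and conserves reads", {
  locus <- test_locus()
  rs <- simulateReads(haplotypeSpec("A", variants = "c.518T>A"),
                      haplotypeSpec("B", structure = "DEL_CHIMERA", bin = "CH-1"),
                      locus, depth = 20, seed = 8)
  cl <- classifyReads(rs, locus)
  counts <- table(factor(cl$classes, levels = CAHscreen:::.READ_CLASSES))
  expect_equal(sum(counts), length(rs))
  rc <- new("ReadSet",
            sequences = Biostrings::reverseComplement(readSequences(rs)),
            qualities = readQualities(rs), truth = truthTags(rs),
            sample = NA_character_)
  clrc <- classifyReads(rc, locus)
  expect_equal(table(factor(clrc$classes, levels = CAHscreen:::.READ_CLASSES)),
               counts)
})

test_that("classification agrees with simulation truth under the default error model", {
  locus <- test_locus()
  n <- 0L; agree <- 0L
  for (s in 1:6) {
    rs <- simulateReads(haplotypeSpec("A"),
                        haplotypeSpec("B", structure = "DEL_CHIMERA", bin = "CH-5"),
                        locus, depth = 120, seed = 100 + s)
    cl <- classifyReads(rs, locus)
    want <- ifelse(grepl(":gene", truthTags(rs)), "FUNCTIONAL",
                   ifelse(grepl(":pseudo", truthTags(rs)), "PSEUDO",
                          "DEL_CHIMERA"))
    n <- n + length(rs)
    agree <- agree + sum(cl$classes == want)
  }
  expect_gt(n, 1000L)
  expect_gte(agree / n, 0.99)
})
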