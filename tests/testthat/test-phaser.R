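# PSV vectors, junction changepoints, bins and phasing.

test_that("PSV vectors reflect the read's paralog state at every site", {
  locus <- test_locus()
  rf <- as.character(geneRef(locus))
  aG <- alignRead(rf, rf)
  expect_true(all(psvGenotypeVector(aG, locus) == "G"))

  p <- psvTable(locus)
  bins <- junctionBins(locus)
  row <- which(bins$label == "CH-3")
  bp <- p$gene_pos[bins$psv_lo[row]] + 4L
  fused <- as.character(buildHaplotype(
    haplotypeSpec("A", structure = "DEL_CHIMERA", bin = "CH-3"),
    locus, breakpoint = bp)$seqs[[1L]])
  v <- psvGenotypeVector(alignRead(fused, rf), locus)
  want <- ifelse(p$gene_pos < bp, "P", "G")
  expect_identical(v, want)

  # an error at a SNV PSV flips the state or goes missing
  snvIdx <- which(p$kind == "SNV")[5L]
  ch <- strsplit(rf, "")[[1L]]
  ch[p$gene_pos[snvIdx] + 1L] <- p$pseudo_allele[snvIdx]
  vP <- psvGenotypeVector(alignRead(paste(ch, collapse = ""), rf), locus)
  expect_equal(vP[snvIdx], "P")
  expect_true(all(vP[-snvIdx] == "G"))
  third <- setdiff(c("A", "C", "G", "T"),
                   c(p$gene_allele[snvIdx], p$pseudo_allele[snvIdx]))[1L]
  ch[p$gene_pos[snvIdx] + 1L] <- third
  vM <- psvGenotypeVector(alignRead(paste(ch, collapse = ""), rf), locus)
  expect_equal(vM[snvIdx], "M")

  # indel PSVs are scored through their exact indel events
  delIdx <- which(p$kind == "del")[1L]
  ch2 <- strsplit(rf, "")[[1L]]
  ch2 <- ch2[-(p$gene_pos[delIdx] + seq_len(nchar(p$gene_allele[delIdx])))]
  vD <- psvGenotypeVector(alignRead(paste(ch2, collapse = ""), rf), locus)
  expect_equal(vD[delIdx], "P")
})

test_that("junction changepoint matches exhaustive search", {
  j <- locateJunction(c("P", "P", "P", "G", "G"))
  expect_equal(j$left_index, 3L)
  expect_equal(j$right_index, 4L)
  expect_equal(j$cost, 0L)

  # cost-1 vector: leftmost minimal cut wins
  j2 <- locateJunction(c("P", "G", "P", "G", "G"))
  b2 <- brute_junction(c("P", "G", "P", "G", "G"))
  expect_equal(j2$cost, b2$cost)
  expect_equal(j2$left_index, b2$left)
  expect_equal(j2$right_index, b2$right)

  expect_equal(locateJunction(c("G", "G", "G", "G"))$sentinel, "no_pseudo")
  expect_equal(locateJunction(c("P", "P", "M", "P"))$sentinel, "no_gene")
  expect_error(locateJunction(c("M", "M", "P")), "informative")

  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:200, 1L)
    v <- sample(c("P", "G", "M"), n, TRUE, prob = c(0.45, 0.45, 0.1))
    if (sum(v != "M") < 2L) next
    mine <- locateJunction(v)
    oracle <- brute_junction(v)
    expect_equal(mine$cost, oracle$cost)
    if (is.na(mine$sentinel)) {
      expect_equal(mine$left_index, oracle$left)
      expect_equal(mine$right_index, oracle$right)
    }
  }
})

test_that("junctions are binned by midpoint with a left-bin tie rule", {
  locus <- test_locus()
  p <- psvTable(locus)
  bins <- junctionBins(locus)
  mkj <- function(li, ri) list(sentinel = NA_character_, left_index = li,
                               right_index = ri, cost = 0L, n_informative = 2L)
  # breakpoints simulated inside a bin come back in that bin
  for (lbl in c("CH-1", "CH-8", "TNX-CH-1")) {
    row <- which(bins$label == lbl)
    b <- binJunction(mkj(bins$psv_lo[row], bins$psv_hi[row]), locus)
    expect_equal(b$label, lbl)
    expect_false(b$ambiguous)
  }
  # an interval straddling a boundary: left bin, flagged ambiguous
  row <- which(bins$label == "CH-2")
  jAmb <- mkj(bins$psv_hi[row], bins$psv_hi[row] + 1L)
  bAmb <- binJunction(jAmb, locus)
  expect_equal(bAmb$label, "CH-2")
  expect_true(bAmb$ambiguous)
  # sentinels cannot be binned
  expect_error(binJunction(list(sentinel = "no_pseudo"), locus), "sentinel")
  # MISSING states do not change the assignment (junction is defined by the
  # informative PSVs only)
  v <- ifelse(p$gene_pos < bins$end[3L] - 1L, "P", "G")
  withM <- v; withM[c(1L, length(v))] <- "M"
  j1 <- locateJunction(v); j2 <- locateJunction(withM)
  if (is.na(j1$sentinel) && is.na(j2$sentinel))
    expect_equal(binJunction(j1, locus)$label, binJunction(j2, locus)$label)
})

test_that("phasing separates haplotypes and is stable under read order", {
  # perfect single-het partition
  alleles <- c(lapply(stats::setNames(sprintf("a%02d", 1:6), sprintf("a%02d", 1:6)),
                      function(i) "ref"),
               lapply(stats::setNames(sprintf("b%02d", 1:6), sprintf("b%02d", 1:6)),
                      function(i) "alt"))
  ph <- phaseReads(alleles)
  expect_equal(length(ph$groups), 2L)
  expect_setequal(lapply(ph$groups, sort),
                  list(sprintf("a%02d", 1:6), sprintf("b%02d", 1:6)))
  # shuffled input gives the same partition
  ph2 <- phaseReads(alleles[sample(names(alleles))])
  expect_equal(ph2$groups, ph$groups)

  # no heterozygous site: one trivial group
  hom <- lapply(stats::setNames(nm = sprintf("r%02d", 1:5)),
                function(i) character(0))
  expect_equal(length(phaseReads(hom)$groups), 1L)

  # a read conflicting with both consensi is set aside as noise
  m5 <- c(lapply(stats::setNames(nm = sprintf("a%02d", 1:5)),
                 function(i) rep("ref", 5L)),
          lapply(stats::setNames(nm = sprintf("b%02d", 1:5)),
                 function(i) rep("alt", 5L)),
          list(zz = c("ref", "alt", "ref", "alt", "ref")))
  ph3 <- phaseReads(m5)
  expect_equal(ph3$noise, "zz")

  # agreement with an exhaustive minimum-error oracle on noisy small cases
  # (10 sites: one flipped site is still within the 80% agreement band, so
  # the corrupted read stays in its true group, exactly as the oracle says)
  set.seed(123)
  for (rep_ in 1:20) {
    truthA <- sample(c("ref", "alt"), 10L, TRUE)
    truthB <- ifelse(truthA == "ref", "alt", "ref")
    reads <- list()
    for (i in 1:4) reads[[sprintf("a%02d", i)]] <- truthA
    for (i in 1:4) reads[[sprintf("b%02d", i)]] <- truthB
    flip <- sample(10L, 1L)
    reads[["a01"]][flip] <- ifelse(reads[["a01"]][flip] == "ref", "alt", "ref")
    mine <- phaseReads(reads)
    oracle <- brute_phase(reads)
    expect_equal(length(mine$groups), 2L)
    expect_setequal(lapply(mine$groups, sort), oracle$groups)
    expect_length(mine$noise, 0L)
  }
  # with few sites a single flip exceeds the 20% conflict rule: the
  # corrupted read is set aside as noise rather than forced into a group
  reads4 <- list(a01 = c("alt", "ref", "ref", "ref"),
                 a02 = rep("ref", 4L), a03 = rep("ref", 4L),
                 b01 = rep("alt", 4L), b02 = rep("alt", 4L),
                 b03 = rep("alt", 4L))
  ph4 <- phaseReads(reads4)
  expect_equal(ph4$noise, "a01")
  expect_setequal(lapply(ph4$groups, sort),
                  list(c("a02", "a03"), c("b01", "b02", "b03")))
})

test_that("phasing recovers the simulated haplotype partition", {
  locus <- test_locus(); kb <- test_kb()
  cs <- table1Specs()[[1L]]
  rs <- simulateReads(cs$hapA, cs$hapB, locus, depth = 40,
                      error_model = errorModel(0, 0, 0), seed = 21)
  dp <- screenSample(rs, locus, kb)
  expect_setequal(
    list(sort(variantSet(dp@hapA)), sort(variantSet(dp@hapB))),
    list(sort(cs$hapA@variants), sort(cs$hapB@variants)))
})
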