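# Diplotype construction and CCS-like read simulation.

#' Construct an error model
#'
#' Defaults emulate residual circular-consensus error (accuracy well above
#' Q20): 0.3% substitutions, 0.1% insertions, 0.1% deletions per base.
#'
#' @param substitution,ins,del per-base probabilities in `[0, 0.05]`.
#' @return an [ErrorModel-class].
#' @export
errorModel <- function(substitution = 0.003, ins = 0.001, del = 0.001) {
  new("ErrorModel", substitutionRate = substitution, insRate = ins,
      delRate = del)
}

#' Construct a haplotype specification
#'
#' @param label haplotype label.
#' @param variants coding-style variant names carried by the haplotype.
#' @param structure `"NORMAL"`, `"DEL_CHIMERA"`, `"CONV_CHIMERA"`,
#'   `"TNX_CHIMERA"` or `"DUP_FUSION"`.
#' @param bin junction bin label for chimeric structures.
#' @param copies intact functional-gene copies (`DUP_FUSION` only).
#' @param fusedVariants variant names on the gene-derived segment of the
#'   fused copy (`DUP_FUSION` only).
#' @return a [HaplotypeSpec-class].
#' @export
haplotypeSpec <- function(label, variants = character(0),
                          structure = "NORMAL", bin = NA_character_,
                          copies = 1L, fusedVariants = character(0)) {
  new("HaplotypeSpec", label = label, variants = as.character(variants),
      structure = structure, bin = bin, copies = as.integer(copies),
      fusedVariants = as.character(fusedVariants))
}

# Uniform breakpoint strictly between the first and last PSV of a bin
# (never inside an indel PSV), using the current RNG stream.
.sampleBreakpoint <- function(locus, bin) {
  b <- locus@junctionBins
  row <- which(b$label == bin)
  if (!length(row)) stop("unknown junction bin: ", bin)
  p <- locus@psvs
  lo <- p$gene_pos[b$psv_lo[row]] + max(1L, nchar(p$gene_allele[b$psv_lo[row]])) + 1L
  hi <- p$gene_pos[b$psv_hi[row]] - 1L
  if (lo >= hi) return(as.integer(floor((lo + hi) / 2)))
  lo + sample.int(hi - lo, 1L)
}

# Apply parsed variant events to a character vector holding a sequence whose
# coordinate `off` maps reference position `gene_pos` to index
# gene_pos - shift + 1. Events are applied right-to-left.
.applyEvents <- function(chars, events, shift = 0L) {
  if (!nrow(events)) return(chars)
  events <- events[order(events$gene_pos, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    idx <- e$gene_pos - shift + 1L
    if (e$kind == "SNV") {
      chars[idx] <- e$alt
    } else if (e$kind == "del") {
      chars <- chars[-(idx:(idx + nchar(e$ref) - 1L))]
    } else {  # ins / dup: insert alt before gene_pos
      chars <- append(chars, strsplit(e$alt, "")[[1L]], after = idx - 1L)
    }
  }
  chars
}

.parseVariantEvents <- function(variants, locus) {
  if (!length(variants))
    return(data.frame(name = character(0), gene_pos = integer(0),
                      ref = character(0), alt = character(0),
                      kind = character(0)))
  do.call(rbind, lapply(variants, parseCodingName, locus = locus))
}

#' Build the amplicon sequences of one haplotype
#'
#' `NORMAL` yields a functional-gene amplicon (with the spec's variants
#' applied) plus a pseudogene amplicon. `DEL_CHIMERA` / `TNX_CHIMERA` yield a
#' single fused amplicon: pseudogene reference up to a breakpoint inside the
#' named bin, functional-gene reference after it, flanked by the
#' pseudo-forward and gene-reverse primers. `CONV_CHIMERA` yields a
#' functional-gene amplicon whose 5' body tract carries the pseudogene
#' alleles up to the breakpoint (gene primers retained), plus the pseudogene
#' amplicon. `DUP_FUSION` yields the fused amplicon, `copies` intact gene
#' amplicons and the pseudogene amplicon.
#'
#' @param spec a [HaplotypeSpec-class].
#' @param locus a [LocusModel-class].
#' @param breakpoint optional fixed 0-based breakpoint on `geneRef`; sampled
#'   uniformly inside the bin (current RNG stream) when `NULL`.
#' @return list with `seqs` ([Biostrings::DNAStringSet], one per amplicon),
#'   `types` (`"gene"`, `"pseudo"`, `"fused"`, `"conv"`), and `breakpoint`.
#' @export
buildHaplotype <- function(spec, locus, breakpoint = NULL) {
  validObject(spec)
  gene <- strsplit(as.character(locus@geneRef), "")[[1L]]
  pseudo <- strsplit(as.character(locus@pseudoRef), "")[[1L]]
  events <- .parseVariantEvents(spec@variants, locus)
  bp <- NA_integer_
  needBp <- spec@structure %in% c("DEL_CHIMERA", "TNX_CHIMERA", "CONV_CHIMERA",
                                  "DUP_FUSION")
  if (needBp)
    bp <- if (is.null(breakpoint)) .sampleBreakpoint(locus, spec@bin)
          else as.integer(breakpoint)

  fusedSeq <- function(fusedEvents) {
    pre <- .pseudoPrefixLen(locus, bp)
    out <- c(pseudo[seq_len(pre)], gene[(bp + 1L):length(gene)])
    if (nrow(fusedEvents)) {
      if (any(fusedEvents$gene_pos < bp))
        stop("variant coordinate deleted by the structure: ",
             paste(fusedEvents$name[fusedEvents$gene_pos < bp], collapse = ", "))
      # gene-side coordinates shift by (pre - bp)
      out <- .applyEvents(out, fusedEvents, shift = bp - pre)
    }
    out
  }

  seqs <- list(); types <- character(0)
  add <- function(chars, type) {
    seqs[[length(seqs) + 1L]] <<- paste(chars, collapse = "")
    types <<- c(types, type)
  }
  st <- spec@structure
  if (st == "NORMAL") {
    add(.applyEvents(gene, events), "gene")
    add(pseudo, "pseudo")
  } else if (st %in% c("DEL_CHIMERA", "TNX_CHIMERA")) {
    add(fusedSeq(events), "fused")
  } else if (st == "CONV_CHIMERA") {
    if (nrow(events) && any(events$gene_pos < bp & events$gene_pos >= locus@bodyStart))
      stop("variant coordinate deleted by the structure (conversion tract)")
    pre <- .pseudoPrefixLen(locus, bp)
    conv <- c(gene[seq_len(locus@bodyStart)],
              pseudo[(locus@bodyStart + 1L):pre],
              gene[(bp + 1L):length(gene)])
    conv <- .applyEvents(conv, events, shift = bp - pre)
    add(conv, "conv")
    add(pseudo, "pseudo")
  } else {  # DUP_FUSION
    fe <- .parseVariantEvents(spec@fusedVariants, locus)
    add(fusedSeq(fe), "fused")
    for (i in seq_len(spec@copies)) add(.applyEvents(gene, events), "gene")
    add(pseudo, "pseudo")
  }
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- paste0(spec@label, ":", types,
                       ifelse(duplicated(types), paste0(".", seq_along(types)), ""))
  list(seqs = dss, types = types, breakpoint = bp)
}

# Inject per-base errors into a character vector; indel counts are tiny so
# targeted splicing is cheapest.
.injectErrors <- function(chars, em) {
  L <- length(chars)
  ns <- stats::rbinom(1L, L, em@substitutionRate)
  if (ns > 0L) {
    at <- sample.int(L, ns)
    chars[at] <- vapply(chars[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1L))
  }
  nd <- stats::rbinom(1L, L, em@delRate)
  ni <- stats::rbinom(1L, L, em@insRate)
  if (nd + ni > 0L) {
    ops <- data.frame(pos = c(if (nd) sample.int(L, nd) else integer(0),
                              if (ni) sample.int(L, ni) else integer(0)),
                      type = rep(c("D", "I"), c(nd, ni)))
    ops <- ops[order(ops$pos, decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(ops))) {
      if (ops$type[i] == "D") chars <- chars[-ops$pos[i]]
      else chars <- append(chars, sample(c("A", "C", "G", "T"), 1L),
                           after = ops$pos[i])
    }
  }
  chars
}

#' Simulate reads for a diplotype
#'
#' Every amplicon of each haplotype is sampled `round(depth / 2)` times
#' full-length (deterministic allocation, so small-depth tests are exact),
#' per-base errors are injected from the error model, and truth tags record
#' the generating haplotype and amplicon. Deterministic for a fixed seed.
#'
#' @param hapA,hapB [HaplotypeSpec-class] objects.
#' @param locus a [LocusModel-class].
#' @param depth target per-haplotype coverage (>= 1).
#' @param error_model an [ErrorModel-class].
#' @param barcode optional barcode string prepended to every read.
#' @param seed integer seed.
#' @param case_id sample label used in read ids.
#' @return a [ReadSet-class].
#' @export
simulateReads <- function(hapA, hapB, locus, depth = 100L,
                          error_model = errorModel(), barcode = NULL,
                          seed = 1L, case_id = "sample") {
  if (depth < 1L) stop("depth must be >= 1")
  withSeed(seed, {
    built <- list(A = buildHaplotype(hapA, locus), B = buildHaplotype(hapB, locus))
    nPer <- max(1L, as.integer(round(depth / 2)))
    bc <- if (is.null(barcode)) character(0) else strsplit(barcode, "")[[1L]]
    seqs <- list(); quals <- list(); truth <- character(0); ids <- character(0)
    k <- 0L
    for (h in c("A", "B")) {
      amp <- built[[h]]
      for (a in seq_along(amp$seqs)) {
        tmpl <- strsplit(as.character(amp$seqs[[a]]), "")[[1L]]
        tag <- paste0(h, ":", amp$types[a])
        for (r in seq_len(nPer)) {
          k <- k + 1L
          rd <- c(bc, .injectErrors(tmpl, error_model))
          seqs[[k]] <- paste(rd, collapse = "")
          quals[[k]] <- strrep("I", length(rd))
          truth[k] <- tag
          ids[k] <- sprintf("%s_%s_%s_r%03d", case_id, h, amp$types[a], r)
        }
      }
    }
    dss <- Biostrings::DNAStringSet(unlist(seqs))
    names(dss) <- ids
    q <- Biostrings::BStringSet(unlist(quals))
    names(q) <- ids
    new("ReadSet", sequences = dss, qualities = q, truth = truth,
        sample = case_id)
  })
}

#' Deterministic barcode table
#'
#' Greedy seeded construction of `n` barcodes with pairwise Hamming distance
#' of at least `min_dist`.
#'
#' @param n number of barcodes.
#' @param width barcode length.
#' @param min_dist minimum pairwise Hamming distance.
#' @return named character vector (`BC001`, `BC002`, ...).
#' @export
defaultBarcodes <- function(n = 96L, width = 16L, min_dist = 3L) {
  withSeed(7731L, {
    out <- character(0)
    while (length(out) < n) {
      cand <- randomDNA(width)
      if (!length(out) || all(hammingDist(cand, out) >= min_dist))
        out <- c(out, cand)
    }
    names(out) <- sprintf("BC%03d", seq_len(n))
    out
  })
}
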