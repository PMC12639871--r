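# Barcode demultiplexing and primer-pair read classification.

.READ_CLASSES <- c("FUNCTIONAL", "PSEUDO", "DEL_CHIMERA", "CONV_CHIMERA",
                   "TNX_CHIMERA", "UNASSIGNED")

# Hamming distance between every sequence prefix and one barcode.
.prefixMismatches <- function(seqs, barcode) {
  bl <- nchar(barcode)
  pre <- Biostrings::subseq(seqs, 1L, pmin(Biostrings::width(seqs), bl))
  out <- rep.int(bl, length(seqs))
  ok <- Biostrings::width(pre) == bl
  if (any(ok)) {
    m <- matrix(unlist(strsplit(as.character(pre[ok]), "")), ncol = bl,
                byrow = TRUE)
    bc <- strsplit(barcode, "")[[1L]]
    out[ok] <- rowSums(m != matrix(bc, nrow = sum(ok), ncol = bl, byrow = TRUE))
  }
  out
}

#' Demultiplex reads by leading barcode
#'
#' A read is assigned iff its leading barcode matches a table entry with at
#' most one mismatch (both orientations are tried; reads matched on the
#' reverse strand are reverse-complemented so downstream stages see a
#' consistent orientation). Matched barcodes are stripped. Everything else
#' lands in the `"undetermined"` bin; bin sizes always sum to the input
#' size.
#'
#' @param rs a [ReadSet-class] of pooled reads.
#' @param barcode_table named character vector (sample -> barcode); barcodes
#'   must be equal-length with pairwise Hamming distance >= 3.
#' @param max_mismatch per-barcode mismatch tolerance (default 1).
#' @return named list of [ReadSet-class] objects (samples plus
#'   `"undetermined"`).
#' @export
demultiplexReads <- function(rs, barcode_table, max_mismatch = 1L) {
  bcs <- barcode_table
  if (is.null(names(bcs)) || any(names(bcs) == ""))
    stop("barcode table must be a named vector (sample -> barcode)")
  if (length(unique(nchar(bcs))) != 1L)
    stop("barcodes must have equal length")
  if (length(bcs) > 1L) {
    for (i in seq_len(length(bcs) - 1L)) {
      d <- hammingDist(bcs[i], bcs[(i + 1L):length(bcs)])
      if (any(d < 3L))
        stop("barcodes violate the pairwise Hamming distance >= 3 precondition")
    }
  }
  bl <- nchar(bcs[[1L]])
  seqs <- rs@sequences
  mm <- vapply(bcs, function(b) .prefixMismatches(seqs, b),
               numeric(length(seqs)))
  mm <- matrix(mm, nrow = length(seqs))
  hit <- apply(mm, 1L, function(r) {
    w <- which(r <= max_mismatch)
    if (length(w) == 1L) w else NA_integer_
  })
  rcseqs <- Biostrings::reverseComplement(seqs)
  needRC <- is.na(hit)
  if (any(needRC)) {
    mm2 <- vapply(bcs, function(b) .prefixMismatches(rcseqs[needRC], b),
                  numeric(sum(needRC)))
    mm2 <- matrix(mm2, nrow = sum(needRC))
    hit2 <- apply(mm2, 1L, function(r) {
      w <- which(r <= max_mismatch)
      if (length(w) == 1L) w else NA_integer_
    })
    hit[needRC] <- hit2
  } else {
    hit2 <- integer(0)
  }
  flipped <- logical(length(seqs))
  flipped[needRC] <- !is.na(hit[needRC])

  out <- vector("list", length(bcs) + 1L)
  names(out) <- c(names(bcs), "undetermined")
  for (s in seq_along(bcs)) {
    idx <- which(hit == s)
    if (!length(idx)) {
      out[[s]] <- new("ReadSet", sequences = Biostrings::DNAStringSet(),
                      qualities = Biostrings::BStringSet(),
                      truth = character(0), sample = names(bcs)[s])
      next
    }
    sq <- seqs[idx]
    sq[flipped[idx]] <- rcseqs[idx][flipped[idx]]
    q <- rs@qualities[idx]
    q[flipped[idx]] <- Biostrings::BStringSet(
      vapply(as.character(q[flipped[idx]]),
             function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = ""),
             character(1L), USE.NAMES = FALSE))
    sq <- Biostrings::subseq(sq, bl + 1L)
    q <- Biostrings::subseq(q, bl + 1L)
    out[[s]] <- new("ReadSet", sequences = sq, qualities = q,
                    truth = rs@truth[idx], sample = names(bcs)[s])
  }
  und <- which(is.na(hit))
  out[["undetermined"]] <- new("ReadSet", sequences = seqs[und],
                               qualities = rs@qualities[und],
                               truth = rs@truth[und],
                               sample = "undetermined")
  out
}

# primer presence in head/tail windows, one orientation
.primerHits <- function(seqs, primers, window) {
  w <- Biostrings::width(seqs)
  head_ <- Biostrings::subseq(seqs, 1L, pmin(w, window))
  tail_ <- Biostrings::subseq(seqs, pmax(1L, w - window + 1L), w)
  fwdNames <- intersect(c("gene_fwd", "pseudo_fwd", "conv_fwd"), names(primers))
  revNames <- intersect(c("gene_rev", "pseudo_rev", "tnx_rev"), names(primers))
  # one edit (mismatch or indel) tolerated: high-accuracy long reads rarely
  # corrupt a 20-mer twice, but single indel errors are as common as
  # substitutions
  fwd <- vapply(fwdNames, function(p)
    Biostrings::vcountPattern(primers[[p]], head_, max.mismatch = 1L,
                              with.indels = TRUE) > 0L,
    logical(length(seqs)))
  rev_ <- vapply(revNames, function(p)
    Biostrings::vcountPattern(revcomp(primers[[p]]), tail_,
                              max.mismatch = 1L, with.indels = TRUE) > 0L,
    logical(length(seqs)))
  list(fwd = matrix(fwd, nrow = length(seqs),
                    dimnames = list(NULL, fwdNames)),
       rev = matrix(rev_, nrow = length(seqs),
                    dimnames = list(NULL, revNames)))
}

.classFromHits <- function(hits) {
  f <- hits$fwd; r <- hits$rev
  n <- nrow(f)
  cls <- rep("UNASSIGNED", n)
  one <- function(m, name) if (name %in% colnames(m)) m[, name] else rep(FALSE, n)
  gF <- one(f, "gene_fwd"); pF <- one(f, "pseudo_fwd"); cF <- one(f, "conv_fwd")
  gR <- one(r, "gene_rev"); pR <- one(r, "pseudo_rev"); tR <- one(r, "tnx_rev")
  uniqF <- rowSums(f) == 1L
  uniqR <- rowSums(r) == 1L
  set <- function(cond, label) cls[uniqF & uniqR & cond & cls == "UNASSIGNED"] <<- label
  set(gF & gR, "FUNCTIONAL")
  set(pF & pR, "PSEUDO")
  set(pF & gR, "DEL_CHIMERA")
  set(cF & gR, "CONV_CHIMERA")
  set(pF & tR, "TNX_CHIMERA")
  cls
}

#' Classify reads into amplicon categories by their primer pairs
#'
#' Looks for a forward primer within the first `window` bases and the
#' reverse-complemented reverse primer within the last `window` bases, each
#' tolerating one mismatch. (gene-F, gene-R) reads are the functional gene;
#' (pseudo-F, pseudo-R) the pseudogene; (pseudo-F, gene-R) the
#' 30-kb-deletion chimera family (TNXA/TNXB chimeras are separated later by
#' junction bin); a configured `conv_fwd` primer maps (conv-F, gene-R) to
#' conversion chimeras. Classification is orientation-insensitive; nothing
#' is dropped — unmatched reads are `UNASSIGNED`.
#'
#' @param rs a [ReadSet-class] (barcodes already stripped).
#' @param locus a [LocusModel-class] (its primer set is used).
#' @param window search window; default primer length + 5.
#' @return list with `classes` (character vector, one of FUNCTIONAL, PSEUDO,
#'   DEL_CHIMERA, CONV_CHIMERA, TNX_CHIMERA, UNASSIGNED), and `reads` (the
#'   input with reverse-strand reads flipped to the forward orientation).
#' @export
classifyReads <- function(rs, locus, window = NULL) {
  primers <- locus@primers
  if (is.null(window)) window <- nchar(primers[[1L]]) + 5L
  seqs <- rs@sequences
  cls <- .classFromHits(.primerHits(seqs, primers, window))
  unas <- cls == "UNASSIGNED"
  flipped <- logical(length(seqs))
  if (any(unas)) {
    rc <- Biostrings::reverseComplement(seqs[unas])
    cls2 <- .classFromHits(.primerHits(rc, primers, window))
    fixed <- cls2 != "UNASSIGNED"
    idx <- which(unas)[fixed]
    cls[idx] <- cls2[fixed]
    flipped[idx] <- TRUE
    seqs[idx] <- rc[fixed]
  }
  q <- rs@qualities
  if (any(flipped)) {
    q[flipped] <- Biostrings::BStringSet(
      vapply(as.character(q[flipped]),
             function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = ""),
             character(1L), USE.NAMES = FALSE))
  }
  oriented <- new("ReadSet", sequences = seqs, qualities = q,
                  truth = rs@truth, sample = rs@sample)
  names(cls) <- names(seqs)
  list(classes = cls, reads = oriented)
}

#' Classify a single read
#'
#' @param sequence character or `DNAString` read sequence.
#' @param locus a [LocusModel-class].
#' @param window see [classifyReads()].
#' @return a single class label.
#' @export
classifyRead <- function(sequence, locus, window = NULL) {
  s <- Biostrings::DNAStringSet(as.character(sequence))
  names(s) <- "read"
  rs <- new("ReadSet", sequences = s,
            qualities = Biostrings::BStringSet(strrep("I", nchar(as.character(sequence)))),
            truth = NA_character_, sample = NA_character_)
  unname(classifyReads(rs, locus, window)$classes)
}
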