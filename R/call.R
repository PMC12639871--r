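# Pileup-based small-variant calling with a coverage floor.

# Per-position coverage over the reference from alignment spans.
.alignmentCoverage <- function(alignments, refLen) {
  if (!length(alignments)) return(integer(refLen))
  ir <- IRanges::IRanges(
    start = vapply(alignments, function(a) a$ref_start + 1L, integer(1L)),
    end = vapply(alignments, function(a) a$ref_end, integer(1L)))
  as.integer(IRanges::coverage(ir, width = refLen))
}

# Reference positions never eligible for small-variant calls: the primer
# margins and the paralog signature sites themselves (PSVs are paralog
# identity, not sample variation).
.excludedPositions <- function(locus) {
  n <- length(locus@geneRef)
  margin <- locus@config$primer_len + 2L
  ex <- c(seq.int(0L, margin - 1L), seq.int(n - margin, n - 1L))
  p <- locus@psvs
  if (nrow(p)) {
    for (i in seq_len(nrow(p))) {
      w <- max(1L, nchar(p$gene_allele[i]))
      ex <- c(ex, seq.int(p$gene_pos[i] - 1L, p$gene_pos[i] + w))
    }
  }
  unique(ex)
}

#' Call small variants from a set of alignments
#'
#' Builds a per-column pileup, emits alleles whose fraction reaches the
#' heterozygous band (`>= het_band[1]`; `>= het_band[2]` is called HOM,
#' otherwise HET), applies the minimum coverage depth floor (columns below
#' it are no-calls and reported in the mask), left-normalises indels, and
#' labels calls with coding-style names via the exon map. PSV columns and
#' primer margins never yield calls.
#'
#' @param alignments list of `cahAlignment` objects (gene-reference).
#' @param locus a [LocusModel-class].
#' @param min_depth minimum coverage depth (default 30).
#' @param het_band two fractions: emit threshold and HOM threshold.
#' @return list with `calls` (data.frame: `gene_pos`, `ref`, `alt`, `kind`,
#'   `depth`, `alt_count`, `frac`, `zygosity`, `name`) and `mask`
#'   (data.frame of 0-based half-open no-call intervals).
#' @export
callSmallVariants <- function(alignments, locus, min_depth = 30L,
                              het_band = c(0.2, 0.8)) {
  refLen <- length(locus@geneRef)
  cov <- .alignmentCoverage(alignments, refLen)
  lowRle <- S4Vectors::Rle(cov < min_depth)
  runs <- S4Vectors::runValue(lowRle)
  ends <- cumsum(S4Vectors::runLength(lowRle))
  starts <- ends - S4Vectors::runLength(lowRle) + 1L
  mask <- data.frame(start = starts[runs] - 1L, end = ends[runs])
  empty <- data.frame(gene_pos = integer(0), ref = character(0),
                      alt = character(0), kind = character(0),
                      depth = integer(0), alt_count = integer(0),
                      frac = numeric(0), zygosity = character(0),
                      name = character(0))
  evs <- lapply(alignments, `[[`, "events")
  evs <- evs[vapply(evs, nrow, integer(1L)) > 0L]
  if (!length(evs)) return(list(calls = empty, mask = mask))
  ev <- do.call(rbind, evs)
  key <- paste(ev$ref_pos, ev$type, ev$ref, ev$alt, sep = "\r")
  tab <- table(key)
  uk <- strsplit(names(tab), "\r", fixed = TRUE)
  pos <- vapply(uk, function(x) as.integer(x[1L]), integer(1L))
  type <- vapply(uk, `[`, character(1L), 2L)
  refA <- vapply(uk, function(x) if (length(x) >= 3L) x[3L] else "", character(1L))
  altA <- vapply(uk, function(x) if (length(x) >= 4L) x[4L] else "", character(1L))
  cnt <- as.integer(tab)
  excl <- .excludedPositions(locus)
  rows <- list()
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (p < 0L || p >= refLen || p %in% excl) next
    d <- cov[p + 1L]
    if (d < min_depth) next
    frac <- cnt[i] / d
    if (frac < het_band[1L]) next
    zyg <- if (frac >= het_band[2L]) "HOM" else "HET"
    kind <- switch(type[i], X = "SNV", D = "del", I = "ins")
    nm <- formatCodingName(p, refA[i], altA[i],
                           if (type[i] == "X") "SNV"
                           else if (type[i] == "D") "del" else "ins",
                           locus)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_pos = p, ref = refA[i], alt = altA[i], kind = kind,
      depth = d, alt_count = cnt[i], frac = frac, zygosity = zyg,
      name = if (is.null(nm) || is.na(nm)) NA_character_ else nm,
      stringsAsFactors = FALSE)
  }
  calls <- if (length(rows)) do.call(rbind, rows) else empty
  calls <- calls[order(calls$gene_pos), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, mask = mask)
}

#' Write calls as a minimal VCF 4.2
#'
#' One sample column with `GT:DP:AD`; `POS` is 1-based; indels use the
#' anchored-base convention; `ID` carries the coding-style name.
#'
#' @param calls data.frame from [callSmallVariants()].
#' @param locus a [LocusModel-class].
#' @param path output file.
#' @param sample sample name for the genotype column.
#' @export
writeCallsVcf <- function(calls, locus, path, sample = "SAMPLE") {
  gene <- as.character(locus@geneRef)
  contig <- "toy_gene"
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", contig, nchar(gene)),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
             "##FORMAT=<ID=AD,Number=1,Type=Integer,Description=\"Alt depth\">",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample, sep = "\t"))
  if (nrow(calls)) {
    recs <- vapply(seq_len(nrow(calls)), function(i) {
      c_ <- calls[i, ]
      if (c_$kind == "SNV") {
        pos1 <- c_$gene_pos + 1L; ref <- c_$ref; alt <- c_$alt
      } else if (c_$kind == "del") {
        pos1 <- c_$gene_pos  # anchored base before the deletion (1-based)
        anchor <- substring(gene, pos1, pos1)
        ref <- paste0(anchor, c_$ref); alt <- anchor
      } else {
        pos1 <- c_$gene_pos  # insertion before gene_pos: anchor base before
        anchor <- substring(gene, pos1, pos1)
        ref <- anchor; alt <- paste0(anchor, c_$alt)
      }
      gt <- if (c_$zygosity == "HOM") "1/1" else "0/1"
      paste(contig, pos1, ifelse(is.na(c_$name), ".", c_$name), ref, alt,
            ".", "PASS", ".", "GT:DP:AD",
            sprintf("%s:%d:%d", gt, c_$depth, c_$alt_count), sep = "\t")
    }, character(1L))
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the no-call mask as BED (0-based half-open)
#'
#' @param mask data.frame with `start`, `end`.
#' @param path output file.
#' @param contig contig name.
#' @export
writeMaskBed <- function(mask, path, contig = "toy_gene") {
  if (nrow(mask))
    writeLines(sprintf("%s\t%d\t%d\tlow_depth", contig, mask$start, mask$end),
               path)
  else writeLines(character(0), path)
  invisible(path)
}
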