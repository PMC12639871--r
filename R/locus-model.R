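# Toy two-paralog locus: construction, PSV derivation, serialisation.

# Fixed reference alleles pinned into the toy gene so that the packaged
# knowledge-base names (HGVS-style, transcribed from the study tables) map
# onto the toy coordinates with consistent reference alleles. Positions are
# coding-space; contexts for the indel anchors are pinned separately so that
# left-normalisation is unambiguous.
.ANCHOR_SNVS <- data.frame(
  coding = c("92", "293-13", "518", "844", "955", "1069",
             "*1215", "*1316", "*1351"),
  ref = c("C", "C", "T", "G", "C", "C", "C", "C", "G"),
  stringsAsFactors = FALSE)

#' Default configuration for the toy locus
#'
#' The toy locus is a desk-scale stand-in for the ~30 kb CYP21A2-TNXB /
#' CYP21A1P-TNXA pair: a 5-exon gene (CDS 1,100 nt) with a long 3'UTR (so
#' that deep-UTR variant names such as `c.*1351G>C` map), a downstream flank
#' standing in for the TNXB/TNXA segment, and locus-specific 20-mer primers
#' at both ends. PSV density defaults to roughly one per 150 nt (20 PSVs:
#' 16 gene-region SNVs, 2 gene-region indels, 2 flank SNVs), giving nine
#' informative gene-body junction bins (CH-1..CH-9) plus one flank bin
#' (TNX-CH-1).
#'
#' @param seed integer seed; the locus is byte-identical for a fixed seed.
#' @param divergence optional overall substitution divergence in `[0, 0.1]`;
#'   when given it overrides the PSV counts (`0` builds an undiverged pair
#'   with no PSVs).
#' @return a named list of locus parameters.
#' @export
toyLocusConfig <- function(seed = 1021L, divergence = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    primer_len = 20L,
    utr5 = 40L,
    exon_lens = c(150L, 142L, 308L, 300L, 200L),
    intron_len = 80L,
    utr3 = 1360L,
    flank = 260L,
    psv_snvs = 16L,
    psv_indels = 2L,
    flank_psvs = 2L,
    n_bins = 9L,
    divergence = divergence)
  cfg
}

.bodyLen <- function(cfg) {
  cfg$utr5 + sum(cfg$exon_lens) + cfg$intron_len * (length(cfg$exon_lens) - 1L) +
    cfg$utr3 + cfg$flank
}

# cdsMap for a config, with reference coordinates including the leading
# primer (offset = primer_len).
.makeCdsMap <- function(cfg) {
  off <- cfg$primer_len + cfg$utr5
  starts <- integer(length(cfg$exon_lens))
  cs <- 1L
  rows <- vector("list", length(cfg$exon_lens))
  pos <- off
  for (e in seq_along(cfg$exon_lens)) {
    len <- cfg$exon_lens[e]
    rows[[e]] <- data.frame(exon = e, ref_start = pos, ref_end = pos + len,
                            coding_start = cs, coding_end = cs + len - 1L)
    pos <- pos + len + if (e < length(cfg$exon_lens)) cfg$intron_len else 0L
    cs <- cs + len
  }
  do.call(rbind, rows)
}

#' Build the packaged toy locus
#'
#' Generates the functional-gene reference, derives the pseudogene from it by
#' planting the configured substitutions and indels (plus diverged primers),
#' re-derives the signature variants from the pairwise alignment of the two
#' bodies, and tiles the PSV span into junction bins.
#'
#' Deterministic for a fixed `config$seed`; the caller's RNG stream is left
#' untouched.
#'
#' @param config list from [toyLocusConfig()].
#' @return a [LocusModel-class].
#' @examples
#' locus <- buildToyLocus()
#' locus
#' @export
buildToyLocus <- function(config = toyLocusConfig()) {
  cfg <- config
  if (!is.null(cfg$divergence)) {
    if (cfg$divergence < 0 || cfg$divergence > 0.1)
      stop("divergence must lie in [0, 0.1]")
    n <- round(cfg$divergence * .bodyLen(cfg))
    if (n == 0) {
      cfg$psv_snvs <- 0L; cfg$psv_indels <- 0L; cfg$flank_psvs <- 0L
    } else {
      cfg$flank_psvs <- min(cfg$flank_psvs, n)
      cfg$psv_indels <- min(cfg$psv_indels, max(0L, n - cfg$flank_psvs))
      cfg$psv_snvs <- max(0L, n - cfg$psv_indels - cfg$flank_psvs)
    }
  }
  bodyLen <- .bodyLen(cfg)
  if (bodyLen + 2L * cfg$primer_len < 1500L)
    stop("locus too short: total reference must be >= 1500 nt")
  cdsMap <- .makeCdsMap(cfg)
  cdsLen <- sum(cfg$exon_lens)
  utr3Start <- cdsMap$ref_end[nrow(cdsMap)]
  flankStart <- utr3Start + cfg$utr3
  bodyStart <- cfg$primer_len
  bodyEnd <- cfg$primer_len + bodyLen

  built <- withSeed(cfg$seed, {
    body <- strsplit(randomDNA(bodyLen), "", fixed = TRUE)[[1L]]
    setAt <- function(refPos, base) {
      # refPos is a 0-based coordinate on geneRef; body starts at primer_len
      body[refPos - cfg$primer_len + 1L] <<- base
    }
    # pin anchor SNV reference alleles (skipped when outside the locus)
    anchorPos <- integer(0)
    for (i in seq_len(nrow(.ANCHOR_SNVS))) {
      pos <- tryCatch(
        .codingTokenToRef(.ANCHOR_SNVS$coding[i], cdsMap, utr3Start,
                          cdsLen, cfg$utr3),
        error = function(e) NA_integer_)
      if (!is.na(pos)) {
        setAt(pos, .ANCHOR_SNVS$ref[i])
        anchorPos <- c(anchorPos, pos)
      }
    }
    # indel anchors: c.740del and c.923dup need locally unique contexts
    p740 <- tryCatch(.codingTokenToRef("740", cdsMap, utr3Start, cdsLen, cfg$utr3),
                     error = function(e) NA_integer_)
    if (!is.na(p740)) {
      setAt(p740 - 1L, "A"); setAt(p740, "G"); setAt(p740 + 1L, "T")
      anchorPos <- c(anchorPos, p740 + (-1:1))
    }
    p923 <- tryCatch(.codingTokenToRef("923", cdsMap, utr3Start, cdsLen, cfg$utr3),
                     error = function(e) NA_integer_)
    if (!is.na(p923)) {
      setAt(p923 - 1L, "A"); setAt(p923, "C"); setAt(p923 + 1L, "G")
      anchorPos <- c(anchorPos, p923 + (-1:1))
    }

    # --- place planted edits (the ground-truth PSV script) ---
    forbidden <- c(anchorPos, bodyStart, bodyEnd - 1L)
    placePositions <- function(n, lo, hi) {
      if (n == 0L) return(integer(0))
      base <- round(seq(lo, hi, length.out = n)) +
        sample(-15:15, n, replace = TRUE)
      for (i in seq_along(base)) {
        while (any(abs(base[i] - forbidden) <= 8L)) base[i] <- base[i] + 9L
        forbidden <- c(forbidden, base[i] + (-2:3))
      }
      sort(as.integer(base))
    }
    nGene <- cfg$psv_snvs + cfg$psv_indels
    genePos <- placePositions(nGene, bodyStart + 60L, flankStart - 40L)
    flankPos <- placePositions(cfg$flank_psvs, flankStart + 20L, bodyEnd - 30L)
    # choose which gene-region slots become indels: spread them out
    indelSlots <- integer(0)
    if (cfg$psv_indels > 0L && nGene >= cfg$psv_indels + 2L)
      indelSlots <- round(seq(3L, nGene - 2L, length.out = cfg$psv_indels))
    edits <- vector("list", nGene + length(flankPos))
    k <- 0L
    for (i in seq_along(genePos)) {
      k <- k + 1L
      pos <- genePos[i]
      if (i %in% indelSlots) {
        if (k %% 2L == 0L) {
          # deletion PSV: pseudogene lacks two gene bases; pin context so the
          # event cannot shift under left-normalisation
          setAt(pos - 1L, "A"); setAt(pos, "C"); setAt(pos + 1L, "G")
          setAt(pos + 2L, "T")
          edits[[k]] <- list(kind = "del", gene_pos = pos,
                             gene_allele = "CG", pseudo_allele = "")
        } else {
          # insertion PSV: pseudogene carries two extra bases before `pos`
          setAt(pos - 1L, "G"); setAt(pos, "T")
          edits[[k]] <- list(kind = "ins", gene_pos = pos,
                             gene_allele = "", pseudo_allele = "CA")
        }
      } else {
        ref <- body[pos - cfg$primer_len + 1L]
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        edits[[k]] <- list(kind = "SNV", gene_pos = pos,
                           gene_allele = ref, pseudo_allele = alt)
      }
    }
    for (pos in flankPos) {
      k <- k + 1L
      ref <- body[pos - cfg$primer_len + 1L]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      edits[[k]] <- list(kind = "SNV", gene_pos = pos,
                         gene_allele = ref, pseudo_allele = alt)
    }
    edits <- edits[seq_len(k)]

    # apply edits right-to-left to obtain the pseudogene body
    pbody <- body
    ord <- order(vapply(edits, `[[`, numeric(1), "gene_pos"), decreasing = TRUE)
    for (e in edits[ord]) {
      i <- e$gene_pos - cfg$primer_len + 1L  # 1-based body index
      if (e$kind == "SNV") {
        pbody[i] <- e$pseudo_allele
      } else if (e$kind == "del") {
        pbody <- pbody[-(i:(i + nchar(e$gene_allele) - 1L))]
      } else {
        pbody <- append(pbody, strsplit(e$pseudo_allele, "")[[1L]], after = i - 1L)
      }
    }

    # locus-specific primers (must be mutually dissimilar and unique)
    primers <- NULL
    for (try in 1:100) {
      cand <- c(gene_fwd = randomDNA(cfg$primer_len),
                gene_rev_site = randomDNA(cfg$primer_len),
                pseudo_fwd = randomDNA(cfg$primer_len),
                pseudo_rev_site = randomDNA(cfg$primer_len))
      ok <- TRUE
      for (i in 1:3) for (j in (i + 1):4)
        if (hammingDist(cand[i], cand[j]) < 5L) ok <- FALSE
      if (ok) { primers <- cand; break }
    }
    list(body = body, pbody = pbody, edits = edits, primers = primers)
  })

  geneSeq <- paste0(built$primers[["gene_fwd"]],
                    paste(built$body, collapse = ""),
                    built$primers[["gene_rev_site"]])
  pseudoSeq <- paste0(built$primers[["pseudo_fwd"]],
                      paste(built$pbody, collapse = ""),
                      built$primers[["pseudo_rev_site"]])
  geneRef <- Biostrings::DNAString(geneSeq)
  pseudoRef <- Biostrings::DNAString(pseudoSeq)

  # primer uniqueness / ambiguity guard
  .checkPrimer <- function(site, own, other, what) {
    nOwn <- Biostrings::countPattern(site, own, max.mismatch = 1)
    nOther <- Biostrings::countPattern(site, other, max.mismatch = 1)
    if (nOwn != 1L)
      stop(sprintf("primer %s must occur exactly once in its reference", what))
    if (nOther != 0L)
      stop(sprintf("primer %s occurs in both references: ambiguous classification", what))
  }
  .checkPrimer(built$primers[["gene_fwd"]], geneRef, pseudoRef, "gene_fwd")
  .checkPrimer(built$primers[["gene_rev_site"]], geneRef, pseudoRef, "gene_rev")
  .checkPrimer(built$primers[["pseudo_fwd"]], pseudoRef, geneRef, "pseudo_fwd")
  .checkPrimer(built$primers[["pseudo_rev_site"]], pseudoRef, geneRef, "pseudo_rev")

  # PSVs re-derived from the alignment of the homologous bodies
  psvs <- deriveSignatureVariants(paste(built$body, collapse = ""),
                                  paste(built$pbody, collapse = ""),
                                  min_identity = 0.9)
  if (nrow(psvs)) {
    psvs$gene_pos <- psvs$gene_pos + cfg$primer_len
    psvs$pseudo_pos <- psvs$pseudo_pos + cfg$primer_len
    psvs$region <- ifelse(psvs$gene_pos >= flankStart, "flank", "gene")
  } else {
    psvs$region <- character(0)
  }

  bins <- .makeJunctionBins(psvs, cfg$n_bins)
  cfg$flank_start <- flankStart
  new("LocusModel",
      geneRef = geneRef, pseudoRef = pseudoRef,
      primers = c(gene_fwd = unname(built$primers[["gene_fwd"]]),
                  gene_rev = revcomp(built$primers[["gene_rev_site"]]),
                  pseudo_fwd = unname(built$primers[["pseudo_fwd"]]),
                  pseudo_rev = revcomp(built$primers[["pseudo_rev_site"]])),
      cdsMap = cdsMap, psvs = psvs, junctionBins = bins,
      bodyStart = as.integer(bodyStart), bodyEnd = as.integer(bodyEnd),
      utr3Start = as.integer(utr3Start), config = cfg)
}

# Tile the PSV span into n_bins gene-region bins (CH-1..CH-n) plus one flank
# bin (TNX-CH-1) when flank PSVs exist. Bin boundaries sit halfway between
# the last PSV of one bin and the first PSV of the next, so a breakpoint
# placed between two PSVs of the same bin is recovered in that bin.
.makeJunctionBins <- function(psvs, n_bins) {
  empty <- data.frame(label = character(0), start = integer(0),
                      end = integer(0), psv_lo = integer(0),
                      psv_hi = integer(0), region = character(0))
  if (nrow(psvs) < 2L) return(empty)
  geneIdx <- which(psvs$region == "gene")
  flankIdx <- which(psvs$region == "flank")
  groups <- list()
  if (length(geneIdx) >= 2L) {
    nb <- min(n_bins, floor(length(geneIdx) / 2))
    split_ <- split(geneIdx, cut(seq_along(geneIdx), nb, labels = FALSE))
    for (g in seq_along(split_))
      groups[[length(groups) + 1L]] <-
        list(label = paste0("CH-", g), idx = split_[[g]], region = "gene")
  }
  if (length(flankIdx) >= 1L)
    groups[[length(groups) + 1L]] <-
      list(label = "TNX-CH-1", idx = flankIdx, region = "flank")
  if (!length(groups)) return(empty)
  rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]$idx
    firstPos <- psvs$gene_pos[idx[1L]]
    lastPos <- psvs$gene_pos[idx[length(idx)]]
    start <- if (g == 1L) firstPos
             else rows[[g - 1L]]$end
    end <- if (g == length(groups)) lastPos + 1L
           else {
             nxt <- psvs$gene_pos[groups[[g + 1L]]$idx[1L]]
             as.integer(floor((lastPos + nxt) / 2)) + 1L
           }
    rows[[g]] <- data.frame(label = groups[[g]]$label, start = start,
                            end = end, psv_lo = idx[1L],
                            psv_hi = idx[length(idx)],
                            region = groups[[g]]$region)
  }
  do.call(rbind, rows)
}

#' Derive paralog signature variants from a reference pair
#'
#' Globally aligns the two homologous sequences with affine gap penalties
#' (match +2, mismatch -4, gap open -6, extend -1) and reports every
#' mismatch column as a SNV PSV and every gap run as a single indel PSV,
#' with positions on the first (gene) sequence, sorted.
#'
#' @param gene_seq,pseudo_seq character or `DNAString` sequences (ACGT).
#' @param min_identity alignment identity below which the pair is rejected
#'   as non-homologous (default 0.5).
#' @return data.frame with columns `gene_pos`, `pseudo_pos` (0-based),
#'   `kind` ("SNV"/"ins"/"del"), `gene_allele`, `pseudo_allele`. For "ins"
#'   PSVs `gene_pos` is the 0-based index of the gene base following the
#'   inserted pseudogene bases.
#' @export
deriveSignatureVariants <- function(gene_seq, pseudo_seq, min_identity = 0.5) {
  g <- as.character(gene_seq); p <- as.character(pseudo_seq)
  if (nchar(g) == 0L || nchar(p) == 0L) stop("empty sequence")
  if (grepl("[^ACGT]", g) || grepl("[^ACGT]", p))
    stop("sequences must use the ACGT alphabet")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(g), Biostrings::DNAString(p), type = "global",
    substitutionMatrix = mat, gapOpening = 6, gapExtension = 1)
  if (Biostrings::pid(aln) / 100 < min_identity)
    stop(sprintf("alignment identity %.1f%% below %.0f%%: sequences not homologous",
                 Biostrings::pid(aln), 100 * min_identity))
  ga <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  gi <- cumsum(ga != "-")  # gene bases consumed up to column
  pi_ <- cumsum(pa != "-")
  kind <- ifelse(ga == "-", "ins", ifelse(pa == "-", "del",
                 ifelse(ga != pa, "SNV", "match")))
  rows <- list()
  r <- rle(kind)
  endCol <- cumsum(r$lengths)
  startCol <- endCol - r$lengths + 1L
  for (i in seq_along(r$values)) {
    v <- r$values[i]
    if (v == "match") next
    s <- startCol[i]; e <- endCol[i]
    if (v == "SNV") {
      for (col in s:e)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_pos = gi[col] - 1L, pseudo_pos = pi_[col] - 1L, kind = "SNV",
          gene_allele = ga[col], pseudo_allele = pa[col])
    } else if (v == "del") {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_pos = gi[s] - 1L, pseudo_pos = pi_[s], kind = "del",
        gene_allele = paste(ga[s:e], collapse = ""), pseudo_allele = "")
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_pos = gi[s], pseudo_pos = pi_[s] - 1L, kind = "ins",
        gene_allele = "", pseudo_allele = paste(pa[s:e], collapse = ""))
    }
  }
  if (!length(rows))
    return(data.frame(gene_pos = integer(0), pseudo_pos = integer(0),
                      kind = character(0), gene_allele = character(0),
                      pseudo_allele = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$gene_pos), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# Number of pseudogene bases homologous to the first `b` gene-reference
# bases (0-based breakpoint b on geneRef). Breakpoints inside indel PSVs are
# not supported (the simulator never places them there).
.pseudoPrefixLen <- function(locus, b) {
  p <- locus@psvs
  if (!nrow(p)) return(b)
  ins <- p$kind == "ins" & p$gene_pos <= b
  del <- p$kind == "del" & (p$gene_pos + nchar(p$gene_allele)) <= b
  b + sum(nchar(p$pseudo_allele[ins])) - sum(nchar(p$gene_allele[del]))
}

#' Write locus reference files
#'
#' Emits the two references as a multi-record FASTA plus one JSON document
#' with the primers, exon map, PSV table, junction bins and build
#' configuration.
#'
#' @param locus a [LocusModel-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeLocusFiles <- function(locus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "references.fasta")
  refs <- Biostrings::DNAStringSet(c(functional_gene = as.character(locus@geneRef),
                                     pseudogene = as.character(locus@pseudoRef)))
  Biostrings::writeXStringSet(refs, fa)
  js <- file.path(dir, "locus.json")
  meta <- list(primers = as.list(locus@primers),
               cds_map = locus@cdsMap, psvs = locus@psvs,
               junction_bins = locus@junctionBins,
               body_start = locus@bodyStart, body_end = locus@bodyEnd,
               utr3_start = locus@utr3Start, config = locus@config)
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(fasta = fa, json = js))
}

#' Load a locus written by [writeLocusFiles()]
#'
#' @param dir directory containing `references.fasta` and `locus.json`.
#' @return a [LocusModel-class].
#' @export
loadLocusFiles <- function(dir) {
  refs <- Biostrings::readDNAStringSet(file.path(dir, "references.fasta"))
  meta <- jsonlite::read_json(file.path(dir, "locus.json"), simplifyVector = TRUE)
  psvs <- as.data.frame(meta$psvs)
  psvs$gene_allele[is.na(psvs$gene_allele)] <- ""
  psvs$pseudo_allele[is.na(psvs$pseudo_allele)] <- ""
  cfg <- meta$config
  cfg$exon_lens <- as.integer(cfg$exon_lens)
  new("LocusModel",
      geneRef = refs[["functional_gene"]], pseudoRef = refs[["pseudogene"]],
      primers = unlist(meta$primers), cdsMap = as.data.frame(meta$cds_map),
      psvs = psvs, junctionBins = as.data.frame(meta$junction_bins),
      bodyStart = as.integer(meta$body_start), bodyEnd = as.integer(meta$body_end),
      utr3Start = as.integer(meta$utr3_start), config = cfg)
}
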