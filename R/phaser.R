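# PSV state vectors, chimera junction localisation, and read-backed phasing.

#' PSV genotype vector of one aligned read
#'
#' Scores each covered signature site as `"G"` (gene allele), `"P"`
#' (pseudogene allele) or `"M"` (missing: uncovered or a third allele).
#'
#' @param aln a `cahAlignment` against the gene reference.
#' @param locus a [LocusModel-class].
#' @return character vector of length `nrow(psvTable(locus))`.
#' @export
psvGenotypeVector <- function(aln, locus) {
  p <- locus@psvs
  n <- nrow(p)
  out <- rep("M", n)
  if (!n) return(out)
  ev <- aln$events
  for (i in seq_len(n)) {
    pos <- p$gene_pos[i]
    w <- max(1L, nchar(p$gene_allele[i]))
    if (pos - 1L < aln$ref_start || pos + w > aln$ref_end) next
    if (p$kind[i] == "SNV") {
      hit <- ev$type == "X" & ev$ref_pos == pos
      covDel <- ev$type == "D" &
        ev$ref_pos <= pos & (ev$ref_pos + nchar(ev$ref)) > pos
      if (any(covDel)) next  # M
      if (!any(hit)) out[i] <- "G"
      else if (ev$alt[which(hit)[1L]] == p$pseudo_allele[i]) out[i] <- "P"
    } else if (p$kind[i] == "del") {
      exact <- ev$type == "D" & ev$ref_pos == pos &
        nchar(ev$ref) == nchar(p$gene_allele[i])
      overl <- (ev$type == "D" &
                  ev$ref_pos < pos + w & (ev$ref_pos + nchar(ev$ref)) > pos) |
               (ev$type == "X" & ev$ref_pos >= pos & ev$ref_pos < pos + w)
      if (any(exact)) out[i] <- "P"
      else if (!any(overl)) out[i] <- "G"
    } else {  # ins PSV
      hit <- ev$type == "I" & ev$ref_pos == pos
      if (!any(hit)) out[i] <- "G"
      else if (ev$alt[which(hit)[1L]] == p$pseudo_allele[i]) out[i] <- "P"
    }
  }
  out
}

#' Locate a chimera junction in a PSV state vector
#'
#' Over all cut points `c` in `0..n` (on the informative, non-missing
#' states) minimises the number of `"G"` states before the cut plus the
#' number of `"P"` states after it; the leftmost minimal cut wins. The
#' junction is reported as the open interval between the last informative
#' pseudo-side PSV and the first informative gene-side PSV. A cut at 0 means
#' the read has no pseudogene segment; a cut at `n` no gene segment
#' (sentinels).
#'
#' @param states character vector over `"G"`, `"P"`, `"M"`.
#' @return list: `sentinel` (`NA`, `"no_pseudo"` or `"no_gene"`),
#'   `left_index`/`right_index` (1-based indices into the full PSV list, the
#'   junction lies strictly between them), `cost`, `n_informative`.
#' @export
locateJunction <- function(states) {
  inf <- which(states != "M")
  k <- length(inf)
  if (k < 2L) stop("need at least 2 informative PSV states")
  g <- states[inf] == "G"
  cumG <- c(0L, cumsum(g))
  cumP <- c(0L, cumsum(!g))
  totP <- cumP[k + 1L]
  cost <- cumG[1:(k + 1L)] + (totP - cumP[1:(k + 1L)])
  cstar <- which.min(cost) - 1L  # leftmost minimum
  res <- list(sentinel = NA_character_, left_index = NA_integer_,
              right_index = NA_integer_, cost = cost[cstar + 1L],
              n_informative = k)
  if (cstar == 0L) res$sentinel <- "no_pseudo"
  else if (cstar == k) res$sentinel <- "no_gene"
  else {
    res$left_index <- inf[cstar]
    res$right_index <- inf[cstar + 1L]
  }
  res
}

#' Assign a junction to a named bin
#'
#' The junction interval midpoint selects the bin; an interval straddling a
#' bin boundary falls back to the bin of the left informative PSV and is
#' flagged ambiguous.
#'
#' @param junction result of [locateJunction()] (non-sentinel).
#' @param locus a [LocusModel-class].
#' @return list: `label`, `ambiguous`.
#' @export
binJunction <- function(junction, locus) {
  if (!is.na(junction$sentinel))
    stop("cannot bin a sentinel junction (", junction$sentinel, ")")
  bins <- locus@junctionBins
  p <- locus@psvs
  posL <- p$gene_pos[junction$left_index]
  posR <- p$gene_pos[junction$right_index]
  binAt <- function(pos) {
    r <- which(bins$start <= pos & pos < bins$end)
    if (!length(r)) NA_integer_ else r
  }
  bL <- binAt(posL); bR <- binAt(posR)
  if (is.na(bL) && is.na(bR)) stop("junction outside all bins")
  if (!identical(bL, bR)) {
    if (is.na(bL)) stop("junction outside all bins")
    return(list(label = bins$label[bL], ambiguous = TRUE))
  }
  mid <- as.integer(floor((posL + posR) / 2))
  bM <- binAt(mid)
  list(label = bins$label[bM], ambiguous = FALSE)
}

#' Phase reads into two haplotype groups
#'
#' Greedy two-cluster agglomeration on allele-vector agreement at
#' heterozygous sites. Full-length amplicon reads vote at every site, so the
#' two true haplotype vectors dominate: the clusters are seeded with the two
#' most frequent distinct allele vectors (ties broken lexicographically),
#' every read joins the consensus it agrees with at >= 80% of sites, and one
#' refinement pass recomputes the majority consensi and reassigns. Reads
#' conflicting with both consensi at more than 20% of sites are set aside as
#' noise; a third incompatible vector carried by >= 20% of reads raises the
#' `multi_allele` flag (relevant for fusion duplications) and the best two
#' clusters are kept. With no heterozygous sites all reads form one group.
#' The output is independent of read order (ids are sorted internally).
#'
#' @param alleles named list: read id -> character vector of alleles at the
#'   het sites (a consistent site order across reads).
#' @return list: `groups` (list of read-id vectors, length 1 or 2),
#'   `consensus` (list of allele vectors), `noise` (read ids),
#'   `multi_allele` (logical).
#' @export
phaseReads <- function(alleles) {
  ids <- sort(names(alleles))
  n <- length(ids)
  if (!n) stop("no reads to phase")
  k <- length(alleles[[1L]])
  if (k == 0L)
    return(list(groups = list(ids), consensus = list(character(0)),
                noise = character(0), multi_allele = FALSE))
  m <- do.call(rbind, alleles[ids])
  consOf <- function(rows) {
    apply(m[rows, , drop = FALSE], 2L, function(col) {
      t_ <- sort(table(col), decreasing = TRUE)
      nm <- names(t_)[t_ == max(t_)]
      sort(nm)[1L]
    })
  }
  agree <- function(i, cons) mean(m[i, ] == cons)
  # seed with the two most frequent distinct vectors
  key <- apply(m, 1L, paste, collapse = "|")
  tab <- table(key)
  tab <- tab[order(-as.integer(tab), names(tab))]
  seed1 <- strsplit(names(tab)[1L], "|", fixed = TRUE)[[1L]]
  cons <- list(seed1)
  if (length(tab) > 1L)
    cons[[2L]] <- strsplit(names(tab)[2L], "|", fixed = TRUE)[[1L]]
  assignAll <- function(cons) {
    vapply(seq_len(n), function(i) {
      sc <- vapply(cons, function(cc) agree(i, cc), numeric(1L))
      b <- which.max(sc)
      if (sc[b] >= 0.8) b else NA_integer_
    }, integer(1L))
  }
  assign_ <- assignAll(cons)
  # one refinement pass on the majority consensus of each cluster
  for (g in seq_along(cons)) {
    rows <- which(assign_ == g)
    if (length(rows)) cons[[g]] <- consOf(rows)
  }
  if (length(cons) == 2L && identical(cons[[1L]], cons[[2L]]))
    cons <- cons[1L]
  assign_ <- assignAll(cons)
  noiseIdx <- which(is.na(assign_))
  multi <- FALSE
  if (length(noiseIdx) >= max(2L, ceiling(0.2 * n))) {
    vecs <- apply(m[noiseIdx, , drop = FALSE], 1L, paste, collapse = "|")
    if (max(table(vecs)) >= 0.2 * n) multi <- TRUE
  }
  groups <- lapply(seq_along(cons), function(g) ids[which(assign_ == g)])
  keep <- lengths(groups) > 0L
  groups <- groups[keep]
  cons <- lapply(groups, function(g) consOf(match(g, ids)))
  list(groups = groups, consensus = cons, noise = ids[noiseIdx],
       multi_allele = multi)
}

#' Majority consensus of PSV vectors
#'
#' @param vectors list of PSV state vectors (equal length).
#' @return single consensus vector; ties prefer the non-missing state, then
#'   `"G"`.
#' @export
consensusPsvVector <- function(vectors) {
  m <- do.call(rbind, vectors)
  apply(m, 2L, function(col) {
    col2 <- col[col != "M"]
    if (!length(col2)) return("M")
    t_ <- table(factor(col2, levels = c("G", "P")))
    if (t_[["P"]] > t_[["G"]]) "P" else "G"
  })
}
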