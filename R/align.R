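# Semi-global (fitting) alignment of amplicon reads to the functional-gene
# reference, and event extraction.

#' Default alignment scoring
#'
#' Match +2, mismatch -4, gap open -6, gap extend -1 (a gap of length L
#' costs 6 + L).
#' @return named list of scores.
#' @export
alignScoring <- function() {
  list(match = 2, mismatch = -4, gap_open = 6, gap_ext = 1)
}

# Left-normalise indel events against the reference (VCF convention); the
# event data.frame has columns ref_pos (0-based), type (X/I/D), ref, alt.
.normalizeEvents <- function(events, refChars) {
  if (!nrow(events)) return(events)
  for (i in which(events$type == "D")) {
    p <- events$ref_pos[i]; L <- nchar(events$ref[i])
    while (p > 0L && refChars[p] == refChars[p + L]) p <- p - 1L
    if (p != events$ref_pos[i]) {
      events$ref_pos[i] <- p
      events$ref[i] <- paste(refChars[(p + 1L):(p + L)], collapse = "")
    }
  }
  for (i in which(events$type == "I")) {
    p <- events$ref_pos[i]; s <- strsplit(events$alt[i], "")[[1L]]
    L <- length(s)
    while (p > 0L && refChars[p] == s[L]) {
      s <- c(refChars[p], s[-L])
      p <- p - 1L
    }
    if (p != events$ref_pos[i]) {
      events$ref_pos[i] <- p
      events$alt[i] <- paste(s, collapse = "")
    }
  }
  events
}

#' Align one read to a reference
#'
#' Optimal semi-global affine-gap alignment (read aligned end-to-end,
#' reference prefix/suffix free), computed by a banded dynamic program; with
#' `band` covering the full matrix the result is the exact unbanded optimum.
#' Deterministic, fixed tie order; indels are left-normalised at the event
#' level.
#'
#' @param read character or `DNAString`.
#' @param ref character or `DNAString` reference.
#' @param scoring list from [alignScoring()].
#' @param band band half-width around the main diagonal (`NULL`: automatic,
#'   generous for full-length amplicon reads; use `nchar(ref)` for exact
#'   unbanded alignment of arbitrary sequences).
#' @param read_id id stored in the result.
#' @return object of class `"cahAlignment"`: `read_id`, `score`,
#'   `ref_start`/`ref_end` (0-based half-open), `cigar` (data.frame
#'   `op`/`len` over `=`, `X`, `I`, `D`), `events` (data.frame `ref_pos`,
#'   `type`, `ref`, `alt`), `identity` (matched fraction of alignment
#'   columns).
#' @export
alignRead <- function(read, ref, scoring = alignScoring(), band = NULL,
                      read_id = "read") {
  rd <- as.character(read); rf <- as.character(ref)
  if (is.null(band)) band <- abs(nchar(rf) - nchar(rd)) + 64L
  res <- .fit_align_cpp(rd, rf, scoring$match, scoring$mismatch,
                        scoring$gap_open, scoring$gap_ext, as.integer(band))
  op <- res$op; len <- res$len
  refChars <- strsplit(rf, "")[[1L]]
  # walk the cigar to collect difference events
  i <- 0L; j <- res$ref_start
  ev <- vector("list", length(op))
  for (k in seq_along(op)) {
    o <- op[k]; L <- len[k]
    if (o == "=") { i <- i + L; j <- j + L }
    else if (o == "X") {
      ev[[k]] <- data.frame(
        ref_pos = j + 0:(L - 1L), type = "X",
        ref = strsplit(substring(rf, j + 1L, j + L), "")[[1L]],
        alt = strsplit(substring(rd, i + 1L, i + L), "")[[1L]])
      i <- i + L; j <- j + L
    } else if (o == "D") {
      ev[[k]] <- data.frame(ref_pos = j, type = "D",
                            ref = substring(rf, j + 1L, j + L), alt = "")
      j <- j + L
    } else {  # I
      ev[[k]] <- data.frame(ref_pos = j, type = "I", ref = "",
                            alt = substring(rd, i + 1L, i + L))
      i <- i + L
    }
  }
  ev <- ev[!vapply(ev, is.null, logical(1L))]
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(ref_pos = integer(0), type = character(0),
                            ref = character(0), alt = character(0))
  events <- .normalizeEvents(events, refChars)
  ncols <- sum(len)
  nmatch <- sum(len[op == "="])
  structure(list(read_id = read_id, score = res$score,
                 ref_start = res$ref_start, ref_end = res$ref_end,
                 cigar = data.frame(op = op, len = len),
                 events = events, identity = nmatch / ncols),
            class = "cahAlignment")
}

#' Align a read set, dropping low-identity reads
#'
#' @param rs a [ReadSet-class].
#' @param ref reference sequence.
#' @param scoring,band see [alignRead()].
#' @param min_identity reads below this alignment identity are flagged and
#'   excluded (default 0.7).
#' @return list with `alignments` (list of `cahAlignment`) and `excluded`
#'   (read ids that failed the identity floor).
#' @export
alignReads <- function(rs, ref, scoring = alignScoring(), band = NULL,
                       min_identity = 0.7) {
  rf <- as.character(ref)
  seqs <- as.character(rs@sequences)
  alns <- vector("list", length(seqs))
  for (i in seq_along(seqs))
    alns[[i]] <- alignRead(seqs[[i]], rf, scoring, band,
                           read_id = names(seqs)[i])
  ok <- vapply(alns, function(a) a$identity >= min_identity, logical(1L))
  list(alignments = alns[ok],
       excluded = vapply(alns[!ok], `[[`, character(1L), "read_id"))
}
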