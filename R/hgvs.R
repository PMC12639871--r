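# Coding-style (HGVS-like) variant names on the toy locus.
#
# Supported grammar subset:
#   c.<N><R>><A>        exonic SNV
#   c.<N>+<M><R>><A>    intronic, downstream of exon end N
#   c.<N>-<M><R>><A>    intronic, upstream of exon start N
#   c.*<N><R>><A>       3'UTR SNV
#   c.<N>dup            single-base duplication
#   c.<N>del            single-base deletion
# Coding positions are 1-based; reference coordinates 0-based.

.parseError <- function(msg, name) {
  stop(structure(class = c("cah_parse_error", "error", "condition"),
                 list(message = sprintf("%s: '%s'", msg, name), call = NULL)))
}

.refMismatchError <- function(name, expected, found) {
  stop(structure(class = c("cah_ref_mismatch", "error", "condition"),
                 list(message = sprintf(
                   "reference allele mismatch for '%s': name says %s, reference has %s",
                   name, expected, found), call = NULL)))
}

# Resolve a coding-position token ("740", "293-13", "292+5", "*1351") to a
# 0-based position on geneRef.
.codingTokenToRef <- function(token, cdsMap, utr3Start, cdsLen, utr3Len) {
  if (grepl("^\\*\\d+$", token)) {
    n <- as.integer(sub("^\\*", "", token))
    if (n < 1L || n > utr3Len) stop("3'UTR position out of range")
    return(utr3Start + n - 1L)
  }
  m <- regmatches(token, regexec("^(\\d+)([+-])(\\d+)$", token))[[1L]]
  if (length(m)) {
    n <- as.integer(m[2L]); off <- as.integer(m[4L])
    if (m[3L] == "-") {
      row <- which(cdsMap$coding_start == n)
      if (!length(row)) stop("offset anchor is not an exon start")
      if (row == 1L) stop("no intron upstream of exon 1")
      pos <- cdsMap$ref_start[row] - off
      if (pos < cdsMap$ref_end[row - 1L]) stop("intron offset out of range")
    } else {
      row <- which(cdsMap$coding_end == n)
      if (!length(row)) stop("offset anchor is not an exon end")
      if (row == nrow(cdsMap)) stop("no intron downstream of the last exon")
      pos <- cdsMap$ref_end[row] - 1L + off
      if (pos >= cdsMap$ref_start[row + 1L]) stop("intron offset out of range")
    }
    return(pos)
  }
  if (grepl("^\\d+$", token)) {
    n <- as.integer(token)
    if (n < 1L || n > cdsLen) stop("coding position out of CDS range")
    row <- which(cdsMap$coding_start <= n & n <= cdsMap$coding_end)
    return(cdsMap$ref_start[row] + (n - cdsMap$coding_start[row]))
  }
  stop("unparseable coding position")
}

#' Parse a coding-style variant name against the toy locus
#'
#' Maps an HGVS-like name (exonic/intronic/3'UTR SNVs, single-base `dup` and
#' `del`) to reference coordinates and validates the stated reference allele
#' against the functional-gene reference. Parse failures raise a condition of
#' class `cah_parse_error`; a valid name whose reference allele disagrees
#' with the locus raises `cah_ref_mismatch`.
#'
#' @param name variant name, e.g. `"c.518T>A"`, `"c.293-13C>G"`, `"c.923dup"`.
#' @param locus a [LocusModel-class].
#' @return a one-row data.frame: `name`, `gene_pos` (0-based), `ref`, `alt`,
#'   `kind` ("SNV", "ins", "del", "dup"). For `dup`, `gene_pos` is the
#'   0-based index of the base following the inserted copy (insertion-event
#'   convention).
#' @export
parseCodingName <- function(name, locus) {
  cfg <- locus@config
  cdsLen <- sum(cfg$exon_lens)
  gene <- as.character(locus@geneRef)
  baseAt <- function(pos) substring(gene, pos + 1L, pos + 1L)
  tok2ref <- function(token) {
    tryCatch(
      .codingTokenToRef(token, locus@cdsMap, locus@utr3Start, cdsLen, cfg$utr3),
      error = function(e) .parseError(conditionMessage(e), name))
  }
  m <- regmatches(name, regexec(
    "^c\\.(\\*?\\d+(?:[+-]\\d+)?)([ACGT])>([ACGT])$", name))[[1L]]
  if (length(m)) {
    pos <- tok2ref(m[2L])
    found <- baseAt(pos)
    if (found != m[3L]) .refMismatchError(name, m[3L], found)
    return(data.frame(name = name, gene_pos = pos, ref = m[3L], alt = m[4L],
                      kind = "SNV", stringsAsFactors = FALSE))
  }
  m <- regmatches(name, regexec("^c\\.(\\*?\\d+(?:[+-]\\d+)?)(dup|del)$", name))[[1L]]
  if (length(m)) {
    pos <- tok2ref(m[2L])
    b <- baseAt(pos)
    if (m[3L] == "del")
      return(data.frame(name = name, gene_pos = pos, ref = b, alt = "",
                        kind = "del", stringsAsFactors = FALSE))
    # dup: a copy of the base at `pos` inserted after it
    return(data.frame(name = name, gene_pos = pos + 1L, ref = "", alt = b,
                      kind = "dup", stringsAsFactors = FALSE))
  }
  .parseError("unsupported variant name grammar", name)
}

# Map a 0-based reference position to a coding-position token.
.refToCodingToken <- function(pos, locus) {
  cm <- locus@cdsMap
  cfg <- locus@config
  row <- which(cm$ref_start <= pos & pos < cm$ref_end)
  if (length(row))
    return(as.character(cm$coding_start[row] + (pos - cm$ref_start[row])))
  if (pos >= locus@utr3Start && pos < locus@utr3Start + cfg$utr3)
    return(paste0("*", pos - locus@utr3Start + 1L))
  # intron: anchor to the nearer exon boundary (ties go to the '+' side)
  prev <- which(cm$ref_end <= pos)
  nxt <- which(cm$ref_start > pos)
  if (length(prev) && length(nxt)) {
    pe <- max(prev); ns <- min(nxt)
    dPlus <- pos - (cm$ref_end[pe] - 1L)
    dMinus <- cm$ref_start[ns] - pos
    if (dPlus <= dMinus)
      return(paste0(cm$coding_end[pe], "+", dPlus))
    return(paste0(cm$coding_start[ns], "-", dMinus))
  }
  if (pos < cm$ref_start[1L] && pos >= locus@bodyStart)
    return(paste0("-", cm$ref_start[1L] - pos))
  stop("position outside the named region of the locus")
}

#' Format a variant as a coding-style name
#'
#' Inverse of [parseCodingName()] for the supported grammar. Insertion events
#' that duplicate the immediately preceding base are named `c.Ndup`; other
#' insertions get `c.N_N+1insSEQ`; multi-base deletions `c.N_Mdel`.
#'
#' @param gene_pos 0-based reference position (for insertions, the index of
#'   the base following the inserted sequence).
#' @param ref,alt reference/alternate alleles (`""` on the empty side of an
#'   indel).
#' @param kind `"SNV"`, `"del"`, `"ins"` or `"dup"`.
#' @param locus a [LocusModel-class].
#' @return the coding-style name, or `NA_character_` if the position falls
#'   outside the nameable region.
#' @export
formatCodingName <- function(gene_pos, ref, alt, kind, locus) {
  tok <- tryCatch(.refToCodingToken(gene_pos, locus), error = function(e) NA)
  if (kind == "SNV") {
    if (is.na(tok)) return(NA_character_)
    return(paste0("c.", tok, ref, ">", alt))
  }
  if (kind == "del") {
    if (is.na(tok)) return(NA_character_)
    if (nchar(ref) == 1L) return(paste0("c.", tok, "del"))
    tok2 <- tryCatch(.refToCodingToken(gene_pos + nchar(ref) - 1L, locus),
                     error = function(e) NA)
    if (is.na(tok2)) return(NA_character_)
    return(paste0("c.", tok, "_", tok2, "del"))
  }
  # insertion before gene_pos; a copy of the adjacent reference bases on
  # either side is a duplication (events arrive left-normalised, so the
  # duplicated copy usually sits to the right)
  gene <- as.character(locus@geneRef)
  L <- nchar(alt)
  prevTok <- tryCatch(.refToCodingToken(gene_pos - 1L, locus),
                      error = function(e) NA)
  if (is.na(prevTok)) return(NA_character_)
  dupName <- function(from0, to0) {
    t1 <- tryCatch(.refToCodingToken(from0, locus), error = function(e) NA)
    if (is.na(t1)) return(NA_character_)
    if (from0 == to0) return(paste0("c.", t1, "dup"))
    t2 <- tryCatch(.refToCodingToken(to0, locus), error = function(e) NA)
    if (is.na(t2)) return(NA_character_)
    paste0("c.", t1, "_", t2, "dup")
  }
  if (L >= 1L && gene_pos - L >= 0L &&
      substring(gene, gene_pos - L + 1L, gene_pos) == alt)
    return(dupName(gene_pos - L, gene_pos - 1L))
  if (L >= 1L && gene_pos + L <= nchar(gene) &&
      substring(gene, gene_pos + 1L, gene_pos + L) == alt)
    return(dupName(gene_pos, gene_pos + L - 1L))
  if (is.na(tok)) return(NA_character_)
  paste0("c.", prevTok, "_", tok, "ins", alt)
}
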