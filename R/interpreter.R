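# Knowledge-base annotation and duplication-aware screening verdicts.

.SEVERITY <- c(NC = 1L, SV = 2L, SW = 3L)

#' Chimera class label of a structural haplotype
#'
#' @param structure structure class.
#' @param bin junction bin label.
#' @return the field-standard label, e.g. `"CYP21A1P/CYP21A2_CH-1"`,
#'   `"TNXA/TNXB_CH-1"`, `"CYP21A2/CYP21A1P_CH-3"`, or `NA` for
#'   non-chimeric structures.
#' @export
structureLabel <- function(structure, bin) {
  if (is.na(bin)) return(NA_character_)
  suffix <- sub("^TNX-", "", bin)
  switch(structure,
         DEL_CHIMERA = paste0("CYP21A1P/CYP21A2_", suffix),
         TNX_CHIMERA = paste0("TNXA/TNXB_", suffix),
         DUP_FUSION = paste0("CYP21A1P/CYP21A2_", suffix, "(fused copy)"),
         CONV_CHIMERA = paste0("CYP21A2/CYP21A1P_", suffix),
         NA_character_)
}

#' Annotate variant names against the knowledge base
#'
#' Variants absent from the knowledge base are tagged `"unknown"` and never
#' count as pathogenic.
#'
#' @param names character vector of variant names (coding-style or chimera
#'   class labels).
#' @param kb a [VariantKB-class].
#' @return data.frame: `name`, `classification`, `phenotype`.
#' @export
annotateVariants <- function(names, kb) .kbLookup(kb, names)

# Pathogenic content of one haplotype call (the P/LP variants plus a
# deletion-class structure, if any), as a character signature.
.pathoSignature <- function(hap, kb) {
  ann <- .kbLookup(kb, hap@variants)
  sig <- sort(ann$name[ann$classification %in% c("P", "LP")])
  if (hap@structure %in% c("DEL_CHIMERA", "TNX_CHIMERA"))
    sig <- c(sig, structureLabel(hap@structure, hap@bin))
  if (hap@structure == "CONV_CHIMERA") {
    lbl <- structureLabel(hap@structure, hap@bin)
    cls <- .kbLookup(kb, lbl)$classification
    if (cls %in% c("P", "LP")) sig <- c(sig, lbl)
  }
  sig
}

# Most-severe phenotype among a haplotype's pathogenic content.
.hapPhenotype <- function(hap, kb) {
  sig <- .pathoSignature(hap, kb)
  if (!length(sig)) return(NA_character_)
  ph <- .kbLookup(kb, sig)$phenotype
  sev <- .SEVERITY[ph[ph %in% names(.SEVERITY)]]
  if (!length(sev)) return(NA_character_)
  names(.SEVERITY)[match(max(sev), .SEVERITY)]
}

#' Call the per-sample diplotype verdict
#'
#' A haplotype counts as a pathogenic allele iff it has pathogenic content
#' (at least one P/LP variant, or a deletion-class chimera structure) AND
#' does not retain an intact P/LP-free functional-gene copy (`intactCopy`),
#' which is what keeps fusion-duplication carriers from being over-called.
#' Status is AFFECTED with two pathogenic alleles, CARRIER with one,
#' NEGATIVE with none. The predicted phenotype of an affected diplotype is
#' the milder of the two allele phenotypes under the severity order
#' SW > SV > NC (predicted, not diagnostic).
#'
#' @param hapA,hapB [HaplotypeCall-class] objects.
#' @param kb a [VariantKB-class].
#' @param sample sample id.
#' @param calls,mask,classCounts,notes optional evidence carried through to
#'   the report.
#' @return a [DiplotypeCall-class].
#' @export
callDiplotype <- function(hapA, hapB, kb, sample = "sample",
                          calls = NULL, mask = NULL,
                          classCounts = integer(0), notes = character(0)) {
  sigs <- list(A = .pathoSignature(hapA, kb), B = .pathoSignature(hapB, kb))
  isPatho <- function(hap, sig) length(sig) > 0L && !isTRUE(hap@intactCopy)
  pa <- sum(isPatho(hapA, sigs$A), isPatho(hapB, sigs$B))
  status <- c("NEGATIVE", "CARRIER", "AFFECTED")[pa + 1L]
  mode <- if (pa == 0L) "none"
          else if (pa == 1L) "het"
          else if (identical(sigs$A, sigs$B) && length(sigs$A) == 1L) "hom"
          else "CHet"
  phen <- NA_character_
  if (pa == 2L) {
    pA <- .hapPhenotype(hapA, kb); pB <- .hapPhenotype(hapB, kb)
    sev <- .SEVERITY[c(pA, pB)]
    if (all(!is.na(sev)))
      phen <- names(.SEVERITY)[match(min(sev), .SEVERITY)]
    else if (any(!is.na(sev)))
      phen <- names(.SEVERITY)[match(min(sev, na.rm = TRUE), .SEVERITY)]
  }
  annRows <- list()
  for (h in list(hapA, hapB)) {
    nm <- h@variants
    lbl <- structureLabel(h@structure, h@bin)
    if (!is.na(lbl) && h@structure != "DUP_FUSION") nm <- c(nm, lbl)
    if (length(nm)) {
      a <- .kbLookup(kb, nm)
      a$hap <- h@label
      annRows[[length(annRows) + 1L]] <- a
    }
  }
  ann <- if (length(annRows)) do.call(rbind, annRows)
         else data.frame(name = character(0), classification = character(0),
                         phenotype = character(0), hap = character(0))
  # trans flag: the variant's haplotype differs from the other pathogenic one
  ann$trans <- logical(nrow(ann))
  if (nrow(ann) && mode == "CHet")
    ann$trans <- ann$classification %in% c("P", "LP")
  new("DiplotypeCall", sample = sample, hapA = hapA, hapB = hapB,
      status = status, pathogenicAlleles = as.integer(pa),
      genotypeMode = mode, predictedPhenotype = phen,
      annotations = ann,
      calls = calls %||% data.frame(),
      mask = mask %||% data.frame(),
      classCounts = classCounts, notes = notes)
}

#' Render a screening report
#'
#' @param dp a [DiplotypeCall-class].
#' @param format `"json"` or `"text"`.
#' @return a character scalar (JSON document or text block).
#' @export
renderReport <- function(dp, format = c("json", "text")) {
  if (!format[1L] %in% c("json", "text")) stop("unknown report format: ", format[1L])
  format <- match.arg(format)
  hapDesc <- function(h) list(
    label = h@label, supporting_reads = h@supportingReads,
    variants = as.list(h@variants), structure = h@structure,
    bin = h@bin, intact_copy = h@intactCopy,
    structure_label = structureLabel(h@structure, h@bin))
  obj <- list(schema = "cahscreen-report/1",
              sample = dp@sample, status = dp@status,
              pathogenic_alleles = dp@pathogenicAlleles,
              genotype_mode = dp@genotypeMode,
              predicted_phenotype = dp@predictedPhenotype,
              haplotypes = list(A = hapDesc(dp@hapA), B = hapDesc(dp@hapB)),
              annotations = dp@annotations,
              class_counts = as.list(dp@classCounts),
              notes = as.list(dp@notes))
  if (format == "json")
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                         dataframe = "rows", null = "null",
                                         na = "null")))
  lines <- c(sprintf("sample: %s", dp@sample),
             sprintf("status: %s (%d pathogenic alleles)", dp@status,
                     dp@pathogenicAlleles),
             sprintf("genotype: %s   predicted phenotype: %s",
                     dp@genotypeMode, dp@predictedPhenotype %||% "NA"))
  for (h in list(dp@hapA, dp@hapB)) {
    lbl <- structureLabel(h@structure, h@bin)
    lines <- c(lines, sprintf("haplotype %s (%d reads): %s%s", h@label,
                              h@supportingReads, h@structure,
                              if (!is.na(lbl)) paste0(" [", lbl, "]") else ""))
    ann <- dp@annotations
    ann <- ann[ann$hap == h@label, , drop = FALSE]
    for (i in seq_len(nrow(ann)))
      lines <- c(lines, sprintf("  %-28s %-3s %-7s%s", ann$name[i],
                                ann$classification[i], ann$phenotype[i],
                                if (isTRUE(ann$trans[i])) " t" else ""))
  }
  if (length(dp@notes)) lines <- c(lines, paste("note:", dp@notes))
  paste(lines, collapse = "\n")
}
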