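#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom Biostrings DNAString DNAStringSet BStringSet
#' @useDynLib CAHscreen, .registration = TRUE
NULL

#' Toy two-paralog locus model
#'
#' Holds the paired functional-gene / pseudogene references (stand-ins for the
#' CYP21A2-TNXB and CYP21A1P-TNXA builds), the four category-defining primer
#' pairs, the exon map used to translate HGVS-style coding names to reference
#' coordinates, the paralog signature variants (PSVs) derived from the
#' pairwise alignment of the two references, and the junction bins (CH-1 ...
#' CH-9 over the gene body, TNX-CH-1 over the downstream flank) used to label
#' chimera breakpoints.
#'
#' Coordinates are 0-based half-open on `geneRef`; coding names are 1-based.
#'
#' @slot geneRef [Biostrings::DNAString] functional-gene amplicon reference.
#' @slot pseudoRef [Biostrings::DNAString] pseudogene amplicon reference.
#' @slot primers named character vector with elements `gene_fwd`, `gene_rev`,
#'   `pseudo_fwd`, `pseudo_rev` (primer sequences, 5'->3' on the plus strand;
#'   reverse primers are stored as the reference top-strand site, i.e. the
#'   read carries their reverse complement at its 3' end). An optional
#'   `conv_fwd` element enables classifier-level conversion-chimera calls.
#' @slot cdsMap data.frame of exon intervals: `exon`, `ref_start`, `ref_end`
#'   (0-based half-open), `coding_start`, `coding_end` (1-based inclusive).
#' @slot psvs data.frame of signature variants: `gene_pos`, `pseudo_pos`
#'   (0-based), `kind` ("SNV", "ins", "del"), `gene_allele`, `pseudo_allele`,
#'   `region` ("gene" or "flank"). For "ins" PSVs `gene_pos` is the position
#'   of the reference base following the inserted pseudogene bases.
#' @slot junctionBins data.frame: `label`, `start`, `end` (0-based half-open
#'   on `geneRef`), `psv_lo`, `psv_hi` (row indices of the PSVs the bin
#'   contains), `region`.
#' @slot bodyStart,bodyEnd integer bounds of the homologous body (the region
#'   between the locus-specific primers) on `geneRef`.
#' @slot utr3Start integer 0-based position of coding position `*1`.
#' @slot config list of the parameters the locus was built from.
#' @export
setClass("LocusModel", representation(
  geneRef = "DNAString", pseudoRef = "DNAString",
  primers = "character", cdsMap = "data.frame", psvs = "data.frame",
  junctionBins = "data.frame", bodyStart = "integer", bodyEnd = "integer",
  utr3Start = "integer", config = "list"))

setValidity("LocusModel", function(object) {
  msgs <- character(0)
  need <- c("gene_fwd", "gene_rev", "pseudo_fwd", "pseudo_rev")
  if (!all(need %in% names(object@primers)))
    msgs <- c(msgs, "primers must contain gene_fwd, gene_rev, pseudo_fwd, pseudo_rev")
  p <- object@psvs
  if (nrow(p)) {
    if (any(p$gene_allele == p$pseudo_allele))
      msgs <- c(msgs, "PSV gene and pseudo alleles must differ")
    if (is.unsorted(p$gene_pos, strictly = TRUE))
      msgs <- c(msgs, "PSV positions must be strictly increasing")
  }
  b <- object@junctionBins
  if (nrow(b) > 1L) {
    if (any(b$start[-1L] != b$end[-nrow(b)]))
      msgs <- c(msgs, "junction bins must tile without gaps or overlap")
  }
  if (length(msgs)) msgs else TRUE
})

#' Set of barcoded amplicon reads
#'
#' A lightweight container for simulated or loaded amplicon reads: sequences,
#' Phred+33 qualities, and (for simulated data) per-read truth tags naming the
#' generating haplotype and amplicon.
#'
#' @slot sequences [Biostrings::DNAStringSet], names are read ids.
#' @slot qualities [Biostrings::BStringSet] Phred+33 strings, same lengths.
#' @slot truth character vector of truth tags (`NA` for real data).
#' @slot sample single sample label (`NA` before demultiplexing).
#' @export
setClass("ReadSet", representation(
  sequences = "DNAStringSet", qualities = "BStringSet",
  truth = "character", sample = "character"))

setValidity("ReadSet", function(object) {
  msgs <- character(0)
  n <- length(object@sequences)
  if (length(object@qualities) != n)
    msgs <- c(msgs, "sequences and qualities must have equal length")
  else if (n && !all(Biostrings::width(object@sequences) ==
                     Biostrings::width(object@qualities)))
    msgs <- c(msgs, "per-read quality string must match sequence length")
  if (n && any(Biostrings::width(object@sequences) == 0L))
    msgs <- c(msgs, "zero-length read")
  if (length(object@truth) != n)
    msgs <- c(msgs, "truth tags must have one entry per read")
  if (length(msgs)) msgs else TRUE
})

#' Per-base sequencing error model
#'
#' Emulates circular-consensus (HiFi-like, accuracy >= Q20) residual errors.
#' All rates are per-base probabilities and must lie in `[0, 0.05]`.
#'
#' @slot substitutionRate,insRate,delRate numeric scalars.
#' @export
setClass("ErrorModel", representation(
  substitutionRate = "numeric", insRate = "numeric", delRate = "numeric"))

setValidity("ErrorModel", function(object) {
  r <- c(object@substitutionRate, object@insRate, object@delRate)
  if (length(r) != 3L || any(is.na(r)) || any(r < 0) || any(r > 0.05))
    "all error rates must be in [0, 0.05]" else TRUE
})

#' Haplotype specification for the simulator
#'
#' Describes one haplotype of a diplotype to simulate: its small variants
#' (HGVS-style coding names) and its structure class.
#'
#' @slot label haplotype label.
#' @slot variants character vector of coding names applied to the
#'   functional-gene amplicon (or to the gene-derived segment of a chimera).
#' @slot structure one of `"NORMAL"`, `"DEL_CHIMERA"`, `"CONV_CHIMERA"`,
#'   `"TNX_CHIMERA"`, `"DUP_FUSION"`.
#' @slot bin junction bin label for chimeric structures (`NA` otherwise).
#' @slot copies number of intact functional-gene copies (>= 1; only
#'   meaningful for `DUP_FUSION`).
#' @slot fusedVariants coding names applied to the gene-derived segment of
#'   the fused copy of a `DUP_FUSION` haplotype.
#' @export
setClass("HaplotypeSpec", representation(
  label = "character", variants = "character", structure = "character",
  bin = "character", copies = "integer", fusedVariants = "character"))

.STRUCTURES <- c("NORMAL", "DEL_CHIMERA", "CONV_CHIMERA", "TNX_CHIMERA",
                 "DUP_FUSION")

setValidity("HaplotypeSpec", function(object) {
  msgs <- character(0)
  if (!object@structure %in% .STRUCTURES)
    msgs <- c(msgs, paste("structure must be one of:",
                          paste(.STRUCTURES, collapse = ", ")))
  if (object@structure %in% c("DEL_CHIMERA", "CONV_CHIMERA", "TNX_CHIMERA",
                              "DUP_FUSION") && is.na(object@bin))
    msgs <- c(msgs, "chimeric structures need a junction bin")
  if (object@copies < 1L)
    msgs <- c(msgs, "copies must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Pathogenic-variant knowledge base
#'
#' Curated lookup table of variant classifications (P / LP / VUS) and
#' phenotype annotations (SW / SV / NC / unknown) replacing a full ACMG
#' evidence engine. Structural alleles (30-kb-deletion chimera classes) are
#' keyed by their class label, e.g. `"CYP21A1P/CYP21A2_CH-1"`.
#'
#' @slot entries data.frame with columns `name`, `classification`,
#'   `phenotype`, `allele_tally`.
#' @export
setClass("VariantKB", representation(entries = "data.frame"))

setValidity("VariantKB", function(object) {
  e <- object@entries
  msgs <- character(0)
  if (!all(c("name", "classification", "phenotype") %in% colnames(e)))
    msgs <- c(msgs, "entries need name, classification, phenotype columns")
  else {
    if (anyDuplicated(e$name))
      msgs <- c(msgs, "duplicate variant names in knowledge base")
    if (nrow(e) && any(is.na(e$classification) | e$classification == ""))
      msgs <- c(msgs, "missing classification")
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-allele haplotype call
#'
#' One of the two alleles of a screened sample: its supporting read count,
#' small-variant set, structure class with junction bin, and whether the
#' haplotype retains an intact (non-chimeric, P/LP-free) functional-gene
#' copy — the duplication-aware flag that keeps fusion-duplication carriers
#' from being counted as pathogenic alleles.
#'
#' @slot label `"A"` or `"B"`.
#' @slot supportingReads integer.
#' @slot variants character vector of coding names.
#' @slot structure structure class (see [HaplotypeSpec-class]).
#' @slot bin junction bin label or `NA`.
#' @slot intactCopy logical; `TRUE` iff the haplotype retains at least one
#'   full-length non-chimeric functional amplicon free of P/LP variants.
#' @export
setClass("HaplotypeCall", representation(
  label = "character", supportingReads = "integer", variants = "character",
  structure = "character", bin = "character", intactCopy = "logical"))

#' Per-sample screening verdict
#'
#' @slot sample sample id.
#' @slot hapA,hapB [HaplotypeCall-class] objects.
#' @slot status `"AFFECTED"` (2 pathogenic alleles), `"CARRIER"` (1) or
#'   `"NEGATIVE"` (0).
#' @slot pathogenicAlleles integer 0..2.
#' @slot genotypeMode `"hom"`, `"CHet"`, `"het"` or `"none"`.
#' @slot predictedPhenotype `"SW"`, `"SV"`, `"NC"` or `NA` — the milder of
#'   the two allele phenotypes (predicted, not diagnostic).
#' @slot annotations data.frame of per-variant classifications.
#' @slot calls data.frame of raw small-variant calls (pre-phasing).
#' @slot mask data.frame of no-call intervals (depth below the floor).
#' @slot classCounts named integer vector of read-class counts.
#' @slot notes character vector of warnings/notes accumulated by the run.
#' @export
setClass("DiplotypeCall", representation(
  sample = "character", hapA = "HaplotypeCall", hapB = "HaplotypeCall",
  status = "character", pathogenicAlleles = "integer",
  genotypeMode = "character", predictedPhenotype = "character",
  annotations = "data.frame", calls = "data.frame", mask = "data.frame",
  classCounts = "integer", notes = "character"))

setValidity("DiplotypeCall", function(object) {
  want <- c("0" = "NEGATIVE", "1" = "CARRIER", "2" = "AFFECTED")
  if (!identical(unname(want[as.character(object@pathogenicAlleles)]),
                 object@status))
    "status must follow pathogenicAlleles (2=AFFECTED, 1=CARRIER, 0=NEGATIVE)"
  else TRUE
})

#' Beta posterior summary
#'
#' Jeffreys-prior binomial posterior: `Beta(x + 0.5, n - x + 0.5)` with its
#' mean and the equal-tailed credible interval.
#'
#' @slot alpha,beta positive shape parameters.
#' @slot mean posterior mean `alpha / (alpha + beta)`.
#' @slot criLow,criHigh equal-tailed credible-interval bounds.
#' @slot level interval mass (default 0.95).
#' @export
setClass("PosteriorSummary", representation(
  alpha = "numeric", beta = "numeric", mean = "numeric",
  criLow = "numeric", criHigh = "numeric", level = "numeric"))

setValidity("PosteriorSummary", function(object) {
  if (object@alpha <= 0 || object@beta <= 0) return("shapes must be positive")
  if (abs(object@mean - object@alpha / (object@alpha + object@beta)) > 1e-12)
    return("mean must equal alpha/(alpha+beta)")
  if (object@criLow > object@criHigh) return("criLow must be <= criHigh")
  TRUE
})
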