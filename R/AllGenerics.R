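# Accessor generics and show methods.

#' @describeIn LocusModel-class functional-gene reference sequence.
#' @param x,object a `LocusModel`.
#' @export
setGeneric("geneRef", function(x) standardGeneric("geneRef"))
#' @describeIn LocusModel-class pseudogene reference sequence.
#' @export
setGeneric("pseudoRef", function(x) standardGeneric("pseudoRef"))
#' @describeIn LocusModel-class named primer vector.
#' @export
setGeneric("primerSet", function(x) standardGeneric("primerSet"))
#' @describeIn LocusModel-class PSV table.
#' @export
setGeneric("psvTable", function(x) standardGeneric("psvTable"))
#' @describeIn LocusModel-class junction-bin table.
#' @export
setGeneric("junctionBins", function(x) standardGeneric("junctionBins"))
#' @describeIn LocusModel-class exon/coding interval map.
#' @export
setGeneric("cdsMap", function(x) standardGeneric("cdsMap"))

setMethod("geneRef", "LocusModel", function(x) x@geneRef)
setMethod("pseudoRef", "LocusModel", function(x) x@pseudoRef)
setMethod("primerSet", "LocusModel", function(x) x@primers)
setMethod("psvTable", "LocusModel", function(x) x@psvs)
setMethod("junctionBins", "LocusModel", function(x) x@junctionBins)
setMethod("cdsMap", "LocusModel", function(x) x@cdsMap)

setMethod("show", "LocusModel", function(object) {
  cat(sprintf("LocusModel: gene %d nt / pseudo %d nt, %d PSVs (%d SNV, %d indel), %d junction bins\n",
              length(object@geneRef), length(object@pseudoRef),
              nrow(object@psvs), sum(object@psvs$kind == "SNV"),
              sum(object@psvs$kind != "SNV"), nrow(object@junctionBins)))
  cat(sprintf("  CDS %d nt over %d exons; 3'UTR starts at ref %d\n",
              max(object@cdsMap$coding_end), nrow(object@cdsMap),
              object@utr3Start))
})

#' @describeIn ReadSet-class read sequences as a `DNAStringSet`.
#' @param x,object a `ReadSet`.
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))
#' @describeIn ReadSet-class Phred+33 quality strings.
#' @export
setGeneric("readQualities", function(x) standardGeneric("readQualities"))
#' @describeIn ReadSet-class simulation truth tags (NA for real reads).
#' @export
setGeneric("truthTags", function(x) standardGeneric("truthTags"))

setMethod("readSequences", "ReadSet", function(x) x@sequences)
setMethod("readQualities", "ReadSet", function(x) x@qualities)
setMethod("truthTags", "ReadSet", function(x) x@truth)
setMethod("length", "ReadSet", function(x) length(x@sequences))
setMethod("names", "ReadSet", function(x) names(x@sequences))

#' @describeIn ReadSet-class subset by index, name or logical vector.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  if (is.logical(i)) i <- which(i)
  new("ReadSet", sequences = x@sequences[i], qualities = x@qualities[i],
      truth = x@truth[i], sample = x@sample)
})

setMethod("show", "ReadSet", function(object) {
  cat(sprintf("ReadSet: %d reads%s%s\n", length(object),
              if (!is.na(object@sample)) paste0(", sample ", object@sample) else "",
              if (any(!is.na(object@truth))) " (with truth tags)" else ""))
})

#' @describeIn VariantKB-class the annotation table.
#' @param x,object a `VariantKB`.
#' @export
setGeneric("kbEntries", function(x) standardGeneric("kbEntries"))
setMethod("kbEntries", "VariantKB", function(x) x@entries)
setMethod("show", "VariantKB", function(object) {
  e <- object@entries
  cat(sprintf("VariantKB: %d entries (%d P, %d LP, %d VUS)\n", nrow(e),
              sum(e$classification == "P"), sum(e$classification == "LP"),
              sum(e$classification == "VUS")))
})

#' @describeIn HaplotypeCall-class variant names carried by the allele.
#' @param x,object a `HaplotypeCall`.
#' @export
setGeneric("variantSet", function(x) standardGeneric("variantSet"))
setMethod("variantSet", "HaplotypeCall", function(x) x@variants)

setMethod("show", "HaplotypeCall", function(object) {
  cat(sprintf("Haplotype %s: %s%s, %d reads, variants: %s%s\n",
              object@label, object@structure,
              if (!is.na(object@bin)) paste0("(", object@bin, ")") else "",
              object@supportingReads,
              if (length(object@variants)) paste(object@variants, collapse = ", ")
              else "none",
              if (isTRUE(object@intactCopy)) " [intact copy retained]" else ""))
})

#' @describeIn DiplotypeCall-class screening status of the sample.
#' @param x,object a `DiplotypeCall`.
#' @export
setGeneric("screenStatus", function(x) standardGeneric("screenStatus"))
setMethod("screenStatus", "DiplotypeCall", function(x) x@status)

setMethod("show", "DiplotypeCall", function(object) {
  cat(sprintf("Sample %s: %s (%d pathogenic allele%s, mode %s, predicted %s)\n",
              object@sample, object@status, object@pathogenicAlleles,
              if (object@pathogenicAlleles == 1L) "" else "s",
              object@genotypeMode, object@predictedPhenotype))
  show(object@hapA); show(object@hapB)
})

setMethod("show", "PosteriorSummary", function(object) {
  cat(sprintf("Beta(%.1f, %.1f): mean %.4f, %d%% CrI [%.4f, %.4f]\n",
              object@alpha, object@beta, object@mean,
              round(object@level * 100), object@criLow, object@criHigh))
})
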