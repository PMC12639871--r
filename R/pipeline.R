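# End-to-end screening of one sample: classify -> align -> call -> junction
# -> phase -> interpret.

.unclassifiableError <- function(frac) {
  stop(structure(class = c("cah_unclassifiable", "error", "condition"),
                 list(message = sprintf(
                   "%.0f%% of reads unassigned: cannot screen sample",
                   100 * frac), call = NULL)))
}

#' Screen a single sample
#'
#' Runs the full per-sample pipeline on barcoded-and-demultiplexed reads:
#' primer-pair classification; alignment of functional-gene and chimera
#' reads to the gene reference; pileup variant calling with the coverage
#' floor (functional reads only); per-read PSV vectors, junction
#' changepoints and bin assignment for chimera reads; read-backed phasing of
#' the functional reads at heterozygous sites; conversion-tract refinement;
#' and duplication-aware diplotype interpretation.
#'
#' Haplotype assembly rules (nF = phased functional groups, nS = structural
#' chimera groups with adequate support):
#' * nF=2, nS=0: two sequence haplotypes.
#' * nF=1, nS=0: homozygous diplotype (both haplotypes the consensus).
#' * nF=1, nS=1: hemizygous pair — the chimera is the second allele, and the
#'   functional group's calls belong to the retained allele (this is how a
#'   variant at apparent 100% fraction plus a deletion chimera is reported
#'   as compound heterozygous).
#' * nF=2, nS=1: fusion duplication — the chimera is an extra fused copy
#'   attached to the functional haplotype with the least pathogenic content;
#'   that haplotype keeps its intact copy and is not counted pathogenic.
#' * nF=0, nS=2: both alleles structural.
#' * other combinations are resolved to the two best-supported entities with
#'   a warning note.
#'
#' @param rs a [ReadSet-class] for one sample (barcode stripped).
#' @param locus a [LocusModel-class].
#' @param kb a [VariantKB-class].
#' @param min_depth minimum coverage depth for variant calls (default 30).
#' @param het_band emit/HOM allele-fraction thresholds.
#' @param conv_min_prefix minimum contiguous pseudo-state prefix (in PSVs)
#'   for a conversion-chimera call on a functional consensus.
#' @param min_support minimum reads for a structural group (`NULL`: 5% of
#'   classified reads, at least 3).
#' @param max_unassigned abort when more than this fraction of reads is
#'   unassigned.
#' @param qc_pseudo also align pseudogene-classified reads to the pseudogene
#'   reference for QC (never contributes calls).
#' @return a [DiplotypeCall-class].
#' @export
screenSample <- function(rs, locus, kb = defaultVariantKB(),
                         min_depth = 30L, het_band = c(0.2, 0.8),
                         conv_min_prefix = 2L, min_support = NULL,
                         max_unassigned = 0.5, qc_pseudo = FALSE) {
  notes <- character(0)
  cl <- classifyReads(rs, locus)
  classes <- cl$classes
  reads <- cl$reads
  counts <- table(factor(classes, levels = .READ_CLASSES))
  classCounts <- stats::setNames(as.integer(counts), names(counts))
  n <- length(classes)
  if (n == 0L) stop("empty read set")
  if (classCounts[["UNASSIGNED"]] / n > max_unassigned)
    .unclassifiableError(classCounts[["UNASSIGNED"]] / n)
  if (is.null(min_support))
    min_support <- max(3L, ceiling(0.05 * sum(classes != "UNASSIGNED")))

  funIdx <- which(classes %in% c("FUNCTIONAL", "CONV_CHIMERA"))
  chiIdx <- which(classes %in% c("DEL_CHIMERA", "TNX_CHIMERA"))

  aligned <- alignReads(reads[c(funIdx, chiIdx)], locus@geneRef)
  if (length(aligned$excluded))
    notes <- c(notes, sprintf("%d reads excluded at <70%% alignment identity",
                              length(aligned$excluded)))
  alnById <- stats::setNames(aligned$alignments,
                             vapply(aligned$alignments, `[[`, character(1L),
                                    "read_id"))
  funIds <- intersect(names(reads@sequences)[funIdx], names(alnById))
  chiIds <- intersect(names(reads@sequences)[chiIdx], names(alnById))

  if (qc_pseudo) {
    pseIdx <- which(classes == "PSEUDO")
    if (length(pseIdx)) {
      qc <- alignReads(reads[pseIdx], locus@pseudoRef)
      if (length(qc$excluded))
        notes <- c(notes, sprintf("pseudogene QC: %d low-identity reads",
                                  length(qc$excluded)))
    }
  }

  # ---- small variants from the functional pileup ----
  vc <- callSmallVariants(alnById[funIds], locus, min_depth = min_depth,
                          het_band = het_band)
  calls <- vc$calls

  # ---- structural groups from chimera reads ----
  structGroups <- list()
  if (length(chiIds)) {
    binOf <- vapply(chiIds, function(id) {
      v <- psvGenotypeVector(alnById[[id]], locus)
      if (sum(v != "M") < 2L) return(NA_character_)
      j <- locateJunction(v)
      if (!is.na(j$sentinel)) return(NA_character_)
      tryCatch(binJunction(j, locus)$label, error = function(e) NA_character_)
    }, character(1L))
    tab <- table(binOf[!is.na(binOf)])
    keep <- names(tab)[tab >= min_support]
    keep <- keep[order(tab[keep], decreasing = TRUE)]
    if (length(keep) > 2L) {
      notes <- c(notes, sprintf(
        "more than two chimera junction groups (%s): keeping the two best-supported",
        paste(keep, collapse = ", ")))
      keep <- keep[1:2]
    }
    for (b in keep) {
      ids <- chiIds[!is.na(binOf) & binOf == b]
      grpCalls <- callSmallVariants(alnById[ids], locus,
                                    min_depth = min(min_depth, length(ids)),
                                    het_band = het_band)$calls
      structGroups[[length(structGroups) + 1L]] <- list(
        bin = b, ids = ids,
        structure = if (grepl("^TNX-", b)) "TNX_CHIMERA" else "DEL_CHIMERA",
        variants = grpCalls$name[!is.na(grpCalls$name) &
                                   grpCalls$frac >= het_band[2L]])
    }
    nDrop <- sum(is.na(binOf)) + sum(tab[setdiff(names(tab), keep)])
    if (nDrop > 0L)
      notes <- c(notes, sprintf("%d chimera reads without a consistent junction",
                                nDrop))
  }

  # ---- phase functional reads at het sites and polymorphic PSV columns ----
  # PSV columns are paralog identity and never become variant calls, but a
  # gene-conversion haplotype differs from a normal one exactly there, so
  # PSV states where the reads disagree join the phasing vectors.
  hetCalls <- calls[calls$zygosity == "HET", , drop = FALSE]
  homCalls <- calls[calls$zygosity == "HOM", , drop = FALSE]
  funGroups <- list()
  if (length(funIds)) {
    psvVecs <- lapply(stats::setNames(funIds, funIds), function(id)
      psvGenotypeVector(alnById[[id]], locus))
    psvMat <- do.call(rbind, psvVecs)
    nP <- colSums(psvMat == "P"); nG <- colSums(psvMat == "G")
    polyPsv <- which(pmin(nP, nG) >= pmax(2, het_band[1L] * (nP + nG)) &
                       (nP + nG) > 0)
    alleleOf <- function(id) {
      ev <- alnById[[id]]$events
      hets <- vapply(seq_len(nrow(hetCalls)), function(r) {
        c_ <- hetCalls[r, ]
        hit <- if (c_$kind == "SNV") {
          ev$type == "X" & ev$ref_pos == c_$gene_pos & ev$alt == c_$alt
        } else if (c_$kind == "del") {
          ev$type == "D" & ev$ref_pos == c_$gene_pos & ev$ref == c_$ref
        } else {
          ev$type == "I" & ev$ref_pos == c_$gene_pos & ev$alt == c_$alt
        }
        if (any(hit)) "alt" else "ref"
      }, character(1L))
      c(hets, psvMat[id, polyPsv])
    }
    alleles <- lapply(stats::setNames(funIds, funIds), alleleOf)
    ph <- phaseReads(alleles)
    if (ph$multi_allele)
      notes <- c(notes, "three or more well-supported allele vectors among functional reads")
    for (g in seq_along(ph$groups)) {
      ids <- ph$groups[[g]]
      vars <- character(0)
      if (nrow(hetCalls))
        vars <- hetCalls$name[ph$consensus[[g]][seq_len(nrow(hetCalls))] == "alt"]
      vars <- c(vars, homCalls$name)
      vars <- vars[!is.na(vars)]
      # conversion refinement on the group consensus PSV states
      cons <- consensusPsvVector(psvVecs[ids])
      structure_ <- "NORMAL"; bin_ <- NA_character_
      infIdx <- which(cons != "M")
      prefP <- 0L
      for (ii in infIdx) { if (cons[ii] == "P") prefP <- prefP + 1L else break }
      if (prefP >= conv_min_prefix && any(cons[infIdx] == "G")) {
        j <- locateJunction(cons)
        if (is.na(j$sentinel)) {
          bb <- tryCatch(binJunction(j, locus), error = function(e) NULL)
          if (!is.null(bb)) {
            structure_ <- "CONV_CHIMERA"; bin_ <- bb$label
            notes <- c(notes, sprintf(
              "functional consensus carries a pseudogene-state 5' tract (%s)",
              bb$label))
          }
        }
      }
      funGroups[[length(funGroups) + 1L]] <- list(
        ids = ids, variants = unique(vars), structure = structure_, bin = bin_)
    }
  }

  # ---- assemble two haplotypes ----
  mkHap <- function(label, grp, kind) {
    if (kind == "fun") {
      ann <- .kbLookup(kb, grp$variants)
      clean <- !any(ann$classification %in% c("P", "LP"))
      new("HaplotypeCall", label = label,
          supportingReads = length(grp$ids), variants = grp$variants,
          structure = grp$structure, bin = grp$bin,
          intactCopy = clean && grp$structure == "NORMAL")
    } else {
      new("HaplotypeCall", label = label,
          supportingReads = length(grp$ids), variants = grp$variants,
          structure = grp$structure, bin = grp$bin, intactCopy = FALSE)
    }
  }
  nF <- length(funGroups); nS <- length(structGroups)
  if (nF == 0L && nS == 0L)
    stop("no usable functional or chimera read groups in sample")
  haps <- NULL
  if (nS == 0L) {
    if (nF == 1L) {
      hA <- mkHap("A", funGroups[[1L]], "fun")
      hB <- mkHap("B", funGroups[[1L]], "fun")
      haps <- list(hA, hB)
    } else {
      ord <- order(vapply(funGroups, function(g)
        paste(sort(g$variants), collapse = ","), character(1L)))
      haps <- list(mkHap("A", funGroups[[ord[1L]]], "fun"),
                   mkHap("B", funGroups[[ord[2L]]], "fun"))
    }
  } else if (nS == 1L && nF == 1L) {
    haps <- list(mkHap("A", funGroups[[1L]], "fun"),
                 mkHap("B", structGroups[[1L]], "struct"))
  } else if (nS == 1L && nF == 2L) {
    # fusion duplication: attach the fused copy to the haplotype with the
    # least pathogenic content; it keeps its intact functional copy
    nPatho <- vapply(funGroups, function(g)
      sum(.kbLookup(kb, g$variants)$classification %in% c("P", "LP")),
      integer(1L))
    carrierIdx <- if (nPatho[2L] <= nPatho[1L]) 2L else 1L
    otherIdx <- 3L - carrierIdx
    hA <- mkHap("A", funGroups[[otherIdx]], "fun")
    dupGrp <- funGroups[[carrierIdx]]
    ann <- .kbLookup(kb, dupGrp$variants)
    hB <- new("HaplotypeCall", label = "B",
              supportingReads = length(dupGrp$ids) +
                length(structGroups[[1L]]$ids),
              variants = dupGrp$variants, structure = "DUP_FUSION",
              bin = structGroups[[1L]]$bin,
              intactCopy = !any(ann$classification %in% c("P", "LP")))
    notes <- c(notes, sprintf(
      "fused gene/pseudogene copy (%s) interpreted as a duplication: intact functional copies retained",
      structGroups[[1L]]$bin))
    haps <- list(hA, hB)
  } else if (nS == 2L && nF == 0L) {
    haps <- list(mkHap("A", structGroups[[1L]], "struct"),
                 mkHap("B", structGroups[[2L]], "struct"))
  } else if (nS == 1L && nF == 0L) {
    # single chimera group only: support decides hom-chimera vs hemizygous
    grp <- structGroups[[1L]]
    haps <- list(mkHap("A", grp, "struct"), mkHap("B", grp, "struct"))
    notes <- c(notes, "only chimera reads present: reported as homozygous structural allele")
  } else {
    notes <- c(notes, sprintf(
      "ambiguous group structure (%d functional, %d structural): keeping the two best-supported entities",
      nF, nS))
    ents <- c(lapply(funGroups, function(g) list(g = g, kind = "fun")),
              lapply(structGroups, function(g) list(g = g, kind = "struct")))
    sup <- vapply(ents, function(e) length(e$g$ids), integer(1L))
    ents <- ents[order(sup, decreasing = TRUE)][1:2]
    haps <- list(mkHap("A", ents[[1L]]$g, ents[[1L]]$kind),
                 mkHap("B", ents[[2L]]$g, ents[[2L]]$kind))
  }
  callDiplotype(haps[[1L]], haps[[2L]], kb,
                sample = if (is.na(rs@sample)) "sample" else rs@sample,
                calls = calls, mask = vc$mask, classCounts = classCounts,
                notes = notes)
}

#' Screen a simulated cohort
#'
#' @param sets named list of [ReadSet-class] objects (one per sample), or a
#'   directory written by [writeCohortFixture()].
#' @param locus a [LocusModel-class].
#' @param kb a [VariantKB-class].
#' @param ... passed to [screenSample()].
#' @return list with `reports` (list of [DiplotypeCall-class]) and `table`
#'   (data.frame: sample, status, genotype_mode).
#' @export
screenCohort <- function(sets, locus, kb = defaultVariantKB(), ...) {
  if (is.character(sets)) {
    files <- list.files(sets, pattern = "\\.fastq$", full.names = TRUE)
    ids <- sub("\\.fastq$", "", basename(files))
    sets <- lapply(stats::setNames(files, ids), function(f)
      readFastqReads(f, sample = sub("\\.fastq$", "", basename(f))))
    # fixture reads are barcoded: strip via demultiplexing against the manifest
    man <- file.path(dirname(files[1L]), "manifest.tsv")
    if (file.exists(man)) {
      m <- utils::read.delim(man, stringsAsFactors = FALSE)
      for (id in ids) {
        bc <- m$barcode[m$id == id]
        dm <- demultiplexReads(sets[[id]], stats::setNames(bc, id))
        sets[[id]] <- dm[[id]]
      }
    }
  }
  reports <- lapply(names(sets), function(id)
    screenSample(sets[[id]], locus, kb, ...))
  names(reports) <- names(sets)
  tab <- data.frame(
    sample = names(sets),
    status = vapply(reports, screenStatus, character(1L)),
    genotype_mode = vapply(reports, function(r) r@genotypeMode, character(1L)),
    stringsAsFactors = FALSE)
  list(reports = reports, table = tab)
}

#' Tally distinct pathogenic variant types across reports
#'
#' Pools the pathogenic (classification `"P"`) content of a list of
#' diplotype reports — coding-style small variants and structural chimera
#' classes alike — and counts, per variant type, the number of samples
#' carrying it.
#'
#' @param reports list of [DiplotypeCall-class].
#' @param kb a [VariantKB-class].
#' @return data.frame: `name`, `cases` (number of samples), sorted by
#'   decreasing case count.
#' @export
pathogenicVariantTally <- function(reports, kb) {
  perCase <- lapply(reports, function(r) {
    nm <- unique(c(.pathoSignature(r@hapA, kb), .pathoSignature(r@hapB, kb)))
    ann <- .kbLookup(kb, nm)
    sub("\\(fused copy\\)$", "", ann$name[ann$classification == "P"])
  })
  all_ <- sort(table(unlist(lapply(perCase, unique))), decreasing = TRUE)
  data.frame(name = names(all_), cases = as.integer(all_),
             stringsAsFactors = FALSE)
}
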