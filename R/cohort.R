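# Packaged cohort specifications and fixture generation.

.specFromList <- function(x, label) {
  haplotypeSpec(label = label,
                variants = unlist(x$variants) %||% character(0),
                structure = x$structure %||% "NORMAL",
                bin = x$bin %||% NA_character_,
                copies = x$copies %||% 1L,
                fusedVariants = unlist(x$fused_variants) %||% character(0))
}

#' Load diplotype specifications from a cohort YAML file
#'
#' @param path YAML file with a top-level `cases` list; each case has an
#'   `id` and `hapA`/`hapB` maps (`variants`, `structure`, `bin`, `copies`,
#'   `fused_variants`).
#' @return list of entries `list(id, hapA, hapB)`.
#' @export
loadCohortSpecs <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y$cases, function(cs)
    list(id = cs$id,
         hapA = .specFromList(cs$hapA %||% list(), "A"),
         hapB = .specFromList(cs$hapB %||% list(), "B")))
}

#' The twelve packaged confirmed-case diplotypes
#'
#' @return list of entries `list(id, hapA, hapB)`.
#' @export
table1Specs <- function() {
  loadCohortSpecs(system.file("extdata", "cohort_table1.yaml",
                              package = "CAHscreen", mustWork = TRUE))
}

#' The packaged 73-sample screening cohort
#'
#' Twelve affected diplotypes, four carriers (one plain heterozygote and
#' three fusion-duplication carriers, each with one pathogenic variant on
#' the non-duplicated haplotype and a fused extra copy whose pathogenic
#' content is neutralised by the retained intact copy), and 57 variant-free
#' samples (a few carrying an uncertain-significance passenger).
#'
#' @return list of entries `list(id, hapA, hapB, truth_status)`.
#' @export
screenCohortSpecs <- function() {
  kb <- defaultVariantKB()
  affected <- table1Specs()
  carriers <- list(
    list(id = "carrier30",
         hapA = haplotypeSpec("A", variants = "c.293-13C>G"),
         hapB = haplotypeSpec("B")),
    list(id = "carrier41",
         hapA = haplotypeSpec("A", variants = "c.518T>A"),
         hapB = haplotypeSpec("B", structure = "DUP_FUSION", bin = "CH-1")),
    list(id = "carrier59",
         hapA = haplotypeSpec("A", variants = "c.293-13C>G"),
         hapB = haplotypeSpec("B", structure = "DUP_FUSION", bin = "CH-8")),
    list(id = "carrier60",
         hapA = haplotypeSpec("A", variants = "c.92C>T"),
         hapB = haplotypeSpec("B", structure = "DUP_FUSION", bin = "CH-1")))
  negatives <- lapply(seq_len(57L), function(i) {
    vA <- if (i %% 19L == 3L) "c.*1316C>T" else character(0)
    vB <- if (i %% 23L == 5L) "c.*1215C>T" else character(0)
    list(id = sprintf("negative%02d", i),
         hapA = haplotypeSpec("A", variants = vA),
         hapB = haplotypeSpec("B", variants = vB))
  })
  out <- c(affected, carriers, negatives)
  for (i in seq_along(out))
    out[[i]]$truth_status <- expectedStatus(out[[i]]$hapA, out[[i]]$hapB, kb)
  out
}

#' Expected screening status of a simulated diplotype
#'
#' Applies the interpreter's allele-counting rule directly to the
#' specification (used as simulation truth): a haplotype is a pathogenic
#' allele iff it carries a P/LP variant or a deletion-class chimera
#' structure, and does not retain an intact P/LP-free functional copy.
#'
#' @param hapA,hapB [HaplotypeSpec-class] objects.
#' @param kb a [VariantKB-class].
#' @return `"AFFECTED"`, `"CARRIER"` or `"NEGATIVE"`.
#' @export
expectedStatus <- function(hapA, hapB, kb) {
  patho <- function(spec) {
    cls <- .kbLookup(kb, spec@variants)$classification
    hasVar <- any(cls %in% c("P", "LP"))
    structural <- spec@structure %in% c("DEL_CHIMERA", "TNX_CHIMERA")
    if (spec@structure == "DUP_FUSION") return(hasVar)  # intact copy retained
    hasVar || structural
  }
  n <- sum(patho(hapA), patho(hapB))
  c("NEGATIVE", "CARRIER", "AFFECTED")[n + 1L]
}

#' Write a simulated cohort fixture to disk
#'
#' One FASTQ per case (truth tags carried in the read headers) plus a
#' `truth.json` manifest with per-case specifications, barcodes and expected
#' statuses. Re-running with the same seed reproduces byte-identical files.
#'
#' @param specs list of entries `list(id, hapA, hapB)` (see [table1Specs()]).
#' @param locus a [LocusModel-class].
#' @param out_dir output directory.
#' @param depth per-haplotype coverage.
#' @param error_model an [ErrorModel-class].
#' @param seed integer master seed; per-case seeds are derived from it.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, a data.frame manifest (`id`, `barcode`, `fastq`,
#'   `n_reads`, `truth_status`).
#' @export
writeCohortFixture <- function(specs, locus, out_dir, depth = 100L,
                               error_model = errorModel(), seed = 1L,
                               overwrite = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("output directory is not empty (use overwrite = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  kb <- defaultVariantKB()
  barcodes <- defaultBarcodes(max(1L, length(specs)))
  rows <- vector("list", length(specs))
  truth <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    cs <- specs[[i]]
    caseSeed <- (as.integer(seed) + 7919L * i) %% 2147483647L
    rs <- simulateReads(cs$hapA, cs$hapB, locus, depth = depth,
                        error_model = error_model, barcode = barcodes[[i]],
                        seed = caseSeed, case_id = cs$id)
    fq <- file.path(out_dir, paste0(cs$id, ".fastq"))
    writeReadSetFastq(rs, fq)
    status <- cs$truth_status %||% expectedStatus(cs$hapA, cs$hapB, kb)
    rows[[i]] <- data.frame(id = cs$id, barcode = unname(barcodes[[i]]),
                            fastq = basename(fq), n_reads = length(rs),
                            truth_status = status, stringsAsFactors = FALSE)
    specDesc <- function(s) list(variants = as.list(s@variants),
                                 structure = s@structure,
                                 bin = s@bin, copies = s@copies,
                                 fused_variants = as.list(s@fusedVariants))
    truth[[i]] <- list(id = cs$id, barcode = unname(barcodes[[i]]),
                       status = status, hapA = specDesc(cs$hapA),
                       hapB = specDesc(cs$hapB))
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
              else data.frame(id = character(0), barcode = character(0),
                              fastq = character(0), n_reads = integer(0),
                              truth_status = character(0))
  jsonlite::write_json(list(seed = as.integer(seed), depth = as.integer(depth),
                            cases = truth),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Write a ReadSet as FASTQ (Phred+33), truth tags in the header comment
#'
#' @param rs a [ReadSet-class].
#' @param path output file.
#' @export
writeReadSetFastq <- function(rs, path) {
  seqs <- rs@sequences
  hasTag <- !is.na(rs@truth)
  nm <- names(seqs)
  nm[hasTag] <- paste0(nm[hasTag], " tag=", rs@truth[hasTag])
  names(seqs) <- nm
  q <- rs@qualities
  names(q) <- nm
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a ReadSet
#'
#' Truth tags written by [writeReadSetFastq()] (`tag=` header comments) are
#' recovered; reads from other sources get `NA` tags.
#'
#' @param path FASTQ file.
#' @param sample optional sample label.
#' @return a [ReadSet-class].
#' @export
readFastqReads <- function(path, sample = NA_character_) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("failed to read FASTQ '", path, "': ",
                             conditionMessage(e)))
  hdr <- names(seqs)
  truth <- ifelse(grepl(" tag=", hdr, fixed = TRUE),
                  sub("^.* tag=", "", hdr), NA_character_)
  ids <- sub(" .*$", "", hdr)
  q <- S4Vectors::mcols(seqs)$qualities
  qs <- Biostrings::BStringSet(as.character(q))
  names(seqs) <- ids
  names(qs) <- ids
  new("ReadSet", sequences = seqs, qualities = qs, truth = truth,
      sample = sample)
}
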