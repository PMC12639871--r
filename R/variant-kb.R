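# Pathogenic-variant knowledge base: curated classification lookup.

.PHENOTYPES <- c("SW", "SV", "NC")

#' Load a variant knowledge base
#'
#' Reads a tab- or comma-separated table with columns `name`,
#' `classification` (P / LP / VUS), `phenotype` (SW / SV / NC; anything else
#' maps to `"unknown"`) and optionally `allele_tally`. Structural alleles are
#' keyed by chimera class label (e.g. `"CYP21A1P/CYP21A2_CH-1"`).
#'
#' @param path table file.
#' @return a [VariantKB-class].
#' @export
loadVariantKB <- function(path) {
  if (!file.exists(path)) stop("knowledge-base file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#", blank.lines.skip = TRUE)
  if (nrow(df) == 0L && ncol(df) == 0L)
    df <- data.frame(name = character(0), classification = character(0),
                     phenotype = character(0))
  need <- c("name", "classification", "phenotype")
  if (!all(need %in% colnames(df)))
    stop("knowledge base needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("duplicate variant names in knowledge base: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  if (nrow(df) && any(is.na(df$classification) | df$classification == ""))
    stop("missing classification for: ",
         paste(df$name[is.na(df$classification) | df$classification == ""],
               collapse = ", "))
  df$phenotype <- ifelse(df$phenotype %in% .PHENOTYPES, df$phenotype, "unknown")
  if (!"allele_tally" %in% colnames(df))
    df$allele_tally <- rep(NA_integer_, nrow(df))
  df <- df[, c("name", "classification", "phenotype", "allele_tally")]
  new("VariantKB", entries = df)
}

#' The packaged knowledge base
#'
#' Eleven pathogenic entries (eight SNVs/indels, three 30-kb-deletion chimera
#' classes) plus the likely-pathogenic and uncertain-significance entries
#' observed alongside them, with the cohort allele tallies.
#'
#' @return a [VariantKB-class].
#' @export
defaultVariantKB <- function() {
  loadVariantKB(system.file("extdata", "variant_kb.tsv",
                            package = "CAHscreen", mustWork = TRUE))
}

# classification lookup with "unknown" fallback
.kbLookup <- function(kb, names) {
  e <- kb@entries
  i <- match(names, e$name)
  data.frame(name = names,
             classification = ifelse(is.na(i), "unknown", e$classification[i]),
             phenotype = ifelse(is.na(i), "unknown", e$phenotype[i]),
             stringsAsFactors = FALSE)
}
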