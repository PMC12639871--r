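# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

test_locus <- function() {
  if (is.null(.fx$locus)) .fx$locus <- buildToyLocus()
  .fx$locus
}

test_kb <- function() {
  if (is.null(.fx$kb)) .fx$kb <- defaultVariantKB()
  .fx$kb
}

# run the 12 packaged confirmed-case diplotypes through the full pipeline
run_table1 <- function(depth, error_model = errorModel(), seed = 20260923L,
                       locus = test_locus(), kb = test_kb()) {
  specs <- table1Specs()
  reports <- vector("list", length(specs))
  names(reports) <- vapply(specs, `[[`, character(1L), "id")
  for (i in seq_along(specs)) {
    cs <- specs[[i]]
    rs <- simulateReads(cs$hapA, cs$hapB, locus, depth = depth,
                        error_model = error_model,
                        seed = (seed + 101L * i) %% 2147483647L,
                        case_id = cs$id)
    reports[[i]] <- screenSample(rs, locus, kb)
  }
  reports
}

# haplotype signature used for exact-genotype comparisons (label-swap safe)
hap_sig <- function(structure, bin, variants) {
  paste(structure, ifelse(is.na(bin), "-", bin),
        paste(sort(variants), collapse = ","), sep = "|")
}

spec_sigs <- function(cs) {
  sig1 <- function(h) hap_sig(h@structure, h@bin, h@variants)
  sort(c(sig1(cs$hapA), sig1(cs$hapB)))
}

call_sigs <- function(dp) {
  sig1 <- function(h) hap_sig(h@structure, h@bin, h@variants)
  sort(c(sig1(dp@hapA), sig1(dp@hapB)))
}

# brute-force changepoint oracle: minimise (#G before cut) + (#P after cut)
# over informative states, leftmost minimal cut
brute_junction <- function(states) {
  inf <- which(states != "M")
  k <- length(inf)
  s <- states[inf]
  best <- Inf; bestc <- NA_integer_
  for (c_ in 0:k) {
    cost <- sum(s[seq_len(c_)] == "G") +
      sum(s[setdiff(seq_len(k), seq_len(c_))] == "P")
    if (cost < best) { best <- cost; bestc <- c_ }
  }
  list(cut = bestc, cost = best,
       left = if (bestc %in% c(0L, k)) NA_integer_ else inf[bestc],
       right = if (bestc %in% c(0L, k)) NA_integer_ else inf[bestc + 1L])
}

# exhaustive two-group phasing oracle for tiny instances: minimise the total
# Hamming distance of reads to their group consensus
brute_phase <- function(alleles) {
  ids <- sort(names(alleles))
  m <- do.call(rbind, alleles[ids])
  n <- nrow(m)
  cons <- function(rows) apply(m[rows, , drop = FALSE], 2L, function(col) {
    t_ <- sort(table(col), decreasing = TRUE)
    sort(names(t_)[t_ == max(t_)])[1L]
  })
  costOf <- function(assign_) {
    tot <- 0L
    for (g in unique(assign_)) {
      rows <- which(assign_ == g)
      cc <- cons(rows)
      tot <- tot + sum(m[rows, , drop = FALSE] !=
                         matrix(cc, nrow = length(rows), ncol = ncol(m), byrow = TRUE))
    }
    tot
  }
  best <- Inf; bestA <- NULL
  for (mask in 0:(2^(n - 1L) - 1L)) {  # fix read 1 in group 1: swap symmetry
    assign_ <- c(1L, as.integer(intToBits(mask))[seq_len(n - 1L)] + 1L)
    cost <- costOf(assign_)
    if (cost < best) { best <- cost; bestA <- assign_ }
  }
  groups <- split(ids, bestA)
  list(groups = lapply(unname(groups), sort), cost = best)
}
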