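# Cohort screening arithmetic and Jeffreys-prior Bayesian posteriors.

#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `dp` decimals (the
#' convention used by every printed screening rate).
#'
#' @param numerator,denominator integers; `denominator` must be positive.
#' @param dp decimal places (default 2).
#' @return numeric percentage.
#' @examples
#' ratePercent(1985, 235999)  # 0.84
#' @export
ratePercent <- function(numerator, denominator, dp = 2L) {
  if (denominator <= 0) stop("denominator must be > 0")
  roundHalfUp(100 * numerator / denominator, dp)
}

#' Incidence as a "1:N" ratio
#'
#' @param cases number of cases (>= 1).
#' @param population population size.
#' @return list with `ratio` (string `"1:N"`) and `n` (integer `N`, rounded
#'   half-up).
#' @examples
#' incidenceRatio(12, 235999)$ratio  # "1:19667"
#' @export
incidenceRatio <- function(cases, population) {
  if (cases < 1) stop("incidence undefined for zero cases")
  n <- as.integer(roundHalfUp(population / cases))
  list(ratio = sprintf("1:%d", n), n = n)
}

#' Jeffreys-prior binomial posterior
#'
#' With prior `Beta(0.5, 0.5)` and `x` successes in `n` trials the posterior
#' is `Beta(x + 0.5, n - x + 0.5)`; the equal-tailed credible interval is
#' obtained by inverting the regularised incomplete beta function
#' ([stats::qbeta]) at the tail probabilities.
#'
#' @param x successes (0 <= x <= n).
#' @param n trials.
#' @param level interval mass (default 0.95).
#' @return a [PosteriorSummary-class].
#' @examples
#' jeffreysPosterior(12, 12)  # Beta(12.5, 0.5), mean 0.9615
#' @export
jeffreysPosterior <- function(x, n, level = 0.95) {
  if (x < 0 || n < 0 || x > n) stop("need 0 <= x <= n")
  a <- x + 0.5; b <- n - x + 0.5
  lo <- (1 - level) / 2
  new("PosteriorSummary", alpha = a, beta = b, mean = a / (a + b),
      criLow = stats::qbeta(lo, a, b), criHigh = stats::qbeta(1 - lo, a, b),
      level = level)
}

#' Confusion-matrix screening metrics
#'
#' Sensitivity posterior from `(tp, tp + fn)`, specificity posterior from
#' `(tn, tn + fp)`, and the raw false-positive rate `fp / (fp + tn)`. An
#' empty margin drops the corresponding posterior with a warning.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @param level credible-interval mass.
#' @return list: `sensitivity_posterior`, `specificity_posterior`
#'   ([PosteriorSummary-class] or `NULL`), `fpr`.
#' @export
confusionMetrics <- function(tp, fp, tn, fn, level = 0.95) {
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be non-negative")
  sens <- if (tp + fn >= 1) jeffreysPosterior(tp, tp + fn, level)
          else { warning("empty positive margin: sensitivity posterior omitted"); NULL }
  spec <- if (tn + fp >= 1) jeffreysPosterior(tn, tn + fp, level)
          else { warning("empty negative margin: specificity posterior omitted"); NULL }
  fpr <- if (fp + tn >= 1) fp / (fp + tn) else NA_real_
  list(sensitivity_posterior = sens, specificity_posterior = spec, fpr = fpr)
}

#' Load cohort counts from TSV or JSON
#'
#' @param path two-column `field`/`value` TSV or a JSON object.
#' @return named list of counts.
#' @export
loadCohortCounts <- function(path) {
  if (grepl("\\.json$", path)) {
    counts <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("field", "value") %in% colnames(df)))
      stop("counts table needs 'field' and 'value' columns")
    counts <- as.list(stats::setNames(df$value, df$field))
  }
  need <- c("screened", "males", "females", "initial_positive",
            "recalled_tested", "recall_positive", "confirmed",
            "confirmed_males", "confirmed_females")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing count fields: ", paste(miss, collapse = ", "))
  with(counts, {
    if (!(confirmed <= recall_positive && recall_positive <= recalled_tested &&
          recalled_tested <= initial_positive && initial_positive <= screened))
      stop("count invariant violated: confirmed <= recall_positive <= recalled_tested <= initial_positive <= screened")
    if (males + females != screened)
      stop("males + females must equal screened")
  })
  counts
}

#' Cohort screening metrics
#'
#' Reproduces the screening arithmetic from the cohort counts: initial
#' positivity rate, recall rate, recall positivity, PPV of initial and
#' recall screening, and overall/sex-specific incidence ratios.
#'
#' @param counts named list from [loadCohortCounts()].
#' @return named list of metrics (percentages half-up to 2 dp; incidence
#'   ratios as `"1:N"`).
#' @examples
#' counts <- loadCohortCounts(system.file("extdata", "cohort_counts.tsv",
#'                                        package = "CAHscreen"))
#' cohortStats(counts)$positivity_initial  # 0.84
#' @export
cohortStats <- function(counts) {
  with(counts, list(
    positivity_initial = ratePercent(initial_positive, screened),
    recall_rate = ratePercent(recalled_tested, initial_positive),
    positivity_recall = ratePercent(recall_positive, recalled_tested),
    ppv_initial = ratePercent(confirmed, initial_positive),
    ppv_recall = ratePercent(confirmed, recall_positive),
    incidence = incidenceRatio(confirmed, screened),
    incidence_males = incidenceRatio(confirmed_males, males),
    incidence_females = incidenceRatio(confirmed_females, females)))
}
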