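#' Welch two-sample t-test (two-tailed, unequal variance)
#'
#' Thin, defensively wrapped front end to \code{stats::t.test} with
#' Welch-Satterthwaite degrees of freedom. Degenerate inputs where both
#' groups have zero variance are resolved by convention: equal means give
#' t = 0, p = 1; different means give the p -> 0 limit with an infinite
#' statistic.
#'
#' @param x,y numeric vectors (length >= 2 each); NAs dropped.
#' @return list: t_statistic, df, p_value, n_a, n_b, mean_a, mean_b,
#'   test_kind = "welch_two_tailed", degenerate flag.
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("welch_t_test requires at least 2 non-missing values per group")
  base <- list(n_a = length(x), n_b = length(y),
               mean_a = mean(x), mean_b = mean(y),
               test_kind = "welch_two_tailed")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(c(list(t_statistic = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                  df = NA_real_, p_value = if (eq) 1 else 0,
                  degenerate = TRUE), base))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  c(list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, degenerate = FALSE), base)
}

#' Paired t-test (two-tailed)
#'
#' One-sample t-test of the within-pair differences against zero. Pairs
#' with a missing member are dropped first. All-zero differences give
#' t = 0, p = 1; constant nonzero differences give the p -> 0 limit.
#'
#' @param a,b numeric vectors of equal length (pair members).
#' @return list: t_statistic, df, p_value, n_pairs, mean_a, mean_b,
#'   test_kind = "paired_two_tailed", degenerate flag.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L)
    stop("paired_t_test requires at least 2 complete pairs")
  d <- a - b
  base <- list(n_pairs = length(a), mean_a = mean(a), mean_b = mean(b),
               test_kind = "paired_two_tailed")
  if (stats::sd(d) == 0) {
    zero <- isTRUE(all.equal(mean(d), 0))
    return(c(list(t_statistic = if (zero) 0 else sign(mean(d)) * Inf,
                  df = length(a) - 1, p_value = if (zero) 1 else 0,
                  degenerate = TRUE), base))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  c(list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, degenerate = FALSE), base)
}

#' Bonferroni-adjusted significance level
#'
#' @param family_alpha family-wise significance level (default 0.05).
#' @param m_tests number of tests in the family (>= 1).
#' @return list of class \code{family_correction}: family_alpha, m_tests,
#'   adjusted_alpha = family_alpha / m_tests (exact).
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m_tests) {
  if (length(m_tests) != 1L || is.na(m_tests) || m_tests < 1L)
    stop("m_tests must be a positive integer")
  if (!(family_alpha > 0 && family_alpha <= 1))
    stop("family_alpha must be in (0, 1]")
  structure(list(family_alpha = family_alpha,
                 m_tests = as.integer(m_tests),
                 adjusted_alpha = family_alpha / m_tests),
            class = "family_correction")
}

#' Per-group mean and median fractions
#'
#' Computes each group's sample count, mean and median over non-missing
#' fractions, sorted by descending median then group name. Groups with no
#' non-missing values are omitted (listed in the \code{omitted} attribute).
#'
#' @param fractions data.frame from \code{\link{fractions_table}}.
#' @param annotations annotation data.frame sharing \code{sample_id}.
#' @param grouping annotation column to group by (default "stratum").
#' @param value fraction column to summarize (default "cterm_fraction").
#' @return data.frame: group, n, mean_fraction, median_fraction.
#' @export
group_summaries <- function(fractions, annotations, grouping = "stratum",
                            value = "cterm_fraction") {
  if (!grouping %in% names(annotations))
    stop("grouping column not found in annotations: ", grouping)
  merged <- merge(fractions[, c("sample_id", value)],
                  annotations[, c("sample_id", grouping)], by = "sample_id")
  omitted <- character(0)
  rows <- NULL
  for (g in unique(merged[[grouping]])) {
    v <- merged[[value]][merged[[grouping]] == g]
    v <- v[!is.na(v)]
    if (length(v) == 0L) { omitted <- c(omitted, g); next }
    rows <- rbind(rows, data.frame(group = g, n = length(v),
                                   mean_fraction = mean(v),
                                   median_fraction = stats::median(v),
                                   stringsAsFactors = FALSE))
  }
  if (is.null(rows))
    rows <- data.frame(group = character(0), n = integer(0),
                       mean_fraction = numeric(0), median_fraction = numeric(0))
  rows <- rows[order(-rows$median_fraction, rows$group), ]
  rownames(rows) <- NULL
  attr(rows, "omitted") <- omitted
  rows
}

#' Run the full per-stratum comparison suite
#'
#' One Welch test per stratum per contrast: wild type vs missense, wild type
#' vs all truncating mutations combined, and (optionally) wild type vs each
#' truncating class (nonsense, splice site, frameshift) separately. Stratum
#' eligibility is decided by \code{\link{build_cohorts}} on the combined
#' groups; per-class tests within eligible strata run whenever the class has
#' at least 2 samples with non-missing fractions. The Bonferroni family size
#' is the number of tests actually executed unless \code{fixed_m} overrides
#' it; each result is flagged significant when p <= adjusted alpha
#' (boundary inclusive).
#'
#' @param fractions data.frame from \code{\link{fractions_table}}.
#' @param classified annotation data.frame with \code{group} column.
#' @param value fraction column to compare.
#' @param contrasts subset of \code{c("missense", "truncating",
#'   "truncating_by_class")}.
#' @param min_group_size minimum group size per stratum.
#' @param family_alpha family-wise alpha.
#' @param fixed_m optional fixed Bonferroni family size.
#' @return list: \code{results} data.frame (stratum, contrast, group_a,
#'   group_b, n_a, n_b, mean_a, mean_b, t_statistic, p_value, significant),
#'   \code{correction} (a \code{family_correction}, NULL when no test ran).
#' @export
run_comparison_suite <- function(fractions, classified,
                                 value = "cterm_fraction",
                                 contrasts = c("missense", "truncating",
                                               "truncating_by_class"),
                                 min_group_size = 5L,
                                 family_alpha = 0.05,
                                 fixed_m = NULL) {
  contrasts <- match.arg(contrasts, several.ok = TRUE)
  merged <- merge(fractions[, c("sample_id", value)],
                  classified, by = "sample_id")
  merged <- merged[!is.na(merged$group) & !is.na(merged[[value]]), ]
  cohorts <- build_cohorts(merged, min_group_size = min_group_size)
  rows <- NULL
  run_one <- function(stratum, label, x, y) {
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    w <- welch_t_test(x, y)
    data.frame(stratum = stratum, contrast = label, group_a = "WT",
               group_b = label, n_a = w$n_a, n_b = w$n_b,
               mean_a = w$mean_a, mean_b = w$mean_b,
               t_statistic = w$t_statistic, p_value = w$p_value,
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(cohorts))) {
    s <- cohorts$stratum[k]; gb <- cohorts$group_b[k]
    d <- merged[merged$stratum == s, ]
    wt <- d[[value]][d$group == "WT"]
    if (gb == "missense" && "missense" %in% contrasts)
      rows <- rbind(rows, run_one(s, "missense", wt,
                                  d[[value]][d$group == "missense"]))
    if (gb == "truncating") {
      if ("truncating" %in% contrasts)
        rows <- rbind(rows, run_one(s, "truncating", wt,
                                    d[[value]][d$group == "truncating"]))
      if ("truncating_by_class" %in% contrasts) {
        for (cl in TRUNCATING_CLASSES) {
          in_cl <- d$group == "truncating" &
            vapply(d$mutation_class, function(m) cl %in% split_classes(m),
                   logical(1))
          rows <- rbind(rows, run_one(s, cl, wt, d[[value]][in_cl]))
        }
      }
    }
  }
  if (is.null(rows)) {
    empty <- data.frame(stratum = character(0), contrast = character(0),
                        group_a = character(0), group_b = character(0),
                        n_a = integer(0), n_b = integer(0),
                        mean_a = numeric(0), mean_b = numeric(0),
                        t_statistic = numeric(0), p_value = numeric(0),
                        significant = logical(0))
    return(list(results = empty, correction = NULL))
  }
  m <- if (is.null(fixed_m)) nrow(rows) else fixed_m
  corr <- bonferroni_alpha(family_alpha, m)
  rows$significant <- rows$p_value <= corr$adjusted_alpha
  rownames(rows) <- NULL
  list(results = rows, correction = corr)
}

#' Paired tumor vs adjacent-normal comparison
#'
#' @param fractions data.frame from \code{\link{fractions_table}}.
#' @param pairs data.frame from \code{\link{build_pairs}}.
#' @param value fraction column to compare.
#' @return \code{\link{paired_t_test}} result on the tumor/normal fraction
#'   pairs (pairs with a missing fraction dropped).
#' @export
paired_comparison <- function(fractions, pairs, value = "cterm_fraction") {
  fr <- stats::setNames(fractions[[value]], fractions$sample_id)
  paired_t_test(unname(fr[pairs$tumor_id]), unname(fr[pairs$normal_id]))
}

#' Bundled per-tissue GTEx summary table
#'
#' The packaged copy of the published per-tissue summary of C-terminal
#' alternative-isoform exonic fractions across 53 GTEx tissue types
#' (median, mean and sample count per tissue).
#'
#' @return data.frame: tissue, median_fraction, mean_fraction, n.
#' @export
gtex_table1 <- function() {
  path <- system.file("extdata", "gtex_table1.tsv",
                      package = "tp53junctions", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Cross-tissue summaries of the bundled GTEx table
#'
#' @param tab data.frame as returned by \code{\link{gtex_table1}}.
#' @return list: n_tissues, mean_of_means_percent (unweighted mean of the
#'   per-tissue mean fractions, in percent), max_median_percent (largest
#'   per-tissue median, in percent).
#' @export
gtex_summary <- function(tab = gtex_table1()) {
  list(n_tissues = nrow(tab),
       mean_of_means_percent = 100 * mean(tab$mean_fraction),
       max_median_percent = 100 * max(tab$median_fraction))
}
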