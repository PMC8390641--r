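#' Exonic fraction of a distinct junction set
#'
#' Core per-sample statistic: mean distinct-junction read count divided by
#' (main-competitor count + mean distinct count). Returns NA when the
#' denominator is zero (no informative reads); zero-denominator samples are
#' excluded from downstream statistics rather than scored 0, which would
#' bias low-coverage samples downward.
#'
#' @param distinct_counts numeric vector of distinct-junction read counts
#'   (averaged when more than one, as for the two C-terminal junctions).
#' @param main_count read count of the competing main-isoform junction.
#' @return proportion in [0, 1], or NA.
#' @export
exonic_fraction <- function(distinct_counts, main_count) {
  d_bar <- mean(distinct_counts)
  denom <- main_count + d_bar
  if (denom <= 0) return(NA_real_)
  d_bar / denom
}

get_count <- function(counts, label) {
  if (is.na(label) || !label %in% names(counts$counts))
    stop("junction label not present in counts: ", label)
  unname(counts$counts[[label]])
}

#' C-terminal alternative-isoform exonic fraction for one sample
#'
#' The two junction counts specific to the p53beta-family C-terminal splice
#' are averaged (arithmetic mean, kept real-valued) before entering the
#' ratio against the competing main-isoform junction.
#'
#' @param counts a \code{junction_counts}.
#' @param catalog a \code{junction_catalog} with a 2-member C-terminal pair.
#' @return list: sample_id, D1, D2, D_bar, M_cterm, cterm_fraction (NA when
#'   all three counts are zero).
#' @export
cterm_fraction <- function(counts, catalog) {
  stopifnot(inherits(counts, "junction_counts"),
            inherits(catalog, "junction_catalog"))
  if (length(catalog$cterm_pair) != 2L)
    stop("catalog does not define a 2-member C-terminal junction pair")
  d1 <- get_count(counts, catalog$cterm_pair[1])
  d2 <- get_count(counts, catalog$cterm_pair[2])
  m <- get_count(counts, catalog$cterm_main)
  list(sample_id = counts$sample_id, D1 = d1, D2 = d2,
       D_bar = (d1 + d2) / 2, M_cterm = m,
       cterm_fraction = exonic_fraction(c(d1, d2), m))
}

#' NM_001126112.2 (5'UTR alternate acceptor) exonic fraction for one sample
#'
#' @param counts a \code{junction_counts}.
#' @param catalog a \code{junction_catalog} defining the 5'UTR junction and
#'   its main competitor.
#' @return list: sample_id, D_utr5, M_utr5, utr5_fraction (NA when both
#'   counts are zero).
#' @export
utr5_fraction <- function(counts, catalog) {
  stopifnot(inherits(counts, "junction_counts"),
            inherits(catalog, "junction_catalog"))
  if (is.na(catalog$utr5_distinct) || is.na(catalog$utr5_main))
    stop("catalog does not define the 5'UTR junction and its competitor")
  d <- get_count(counts, catalog$utr5_distinct)
  m <- get_count(counts, catalog$utr5_main)
  list(sample_id = counts$sample_id, D_utr5 = d, M_utr5 = m,
       utr5_fraction = exonic_fraction(d, m))
}

#' Per-sample table of exonic fractions
#'
#' @param counts_list list of \code{junction_counts} with unique sample ids.
#' @param catalog a \code{junction_catalog}.
#' @return data.frame with one row per sample: sample_id, D1, D2, D_bar,
#'   M_cterm, cterm_fraction, D_utr5, M_utr5, utr5_fraction. Missing
#'   fractions are NA (serialized as empty fields, never 0).
#' @export
fractions_table <- function(counts_list, catalog) {
  if (inherits(counts_list, "junction_counts")) counts_list <- list(counts_list)
  ids <- vapply(counts_list, function(x) x$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(counts_list, function(jc) {
    ct <- cterm_fraction(jc, catalog)
    u5 <- utr5_fraction(jc, catalog)
    data.frame(sample_id = jc$sample_id,
               D1 = ct$D1, D2 = ct$D2, D_bar = ct$D_bar, M_cterm = ct$M_cterm,
               cterm_fraction = ct$cterm_fraction,
               D_utr5 = u5$D_utr5, M_utr5 = u5$M_utr5,
               utr5_fraction = u5$utr5_fraction,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), D1 = integer(0), D2 = integer(0),
               D_bar = numeric(0), M_cterm = integer(0),
               cterm_fraction = numeric(0), D_utr5 = integer(0),
               M_utr5 = integer(0), utr5_fraction = numeric(0))
  rownames(out) <- NULL
  out
}

#' Write a fractions table as TSV (missing fractions as empty fields)
#'
#' @param tab data.frame from \code{\link{fractions_table}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_fractions_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a fractions table from TSV
#'
#' @param path TSV written by \code{\link{write_fractions_table}}.
#' @return data.frame; empty fields become NA.
#' @export
read_fractions_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}
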