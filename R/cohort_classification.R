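#' Thresholds of the wild-type TP53 definition
#'
#' A tumor with no TP53 mutation calls is considered TP53 wild type only
#' when it also shows log2(CN-ratio) above \code{min_log2_cn_ratio} and
#' normalized RSEM expression above \code{min_expression}. Both inequalities
#' are strict: a sample sitting exactly on a threshold is excluded. The
#' gating applies to the wild-type definition only; mutant groups are
#' defined by mutation class alone.
#'
#' @param min_log2_cn_ratio exclusive lower bound on log2(CN-ratio); a
#'   CN-ratio of 1 corresponds to a diploid locus.
#' @param min_expression exclusive lower bound on RSEM-normalized mRNA
#'   expression.
#' @return list of class \code{classification_thresholds}.
#' @export
classification_thresholds <- function(min_log2_cn_ratio = -0.9,
                                      min_expression = 300) {
  structure(list(min_log2_cn_ratio = min_log2_cn_ratio,
                 min_expression = min_expression),
            class = "classification_thresholds")
}

MUTATION_CLASSES <- c("missense", "nonsense", "frameshift", "splice_site")
TRUNCATING_CLASSES <- c("nonsense", "frameshift", "splice_site")

#' Classify one sample's TP53 status
#'
#' Pure function of one sample's annotation: any truncating call (nonsense,
#' frameshift, splice site) puts the sample in the truncating group, taking
#' precedence over coexisting missense calls (flagged
#' \code{mixed_classes_policy}); missense-only samples are missense; samples
#' without mutation calls are wild type when both thresholds are strictly
#' passed, otherwise excluded with a reason (\code{missing_data},
#' \code{low_cn}, \code{low_expression}).
#'
#' @param mutation_classes character vector of call classes (may be empty).
#' @param log2_cn_ratio numeric or NA.
#' @param expression_rsem non-negative numeric or NA.
#' @param thresholds a \code{\link{classification_thresholds}}.
#' @return list: group in {WT, missense, truncating, excluded} and
#'   \code{note} (exclusion reason or mixed-class flag, else NA).
#' @export
classify_tp53_status <- function(mutation_classes, log2_cn_ratio,
                                 expression_rsem,
                                 thresholds = classification_thresholds()) {
  mutation_classes <- mutation_classes[!is.na(mutation_classes) &
                                       nzchar(mutation_classes)]
  bad <- setdiff(mutation_classes, MUTATION_CLASSES)
  if (length(bad))
    stop("unknown mutation class: ", paste(bad, collapse = ", "))
  if (any(mutation_classes %in% TRUNCATING_CLASSES)) {
    mixed <- any(mutation_classes == "missense")
    return(list(group = "truncating",
                note = if (mixed) "mixed_classes_policy" else NA_character_))
  }
  if (any(mutation_classes == "missense"))
    return(list(group = "missense", note = NA_character_))
  if (is.na(log2_cn_ratio) || is.na(expression_rsem))
    return(list(group = "excluded", note = "missing_data"))
  if (!(log2_cn_ratio > thresholds$min_log2_cn_ratio))
    return(list(group = "excluded", note = "low_cn"))
  if (!(expression_rsem > thresholds$min_expression))
    return(list(group = "excluded", note = "low_expression"))
  list(group = "WT", note = NA_character_)
}

#' Read a sample annotation TSV
#'
#' Expected columns: sample_id, cohort (tumor/normal/cell_line), stratum,
#' mutation_class (semicolon-separated list, empty for none), log2_cn_ratio,
#' expression_rsem, pair_id (optional).
#'
#' @param path annotation TSV path.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("sample_id", "cohort", "stratum", "mutation_class",
            "log2_cn_ratio", "expression_rsem")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("annotation TSV missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"pair_id" %in% names(tab)) tab$pair_id <- NA_character_
  tab
}

split_classes <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Classify all samples in an annotation table
#'
#' Tumor and cell-line samples get a TP53 status group; normal-tissue
#' samples are never status-classified (group NA) and enter only paired
#' analyses.
#'
#' @param annotations data.frame as from \code{\link{read_annotations}}.
#' @param thresholds a \code{\link{classification_thresholds}}.
#' @return the annotation data.frame with \code{group} and \code{status_note}
#'   columns appended.
#' @export
classify_samples <- function(annotations,
                             thresholds = classification_thresholds()) {
  n <- nrow(annotations)
  group <- rep(NA_character_, n)
  note <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (identical(annotations$cohort[i], "normal")) next
    st <- classify_tp53_status(split_classes(annotations$mutation_class[i]),
                               annotations$log2_cn_ratio[i],
                               annotations$expression_rsem[i],
                               thresholds)
    group[i] <- st$group
    note[i] <- st$note
  }
  annotations$group <- group
  annotations$status_note <- note
  annotations
}

#' Build per-stratum comparison cohorts
#'
#' For each stratum, emits the wild-type vs missense and wild-type vs
#' truncating contrasts only when both groups reach \code{min_group_size};
#' smaller strata are listed in the \code{skipped} attribute.
#'
#' @param classified annotation data.frame with a \code{group} column (see
#'   \code{\link{classify_samples}}).
#' @param min_group_size minimum samples per group for a contrast to be run.
#' @return data.frame of cohorts: stratum, group_a ("WT"), group_b, n_a, n_b;
#'   attribute \code{skipped} lists contrasts not emitted.
#' @export
build_cohorts <- function(classified, min_group_size = 5L) {
  tumors <- classified[!is.na(classified$group), ]
  out <- NULL
  skipped <- NULL
  for (s in unique(tumors$stratum)) {
    d <- tumors[tumors$stratum == s, ]
    n_wt <- sum(d$group == "WT")
    for (g in c("missense", "truncating")) {
      n_g <- sum(d$group == g)
      row <- data.frame(stratum = s, group_a = "WT", group_b = g,
                        n_a = n_wt, n_b = n_g, stringsAsFactors = FALSE)
      if (n_wt >= min_group_size && n_g >= min_group_size) out <- rbind(out, row)
      else skipped <- rbind(skipped, row)
    }
  }
  if (is.null(out))
    out <- data.frame(stratum = character(0), group_a = character(0),
                      group_b = character(0), n_a = integer(0), n_b = integer(0))
  attr(out, "skipped") <- skipped
  out
}

#' Build tumor-normal pairs
#'
#' Matches tumor and adjacent-normal samples on \code{pair_id}. Unpaired
#' samples are dropped (and reported via the \code{dropped} attribute); a
#' pair_id mapping to two tumors or two normals is an error. When
#' \code{status_filter} is given, only pairs whose tumor member carries that
#' status group are kept.
#'
#' @param classified annotation data.frame with \code{group} (tumors) and
#'   \code{pair_id} columns.
#' @param status_filter optional TP53 group the tumor member must have
#'   (e.g. "WT" or "truncating").
#' @return data.frame: pair_id, tumor_id, normal_id.
#' @export
build_pairs <- function(classified, status_filter = NULL) {
  d <- classified[!is.na(classified$pair_id), ]
  out <- NULL
  dropped <- character(0)
  for (p in unique(d$pair_id)) {
    m <- d[d$pair_id == p, ]
    tum <- m[m$cohort == "tumor", ]
    nor <- m[m$cohort == "normal", ]
    if (nrow(tum) > 1L || nrow(nor) > 1L)
      stop("pair_id ", p, " maps to ", nrow(tum), " tumors and ",
           nrow(nor), " normals")
    if (nrow(tum) == 0L || nrow(nor) == 0L) {
      dropped <- c(dropped, p)
      next
    }
    if (!is.null(status_filter) && !identical(tum$group, status_filter)) next
    out <- rbind(out, data.frame(pair_id = p, tumor_id = tum$sample_id,
                                 normal_id = nor$sample_id,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(pair_id = character(0), tumor_id = character(0),
                      normal_id = character(0))
  attr(out, "dropped") <- dropped
  out
}
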