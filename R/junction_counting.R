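#' Parameters of the junction-read rule
#'
#' Defaults encode the strict rule used throughout: at least 10 aligned
#' nucleotides on each side of the breakpoint, at most half of the read
#' sequence soft-clipped (boundary inclusive), zero mismatches and no
#' insertions or deletions. Duplicate-flagged reads are counted by default
#' (alignments are taken as provided); secondary alignments are not.
#'
#' @param min_flank minimum aligned bases required in the block on each side
#'   of the splice breakpoint.
#' @param max_softclip_fraction maximum soft-clipped fraction of the read
#'   sequence length (hard-clipped bases are absent from the sequence and do
#'   not enter the denominator).
#' @param require_zero_mismatches reject reads with nonzero edit distance or
#'   any insertion/deletion.
#' @param count_duplicates include duplicate-flagged reads.
#' @param count_secondary include secondary alignments.
#' @param nm_mode what to do when the NM (edit distance) tag is absent and
#'   \code{require_zero_mismatches} is on: \code{"strict"} rejects the read;
#'   \code{"permissive"} falls back to the MD tag when present, else rejects.
#' @return list of class \code{counting_params}.
#' @export
counting_params <- function(min_flank = 10L,
                            max_softclip_fraction = 0.5,
                            require_zero_mismatches = TRUE,
                            count_duplicates = TRUE,
                            count_secondary = FALSE,
                            nm_mode = c("strict", "permissive")) {
  nm_mode <- match.arg(nm_mode)
  stopifnot(min_flank >= 1L,
            max_softclip_fraction >= 0, max_softclip_fraction <= 1)
  structure(list(min_flank = as.integer(min_flank),
                 max_softclip_fraction = max_softclip_fraction,
                 require_zero_mismatches = isTRUE(require_zero_mismatches),
                 count_duplicates = isTRUE(count_duplicates),
                 count_secondary = isTRUE(count_secondary),
                 nm_mode = nm_mode),
            class = "counting_params")
}

#' Decompose an alignment into genomic blocks
#'
#' Splits the CIGAR into maximal runs of reference-aligned bases separated by
#' skipped regions (N operators). Each block records its genomic span and the
#' number of aligned read bases it contains (M/=/X; deletions extend the span
#' but contribute no aligned bases). Insertions and deletions are returned as
#' indel evidence; soft-clipped bases are totalled separately.
#'
#' @param cigar CIGAR string of a mapped record.
#' @param pos 1-based leftmost mapped position.
#' @return list with \code{blocks} (data.frame start, end, aligned),
#'   \code{softclip_total}, \code{has_indel}, \code{seq_len} (read sequence
#'   length implied by the CIGAR, soft clips included).
#' @export
read_blocks <- function(cigar, pos) {
  if (is.na(cigar) || cigar == "*") stop("record has no CIGAR")
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  bl <- blocks_from_ops(ops, lens, pos)
  list(blocks = data.frame(start = bl$starts, end = bl$ends,
                           aligned = bl$aligned),
       softclip_total = bl$softclip_total, has_indel = bl$has_indel,
       seq_len = bl$seq_len)
}

blocks_from_ops <- function(ops, lens, pos) {
  cur <- pos
  bstart <- cur
  aligned <- 0L
  span <- 0L
  softclip <- 0L
  has_indel <- FALSE
  seq_len <- 0L
  starts <- integer(0); ends <- integer(0); al <- integer(0)
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      aligned <- aligned + len; span <- span + len; seq_len <- seq_len + len
    } else if (op == "D") {
      span <- span + len; has_indel <- TRUE
    } else if (op == "I") {
      has_indel <- TRUE; seq_len <- seq_len + len
    } else if (op == "S") {
      softclip <- softclip + len; seq_len <- seq_len + len
    } else if (op == "N") {
      starts <- c(starts, bstart); ends <- c(ends, bstart + span - 1L)
      al <- c(al, aligned)
      bstart <- bstart + span + len
      aligned <- 0L; span <- 0L
    } else if (op == "H" || op == "P") {
      # hard clips / padding: no sequence, no reference
    } else stop("unsupported CIGAR operator: ", op)
  }
  starts <- c(starts, bstart); ends <- c(ends, bstart + span - 1L)
  al <- c(al, aligned)
  list(starts = starts, ends = ends, aligned = al,
       softclip_total = softclip, has_indel = has_indel, seq_len = seq_len)
}

# Mismatch count implied by tags: NM minus indel bases when NM is present,
# else (permissive) substitutions counted from the MD tag, else NA.
mismatches_from_tags <- function(nm, md, ops, lens, nm_mode) {
  indel_bases <- sum(lens[ops %in% c("I", "D")])
  if (!is.na(nm)) return(max(0L, nm - indel_bases))
  if (nm_mode == "permissive" && !is.na(md)) {
    body <- gsub("\\^[A-Za-z]+", "", md)
    return(sum(gregexpr("[A-Za-z]", body)[[1]] > 0))
  }
  NA_integer_
}

#' Classify one aligned read against one junction
#'
#' Applies the junction-read rule: the alignment must contain a skipped
#' region whose upstream block ends exactly at the junction donor and whose
#' downstream block starts exactly at the acceptor; the two flanking blocks
#' must each hold at least \code{min_flank} aligned bases; soft-clipping must
#' not exceed the allowed fraction of the read sequence; and (by default) the
#' read must align with zero mismatches and no indels. The reject reason
#' reports the first failed criterion in the fixed order no_splice,
#' breakpoint_mismatch, excess_softclip, has_mismatch/has_indel, short_flank.
#'
#' @param record list with \code{pos}, \code{cigar} and optionally
#'   \code{flag}, \code{nm}, \code{md}, \code{seq_len}, \code{read_id}.
#' @param junction one row of a catalog \code{junctions} table (or a list
#'   with \code{chrom}, \code{donor_end}, \code{acceptor_start},
#'   \code{label}).
#' @param params a \code{\link{counting_params}}.
#' @return list (class \code{read_verdict}): read_id, junction_label,
#'   accepted, reject_reason (NA when accepted).
#' @export
classify_read <- function(record, junction, params = counting_params()) {
  verdict <- function(ok, reason = NA_character_) {
    structure(list(read_id = if (!is.null(record$read_id)) record$read_id else NA_character_,
                   junction_label = junction$label,
                   accepted = ok, reject_reason = reason),
              class = "read_verdict")
  }
  flag <- if (!is.null(record$flag)) record$flag else 0L
  if (bitwAnd(flag, 4L) != 0L) return(verdict(FALSE, "unmapped"))
  if (bitwAnd(flag, 256L) != 0L && !params$count_secondary)
    return(verdict(FALSE, "secondary"))
  bl <- read_blocks(record$cigar, record$pos)
  nb <- nrow(bl$blocks)
  if (nb < 2L) return(verdict(FALSE, "no_splice"))
  hit <- which(bl$blocks$end[-nb] == junction$donor_end &
               bl$blocks$start[-1] == junction$acceptor_start)
  if (length(hit) == 0L) return(verdict(FALSE, "breakpoint_mismatch"))
  i <- hit[1]
  seq_len <- if (!is.null(record$seq_len) && !is.na(record$seq_len))
    record$seq_len else bl$seq_len
  if (bl$softclip_total > params$max_softclip_fraction * seq_len)
    return(verdict(FALSE, "excess_softclip"))
  if (params$require_zero_mismatches) {
    if (bl$has_indel) return(verdict(FALSE, "has_indel"))
    ops <- GenomicAlignments::explodeCigarOps(record$cigar)[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(record$cigar)[[1]]
    mm <- mismatches_from_tags(
      if (is.null(record$nm)) NA_integer_ else record$nm,
      if (is.null(record$md)) NA_character_ else record$md,
      ops, lens, params$nm_mode)
    if (is.na(mm) || mm > 0L) return(verdict(FALSE, "has_mismatch"))
  }
  if (bl$blocks$aligned[i] < params$min_flank ||
      bl$blocks$aligned[i + 1L] < params$min_flank)
    return(verdict(FALSE, "short_flank"))
  verdict(TRUE)
}

#' Read alignments from SAM or BAM into a flat table
#'
#' SAM input is converted through \code{Rsamtools::asBam}. Returns one row
#' per record with qname, flag, rname, pos, cigar, sequence length and the
#' NM/MD tags (NA when absent).
#'
#' @param path SAM or BAM file.
#' @return data.frame of alignment records.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("NM", "MD"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  nm <- res$tag$NM
  md <- res$tag$MD
  data.frame(
    read_id = as.character(res$qname),
    flag = as.integer(res$flag),
    rname = as.character(res$rname),
    pos = as.integer(res$pos),
    cigar = as.character(res$cigar),
    seq_len = if (n) Biostrings::width(res$seq) else integer(0),
    nm = if (is.null(nm)) rep(NA_integer_, n) else as.integer(nm),
    md = if (is.null(md)) rep(NA_character_, n) else as.character(md),
    stringsAsFactors = FALSE)
}

#' Count junction reads in an alignment file
#'
#' Scans every primary record and counts, per catalog junction, the reads
#' accepted under the junction-read rule. A read with several skipped
#' regions can support several junctions (one count per junction at most);
#' records that are unmapped, secondary, or supplementary are excluded
#' (secondary optionally counted), duplicate-flagged reads are counted by
#' default.
#'
#' @param alignments path to a SAM/BAM file, or a data.frame from
#'   \code{\link{read_alignments}}.
#' @param catalog a \code{junction_catalog}.
#' @param params a \code{\link{counting_params}}.
#' @param sample_id sample label stored on the result.
#' @param audit if TRUE, attach a per-read audit data.frame (read_id,
#'   junction_label, accepted, reject_reason) as the \code{audit} element.
#' @return object of class \code{junction_counts}: list(sample_id, counts =
#'   named integer vector over all catalog labels, total_reads_scanned,
#'   audit).
#' @export
count_junction_reads <- function(alignments, catalog,
                                 params = counting_params(),
                                 sample_id = "sample", audit = FALSE) {
  stopifnot(inherits(catalog, "junction_catalog"))
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  jt <- catalog$junctions
  counts <- stats::setNames(integer(nrow(jt)), jt$label)
  jmap <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(jt)))
    assign(sprintf("%s:%d-%d", jt$chrom[k], jt$donor_end[k], jt$acceptor_start[k]),
           jt$label[k], envir = jmap)

  n <- nrow(alignments)
  if (n > 0L && !any(alignments$rname %in% unique(jt$chrom)))
    warning("no alignment uses a catalog chromosome (",
            paste(unique(jt$chrom), collapse = ","),
            "); all counts will be zero")
  has_cigar <- !is.na(alignments$cigar) & alignments$cigar != "*"
  ops_all <- vector("list", n)
  lens_all <- vector("list", n)
  if (any(has_cigar)) {
    ops_all[has_cigar] <- GenomicAlignments::explodeCigarOps(alignments$cigar[has_cigar])
    lens_all[has_cigar] <- GenomicAlignments::explodeCigarOpLengths(alignments$cigar[has_cigar])
  }
  # audit accumulators (grown in chunks; one row per evaluated read/junction)
  a_read <- character(0); a_lbl <- character(0)
  a_acc <- logical(0); a_why <- character(0)
  add_audit <- function(read, lbl, acc, why) {
    a_read[[length(a_read) + 1L]] <<- read
    a_lbl[[length(a_lbl) + 1L]] <<- lbl
    a_acc[[length(a_acc) + 1L]] <<- acc
    a_why[[length(a_why) + 1L]] <<- why
  }
  scanned <- 0L
  for (r in seq_len(n)) {
    flag <- alignments$flag[r]
    if (bitwAnd(flag, 4L) != 0L) next                      # unmapped
    if (bitwAnd(flag, 2048L) != 0L) next                   # supplementary
    if (bitwAnd(flag, 256L) != 0L && !params$count_secondary) next
    if (bitwAnd(flag, 1024L) != 0L && !params$count_duplicates) next
    if (!has_cigar[r]) next
    scanned <- scanned + 1L
    rn <- alignments$rname[r]
    if (!rn %in% jt$chrom) next
    bl <- blocks_from_ops(ops_all[[r]], lens_all[[r]], alignments$pos[r])
    nb <- length(bl$starts)
    if (nb < 2L) {
      if (audit) add_audit(alignments$read_id[r], NA_character_, FALSE, "no_splice")
      next
    }
    matched <- FALSE
    for (i in seq_len(nb - 1L)) {
      key <- sprintf("%s:%d-%d", rn, bl$ends[i], bl$starts[i + 1L])
      lbl <- if (exists(key, envir = jmap, inherits = FALSE))
        get(key, envir = jmap) else NA_character_
      if (is.na(lbl)) next
      matched <- TRUE
      reason <- NA_character_
      if (bl$softclip_total > params$max_softclip_fraction * alignments$seq_len[r]) {
        reason <- "excess_softclip"
      } else if (params$require_zero_mismatches && bl$has_indel) {
        reason <- "has_indel"
      } else if (params$require_zero_mismatches) {
        mm <- mismatches_from_tags(alignments$nm[r], alignments$md[r],
                                   ops_all[[r]], lens_all[[r]], params$nm_mode)
        if (is.na(mm) || mm > 0L) reason <- "has_mismatch"
      }
      if (is.na(reason) &&
          (bl$aligned[i] < params$min_flank ||
           bl$aligned[i + 1L] < params$min_flank))
        reason <- "short_flank"
      if (is.na(reason)) counts[lbl] <- counts[lbl] + 1L
      if (audit) add_audit(alignments$read_id[r], lbl, is.na(reason), reason)
    }
    if (audit && !matched)
      add_audit(alignments$read_id[r], NA_character_, FALSE, "breakpoint_mismatch")
  }
  structure(list(sample_id = sample_id, counts = counts,
                 total_reads_scanned = scanned,
                 audit = if (audit)
                   data.frame(read_id = unlist(a_read) %||% character(0),
                              junction_label = unlist(a_lbl) %||% character(0),
                              accepted = unlist(a_acc) %||% logical(0),
                              reject_reason = unlist(a_why) %||% character(0),
                              stringsAsFactors = FALSE)
                 else NULL),
            class = "junction_counts")
}

#' Build a junction_counts object from explicit counts
#'
#' @param sample_id sample label.
#' @param counts named integer vector, junction label to read count.
#' @param total_reads_scanned total records evaluated.
#' @return object of class \code{junction_counts}.
#' @export
junction_counts <- function(sample_id, counts, total_reads_scanned = sum(counts)) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  structure(list(sample_id = sample_id,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 total_reads_scanned = as.integer(total_reads_scanned),
                 audit = NULL),
            class = "junction_counts")
}

#' Write per-sample junction counts as TSV
#'
#' @param counts_list a \code{junction_counts} or list of them.
#' @param path output TSV (columns sample_id, junction_label, count).
#' @return \code{path}, invisibly.
#' @export
write_junction_counts <- function(counts_list, path) {
  if (inherits(counts_list, "junction_counts")) counts_list <- list(counts_list)
  rows <- do.call(rbind, lapply(counts_list, function(jc)
    data.frame(sample_id = jc$sample_id,
               junction_label = names(jc$counts),
               count = unname(jc$counts))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample junction counts from TSV
#'
#' @param path TSV written by \code{\link{write_junction_counts}}.
#' @return list of \code{junction_counts}, one per sample.
#' @export
read_junction_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "junction_label", "count")
  if (!all(need %in% names(tab)))
    stop("counts TSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(tab, tab$sample_id), function(d)
    junction_counts(d$sample_id[1],
                    stats::setNames(d$count, d$junction_label)))
}
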