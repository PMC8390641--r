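#' Construct a gene model from per-transcript exon tables
#'
#' A gene model is a plain data frame with one row per exon and columns
#' \code{transcript_id}, \code{chrom}, \code{strand}, \code{role},
#' \code{exon_index}, \code{start}, \code{end}. Coordinates are 1-based
#' inclusive (SAM/GFF convention). \code{exon_index} numbers exons in each
#' transcript's own 5'-to-3' order, so on the minus strand genomic
#' coordinates decrease with increasing \code{exon_index}.
#'
#' @param exons data.frame with the columns above.
#' @param junction_roles optional named list mapping transcript accessions to
#'   junction roles: \code{cterm_ref} (the transcript whose two C-terminal
#'   junctions are averaged, p53beta in the bundled model), \code{utr5_ref}
#'   (the 5'UTR alternate-acceptor transcript) and \code{gamma_refs}
#'   (character vector of gamma-family transcripts).
#' @return data.frame of class \code{gene_model}.
#' @export
gene_model <- function(exons, junction_roles = NULL) {
  required <- c("transcript_id", "chrom", "strand", "role", "exon_index",
                "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0L)
    stop("gene model is missing column(s): ", paste(missing_cols, collapse = ", "))
  exons <- as.data.frame(exons)[required]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  exons$exon_index <- as.integer(exons$exon_index)
  if (any(exons$start > exons$end))
    stop("exon with start > end")
  if (!all(exons$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(exons$role %in% c("main", "alternative")))
    stop("role must be 'main' or 'alternative'")
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, ]
    if (nrow(e) < 2L)
      stop("transcript ", tx, " has fewer than 2 exons")
    if (!identical(e$exon_index, seq_len(nrow(e))))
      stop("transcript ", tx, ": exon_index must be 1..n in order")
    if (length(unique(e$strand)) != 1L || length(unique(e$chrom)) != 1L)
      stop("transcript ", tx, ": inconsistent chrom/strand")
    ord <- if (e$strand[1] == "+") order(e$start) else order(-e$start)
    if (!identical(ord, seq_len(nrow(e))))
      stop("transcript ", tx, ": exons not ordered 5'->3' along the transcript")
    e2 <- e[order(e$start), ]
    if (any(e2$start[-1] <= e2$end[-nrow(e2)]))
      stop("transcript ", tx, ": overlapping exons")
  }
  attr(exons, "junction_roles") <- junction_roles
  class(exons) <- c("gene_model", "data.frame")
  exons
}

#' Load a gene model from JSON or GFF3
#'
#' The JSON dialect is
#' \code{\{"chrom": ..., "transcripts": [\{"id","strand","role","exons":
#' [[start,end],...]\}], "junction_roles": ...\}} with exons listed in
#' transcript 5'-to-3' order and 1-based inclusive coordinates. GFF3 input
#' must contain \code{exon} features grouped by \code{Parent}; transcript
#' roles are read from an \code{isoform_role} attribute on \code{mRNA}
#' features (defaulting to \code{alternative} when absent).
#'
#' @param path file path.
#' @param dialect \code{"auto"} (by extension), \code{"json"} or \code{"gff3"}.
#' @return a \code{\link{gene_model}}; transcripts retain file order.
#' @export
load_gene_model <- function(path, dialect = c("auto", "json", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("gene model file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE)) "gff3" else "json"
  }
  if (dialect == "json") load_gene_model_json(path) else load_gene_model_gff3(path)
}

load_gene_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("failed to parse gene model JSON '",
                                           path, "': ", conditionMessage(e)))
  if (is.null(doc$transcripts)) stop("gene model JSON lacks 'transcripts'")
  chrom_default <- doc$chrom
  rows <- lapply(doc$transcripts, function(tx) {
    if (is.null(tx$id) || is.null(tx$exons))
      stop("transcript entry lacks 'id' or 'exons'")
    ex <- do.call(rbind, lapply(tx$exons, function(p) as.integer(unlist(p))))
    if (ncol(ex) != 2L) stop("transcript ", tx$id, ": exons must be [start,end] pairs")
    data.frame(
      transcript_id = tx$id,
      chrom = if (!is.null(tx$chrom)) tx$chrom else chrom_default,
      strand = if (!is.null(tx$strand)) tx$strand else "+",
      role = if (!is.null(tx$role)) tx$role else "alternative",
      exon_index = seq_len(nrow(ex)),
      start = ex[, 1], end = ex[, 2],
      stringsAsFactors = FALSE)
  })
  roles <- doc$junction_roles
  if (!is.null(roles$gamma_refs)) roles$gamma_refs <- unlist(roles$gamma_refs)
  gene_model(do.call(rbind, rows), junction_roles = roles)
}

load_gene_model_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("failed to parse GFF3 '", path, "': ",
                                          conditionMessage(e)))
  meta <- S4Vectors::mcols(gr)
  roles <- character(0)
  is_tx <- !is.na(meta$type) & meta$type %in% c("mRNA", "transcript")
  if (any(is_tx) && "isoform_role" %in% names(meta)) {
    roles <- stats::setNames(as.character(meta$isoform_role[is_tx]),
                             as.character(meta$ID[is_tx]))
  }
  ex <- gr[!is.na(meta$type) & meta$type == "exon"]
  if (length(ex) == 0L) stop("GFF3 '", path, "' contains no exon features")
  parent <- as.character(S4Vectors::mcols(ex)$Parent)
  tx_order <- unique(parent)
  rows <- lapply(tx_order, function(tx) {
    e <- ex[parent == tx]
    strand <- as.character(BiocGenerics::strand(e))[1]
    o <- if (strand == "-") order(-BiocGenerics::start(e)) else order(BiocGenerics::start(e))
    e <- e[o]
    role <- if (tx %in% names(roles)) unname(roles[[tx]]) else "alternative"
    data.frame(
      transcript_id = tx,
      chrom = as.character(GenomeInfoDb::seqnames(e)),
      strand = strand, role = role,
      exon_index = seq_along(e),
      start = BiocGenerics::start(e), end = BiocGenerics::end(e),
      stringsAsFactors = FALSE)
  })
  gene_model(do.call(rbind, rows))
}

#' Write a gene model to JSON or GFF3
#'
#' @param model a \code{\link{gene_model}}.
#' @param path output path.
#' @param dialect \code{"json"} or \code{"gff3"}.
#' @return \code{path}, invisibly.
#' @export
write_gene_model <- function(model, path, dialect = c("json", "gff3")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(model, "gene_model"))
  tx_ids <- unique(model$transcript_id)
  if (dialect == "json") {
    txs <- lapply(tx_ids, function(tx) {
      e <- model[model$transcript_id == tx, ]
      list(id = tx, strand = e$strand[1], role = e$role[1], chrom = e$chrom[1],
           exons = lapply(seq_len(nrow(e)), function(i) c(e$start[i], e$end[i])))
    })
    doc <- list(chrom = model$chrom[1],
                junction_roles = attr(model, "junction_roles"),
                transcripts = txs)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    recs <- lapply(tx_ids, function(tx) {
      e <- model[model$transcript_id == tx, ]
      mrna <- GenomicRanges::GRanges(
        e$chrom[1],
        IRanges::IRanges(min(e$start), max(e$end)),
        strand = e$strand[1], type = "mRNA", ID = tx,
        isoform_role = e$role[1], Parent = NA_character_)
      exons <- GenomicRanges::GRanges(
        e$chrom, IRanges::IRanges(e$start, e$end), strand = e$strand,
        type = "exon", ID = paste0(tx, ".exon", e$exon_index),
        isoform_role = NA_character_, Parent = tx)
      c(mrna, exons)
    })
    gr <- do.call(c, recs)
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Bundled TP53 gene model (GRCh38)
#'
#' Returns the packaged TP53 locus model: the predominant isoform NM_000546.6
#' (p53alpha) plus nine alternatives — the C-terminal beta family
#' (NM_001126114.2 p53beta, NM_001276696.2, NM_001126116.1, NM_001276698.2),
#' the gamma family (NM_001126113.2, NM_001276695.2, NM_001126117.1,
#' NM_001276699.2) and the 5'UTR alternate-acceptor transcript
#' NM_001126112.2 whose exon 2 is 3 bp shorter at the splice acceptor. The
#' model is a packaged data file, so alternative annotation versions can be
#' swapped in via \code{\link{load_gene_model}}.
#'
#' @return a \code{\link{gene_model}} carrying default junction roles.
#' @export
builtin_tp53_model <- function() {
  path <- system.file("extdata", "tp53_model_grch38.json",
                      package = "tp53junctions", mustWork = TRUE)
  load_gene_model(path, dialect = "json")
}

junction_label <- function(chrom, donor_end, acceptor_start) {
  sprintf("%s:%d-%d", chrom, donor_end, acceptor_start)
}

transcript_junctions <- function(e) {
  # e: exon rows of one transcript in 5'->3' order; returns genomic junctions
  n <- nrow(e)
  if (n < 2L) return(NULL)
  a <- e[-n, , drop = FALSE]
  b <- e[-1, , drop = FALSE]
  lo_end <- pmin(a$end, b$end)
  donor_end <- ifelse(a$start < b$start, a$end, b$end)
  acceptor_start <- ifelse(a$start < b$start, b$start, a$start)
  bad <- donor_end >= acceptor_start - 1L
  if (any(bad))
    stop("transcript ", e$transcript_id[1],
         ": adjacent exons without a real intron (>= 1 bp) between them")
  data.frame(chrom = e$chrom[1], donor_end = as.integer(donor_end),
             acceptor_start = as.integer(acceptor_start),
             stringsAsFactors = FALSE)
}

#' Derive the junction catalog from a gene model
#'
#' Every adjacent exon pair in every transcript yields one genomic junction
#' (identified strand-agnostically by chrom, donor end = last base of the
#' genome-upstream exon, acceptor start = first base of the genome-downstream
#' exon); a junction shared by several transcripts is stored once. Junctions
#' present in the main transcript get class \code{main}. Among the rest, the
#' roles configuration names the transcript whose two C-terminal junctions
#' form the averaged pair (\code{cterm_ref}), the 5'UTR alternate-acceptor
#' transcript (\code{utr5_ref}) and the gamma-family transcripts
#' (\code{gamma_refs}); any other non-main junction is classed
#' \code{other_distinct}. The main-isoform competitor of the C-terminal pair
#' (and of the 5'UTR junction) is the main junction sharing the same splice
#' boundary on the same side.
#'
#' @param model a \code{\link{gene_model}}.
#' @param roles junction-role list; defaults to the model's own
#'   \code{junction_roles} attribute.
#' @return object of class \code{junction_catalog}: list with a
#'   \code{junctions} data.frame (label, chrom, donor_end, acceptor_start,
#'   klass, origin) plus \code{cterm_pair}, \code{cterm_main},
#'   \code{utr5_distinct}, \code{utr5_main} labels.
#' @export
derive_junctions <- function(model, roles = NULL) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(roles)) roles <- attr(model, "junction_roles")
  tx_ids <- unique(model$transcript_id)
  main_ids <- unique(model$transcript_id[model$role == "main"])
  if (length(main_ids) != 1L)
    stop("gene model must contain exactly one main transcript, found ",
         length(main_ids))
  for (ref in c(roles$cterm_ref, roles$utr5_ref, roles$gamma_refs))
    if (!ref %in% tx_ids)
      stop("junction role references unknown transcript: ", ref)

  per_tx <- lapply(tx_ids, function(tx) {
    j <- transcript_junctions(model[model$transcript_id == tx, ])
    j$transcript_id <- tx
    j
  })
  all_j <- do.call(rbind, per_tx)
  all_j$label <- junction_label(all_j$chrom, all_j$donor_end, all_j$acceptor_start)
  # deterministic order: genomic position
  uniq <- all_j[!duplicated(all_j$label), c("label", "chrom", "donor_end", "acceptor_start")]
  uniq <- uniq[order(uniq$chrom, uniq$donor_end, uniq$acceptor_start), ]
  rownames(uniq) <- NULL
  origin <- lapply(uniq$label, function(l) sort(unique(all_j$transcript_id[all_j$label == l])))
  uniq$origin <- vapply(origin, paste, character(1), collapse = ",")

  labels_of <- function(tx) unique(all_j$label[all_j$transcript_id == tx])
  main_labels <- labels_of(main_ids)
  uniq$klass <- ifelse(uniq$label %in% main_labels, "main", "other_distinct")

  cterm_pair <- character(0)
  if (!is.null(roles$cterm_ref)) {
    cterm_pair <- setdiff(labels_of(roles$cterm_ref), main_labels)
    if (length(cterm_pair) == 0L)
      warning("C-terminal reference transcript ", roles$cterm_ref,
              " shares all junctions with the main isoform; empty cterm pair")
    else if (length(cterm_pair) != 2L)
      stop("expected exactly 2 C-terminal distinct junctions in ",
           roles$cterm_ref, ", found ", length(cterm_pair))
    uniq$klass[uniq$label %in% cterm_pair] <- "cterm_distinct"
  }
  utr5_distinct <- NA_character_
  if (!is.null(roles$utr5_ref)) {
    u <- setdiff(labels_of(roles$utr5_ref), main_labels)
    if (length(u) != 1L)
      stop("expected exactly 1 distinct junction in 5'UTR reference ",
           roles$utr5_ref, ", found ", length(u))
    utr5_distinct <- u
    uniq$klass[uniq$label == u] <- "utr5_distinct"
  }
  if (!is.null(roles$gamma_refs)) {
    g <- setdiff(unlist(lapply(roles$gamma_refs, labels_of)),
                 c(main_labels, cterm_pair, utr5_distinct))
    uniq$klass[uniq$label %in% g] <- "gamma_distinct"
  }

  competitor <- function(dist_labels) {
    if (length(dist_labels) == 0L) return(NA_character_)
    d <- uniq[uniq$label %in% dist_labels, ]
    m <- uniq[uniq$klass == "main", ]
    hit <- m$label[m$donor_end %in% d$donor_end | m$acceptor_start %in% d$acceptor_start]
    hit <- unique(hit)
    if (length(hit) == 0L) return(NA_character_)
    if (length(hit) > 1L)
      stop("ambiguous main-isoform competitor for junctions ",
           paste(dist_labels, collapse = ", "))
    hit
  }
  cterm_main <- competitor(cterm_pair)
  utr5_main <- if (is.na(utr5_distinct)) NA_character_ else competitor(utr5_distinct)

  if (!is.na(utr5_distinct) && !is.na(utr5_main)) {
    du <- uniq[uniq$label == utr5_distinct, ]
    dm <- uniq[uniq$label == utr5_main, ]
    shift <- abs(du$donor_end - dm$donor_end) + abs(du$acceptor_start - dm$acceptor_start)
    if (shift != 3L)
      warning("5'UTR alternate junction differs from its main competitor by ",
              shift, " bp (expected 3)")
  }

  structure(list(junctions = uniq,
                 cterm_pair = cterm_pair, cterm_main = cterm_main,
                 utr5_distinct = utr5_distinct, utr5_main = utr5_main,
                 roles = roles),
            class = "junction_catalog")
}

#' @export
print.junction_catalog <- function(x, ...) {
  cat("junction_catalog:", nrow(x$junctions), "junctions (",
      sum(x$junctions$klass == "main"), "main,",
      sum(x$junctions$klass == "cterm_distinct"), "cterm,",
      sum(x$junctions$klass == "utr5_distinct"), "utr5,",
      sum(x$junctions$klass == "gamma_distinct"), "gamma )\n")
  if (length(x$cterm_pair)) cat("  cterm pair:", paste(x$cterm_pair, collapse = " + "),
                                "vs", x$cterm_main, "\n")
  if (!is.na(x$utr5_distinct)) cat("  utr5:", x$utr5_distinct, "vs", x$utr5_main, "\n")
  invisible(x)
}

#' Export a junction catalog as TSV
#'
#' @param catalog a \code{junction_catalog}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
export_junction_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "junction_catalog"))
  utils::write.table(
    catalog$junctions[, c("label", "chrom", "donor_end", "acceptor_start",
                          "klass", "origin")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
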