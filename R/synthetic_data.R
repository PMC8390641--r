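# Synthetic-data layer: toy locus, spliced-read simulator with an
# independent truth table, and cohort simulator. All generators restore the
# caller's RNG state and are fully reproducible from their seed.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy TP53-like locus
#'
#' Builds a single-chromosome locus whose transcript topology mirrors the
#' TP53 isoform families: a main transcript with \code{n_main_exons} exons;
#' a C-terminal alternative sharing exons 1-9 and adding two exons inside
#' intron 9 (two junctions absent from main); a 5'UTR alternative whose
#' exon-2 acceptor is shifted by exactly 3 bases; and a gamma-like
#' alternative adding one intron-9 exon. Deterministic given \code{seed}.
#'
#' @param seed integer RNG seed.
#' @param strand "+" (default) or "-"; the minus variant mirrors all
#'   coordinates so strand-invariance can be tested.
#' @param chrom sequence name.
#' @param n_main_exons exons in the main transcript (>= 10).
#' @param outdir optional directory; when given, writes \code{locus.fa} and
#'   \code{model.json} there.
#' @return list: \code{model} (a \code{\link{gene_model}} with junction
#'   roles), \code{seq} (named \code{DNAStringSet}), \code{chrom},
#'   \code{fasta}/\code{model_path} when written.
#' @export
make_toy_locus <- function(seed = 1L, strand = "+", chrom = "toyT",
                           n_main_exons = 11L, outdir = NULL) {
  stopifnot(n_main_exons >= 10L, strand %in% c("+", "-"))
  with_seed(seed, {
    exon_len <- sample(120:240, n_main_exons, replace = TRUE)
    intron_len <- sample(400:900, n_main_exons - 1L, replace = TRUE)
    intron_len[9L] <- 2186L  # hosts the two beta-like and the gamma-like exon
    starts <- integer(n_main_exons)
    ends <- integer(n_main_exons)
    cur <- 101L
    for (i in seq_len(n_main_exons)) {
      starts[i] <- cur
      ends[i] <- cur + exon_len[i] - 1L
      cur <- ends[i] + 1L + if (i < n_main_exons) intron_len[i] else 0L
    }
    b1 <- c(ends[9L] + 601L, ends[9L] + 690L)
    b2 <- c(b1[2L] + 401L, b1[2L] + 529L)
    gx <- c(b2[2L] + 301L, b2[2L] + 467L)
    total_len <- ends[n_main_exons] + 200L

    main <- cbind(starts, ends)
    tx <- list(
      MAIN  = main,
      ALTCT = rbind(main[1:9, , drop = FALSE], b1, b2),
      ALTG  = rbind(main[1:9, , drop = FALSE], gx),
      ALTU5 = {
        m <- main
        m[2L, 1L] <- m[2L, 1L] + 3L  # alternate acceptor: exon 2 loses 3 bp
        m
      })
    if (strand == "-") {
      tx <- lapply(tx, function(m)
        cbind(total_len - m[, 2L] + 1L, total_len - m[, 1L] + 1L))
    }
    rows <- do.call(rbind, lapply(names(tx), function(id) {
      m <- tx[[id]]
      # exon rows in the transcript's own 5'->3' order
      o <- if (strand == "+") order(m[, 1L]) else order(-m[, 1L])
      m <- m[o, , drop = FALSE]
      data.frame(transcript_id = id, chrom = chrom, strand = strand,
                 role = if (id == "MAIN") "main" else "alternative",
                 exon_index = seq_len(nrow(m)),
                 start = m[, 1L], end = m[, 2L], stringsAsFactors = FALSE)
    }))
    model <- gene_model(rows, junction_roles = list(
      cterm_ref = "ALTCT", utr5_ref = "ALTU5", gamma_refs = "ALTG"))
    seq <- Biostrings::DNAStringSet(random_dna(total_len))
    names(seq) <- chrom
    out <- list(model = model, seq = seq, chrom = chrom)
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      out$fasta <- file.path(outdir, "locus.fa")
      Biostrings::writeXStringSet(seq, out$fasta)
      out$model_path <- file.path(outdir, "model.json")
      write_gene_model(model, out$model_path, dialect = "json")
    }
    out
  })
}

#' Read-mixture configuration for the spliced-read simulator
#'
#' @param proportions named numeric vector, transcript id to mixture
#'   proportion (must sum to 1).
#' @param read_length read length in bp (48-101 covers the emulated
#'   platforms: 48-76 bp and 101 bp).
#' @param n_reads number of reads to draw.
#' @param softclip_rate probability a read gets terminal aligned bases
#'   converted to soft clips.
#' @param softclip_len_range integer range of clip lengths.
#' @param mismatch_rate probability a read carries one mismatch (edit
#'   distance 1).
#' @param offset_error_rate probability a spliced read has its splice
#'   boundary shifted by one base.
#' @param seed integer RNG seed.
#' @return list of class \code{mixture_config}.
#' @export
mixture_config <- function(proportions, read_length = 76L, n_reads = 1000L,
                           softclip_rate = 0, softclip_len_range = c(5L, 20L),
                           mismatch_rate = 0, offset_error_rate = 0,
                           seed = 1L) {
  stopifnot(!is.null(names(proportions)),
            abs(sum(proportions) - 1) < 1e-8,
            read_length >= 20L, read_length <= 150L)
  structure(list(proportions = proportions,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads),
                 softclip_rate = softclip_rate,
                 softclip_len_range = as.integer(softclip_len_range),
                 mismatch_rate = mismatch_rate,
                 offset_error_rate = offset_error_rate,
                 seed = as.integer(seed)),
            class = "mixture_config")
}

tx_genomic_blocks <- function(model, tx) {
  e <- model[model$transcript_id == tx, ]
  e <- e[order(e$start), ]
  cbind(e$start, e$end)
}

map_read_blocks <- function(exons, t0, len) {
  # exons: ascending genomic [start,end] matrix; t0: 1-based offset along the
  # genomic-ascending exon concatenation; returns the read's genomic blocks
  widths <- exons[, 2L] - exons[, 1L] + 1L
  cum <- cumsum(widths)
  remaining <- len
  pos <- t0
  blocks <- NULL
  for (i in seq_len(nrow(exons))) {
    if (pos > cum[i]) next
    off <- pos - (if (i == 1L) 0L else cum[i - 1L])
    take <- min(remaining, widths[i] - off + 1L)
    gstart <- exons[i, 1L] + off - 1L
    blocks <- rbind(blocks, c(gstart, gstart + take - 1L))
    remaining <- remaining - take
    pos <- pos + take
    if (remaining == 0L) break
  }
  blocks
}

#' Simulate spliced alignments over a locus, with an independent truth table
#'
#' Draws reads from the mixture's transcripts at uniform transcript
#' positions, builds exact spliced alignments (CIGAR with N operators at the
#' true exon boundaries), then injects the configured contamination:
#' boundary offsets (splice shifted one base), terminal soft-clipping
#' (aligned bases converted to clips, so clip and flank lengths interact),
#' and mismatches (reflected in the NM tag). The returned truth table
#' applies the literal junction-read rule (exact catalog boundary, >= 10
#' aligned bases both sides, <= half the read soft-clipped, zero
#' mismatches) to the generator's own block list — it never parses CIGAR —
#' so it serves as an independent oracle for the counting module.
#'
#' @param locus list from \code{\link{make_toy_locus}}.
#' @param mixture a \code{\link{mixture_config}}.
#' @param catalog junction catalog used for the truth qualification flags;
#'   defaults to \code{derive_junctions(locus$model)}.
#' @param sam_path output SAM path (default: tempfile).
#' @param include_nm write NM tags (disable to exercise the missing-tag
#'   policy).
#' @param min_flank flank requirement the truth oracle applies.
#' @return list: \code{sam_path}, \code{truth} (one row per read x skipped
#'   region: read_id, transcript_id, junction_label, in_catalog, flank_ok,
#'   clip_ok, mismatch_ok, qualifies), \code{n_reads}.
#' @export
simulate_alignments <- function(locus, mixture,
                                catalog = derive_junctions(locus$model),
                                sam_path = tempfile(fileext = ".sam"),
                                include_nm = TRUE, min_flank = 10L) {
  model <- locus$model
  chrom <- locus$chrom
  seqlen <- Biostrings::width(locus$seq)[1]
  refseq <- as.character(locus$seq[[1]])
  tx_ids <- names(mixture$proportions)
  blocks_by_tx <- lapply(tx_ids, function(tx) tx_genomic_blocks(model, tx))
  names(blocks_by_tx) <- tx_ids
  txlen <- vapply(blocks_by_tx, function(b) sum(b[, 2L] - b[, 1L] + 1L), numeric(1))
  L <- mixture$read_length
  if (any(txlen < L))
    warning("read length exceeds transcript length for: ",
            paste(tx_ids[txlen < L], collapse = ","))
  cat_labels <- catalog$junctions$label

  with_seed(mixture$seed, {
    n <- mixture$n_reads
    txs <- sample(tx_ids, n, replace = TRUE, prob = mixture$proportions)
    sam_lines <- character(n)
    # truth-table accumulators (one slot per read x skipped region)
    t_read <- character(0); t_tx <- character(0); t_lbl <- character(0)
    t_incat <- logical(0); t_flank <- logical(0); t_clip <- logical(0)
    t_mm <- logical(0)
    for (r in seq_len(n)) {
      tx <- txs[r]
      ex <- blocks_by_tx[[tx]]
      t0 <- sample.int(txlen[tx] - L + 1L, 1L)
      bl <- map_read_blocks(ex, t0, L)
      nb <- nrow(bl)
      # boundary offset contamination
      if (nb >= 2L && stats::runif(1) < mixture$offset_error_rate) {
        j <- if (nb == 2L) 1L else sample.int(nb - 1L, 1L)
        shift <- sample(c(-1L, 1L), 1L)
        us_len <- bl[j, 2L] - bl[j, 1L] + 1L
        ds_len <- bl[j + 1L, 2L] - bl[j + 1L, 1L] + 1L
        if (us_len + shift >= 1L && ds_len - shift >= 1L) {
          bl[j, 2L] <- bl[j, 2L] + shift
          bl[j + 1L, 1L] <- bl[j + 1L, 1L] + shift
        }
      }
      # soft-clip contamination: trim terminal aligned bases into clips
      clip_left <- 0L; clip_right <- 0L
      if (stats::runif(1) < mixture$softclip_rate) {
        len <- sample(seq(mixture$softclip_len_range[1L],
                          mixture$softclip_len_range[2L]), 1L)
        side <- sample(c("left", "right"), 1L)
        if (side == "left") {
          len <- min(len, bl[1L, 2L] - bl[1L, 1L])
          if (len > 0L) { bl[1L, 1L] <- bl[1L, 1L] + len; clip_left <- len }
        } else {
          len <- min(len, bl[nb, 2L] - bl[nb, 1L])
          if (len > 0L) { bl[nb, 2L] <- bl[nb, 2L] - len; clip_right <- len }
        }
      }
      nm <- if (stats::runif(1) < mixture$mismatch_rate) 1L else 0L
      # sequence: clipped tails are random (unaligned) bases
      aligned_seq <- paste(vapply(seq_len(nb), function(i)
        substr(refseq, bl[i, 1L], bl[i, 2L]), character(1)), collapse = "")
      if (nm > 0L) {
        p1 <- sample.int(nchar(aligned_seq), 1L)
        orig <- substr(aligned_seq, p1, p1)
        substr(aligned_seq, p1, p1) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
      }
      seq <- paste0(if (clip_left) random_dna(clip_left) else "",
                    aligned_seq,
                    if (clip_right) random_dna(clip_right) else "")
      widths <- bl[, 2L] - bl[, 1L] + 1L
      cig <- character(0)
      if (clip_left) cig <- paste0(clip_left, "S")
      for (i in seq_len(nb)) {
        cig <- c(cig, paste0(widths[i], "M"))
        if (i < nb) cig <- c(cig, paste0(bl[i + 1L, 1L] - bl[i, 2L] - 1L, "N"))
      }
      if (clip_right) cig <- c(cig, paste0(clip_right, "S"))
      rid <- sprintf("read%06d", r)
      tags <- if (include_nm) paste0("\tNM:i:", nm) else ""
      sam_lines[r] <- paste0(rid, "\t0\t", chrom, "\t", bl[1L, 1L],
                             "\t60\t", paste(cig, collapse = ""),
                             "\t*\t0\t0\t", seq, "\t",
                             strrep("I", nchar(seq)), tags)
      # truth oracle: literal rule on the generator's own blocks
      if (nb >= 2L) {
        clip_total <- clip_left + clip_right
        for (i in seq_len(nb - 1L)) {
          m <- length(t_read) + 1L
          t_read[[m]] <- rid
          t_tx[[m]] <- tx
          t_lbl[[m]] <- junction_label(chrom, bl[i, 2L], bl[i + 1L, 1L])
          t_flank[[m]] <- widths[i] >= min_flank && widths[i + 1L] >= min_flank
          t_clip[[m]] <- clip_total <= 0.5 * L
          t_mm[[m]] <- nm == 0L
        }
      }
    }
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                paste0("@SQ\tSN:", chrom, "\tLN:", seqlen))
    writeLines(c(header, sam_lines), sam_path)
    t_incat <- t_lbl %in% cat_labels
    truth <- if (length(t_read))
      data.frame(read_id = t_read, transcript_id = t_tx,
                 junction_label = t_lbl, in_catalog = t_incat,
                 flank_ok = t_flank, clip_ok = t_clip, mismatch_ok = t_mm,
                 qualifies = t_incat & t_flank & t_clip & t_mm,
                 stringsAsFactors = FALSE)
    else NULL
    list(sam_path = sam_path, truth = truth, n_reads = n)
  })
}

#' Oracle junction counts from a truth table
#'
#' Aggregates the truth table's independent qualification flags into
#' per-junction counts, for comparison with \code{\link{count_junction_reads}}.
#'
#' @param truth truth data.frame from \code{\link{simulate_alignments}}.
#' @param catalog the junction catalog (fixes the label set).
#' @return named integer vector over all catalog labels.
#' @export
truth_counts <- function(truth, catalog) {
  out <- stats::setNames(integer(nrow(catalog$junctions)),
                         catalog$junctions$label)
  if (is.null(truth) || nrow(truth) == 0L) return(out)
  q <- truth[truth$qualifies, ]
  if (nrow(q)) {
    tb <- table(q$junction_label)
    out[names(tb)] <- as.integer(tb)
  }
  out
}

#' Simulate a cohort of per-sample junction counts with annotations
#'
#' Emulates the statistical structure of a cohort analysis: per stratum and
#' TP53 status group, each sample's junction counts are drawn binomially at
#' the stated depth around the group's true exonic fraction (the two
#' C-terminal junction counts drawn independently at the same rate, so their
#' average is the unbiased numerator), and annotation fields (mutation
#' class, CN-ratio, expression) are generated so classification reproduces
#' the intended group labels.
#'
#' @param catalog junction catalog providing the label set.
#' @param strata character vector of stratum labels.
#' @param n_per_group samples per (stratum, group).
#' @param groups subset of c("WT","missense","truncating").
#' @param baseline_fraction named numeric (per stratum) or scalar true
#'   C-terminal fraction for WT samples.
#' @param group_effect named additive shift on the true fraction per group
#'   (e.g. c(truncating = 0.02)).
#' @param utr5_fraction_true true 5'UTR-variant fraction (all groups).
#' @param depth expected junction coverage per sample.
#' @param paired if TRUE each tumor gets a matched normal sample (same
#'   baseline fraction, \code{normal_effect} shift).
#' @param normal_effect additive shift for matched normals.
#' @param seed integer RNG seed.
#' @return list: \code{annotations} data.frame, \code{counts} list of
#'   \code{junction_counts}, \code{truth} data.frame of per-sample true
#'   fractions.
#' @export
simulate_cohort <- function(catalog, strata = "stratumA", n_per_group = 20L,
                            groups = c("WT", "missense", "truncating"),
                            baseline_fraction = 0.02, group_effect = numeric(0),
                            utr5_fraction_true = 0.01, depth = 5000L,
                            paired = FALSE, normal_effect = 0, seed = 1L) {
  stopifnot(inherits(catalog, "junction_catalog"))
  base <- if (is.null(names(baseline_fraction)))
    stats::setNames(rep(baseline_fraction[1], length(strata)), strata)
  else baseline_fraction
  labels <- catalog$junctions$label
  with_seed(seed, {
    ann <- NULL; cnt <- list(); tru <- NULL
    k <- 0L
    draw_counts <- function(sid, p, pu) {
      cts <- stats::setNames(integer(length(labels)), labels)
      cts[catalog$cterm_pair[1]] <- stats::rbinom(1L, depth, p)
      cts[catalog$cterm_pair[2]] <- stats::rbinom(1L, depth, p)
      cts[catalog$cterm_main] <- stats::rbinom(1L, depth, 1 - p)
      if (!is.na(catalog$utr5_distinct)) {
        cts[catalog$utr5_distinct] <- stats::rbinom(1L, depth, pu)
        cts[catalog$utr5_main] <- stats::rbinom(1L, depth, 1 - pu)
      }
      junction_counts(sid, cts, total_reads_scanned = sum(cts))
    }
    for (s in strata) for (g in groups) for (i in seq_len(n_per_group)) {
      k <- k + 1L
      sid <- sprintf("S%04d_%s_%s", k, s, g)
      eff <- if (g %in% names(group_effect)) group_effect[[g]] else 0
      p <- min(1, max(0, base[[s]] + eff))
      mut <- switch(g, WT = "", missense = "missense",
                    truncating = sample(TRUNCATING_CLASSES, 1L))
      pid <- if (paired) sprintf("P%04d", k) else NA_character_
      ann <- rbind(ann, data.frame(
        sample_id = sid, cohort = "tumor", stratum = s,
        mutation_class = mut,
        log2_cn_ratio = round(stats::rnorm(1L, 0, 0.2), 3),
        expression_rsem = round(stats::runif(1L, 500, 3000), 1),
        pair_id = pid, stringsAsFactors = FALSE))
      cnt[[sid]] <- draw_counts(sid, p, utr5_fraction_true)
      tru <- rbind(tru, data.frame(sample_id = sid, stratum = s, group = g,
                                   true_fraction = p, stringsAsFactors = FALSE))
      if (paired) {
        nid <- paste0(sid, "_N")
        pn <- min(1, max(0, base[[s]] + normal_effect))
        ann <- rbind(ann, data.frame(
          sample_id = nid, cohort = "normal", stratum = s,
          mutation_class = "", log2_cn_ratio = NA_real_,
          expression_rsem = NA_real_, pair_id = pid,
          stringsAsFactors = FALSE))
        cnt[[nid]] <- draw_counts(nid, pn, utr5_fraction_true)
        tru <- rbind(tru, data.frame(sample_id = nid, stratum = s,
                                     group = "normal", true_fraction = pn,
                                     stringsAsFactors = FALSE))
      }
    }
    list(annotations = ann, counts = unname(cnt), truth = tru)
  })
}
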