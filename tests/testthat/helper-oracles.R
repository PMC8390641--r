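# Independent closed-form oracles and small fixture builders shared by the
# test files. The oracles deliberately avoid the code paths they check.

# Welch t-test from the textbook formula (no call into stats::t.test)
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# paired t-test as a one-sample t on differences, from the formula
paired_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

# junction_counts with only the averaged-pair and utr5 labels filled in
make_counts <- function(catalog, sample_id, d1, d2, m, du = 0L, mu = 0L) {
  cts <- stats::setNames(integer(nrow(catalog$junctions)),
                         catalog$junctions$label)
  cts[catalog$cterm_pair[1]] <- d1
  cts[catalog$cterm_pair[2]] <- d2
  cts[catalog$cterm_main] <- m
  cts[catalog$utr5_distinct] <- du
  cts[catalog$utr5_main] <- mu
  junction_counts(sample_id, cts)
}

# minimal plus-strand three/four-exon model written as a JSON string
write_toy_model_json <- function(path, transcripts, chrom = "chrZ") {
  doc <- list(chrom = chrom, transcripts = transcripts)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

# one synthetic alignment record for classify_read
rec <- function(pos, cigar, flag = 0L, nm = 0L, md = NA_character_,
                seq_len = NA_integer_, read_id = "r1") {
  list(read_id = read_id, flag = flag, pos = pos, cigar = cigar,
       nm = nm, md = md, seq_len = seq_len)
}
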