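# A junction at donor_end = 1049, acceptor_start = 1650 on "chrZ" (intron
# 1050..1649, i.e. 600 bp) used by most cases below.
toy_junction <- list(chrom = "chrZ", donor_end = 1049L, acceptor_start = 1650L,
                     label = "chrZ:1049-1650")

test_that("read_blocks decomposes CIGARs into genomic blocks", {
  b <- read_blocks("50M600N51M", 1000L)
  expect_identical(b$blocks$start, c(1000L, 1650L))
  expect_identical(b$blocks$end, c(1049L, 1700L))
  expect_identical(b$blocks$aligned, c(50L, 51L))
  expect_identical(b$softclip_total, 0L)
  expect_false(b$has_indel)

  b2 <- read_blocks("30S40M600N31M", 1010L)
  expect_identical(b2$blocks$aligned, c(40L, 31L))
  expect_identical(b2$softclip_total, 30L)
  expect_identical(b2$seq_len, 101L)

  b3 <- read_blocks("50M1I50M", 1000L)
  expect_identical(nrow(b3$blocks), 1L)   # insertion does not split the block
  expect_true(b3$has_indel)
  expect_identical(b3$blocks$aligned, 100L)
})

test_that("the junction-read rule accepts exact, clean, well-flanked reads only", {
  p <- counting_params()
  # all criteria met by construction
  v <- classify_read(rec(1000L, "50M600N50M"), toy_junction, p)
  expect_true(v$accepted)
  expect_true(is.na(v$reject_reason))
  # 5 nt downstream flank: rejected even though the boundary is exact
  v <- classify_read(rec(955L, "95M600N5M"), toy_junction, p)
  expect_false(v$accepted)
  expect_identical(v$reject_reason, "short_flank")
  # 60 of 100 bases soft-clipped
  v <- classify_read(rec(1030L, "60S20M600N20M"), toy_junction, p)
  expect_identical(v$reject_reason, "excess_softclip")
  # exactly half soft-clipped passes (inclusive boundary)
  v <- classify_read(rec(1025L, "50S25M600N25M"), toy_junction, p)
  expect_true(v$accepted)
  # edit distance 1
  v <- classify_read(rec(1000L, "50M600N50M", nm = 1L), toy_junction, p)
  expect_identical(v$reject_reason, "has_mismatch")
  # insertion
  v <- classify_read(rec(1000L, "25M1I25M600N50M"), toy_junction, p)
  expect_identical(v$reject_reason, "has_indel")
  # splice boundary offset by +1
  v <- classify_read(rec(1001L, "50M600N50M"), toy_junction, p)
  expect_identical(v$reject_reason, "breakpoint_mismatch")
  # unspliced read
  v <- classify_read(rec(1000L, "100M"), toy_junction, p)
  expect_identical(v$reject_reason, "no_splice")
  # unmapped / secondary flags
  expect_identical(classify_read(rec(1000L, "50M600N50M", flag = 4L),
                                 toy_junction, p)$reject_reason, "unmapped")
  expect_identical(classify_read(rec(1000L, "50M600N50M", flag = 256L),
                                 toy_junction, p)$reject_reason, "secondary")
})

test_that("missing NM tag policy: strict rejects, permissive falls back to MD", {
  strict <- counting_params(nm_mode = "strict")
  perm <- counting_params(nm_mode = "permissive")
  r_no_tags <- rec(1000L, "50M600N50M", nm = NA_integer_)
  expect_identical(classify_read(r_no_tags, toy_junction, strict)$reject_reason,
                   "has_mismatch")
  r_md_clean <- rec(1000L, "50M600N50M", nm = NA_integer_, md = "100")
  expect_identical(classify_read(r_md_clean, toy_junction, strict)$reject_reason,
                   "has_mismatch")
  expect_true(classify_read(r_md_clean, toy_junction, perm)$accepted)
  r_md_mm <- rec(1000L, "50M600N50M", nm = NA_integer_, md = "40A59")
  expect_identical(classify_read(r_md_mm, toy_junction, perm)$reject_reason,
                   "has_mismatch")
})

test_that("counting a hand-built SAM matches known truth, with audit", {
  loc <- make_toy_locus(seed = 5)
  catalog <- derive_junctions(loc$model)
  jt <- catalog$junctions
  main_j <- jt[jt$label == catalog$cterm_main, ]
  beta_j <- jt[jt$label == catalog$cterm_pair[1], ]
  chrom <- loc$chrom
  qlen <- function(cigar) {   # read length implied by CIGAR (M/I/S ops)
    ops <- strsplit(gsub("[0-9]+", "", cigar), "")[[1]]
    lens <- as.integer(strsplit(cigar, "[A-Z]")[[1]])
    sum(lens[ops %in% c("M", "I", "S")])
  }
  line <- function(id, pos, cigar, nm = 0L, flag = 0L) {
    seq <- strrep("A", qlen(cigar))
    paste(id, flag, chrom, pos, 60, cigar, "*", 0, 0, seq,
          strrep("I", nchar(seq)), paste0("NM:i:", nm), sep = "\t")
  }
  span <- function(j, fl_up, fl_dn)   # CIGAR crossing junction j
    list(pos = j$donor_end - fl_up + 1L,
         cigar = sprintf("%dM%dN%dM", fl_up,
                         j$acceptor_start - j$donor_end - 1L, fl_dn))
  m1 <- span(main_j, 40L, 36L); m2 <- span(main_j, 25L, 51L)
  m3 <- span(main_j, 12L, 64L); b1 <- span(beta_j, 30L, 46L)
  near <- span(main_j, 9L, 67L)       # 9 nt flank: near-miss
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", chrom, "\tLN:", Biostrings::width(loc$seq)[1]),
               line("q1", m1$pos, m1$cigar), line("q2", m2$pos, m2$cigar),
               line("q3", m3$pos, m3$cigar), line("q4", b1$pos, b1$cigar),
               line("q5", near$pos, near$cigar)), sam)
  jc <- count_junction_reads(sam, catalog, sample_id = "fix", audit = TRUE)
  expect_identical(unname(jc$counts[catalog$cterm_main]), 3L)
  expect_identical(unname(jc$counts[catalog$cterm_pair[1]]), 1L)
  expect_identical(sum(jc$counts), 4L)
  expect_identical(jc$total_reads_scanned, 5L)
  expect_identical(jc$audit$reject_reason[jc$audit$read_id == "q5"],
                   "short_flank")
})

test_that("counts are invariant to read order", {
  loc <- make_toy_locus(seed = 6)
  catalog <- derive_junctions(loc$model)
  mix <- mixture_config(c(MAIN = 0.8, ALTCT = 0.1, ALTU5 = 0.1),
                        n_reads = 500, softclip_rate = 0.2,
                        mismatch_rate = 0.1, offset_error_rate = 0.1,
                        seed = 21)
  sim <- simulate_alignments(loc, mix, catalog)
  lines <- readLines(sim$sam_path)
  hdr <- grepl("^@", lines)
  shuffled <- tempfile(fileext = ".sam")
  set.seed(1)
  writeLines(c(lines[hdr], sample(lines[!hdr])), shuffled)
  c1 <- count_junction_reads(sim$sam_path, catalog)
  c2 <- count_junction_reads(shuffled, catalog)
  expect_identical(c1$counts, c2$counts)
})

test_that("relaxing flank or soft-clip thresholds never decreases counts", {
  loc <- make_toy_locus(seed = 8)
  catalog <- derive_junctions(loc$model)
  mix <- mixture_config(c(MAIN = 0.7, ALTCT = 0.2, ALTG = 0.1),
                        n_reads = 800, softclip_rate = 0.4,
                        softclip_len_range = c(10L, 40L),
                        mismatch_rate = 0.1, seed = 31)
  sim <- simulate_alignments(loc, mix, catalog)
  aln <- read_alignments(sim$sam_path)
  base <- count_junction_reads(aln, catalog, counting_params())$counts
  for (p in list(counting_params(min_flank = 5L),
                 counting_params(min_flank = 1L),
                 counting_params(max_softclip_fraction = 0.8),
                 counting_params(min_flank = 1L, max_softclip_fraction = 1))) {
    relaxed <- count_junction_reads(aln, catalog, p)$counts
    expect_true(all(relaxed >= base))
  }
})

test_that("flag filters: duplicates counted by default, secondary excluded", {
  loc <- make_toy_locus(seed = 5)
  catalog <- derive_junctions(loc$model)
  j <- catalog$junctions[catalog$junctions$label == catalog$cterm_main, ]
  cigar <- sprintf("40M%dN40M", j$acceptor_start - j$donor_end - 1L)
  pos <- j$donor_end - 39L
  line <- function(id, flag) paste(id, flag, loc$chrom, pos, 60, cigar, "*",
                                   0, 0, strrep("A", 80), strrep("I", 80),
                                   "NM:i:0", sep = "\t")
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", loc$chrom, "\tLN:",
                      Biostrings::width(loc$seq)[1]),
               line("a", 0L), line("b", 1024L), line("c", 256L),
               line("d", 2048L)), sam)
  aln <- read_alignments(sam)
  deft <- count_junction_reads(aln, catalog)
  expect_identical(unname(deft$counts[catalog$cterm_main]), 2L) # a + dup b
  nodup <- count_junction_reads(aln, catalog,
                                counting_params(count_duplicates = FALSE))
  expect_identical(unname(nodup$counts[catalog$cterm_main]), 1L)
  sec <- count_junction_reads(aln, catalog,
                              counting_params(count_secondary = TRUE))
  expect_identical(unname(sec$counts[catalog$cterm_main]), 3L)
})

test_that("empty input and foreign chromosomes give zero counts", {
  loc <- make_toy_locus(seed = 5)
  catalog <- derive_junctions(loc$model)
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", loc$chrom, "\tLN:",
                      Biostrings::width(loc$seq)[1])), sam)
  jc <- count_junction_reads(sam, catalog)
  expect_true(all(jc$counts == 0L))
  expect_identical(jc$total_reads_scanned, 0L)
  other <- data.frame(read_id = "x", flag = 0L, rname = "chrOther",
                      pos = 100L, cigar = "40M100N40M", seq_len = 80L,
                      nm = 0L, md = NA_character_)
  expect_warning(jc2 <- count_junction_reads(other, catalog),
                 "no alignment uses a catalog chromosome")
  expect_true(all(jc2$counts == 0L))
})

test_that("counts TSV round-trips through write/read", {
  loc <- make_toy_locus(seed = 5)
  catalog <- derive_junctions(loc$model)
  a <- make_counts(catalog, "s1", 2L, 4L, 90L, 1L, 99L)
  b <- make_counts(catalog, "s2", 0L, 0L, 50L)
  path <- tempfile(fileext = ".tsv")
  write_junction_counts(list(a, b), path)
  back <- read_junction_counts(path)
  expect_identical(back$s1$counts, a$counts)
  expect_identical(back$s2$counts, b$counts)
})
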