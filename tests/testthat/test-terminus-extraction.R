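# Hand-written SAM fixtures lock the strand/position convention: the
# terminus is read 2's first sequenced base and its strand is opposite the
# read-2 alignment strand.

write_sam <- function(records, path, contigs = c(chr1 = 1000)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  writeLines(c(hdr, records), path)
}

rec <- function(qname, flag, pos, cigar, seq) {
  sprintf("%s\t%d\tchr1\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
          qname, flag, pos, cigar, seq, strrep("I", nchar(seq)))
}

test_that("terminus position and strand follow the read-2 convention", {
  f <- tempfile(fileext = ".sam")
  write_sam(c(
    rec("p", 129, 101, "50M", strrep("A", 50)),    # + strand [100,150)
    rec("m", 145, 201, "50M", strrep("A", 50))),   # - strand [200,250)
    f)
  aln <- read_read2_alignments(f)
  expect_equal(nrow(aln), 2)
  term <- terminus_from_alignments(aln)
  plus <- term[aln$strand == "+", ]
  minus <- term[aln$strand == "-", ]
  expect_equal(plus$position, 100)
  expect_equal(plus$strand, "-")
  expect_equal(minus$position, 249)
  expect_equal(minus$strand, "+")
})

test_that("non-unique, clipped and first-mate records are excluded", {
  f <- tempfile(fileext = ".sam")
  write_sam(c(
    rec("ok", 129, 101, "50M", strrep("A", 50)),
    rec("low", 129, 111, "50M", strrep("A", 50)),
    rec("sec", 385, 121, "50M", strrep("A", 50)),      # 0x100 secondary
    rec("mate1", 65, 131, "50M", strrep("A", 50)),     # first in pair
    rec("clipP", 129, 141, "5S45M", strrep("A", 50)),  # leading clip, +
    rec("clipM", 145, 151, "45M5S", strrep("A", 50))), # trailing clip, -
    f)
  # mark "low" as MAPQ 3
  lines <- readLines(f)
  lines[grepl("^low", lines)] <- sub("\t60\t", "\t3\t",
                                     lines[grepl("^low", lines)])
  writeLines(lines, f)

  aln <- read_read2_alignments(f, min_mapq = 20)
  expect_setequal(aln$qname, c("ok", "clipP", "clipM"))
  expect_equal(sum(aln$clipped_start), 2)
  term <- terminus_from_alignments(aln)
  expect_equal(nrow(term), 1)  # clipped starts are dropped by default
  expect_equal(nrow(terminus_from_alignments(aln, keep_clipped = TRUE)), 3)
})

test_that("clipped minus-strand spans use the reference width of the CIGAR", {
  f <- tempfile(fileext = ".sam")
  # 10M5D30M consumes 45 reference bases from pos 101 -> span [100,145)
  write_sam(rec("d", 145, 101, "10M5D30M", strrep("A", 40)), f)
  aln <- read_read2_alignments(f)
  expect_equal(aln$end, 145)
  expect_equal(terminus_from_alignments(aln)$position, 144)
})

test_that("the priming filter applies the strict >40% upstream-T rule", {
  # build a genome with exact window compositions around chosen termini
  base <- strrep("C", 400)
  seq <- paste0(
    substr(base, 1, 100),
    paste(rep(c("T", "G"), c(9, 11))[sample.int(20)], collapse = ""),
    substr(base, 1, 80))
  g <- DNAStringSet(setNames(seq, "chrP"))

  win <- function(p) as.character(subseq(g[["chrP"]], p - 19, p))
  # terminus strand "-" at 0-based 120: upstream window is [100,120) = 9 T
  tt <- terminus_table("chrP", 120, "-")
  out <- apply_priming_filter(tt, g)
  expect_equal(nrow(out), 0)   # 9/20 = 45% > 40% -> drop

  # 8 of 20 (40%) survives the strict inequality
  seq2 <- paste0(substr(base, 1, 100),
                 paste(rep(c("T", "G"), c(8, 12)), collapse = ""),
                 substr(base, 1, 80))
  g2 <- DNAStringSet(setNames(seq2, "chrP"))
  expect_equal(nrow(apply_priming_filter(tt, g2)), 1)

  # truncated window at the contig edge: 5 T of 10 available = 50% -> drop
  seq3 <- paste0(strrep("T", 5), strrep("C", 5), strrep("A", 100),
                 substr(base, 1, 300))
  g3 <- DNAStringSet(setNames(seq3, "chrP"))
  expect_equal(nrow(apply_priming_filter(
    terminus_table("chrP", 10, "-"), g3)), 0)

  # plus-strand terminus reads the downstream window as the read-2 strand:
  # A-rich downstream on the reference means T-rich upstream of read 2
  seq4 <- paste0(substr(base, 1, 200), strrep("A", 20),
                 substr(base, 1, 100))
  g4 <- DNAStringSet(setNames(seq4, "chrP"))
  expect_equal(nrow(apply_priming_filter(
    terminus_table("chrP", 199, "+"), g4)), 0)
  expect_equal(nrow(apply_priming_filter(
    terminus_table("chrP", 199, "-"), g4)), 1)
})

test_that("extract_termini aggregates and records the aligned denominator", {
  f <- tempfile(fileext = ".sam")
  write_sam(c(
    rec("a", 129, 101, "50M", strrep("A", 50)),
    rec("b", 129, 101, "50M", strrep("A", 50)),
    rec("c", 129, 101, "50M", strrep("A", 50)),
    rec("d", 145, 201, "50M", strrep("A", 50))),
    f)
  tab <- extract_termini(f, sample_id = "s1", dose_label = "0.1U")
  expect_equal(unique_sites(tab), 2)
  expect_equal(total_termini(tab), 4)
  expect_equal(tab$count[tab$position == 100], 3)
  expect_equal(attr(tab, "total_aligned"), 4)
  nn <- normalize_counts(tab)
  expect_equal(sum(nn$normalized_count), 4 / 4 * 1e6)
})
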