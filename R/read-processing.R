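# Structural filtering and tag trimming of polyG/polyT anchored paired-end
# reads. The library chemistry leaves a 9-11 G anchor at the start of read 1
# and an 11-13 T anchor at the start of read 2; both are required and then
# trimmed before alignment.

#' Read-pair filter configuration
#'
#' Defaults encode the published filtering rules: reject pairs containing an
#' adaptor substring, pairs where either mate has more than 10% N bases or
#' more than 50% bases with Phred quality <= 5; then require the tag
#' structure (read 1 leading G-run of 9-11, read 2 leading T-run of 11-13)
#' and every base of both mates to have Phred quality strictly greater
#' than 20.
#'
#' @param adaptors Character vector of adaptor substrings to screen for
#'   (default: the Illumina TruSeq read-through adaptor stem).
#' @param g_run Accepted read-1 leading G-run length range (inclusive).
#' @param t_run Accepted read-2 leading T-run length range (inclusive).
#' @param min_q Per-base Phred floor; bases must be strictly greater.
#' @param max_n_frac Maximum tolerated N fraction per mate.
#' @param low_q Quality at or below which a base counts as low-quality.
#' @param max_low_q_frac Maximum tolerated low-quality-base fraction.
#' @param phred_offset ASCII offset of the quality encoding (33 = Sanger).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(adaptors = "AGATCGGAAGAGC",
                          g_run = c(9L, 11L), t_run = c(11L, 13L),
                          min_q = 20L, max_n_frac = 0.10,
                          low_q = 5L, max_low_q_frac = 0.50,
                          phred_offset = 33L) {
  stopifnot(length(g_run) == 2, length(t_run) == 2,
            g_run[1] <= g_run[2], t_run[1] <= t_run[2])
  structure(list(adaptors = toupper(adaptors), g_run = g_run, t_run = t_run,
                 min_q = min_q, max_n_frac = max_n_frac, low_q = low_q,
                 max_low_q_frac = max_low_q_frac,
                 phred_offset = phred_offset),
            class = "filter_config")
}

# Length of the maximal leading run of `base` (case-insensitive; N does not
# extend a run).
leading_run_length <- function(seq, base) {
  m <- regexpr(paste0("^[", toupper(base), tolower(base), "]+"), seq)
  ifelse(m == -1L, 0L, attr(m, "match.length"))
}

phred_scores <- function(qual, offset = 33L) {
  lapply(qual, function(x) utf8ToInt(x) - offset)
}

#' Classify read pairs against the structural and quality rules
#'
#' Rules are applied in a fixed order so reject-reason counters are
#' deterministic: `adaptor`, then `n_fraction`, then `low_quality`, then
#' `tag_structure`, then `base_quality`. A pair is kept only if all pass.
#' Malformed pairs (length mismatch between sequence and quality, or empty
#' reads) are rejected with reason `malformed`.
#'
#' @param r1_seq,r1_qual,r2_seq,r2_qual Character vectors of mate sequences
#'   and Phred+33 quality strings, in pair order.
#' @param config A [filter_config()].
#' @return Character vector per pair: `"keep"` or the first failing reason.
#' @export
classify_read_pairs <- function(r1_seq, r1_qual, r2_seq, r2_qual,
                                config = filter_config()) {
  n <- length(r1_seq)
  stopifnot(length(r1_qual) == n, length(r2_seq) == n, length(r2_qual) == n)
  if (n == 0) return(character())
  out <- rep("keep", n)

  malformed <- nchar(r1_seq) != nchar(r1_qual) |
    nchar(r2_seq) != nchar(r2_qual) |
    nchar(r1_seq) == 0 | nchar(r2_seq) == 0
  out[malformed] <- "malformed"
  todo <- !malformed

  s1 <- toupper(r1_seq); s2 <- toupper(r2_seq)

  has_adaptor <- rep(FALSE, n)
  for (ad in config$adaptors) {
    has_adaptor <- has_adaptor | grepl(ad, s1, fixed = TRUE) |
      grepl(ad, s2, fixed = TRUE)
  }
  out[todo & has_adaptor] <- "adaptor"
  todo <- todo & !has_adaptor

  n_frac <- function(s) {
    (nchar(s) - nchar(gsub("N", "", s, fixed = TRUE))) / pmax(nchar(s), 1L)
  }
  bad_n <- n_frac(s1) > config$max_n_frac | n_frac(s2) > config$max_n_frac
  out[todo & bad_n] <- "n_fraction"
  todo <- todo & !bad_n

  q1 <- phred_scores(r1_qual, config$phred_offset)
  q2 <- phred_scores(r2_qual, config$phred_offset)
  lowq_frac <- function(q) {
    vapply(q, function(x) if (length(x) == 0) 0 else mean(x <= config$low_q),
           0)
  }
  bad_lowq <- lowq_frac(q1) > config$max_low_q_frac |
    lowq_frac(q2) > config$max_low_q_frac
  out[todo & bad_lowq] <- "low_quality"
  todo <- todo & !bad_lowq

  g <- leading_run_length(s1, "G")
  t <- leading_run_length(s2, "T")
  bad_tag <- g < config$g_run[1] | g > config$g_run[2] |
    t < config$t_run[1] | t > config$t_run[2]
  out[todo & bad_tag] <- "tag_structure"
  todo <- todo & !bad_tag

  # Per-base floor applies to the untrimmed reads, strictly greater-than.
  minq <- function(q) {
    vapply(q, function(x) if (length(x) == 0) -Inf else min(x), 0)
  }
  bad_q <- !(minq(q1) > config$min_q & minq(q2) > config$min_q)
  out[todo & bad_q] <- "base_quality"

  out
}

#' Trim the polyG/polyT tags from kept pairs
#'
#' Removes the maximal leading G-run from read 1 and the maximal leading
#' T-run from read 2, trimming qualities in lockstep. Pairs that would be
#' emptied are rejected with reason `too_short`.
#'
#' @inheritParams classify_read_pairs
#' @return A list with trimmed `r1_seq`, `r1_qual`, `r2_seq`, `r2_qual` and a
#'   logical `too_short` flag per pair.
#' @export
trim_tag_pairs <- function(r1_seq, r1_qual, r2_seq, r2_qual) {
  g <- leading_run_length(r1_seq, "G")
  t <- leading_run_length(r2_seq, "T")
  too_short <- g >= nchar(r1_seq) | t >= nchar(r2_seq)
  list(r1_seq = substring(r1_seq, g + 1),
       r1_qual = substring(r1_qual, g + 1),
       r2_seq = substring(r2_seq, t + 1),
       r2_qual = substring(r2_qual, t + 1),
       too_short = too_short)
}

read_fastq_ <- function(path) {
  x <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(id = names(x), seq = as.character(x),
       qual = as.character(mcols(x)$qualities))
}

write_fastq_ <- function(id, seq, qual, path) {
  x <- DNAStringSet(seq)
  names(x) <- id
  writeXStringSet(x, path, format = "fastq", qualities = BStringSet(qual))
  invisible(path)
}

#' Filter and trim a FASTQ pair
#'
#' Streams both mate files through [classify_read_pairs()] and
#' [trim_tag_pairs()], writing only kept, trimmed pairs, and returns a
#' report whose per-reason counters sum to the number of input pairs.
#'
#' @param fq1,fq2 Input FASTQ paths (mates in the same order; gzip is
#'   transparent).
#' @param out1,out2 Output FASTQ paths for the trimmed kept pairs.
#' @param config A [filter_config()].
#' @return A `filter_report`: list with `total`, `kept` and a named
#'   `counters` vector of rejected pairs per reason.
#' @export
process_fastq_pair <- function(fq1, fq2, out1, out2,
                               config = filter_config()) {
  a <- read_fastq_(fq1)
  b <- read_fastq_(fq2)
  if (length(a$id) != length(b$id)) {
    stop(sprintf(
      "desynchronized mate files: %d vs %d records (first divergence at record %d)",
      length(a$id), length(b$id), min(length(a$id), length(b$id)) + 1L))
  }
  core <- function(id) sub("[/ ].*$", "", id)
  if (length(a$id) > 0 && any(core(a$id) != core(b$id))) {
    i <- which(core(a$id) != core(b$id))[1]
    stop(sprintf("desynchronized mate files at record %d: '%s' vs '%s'",
                 i, a$id[i], b$id[i]))
  }
  verdict <- classify_read_pairs(a$seq, a$qual, b$seq, b$qual, config)
  keep <- verdict == "keep"
  tr <- trim_tag_pairs(a$seq[keep], a$qual[keep], b$seq[keep], b$qual[keep])
  if (any(tr$too_short)) {
    # structurally valid but nothing left after tag removal
    idx <- which(keep)[tr$too_short]
    verdict[idx] <- "too_short"
    keep <- verdict == "keep"
    ok <- !tr$too_short
    tr <- lapply(tr[c("r1_seq", "r1_qual", "r2_seq", "r2_qual")],
                 `[`, ok)
  }
  write_fastq_(a$id[keep], tr$r1_seq, tr$r1_qual, out1)
  write_fastq_(b$id[keep], tr$r2_seq, tr$r2_qual, out2)
  rejected <- table(verdict[verdict != "keep"])
  report <- structure(
    list(total = length(verdict), kept = sum(keep),
         counters = setNames(as.integer(rejected), names(rejected))),
    class = "filter_report")
  stopifnot(report$kept + sum(report$counters) == report$total)
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d/%d pairs kept\n", x$kept, x$total))
  if (length(x$counters)) {
    for (r in names(x$counters)) {
      cat(sprintf("  rejected %-14s %d\n", r, x$counters[[r]]))
    }
  }
  invisible(x)
}
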