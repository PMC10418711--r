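# From paired alignments to a terminus table. The tailing/priming chemistry
# makes sequenced read 2 the reverse complement of the broken-strand segment
# that ends at the 3'-OH, so:
#   * the terminus position is read 2's first sequenced base (leftmost
#     reference base for + alignments, rightmost for - alignments), and
#   * the terminus strand is the opposite of the read-2 alignment strand.
# This convention is isolated here and locked by synthetic-alignment tests.

#' Internal-priming filter configuration
#'
#' Oligo-dT priming on genomic A-rich tracts mimics a genuine tailed
#' terminus. A terminus is discarded when the fraction of Ts in the 20
#' reference bases immediately 5' of the terminus, read along the read-2
#' alignment strand, is strictly greater than 40%.
#'
#' @param window Upstream window length in bp.
#' @param max_t_fraction Strict upper bound on the window T fraction.
#' @return A list of class `priming_filter_config`.
#' @export
priming_filter_config <- function(window = 20L, max_t_fraction = 0.40) {
  stopifnot(window >= 1, max_t_fraction > 0, max_t_fraction < 1)
  structure(list(window = as.integer(window),
                 max_t_fraction = max_t_fraction),
            class = "priming_filter_config")
}

cigar_first_op <- function(cigar) sub("^[0-9]+([A-Z=]).*$", "\\1", cigar)
cigar_last_op <- function(cigar) sub("^.*[0-9]+([A-Z=])$", "\\1", cigar)

#' Read read-2 alignments from SAM/BAM
#'
#' Loads the second-in-pair alignments that satisfy the uniqueness criteria:
#' mapped, primary, not supplementary, and MAPQ at or above `min_mapq`.
#' SAM input is converted on the fly. Alignments whose first sequenced base
#' (5'-most in read orientation) is soft- or hard-clipped are flagged with
#' `clipped_start = TRUE`; such termini have ambiguous positions and are
#' excluded downstream by default.
#'
#' @param path SAM or BAM file.
#' @param min_mapq Minimum mapping quality treated as "uniquely mapped".
#' @return A data.frame with columns `qname`, `contig`, `strand`, `start`
#'   (0-based), `end` (0-based exclusive), `mapq`, `clipped_start`, plus an
#'   attribute `n_aligned` (read-2 alignments passing the flag/MAPQ filter).
#' @export
read_read2_alignments <- function(path, min_mapq = 20L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(asBam(path, destination = dest,
                                  overwrite = TRUE, indexDestination = FALSE))
  }
  param <- ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar"),
    flag = scanBamFlag(isUnmappedQuery = FALSE, isSecondMateRead = TRUE,
                       isSecondaryAlignment = FALSE,
                       isSupplementaryAlignment = FALSE))
  res <- scanBam(bam, param = param)[[1]]
  mapq <- res$mapq
  mapq[is.na(mapq)] <- 0L
  keep <- mapq >= min_mapq
  cigar <- res$cigar[keep]
  str <- as.character(res$strand)[keep]
  refw <- cigarWidthAlongReferenceSpace(cigar)
  start0 <- res$pos[keep] - 1L
  clipped <- ifelse(str == "+",
                    cigar_first_op(cigar) %in% c("S", "H"),
                    cigar_last_op(cigar) %in% c("S", "H"))
  out <- data.frame(qname = res$qname[keep],
                    contig = as.character(res$rname)[keep],
                    strand = str,
                    start = start0,
                    end = start0 + refw,
                    mapq = mapq[keep],
                    clipped_start = clipped,
                    stringsAsFactors = FALSE)
  attr(out, "n_aligned") <- nrow(out)
  out
}

#' Derive 3'-OH terminus sites from read-2 alignments
#'
#' For a + alignment spanning `[s, e)` the terminus is `(contig, s, "-")`;
#' for a - alignment it is `(contig, e - 1, "+")`.
#'
#' @param aln Data.frame from [read_read2_alignments()].
#' @param keep_clipped Include alignments whose first sequenced base is
#'   clipped (default `FALSE`: ambiguous positions are excluded).
#' @return A data.frame with `contig`, `position`, `strand` (terminus
#'   strand), one row per alignment.
#' @export
terminus_from_alignments <- function(aln, keep_clipped = FALSE) {
  if (!keep_clipped) aln <- aln[!aln$clipped_start, , drop = FALSE]
  plus <- aln$strand == "+"
  data.frame(contig = aln$contig,
             position = ifelse(plus, aln$start, aln$end - 1),
             strand = ifelse(plus, "-", "+"),
             stringsAsFactors = FALSE)
}

#' Apply the A-rich internal-priming filter
#'
#' Examines the reference bases immediately 5' of each terminus along the
#' read-2 alignment strand (the strand opposite the terminus strand) and
#' drops sites whose T fraction exceeds the configured bound. Near contig
#' edges the available bases are used with the same fraction rule.
#'
#' @param table A [terminus_table].
#' @param genome A `DNAStringSet` holding the reference sequences.
#' @param cfg A [priming_filter_config()].
#' @return The filtered [terminus_table]; the number of dropped sites is
#'   recorded in attribute `priming_dropped`.
#' @export
apply_priming_filter <- function(table, genome,
                                 cfg = priming_filter_config()) {
  stopifnot(is_terminus_table(table), is(genome, "DNAStringSet"))
  if (nrow(table) == 0) return(table)
  w <- cfg$window
  drop <- logical(nrow(table))
  glen <- genome_of(genome)
  for (ctg in unique(table$contig)) {
    idx <- which(table$contig == ctg)
    pos <- table$position[idx]
    str <- table$strand[idx]
    len <- glen[[ctg]]
    # terminus strand "-": read 2 aligned +, upstream is [pos-w, pos) on +,
    # count T. terminus strand "+": read 2 aligned -, upstream is
    # [pos+1, pos+1+w) read on -, i.e. count A on the + reference.
    s1 <- ifelse(str == "-", pmax(pos - w, 0), pmin(pos + 1, len))
    e1 <- ifelse(str == "-", pos, pmin(pos + 1 + w, len))
    have <- e1 - s1
    frac <- numeric(length(idx))
    nonempty <- have > 0
    if (any(nonempty)) {
      ir <- IRanges(s1[nonempty] + 1, e1[nonempty])
      views <- extractAt(genome[[ctg]], ir)
      tcount <- ifelse(str[nonempty] == "-",
                       letterFrequency(views, "T")[, 1],
                       letterFrequency(views, "A")[, 1])
      frac[nonempty] <- tcount / have[nonempty]
    }
    drop[idx] <- frac > cfg$max_t_fraction
  }
  out <- table[!drop, , drop = FALSE]
  out <- terminus_table(out$contig, out$position, out$strand, out$count,
                        sample_id = attr(table, "sample_id"),
                        dose_label = attr(table, "dose_label"),
                        total_aligned = attr(table, "total_aligned"))
  attr(out, "priming_dropped") <- sum(drop)
  out
}

#' Extract a terminus table from paired alignments
#'
#' Convenience pipeline: read read-2 alignments, derive termini, optionally
#' apply the internal-priming filter, aggregate into a [terminus_table] and
#' record the aligned-read denominator for normalization.
#'
#' @param path SAM or BAM file.
#' @param sample_id,dose_label Sample metadata.
#' @param genome Optional `DNAStringSet`; when supplied the priming filter
#'   runs against it.
#' @param min_mapq Uniqueness MAPQ floor.
#' @param priming A [priming_filter_config()].
#' @return A [terminus_table] with `total_aligned` set to the number of
#'   qualifying read-2 alignments.
#' @export
extract_termini <- function(path, sample_id = NA_character_,
                            dose_label = NA_character_, genome = NULL,
                            min_mapq = 20L,
                            priming = priming_filter_config()) {
  aln <- read_read2_alignments(path, min_mapq = min_mapq)
  term <- terminus_from_alignments(aln)
  tab <- terminus_table(term$contig, term$position, term$strand,
                        sample_id = sample_id, dose_label = dose_label,
                        total_aligned = attr(aln, "n_aligned"))
  if (!is.null(genome)) tab <- apply_priming_filter(tab, genome, priming)
  tab
}
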