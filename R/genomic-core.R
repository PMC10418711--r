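# Shared coordinate model: interval sets as GRanges (0-based half-open at the
# API surface, BED convention) and 3'-OH terminus tables.

#' Build a genomic interval set
#'
#' Interval sets are represented as [GenomicRanges::GRanges] objects. All
#' coordinates at the package surface follow the BED convention: 0-based,
#' half-open `[start, end)`. A genome (named vector of contig lengths) can be
#' bound to the set, in which case every interval is checked against its
#' contig length.
#'
#' @param contig Character vector of contig names.
#' @param start,end Integer vectors; 0-based half-open coordinates with
#'   `0 <= start < end`.
#' @param strand Strand of each interval: `"+"`, `"-"` or `"*"` (unstranded,
#'   the default).
#' @param label Optional free-text label per interval (stored as `name`).
#' @param genome Optional named vector of contig lengths in bp.
#' @return A `GRanges` object with `seqlengths` set when `genome` is given.
#' @examples
#' gset <- interval_set("chr1", 0, 100, genome = c(chr1 = 1000))
#' @export
interval_set <- function(contig, start, end, strand = "*", label = NULL,
                         genome = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("interval %d is empty or inverted (start=%d end=%d); ",
                 bad, start[bad], end[bad]),
         "intervals are half-open and must be non-empty")
  }
  gr <- GRanges(contig, IRanges(start + 1, end), strand = strand)
  if (!is.null(label)) mcols(gr)$name <- label
  if (!is.null(genome)) gr <- bind_genome(gr, genome)
  sort(gr, ignore.strand = TRUE)
}

#' Attach contig lengths to an interval set
#'
#' @param gr A `GRanges` object.
#' @param genome Named vector of contig lengths.
#' @return `gr` with `seqlengths` set; errors if an interval exceeds its
#'   contig length or names an unknown contig.
#' @export
bind_genome <- function(gr, genome) {
  ctg <- as.character(seqnames(gr))
  unknown <- setdiff(unique(ctg), names(genome))
  if (length(unknown) > 0) {
    stop("contig(s) not in genome table: ", paste(unknown, collapse = ", "))
  }
  over <- end(gr) > genome[ctg]
  if (any(over)) {
    i <- which(over)[1]
    stop(sprintf("interval %d on %s ends at %d, beyond contig length %d",
                 i, ctg[i], end(gr)[i], genome[ctg[i]]))
  }
  gr2 <- GRanges(ctg, IRanges(start(gr), end(gr)), strand = strand(gr),
                 seqinfo = Seqinfo(names(genome),
                                   seqlengths = as.integer(genome)))
  mcols(gr2) <- mcols(gr)
  gr2
}

#' Read a genome table (contig lengths)
#'
#' Accepts a two-column TSV (`contig`, `length`) or a FASTA index (`.fai`,
#' first two columns used).
#'
#' @param path Path to the table.
#' @return Named integer vector of contig lengths.
#' @export
read_genome_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  setNames(as.integer(tab[[2]]), as.character(tab[[1]]))
}

#' Contig lengths of a sequence set
#'
#' @param seqs A `DNAStringSet` (e.g. a loaded genome FASTA).
#' @return Named integer vector of contig lengths.
#' @export
genome_of <- function(seqs) {
  setNames(width(seqs), names(seqs))
}

#' Load intervals from a BED file
#'
#' Reads BED3/BED6 (0-based half-open). Malformed lines are reported with
#' their line numbers; intervals exceeding a bound contig length raise an
#' error naming the contig and line.
#'
#' @param path Path to a BED file.
#' @param genome Optional named vector of contig lengths to validate against.
#' @return A normalized (sorted) `GRanges`.
#' @export
load_intervals <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    gr <- GRanges()
    if (!is.null(genome)) seqlengths(gr) <- integer(0)
    return(gr)
  }
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("BED line ", lineno[which(nf < 3)[1]], " has fewer than 3 fields")
  }
  ctg <- vapply(fields, `[[`, "", 1)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- is.na(s) | is.na(e)
  if (any(bad)) stop("BED line ", lineno[which(bad)[1]],
                     ": non-numeric coordinates")
  bad <- s < 0 | s >= e
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "BED line %d: invalid half-open interval [%s, %s) on %s",
      lineno[i], format(s[i]), format(e[i]), ctg[i]))
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                 ""), NA_character_)
  str <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6, length(f))],
                                ""), "*")
  str[!str %in% c("+", "-")] <- "*"
  if (!is.null(genome)) {
    unknown <- !(ctg %in% names(genome))
    if (any(unknown)) {
      i <- which(unknown)[1]
      stop("BED line ", lineno[i], ": contig ", ctg[i],
           " not in genome table")
    }
    over <- e > genome[ctg]
    if (any(over)) {
      i <- which(over)[1]
      stop(sprintf("BED line %d: interval ends at %s beyond %s length %d",
                   lineno[i], format(e[i]), ctg[i], genome[ctg[i]]))
    }
  }
  gr <- interval_set(ctg, s, e, strand = str,
                     label = if (all(is.na(name))) NULL else name,
                     genome = genome)
  gr
}

#' Save intervals to a BED file
#'
#' Writes BED6 when any interval is stranded or labelled, BED3 otherwise.
#' `load_intervals(save_intervals(x))` round-trips coordinates, order and
#' strands.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_intervals <- function(gr, path) {
  gr <- sort(gr, ignore.strand = TRUE)
  str <- as.character(strand(gr))
  has_meta <- any(str %in% c("+", "-")) || !is.null(mcols(gr)$name)
  df <- data.frame(contig = as.character(seqnames(gr)),
                   start = start(gr) - 1, end = end(gr))
  if (has_meta) {
    df$name <- if (is.null(mcols(gr)$name)) "." else mcols(gr)$name
    df$score <- 0
    df$strand <- ifelse(str %in% c("+", "-"), str, ".")
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Merge overlapping and bookended intervals
#'
#' Joins intervals that overlap or abut (distance 0), strand-agnostically,
#' preserving the union of covered bases. Idempotent.
#'
#' @param gr A `GRanges`.
#' @return A `GRanges` of pairwise non-overlapping, non-bookended intervals.
#' @export
merge_intervals <- function(gr) {
  reduce(gr, ignore.strand = TRUE, min.gapwidth = 1L)
}

#' Count distinct terminus sites falling inside an element set
#'
#' A site is "in" an element when `element.start <= position < element.end`.
#' Each distinct (contig, position, strand) site is counted once regardless of
#' how many elements contain it. Strand-agnostic by default.
#'
#' @param table A [terminus_table].
#' @param elements A `GRanges` of elements.
#' @param stranded If `TRUE`, a site only matches elements on its own strand.
#' @return Integer count of distinct sites inside at least one element.
#' @export
count_sites_in <- function(table, elements, stranded = FALSE) {
  stopifnot(is_terminus_table(table))
  if (nrow(table) == 0 || length(elements) == 0) return(0L)
  gr <- sites_as_granges(table)
  sum(countOverlaps(gr, elements, ignore.strand = !stranded) > 0)
}

#' Count intervals of one set overlapping another
#'
#' Overlap means at least one shared base; bookended intervals do not
#' overlap. Strand-agnostic by default.
#'
#' @param a,b `GRanges` objects.
#' @param stranded If `TRUE`, overlaps must be on the same strand.
#' @return Number of intervals of `a` overlapping at least one interval of
#'   `b`.
#' @export
overlapping_interval_count <- function(a, b, stranded = FALSE) {
  sum(countOverlaps(a, b, ignore.strand = !stranded, minoverlap = 1L) > 0)
}

# ---- terminus tables -------------------------------------------------------

#' Build a terminus table
#'
#' A terminus table holds the 3'-OH terminus sites of one sample: one row per
#' distinct (contig, position, strand) with the number of termini observed
#' there. Positions are 0-based single bases; the strand is the strand of the
#' broken (tailed) strand. Repeated input sites are aggregated by summing
#' their counts.
#'
#' @param contig Character vector of contig names.
#' @param position Integer vector of 0-based terminus positions.
#' @param strand `"+"` or `"-"` per terminus.
#' @param count Termini observed per input row (default 1).
#' @param sample_id,dose_label Sample metadata; `dose_label` is typically one
#'   of `control`, `0.01U`, `0.1U`, `1U`, `10U`.
#' @param total_aligned Library-size denominator used by
#'   [normalize_counts()]; defaults to the total terminus count.
#' @return A `terminus_table` (data.frame with columns `contig`, `position`,
#'   `strand`, `count` and attributes `sample_id`, `dose_label`,
#'   `total_aligned`).
#' @export
terminus_table <- function(contig = character(), position = integer(),
                           strand = character(), count = 1L,
                           sample_id = NA_character_,
                           dose_label = NA_character_,
                           total_aligned = NULL) {
  n <- length(position)
  stopifnot(length(contig) %in% c(1L, n), length(strand) %in% c(1L, n))
  if (n > 0 && length(contig) == 1L) contig <- rep(contig, n)
  if (n > 0 && length(strand) == 1L) strand <- rep(strand, n)
  count <- rep(as.numeric(count), length.out = n)
  if (any(count < 1)) stop("terminus counts must be >= 1")
  if (!all(strand %in% c("+", "-"))) {
    stop("terminus strand must be '+' or '-'")
  }
  df <- data.frame(contig = as.character(contig),
                   position = as.numeric(position),
                   strand = as.character(strand), count = count,
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    key <- paste(df$contig, df$position, df$strand, sep = "\r")
    if (anyDuplicated(key)) {
      agg <- rowsum(df$count, key)
      parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
      df <- data.frame(contig = vapply(parts, `[[`, "", 1),
                       position = as.numeric(vapply(parts, `[[`, "", 2)),
                       strand = vapply(parts, `[[`, "", 3),
                       count = agg[, 1], stringsAsFactors = FALSE)
    }
    df <- df[order(df$contig, df$position, df$strand), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df,
            class = c("terminus_table", "data.frame"),
            sample_id = sample_id, dose_label = dose_label,
            total_aligned = if (is.null(total_aligned)) sum(df$count)
                            else total_aligned)
}

#' @rdname terminus_table
#' @param x Object to test.
#' @export
is_terminus_table <- function(x) inherits(x, "terminus_table")

#' Total termini in a table
#' @param table A [terminus_table].
#' @return Sum of site counts.
#' @export
total_termini <- function(table) sum(table$count)

#' Number of distinct terminus sites
#' @param table A [terminus_table].
#' @return Number of distinct (contig, position, strand) sites.
#' @export
unique_sites <- function(table) nrow(table)

#' Terminus sites as width-1 GRanges
#' @param table A [terminus_table].
#' @param genome Optional named contig-length vector.
#' @return A `GRanges` with a `count` metadata column.
#' @export
sites_as_granges <- function(table, genome = NULL) {
  gr <- GRanges(table$contig,
                IRanges(table$position + 1, width = 1L),
                strand = table$strand)
  mcols(gr)$count <- table$count
  if (!is.null(genome)) gr <- bind_genome(gr, genome)
  gr
}

#' Normalize terminus counts by a library-size denominator
#'
#' Adds a `normalized_count` column: `count / denominator * scale`
#' (counts-per-million by default). Raw counts are retained.
#'
#' @param table A [terminus_table].
#' @param denominator Aligned-read (or terminus) count; must be positive.
#'   Defaults to the table's `total_aligned` attribute.
#' @param scale Multiplier applied after division; default `1e6`.
#' @return The table with a `normalized_count` column.
#' @export
normalize_counts <- function(table, denominator = NULL, scale = 1e6) {
  if (is.null(denominator)) denominator <- attr(table, "total_aligned")
  if (is.null(denominator) || is.na(denominator) || denominator <= 0) {
    stop("normalization denominator must be > 0")
  }
  table$normalized_count <- table$count / denominator * scale
  table
}

#' Write a terminus table as TSV
#' @param table A [terminus_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_terminus_tsv <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a terminus table from TSV
#' @param path Path written by [write_terminus_tsv()].
#' @param sample_id,dose_label Sample metadata.
#' @param total_aligned Optional library-size denominator.
#' @return A [terminus_table].
#' @export
read_terminus_tsv <- function(path, sample_id = NA_character_,
                              dose_label = NA_character_,
                              total_aligned = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  terminus_table(df$contig, df$position, df$strand, df$count,
                 sample_id = sample_id, dose_label = dose_label,
                 total_aligned = total_aligned)
}

#' @export
print.terminus_table <- function(x, ...) {
  cat(sprintf(
    "terminus_table: %d unique sites, %s termini (sample=%s dose=%s)\n",
    nrow(x), format(total_termini(x)), attr(x, "sample_id"),
    attr(x, "dose_label")))
  if (nrow(x) > 0) print(head(as.data.frame(x), 6))
  invisible(x)
}
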