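# Strand-displacement analytics on the circular mitochondrial genome.
# Under the strand-displacement replication model the parental heavy (H)
# strand spends part of each replication cycle single-stranded; regions
# closer to the heavy-strand origin (inside the NCR) stay exposed longer.
# The genome outside the NCR and the OL stem-loop is split into Q1-Q4 and
# the P1 sensitivity of each region/strand is summarized as H/L ratios and
# essDNA indices.

#' Mitochondrial annotation
#'
#' Region coordinates are supplied 1-based inclusive, as conventionally
#' printed for the mitochondrial genome, and converted internally to 0-based
#' half-open. The NCR wraps around the origin and is represented as two
#' linear sub-intervals sharing one label; all counting treats them as one
#' region. By default the NCR is the complement of Q1-Q4 and OL, and OL is
#' the single excluded position between Q3 and Q2.
#'
#' The heavy strand is mapped to the reference minus strand by default: the
#' displayed mitochondrial reference strand is the G-poor light strand, so
#' the G-rich heavy strand is its complement. This mapping is configurable
#' because annotation sources differ.
#'
#' @param contig Mitochondrial contig name.
#' @param genome_length Length in bp (16,571 for the hg19 chrM).
#' @param h_strand Reference strand carrying the heavy strand: `"-"`
#'   (default) or `"+"`.
#' @param q1,q2,q3,q4 1-based inclusive `(from, to)` pairs.
#' @param ol 1-based inclusive pair for the OL stem-loop; default is the gap
#'   between Q3 and Q2.
#' @param ncr Optional 1-based inclusive pair; by default the wrapped
#'   complement of Q1-Q4 and OL.
#' @return A `mito_annotation` object.
#' @export
mito_annotation <- function(contig = "chrM", genome_length = 16571L,
                            h_strand = c("-", "+"),
                            q1 = c(10593, 16024), q2 = c(5160, 10592),
                            q3 = c(2869, 5158), q4 = c(579, 2868),
                            ol = NULL, ncr = NULL) {
  h_strand <- match.arg(h_strand)
  to0 <- function(p) cbind(start = p[1] - 1, end = p[2])
  if (is.null(ol)) ol <- c(q3[2] + 1, q2[1] - 1)
  regions <- list(Q1 = to0(q1), Q2 = to0(q2), Q3 = to0(q3), Q4 = to0(q4),
                  OL = to0(ol))
  if (is.null(ncr)) {
    lo <- min(vapply(regions, function(m) min(m[, "start"]), 0))
    hi <- max(vapply(regions, function(m) max(m[, "end"]), 0))
    ncr0 <- rbind(cbind(start = hi, end = genome_length),
                  cbind(start = 0, end = lo))
    ncr0 <- ncr0[ncr0[, "end"] > ncr0[, "start"], , drop = FALSE]
    regions$NCR <- ncr0
  } else {
    regions$NCR <- to0(ncr)
  }
  covered <- rep(FALSE, genome_length)
  for (m in regions) {
    for (r in seq_len(nrow(m))) {
      span <- seq(m[r, "start"] + 1, m[r, "end"])
      if (any(covered[span])) stop("mito regions overlap")
      covered[span] <- TRUE
    }
  }
  if (!all(covered)) {
    stop("mito regions do not cover the genome (",
         sum(!covered), " bp uncovered)")
  }
  structure(list(contig = contig, genome_length = as.integer(genome_length),
                 h_strand = h_strand, regions = regions),
            class = "mito_annotation")
}

#' Read a mitochondrial annotation from a key=value file
#'
#' Keys: `contig`, `genome_length`, `h_strand`, and `q1`..`q4`, `ol`, `ncr`
#' as comma-separated 1-based inclusive pairs. Missing optional keys fall
#' back to the [mito_annotation()] defaults.
#'
#' @param path File of `key = value` lines; `#` starts a comment.
#' @return A `mito_annotation`.
#' @export
read_mito_annotation <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=")
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, `[[`, "", 2))
  get <- function(k, default = NULL, pair = FALSE) {
    if (!k %in% keys) return(default)
    v <- vals[match(k, keys)]
    if (pair) as.numeric(trimws(strsplit(v, ",")[[1]])) else v
  }
  args <- list(
    contig = get("contig", "chrM"),
    genome_length = as.integer(get("genome_length", "16571")),
    h_strand = get("h_strand", "-"))
  for (k in c("q1", "q2", "q3", "q4", "ol", "ncr")) {
    v <- get(k, pair = TRUE)
    if (!is.null(v)) args[[k]] <- v
  }
  do.call(mito_annotation, args)
}

mito_region_names <- function(anno) names(anno$regions)

# Reference strand carrying the requested mitochondrial strand.
mito_ref_strand <- function(anno, strand = c("H", "L")) {
  strand <- match.arg(strand)
  if (strand == "H") anno$h_strand else setdiff(c("+", "-"), anno$h_strand)
}

in_mito_region <- function(position, anno, region) {
  m <- anno$regions[[region]]
  if (is.null(m)) stop("unknown mitochondrial region: ", region)
  hit <- rep(FALSE, length(position))
  for (r in seq_len(nrow(m))) {
    hit <- hit | (position >= m[r, "start"] & position < m[r, "end"])
  }
  hit
}

#' Per-region, per-strand terminus summaries
#'
#' Counts termini on the mapped H or L strand of a (possibly wrapped)
#' mitochondrial region in one of three modes: `termini` (every terminus,
#' redundant positions counted multiply), `sites` (distinct genomic
#' coordinates only) or `depth` (termini per site). Depth over zero sites is
#' reported as `NA` rather than 0.
#'
#' @param table A [terminus_table] restricted to (or containing) the
#'   mitochondrial contig.
#' @param anno A [mito_annotation()].
#' @param region Region name (`Q1`..`Q4`, `OL`, `NCR`).
#' @param strand `"H"` or `"L"`.
#' @param mode Counting mode.
#' @return A single number.
#' @export
strand_region_counts <- function(table, anno, region,
                                 strand = c("H", "L"),
                                 mode = c("termini", "sites", "depth")) {
  strand <- match.arg(strand)
  mode <- match.arg(mode)
  ref <- mito_ref_strand(anno, strand)
  sel <- table$contig == anno$contig & table$strand == ref &
    in_mito_region(table$position, anno, region)
  n_term <- sum(table$count[sel])
  n_site <- sum(sel)
  switch(mode,
         termini = n_term,
         sites = n_site,
         depth = if (n_site == 0) NA_real_ else n_term / n_site)
}

#' Heavy/light strand ratio in a region
#'
#' @inheritParams strand_region_counts
#' @return `H / L` under the chosen mode. A zero L-strand denominator yields
#'   `Inf` (flagged with a warning), never a silent drop.
#' @export
hl_ratio <- function(table, anno, region = "NCR",
                     mode = c("termini", "sites", "depth")) {
  mode <- match.arg(mode)
  h <- strand_region_counts(table, anno, region, "H", mode)
  l <- strand_region_counts(table, anno, region, "L", mode)
  if (is.na(h) || is.na(l)) return(NA_real_)
  if (l == 0) {
    warning("L-strand ", mode, " count is zero in ", region,
            "; H/L ratio is infinite")
    return(Inf)
  }
  h / l
}

#' H/L ratio normalized to the untreated control
#'
#' @param treated,control [terminus_table]s for the P1-treated sample and
#'   its untreated control.
#' @inheritParams strand_region_counts
#' @return `hl_ratio(treated) / hl_ratio(control)`.
#' @export
normalized_hl_ratio <- function(treated, control, anno, region = "NCR",
                                mode = c("termini", "sites", "depth")) {
  mode <- match.arg(mode)
  rt <- hl_ratio(treated, anno, region, mode)
  rc <- hl_ratio(control, anno, region, mode)
  if (is.na(rc) || rc == 0 || !is.finite(rc)) {
    stop("control H/L ratio undefined or zero in ", region)
  }
  rt / rc
}

#' essDNA index of a region and strand
#'
#' Ratio of region/strand terminus fractions, treated over control: each
#' sample's count is normalized by its total mitochondrial count in the same
#' mode, so the index is invariant to library size and to any normalization
#' scale factor. An index above 1 marks P1 sensitivity, i.e. single-stranded
#' character.
#'
#' @inheritParams normalized_hl_ratio
#' @param strand `"H"` or `"L"`.
#' @param mode `termini` (default) or `sites`.
#' @return The index; zero control signal in the region/strand raises an
#'   error (flagged, not silently dropped).
#' @export
essdna_index <- function(treated, control, anno, region,
                         strand = c("H", "L"),
                         mode = c("termini", "sites")) {
  strand <- match.arg(strand)
  mode <- match.arg(mode)
  tot <- function(tab) {
    sel <- tab$contig == anno$contig
    if (mode == "termini") sum(tab$count[sel]) else sum(sel)
  }
  ct <- strand_region_counts(treated, anno, region, strand, mode)
  cc <- strand_region_counts(control, anno, region, strand, mode)
  tt <- tot(treated)
  tc <- tot(control)
  if (tt == 0 || tc == 0) stop("empty mitochondrial table")
  if (cc == 0) stop("control has no ", mode, " in ", region, "/", strand,
                    "; essDNA index undefined")
  (ct / tt) / (cc / tc)
}

#' Two-sided paired t-test over replicates
#'
#' Classical paired Student's t-test, pairing by replicate index. Zero
#' variance of the differences is flagged: identical vectors give `t = 0`,
#' `p = 1`; a constant non-zero difference is reported as degenerate with
#' `p = NA`.
#'
#' @param a,b Numeric vectors of per-replicate values (equal length >= 2).
#' @return List with `t`, `p`, `df` and a logical `degenerate` flag.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, df = length(d) - 1, degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p = NA_real_, df = length(d) - 1,
                degenerate = TRUE))
  }
  ht <- t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Long-format mitochondrial strand summary
#'
#' All region x strand x mode counts for a set of samples, suitable for TSV
#' export.
#'
#' @param tables Named list of [terminus_table]s.
#' @param anno A [mito_annotation()].
#' @return A data.frame with columns `sample`, `region`, `strand`, `mode`,
#'   `value`.
#' @export
mito_strand_summary <- function(tables, anno) {
  grid <- expand.grid(sample = names(tables),
                      region = mito_region_names(anno),
                      strand = c("H", "L"),
                      mode = c("termini", "sites", "depth"),
                      stringsAsFactors = FALSE)
  grid$value <- mapply(function(s, r, st, m) {
    strand_region_counts(tables[[s]], anno, r, st, m)
  }, grid$sample, grid$region, grid$strand, grid$mode)
  grid
}
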