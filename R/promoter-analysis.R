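# Promoter/TSS association analysis: proximity classification, CAGE-support
# filtering, gene assignment, expression comparison and a database-free
# gene-set over-representation test.

#' TSS record table
#'
#' @param contig,position,strand,gene_id Vectors describing each TSS;
#'   positions are 0-based single bases.
#' @return A data.frame of class `tss_records`.
#' @export
tss_records <- function(contig, position, strand = "*", gene_id) {
  n <- length(position)
  df <- data.frame(contig = rep_len(as.character(contig), n),
                   position = as.numeric(position),
                   strand = rep_len(as.character(strand), n),
                   gene_id = rep_len(as.character(gene_id), n),
                   stringsAsFactors = FALSE)
  structure(df, class = c("tss_records", "data.frame"))
}

#' Read TSS records from BED6
#'
#' The BED name field carries the gene id; the TSS position is the BED
#' start (0-based).
#'
#' @param path BED6 path.
#' @return A [tss_records] table.
#' @export
read_tss_bed <- function(path) {
  gr <- load_intervals(path)
  tss_records(as.character(seqnames(gr)), start(gr) - 1,
              as.character(strand(gr)),
              if (is.null(mcols(gr)$name)) NA_character_ else
                mcols(gr)$name)
}

# Closed +/- radius window around each TSS point, as 0-based half-open
# [pos - radius, pos + radius + 1), clipped at the contig origin.
tss_windows_ <- function(tss, radius) {
  GRanges(tss$contig,
          IRanges(pmax(tss$position - radius, 0) + 1,
                  tss$position + radius + 1))
}

#' Classify promoters as TSS-proximal or distal
#'
#' A promoter is proximal when its interval overlaps the closed
#' `+/- radius` window around any TSS (default anchor), or, with
#' `anchor = "midpoint"`, when its midpoint lies within `radius` of a TSS.
#'
#' @param promoters A `GRanges` of promoter intervals.
#' @param tss A [tss_records] table.
#' @param radius Window radius in bp (default 1000).
#' @param anchor `"overlap"` (interval overlap, default) or `"midpoint"`.
#' @return List with `proximal`, `distal`, `percent` (proximal percentage
#'   rounded to one decimal) and the logical `is_proximal` vector.
#' @export
classify_promoter_proximity <- function(promoters, tss, radius = 1000,
                                        anchor = c("overlap", "midpoint")) {
  anchor <- match.arg(anchor)
  stopifnot(radius > 0)
  if (length(promoters) == 0) stop("empty promoter set")
  if (anchor == "midpoint") {
    mid <- floor((start(promoters) - 1 + end(promoters) - 1) / 2)
    query <- GRanges(seqnames(promoters), IRanges(mid + 1, width = 1))
  } else {
    query <- promoters
  }
  prox <- countOverlaps(query, tss_windows_(tss, radius),
                        ignore.strand = TRUE) > 0
  list(proximal = sum(prox), distal = sum(!prox),
       percent = round(100 * mean(prox), 1), is_proximal = prox)
}

#' Restrict TSSs to those supported by CAGE peaks
#'
#' Keeps TSSs whose position falls inside at least one CAGE peak interval.
#' Output is a subset of the input and the operation is idempotent.
#'
#' @param tss A [tss_records] table.
#' @param cage_peaks A `GRanges` of CAGE peaks.
#' @return The supported subset of `tss`.
#' @export
cage_supported_tss <- function(tss, cage_peaks) {
  if (nrow(tss) == 0) return(tss)
  pts <- GRanges(tss$contig, IRanges(tss$position + 1, width = 1))
  keep <- countOverlaps(pts, cage_peaks, ignore.strand = TRUE) > 0
  out <- tss[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tss_records", "data.frame"))
}

#' Assign promoters to genes by TSS proximity
#'
#' Every gene whose TSS window (`+/- radius`) overlaps the promoter is
#' assigned; a promoter may sit between two genes and receive both.
#'
#' @inheritParams classify_promoter_proximity
#' @return A list, one character vector of gene ids per promoter (empty for
#'   unassigned promoters); names follow `names(promoters)` when present.
#' @export
assign_promoter_genes <- function(promoters, tss, radius = 1000) {
  out <- rep(list(character()), length(promoters))
  if (length(promoters) > 0 && nrow(tss) > 0) {
    hits <- findOverlaps(promoters, tss_windows_(tss, radius),
                         ignore.strand = TRUE)
    if (length(hits) > 0) {
      sp <- split(tss$gene_id[subjectHits(hits)], queryHits(hits))
      for (k in names(sp)) out[[as.integer(k)]] <- unique(sp[[k]])
    }
  }
  if (!is.null(names(promoters))) names(out) <- names(promoters)
  out
}

#' Compare expression between gene groups
#'
#' Computes per-group per-replicate mean TPM (and medians), and for two
#' groups a two-sided paired t-test across replicates of the group means.
#'
#' @param groups Named list of gene-id vectors.
#' @param expr Data.frame with a `gene_id` column and one numeric TPM
#'   column per replicate.
#' @return List with `means` (group x replicate matrix), `medians`, and for
#'   two groups `t` and `p` from [paired_t_test()]. Groups with no
#'   expressed gene are flagged with a warning and `NA` rows.
#' @export
compare_expression <- function(groups, expr) {
  stopifnot(is.list(groups), !is.null(names(groups)),
            "gene_id" %in% names(expr))
  reps <- setdiff(names(expr), "gene_id")
  stopifnot(length(reps) >= 1)
  means <- matrix(NA_real_, nrow = length(groups), ncol = length(reps),
                  dimnames = list(names(groups), reps))
  medians <- means
  for (g in names(groups)) {
    rows <- expr$gene_id %in% groups[[g]]
    if (!any(rows)) {
      warning("group '", g, "' has no genes in the expression table")
      next
    }
    for (r in reps) {
      means[g, r] <- mean(expr[[r]][rows])
      medians[g, r] <- stats::median(expr[[r]][rows])
    }
  }
  out <- list(means = means, medians = medians)
  if (length(groups) == 2 && length(reps) >= 2 && !anyNA(means)) {
    tt <- paired_t_test(means[1, ], means[2, ])
    out$t <- tt$t
    out$p <- tt$p
  }
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction; two-sided p from the chi-square
#' distribution with 1 df. Cells are given row-wise:
#' `(a, b)` = group 1 (e.g. proximal, distal), `(c, d)` = group 2.
#'
#' @param a,b,c,d Non-negative cell counts with positive margins.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List with `chi2` and `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  stopifnot(all(m >= 0), all(rowSums(m) > 0), all(colSums(m) > 0))
  ht <- suppressWarnings(chisq.test(m, correct = correct))
  list(chi2 = unname(ht$statistic), p = ht$p.value)
}

#' Gene-set over-representation by the hypergeometric test
#'
#' Database-free analog of a GO over-representation run: for each set, the
#' upper-tail hypergeometric probability of observing at least the given
#' overlap between the hit list and the set, drawn from the universe, with
#' BH correction across sets. Results are ranked by p.
#'
#' @param hits Character vector of hit gene ids (must lie in the universe).
#' @param sets Named list of gene-id vectors (restricted to the universe).
#' @param universe Character vector of background gene ids.
#' @return Data.frame with `set_id`, `set_size`, `n_hits`, `overlap`, `p`,
#'   `q`, ordered by increasing `p`.
#' @export
gene_set_overrepresentation <- function(hits, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  rows <- lapply(names(sets), function(id) {
    s <- intersect(unique(sets[[id]]), universe)
    ov <- length(intersect(hits, s))
    p <- phyper(ov - 1, length(s), length(universe) - length(s),
                length(hits), lower.tail = FALSE)
    data.frame(set_id = id, set_size = length(s), n_hits = length(hits),
               overlap = ov, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
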