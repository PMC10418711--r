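# Enrichment of clustered P1 cut sites in genomic element classes, plus the
# hierarchical region-to-class assignment and multi-set (Venn) overlap
# analysis used to compare annotation databases.

#' Enrichment odds ratio
#'
#' `odds ratio = EP / (TP * (EL / GL))`: the fraction of clustered cut sites
#' inside an element class over the fraction of the genome the class covers.
#'
#' @param ep Clustered P1 cut sites inside the class.
#' @param tp Total clustered P1 cut sites in the sample.
#' @param el Total bases covered by the class.
#' @param gl Total genome length.
#' @return The odds ratio (scale-invariant in `EL`/`GL`).
#' @export
odds_ratio <- function(ep, tp, el, gl) {
  stopifnot(tp > 0, el > 0, gl > 0, ep >= 0, ep <= tp, el <= gl)
  ep / (tp * (el / gl))
}

#' Per-class enrichment profile of clustered cut sites
#'
#' Each element class is merged (self-overlap-free) before computing its
#' covered length `EL`; `EP` counts distinct clustered sites inside the
#' class via [count_sites_in()]. A site inside two classes contributes to
#' both: each class is a marginal enrichment question.
#'
#' @param clustered A [terminus_table] of clustered P1 cut sites.
#' @param elements Named list of `GRanges`, one per element class.
#' @param genome Named contig-length vector (defines `GL`).
#' @return Data.frame with `class`, `EP`, `TP`, `EL`, `GL`, `odds_ratio`;
#'   classes covering zero bases are skipped with a warning.
#' @export
element_enrichment_profile <- function(clustered, elements, genome) {
  stopifnot(is_terminus_table(clustered), length(names(elements)) ==
              length(elements))
  tp <- unique_sites(clustered)
  gl <- sum(as.numeric(genome))
  rows <- lapply(names(elements), function(cl) {
    merged <- merge_intervals(elements[[cl]])
    el <- sum(as.numeric(width(merged)))
    if (el == 0) {
      warning("element class '", cl, "' covers zero bases; skipped")
      return(NULL)
    }
    ep <- count_sites_in(clustered, merged)
    data.frame(class = cl, EP = ep, TP = tp, EL = el, GL = gl,
               odds_ratio = if (tp > 0) odds_ratio(ep, tp, el, gl)
                            else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(class = character(), EP = integer(), TP = integer(),
                      EL = numeric(), GL = numeric(),
                      odds_ratio = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Hierarchically assign regions to ordered element classes
#'
#' Each region is assigned to the first class in the supplied order that it
#' overlaps by at least one base; regions overlapping no class fall into
#' `"others"`. Assignment is exclusive (unlike the marginal enrichment
#' profile) and independent of region input order.
#'
#' @param regions A `GRanges` of regions.
#' @param classes Named list of `GRanges` in priority order.
#' @return A data.frame with `class` (including `others`), `count`,
#'   `fraction` (summing to 1); the per-region class vector is attached as
#'   attribute `assignment`.
#' @export
hierarchical_assign <- function(regions, classes) {
  stopifnot(length(names(classes)) == length(classes))
  n <- length(regions)
  assigned <- rep("others", n)
  open <- rep(TRUE, n)
  for (cl in names(classes)) {
    if (!any(open)) break
    hit <- countOverlaps(regions, classes[[cl]], ignore.strand = TRUE,
                         minoverlap = 1L) > 0
    take <- open & hit
    assigned[take] <- cl
    open <- open & !take
  }
  levels <- c(names(classes), "others")
  counts <- setNames(integer(length(levels)), levels)
  tb <- table(assigned)
  counts[names(tb)] <- as.integer(tb)
  out <- data.frame(class = levels, count = as.integer(counts),
                    fraction = if (n > 0) as.integer(counts) / n else
                      rep(NA_real_, length(levels)),
                    stringsAsFactors = FALSE)
  attr(out, "assignment") <- assigned
  out
}

#' Multi-set overlap (Venn) membership
#'
#' For 2-4 interval sets, counts for each set how many of its intervals
#' overlap each combination of the other sets. An interval is "unique" when
#' it overlaps no interval of any other set; unique fractions are also
#' formatted as percentages rounded (half-even) to two decimals, matching
#' the conventional Venn reporting precision.
#'
#' @param sets Named list of 2-4 `GRanges`.
#' @return List with `summary` (per set: `n`, `n_unique`, `pct_unique`),
#'   `patterns` (per set: overlap pattern over the other sets and its
#'   count) and `pairwise` (for each ordered pair, intervals of the first
#'   set overlapping the second, with percentage).
#' @export
multiset_membership <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, length(sets) <= 4,
            !is.null(names(sets)))
  nm <- names(sets)
  memb <- lapply(nm, function(a) {
    others <- setdiff(nm, a)
    hits <- vapply(others, function(b) {
      countOverlaps(sets[[a]], sets[[b]], ignore.strand = TRUE,
                    minoverlap = 1L) > 0
    }, logical(length(sets[[a]])))
    if (length(sets[[a]]) == 1) hits <- matrix(hits, nrow = 1,
                                               dimnames = list(NULL, others))
    hits
  })
  names(memb) <- nm
  summary <- do.call(rbind, lapply(nm, function(a) {
    m <- memb[[a]]
    uniq <- if (nrow(m) == 0) 0L else sum(rowSums(m) == 0)
    n <- length(sets[[a]])
    data.frame(set = a, n = n, n_unique = uniq,
               pct_unique = round(100 * uniq / n, 2),
               stringsAsFactors = FALSE)
  }))
  patterns <- do.call(rbind, lapply(nm, function(a) {
    m <- memb[[a]]
    if (nrow(m) == 0) return(NULL)
    pat <- apply(m, 1, function(r) {
      hit <- colnames(m)[r]
      if (length(hit) == 0) "none" else paste(hit, collapse = "&")
    })
    tb <- table(pat)
    data.frame(set = a, pattern = names(tb), count = as.integer(tb),
               stringsAsFactors = FALSE)
  }))
  pairwise <- do.call(rbind, lapply(nm, function(a) {
    m <- memb[[a]]
    do.call(rbind, lapply(colnames(m), function(b) {
      cnt <- sum(m[, b])
      data.frame(set = a, other = b, overlapping = cnt,
                 pct = round(100 * cnt / length(sets[[a]]), 2),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summary) <- NULL
  list(summary = summary, patterns = patterns, pairwise = pairwise)
}

#' Region size summary
#'
#' Sizes are `end - start`; the median uses lower interpolation (the lower
#' of the two middle values for even counts).
#'
#' @param regions A non-empty `GRanges`.
#' @param breaks Passed to [graphics::hist()] machinery for the histogram
#'   (default `"Sturges"`).
#' @return List with `min`, `median`, `max` and a `histogram` data.frame
#'   (`lower`, `upper`, `count`).
#' @export
region_size_summary <- function(regions, breaks = "Sturges") {
  if (length(regions) == 0) stop("empty region set")
  sizes <- sort(as.numeric(width(regions)))
  n <- length(sizes)
  med <- sizes[floor((n + 1) / 2)]
  h <- graphics::hist(sizes, breaks = breaks, plot = FALSE)
  list(min = sizes[1], median = med, max = sizes[n],
       histogram = data.frame(lower = h$breaks[-length(h$breaks)],
                              upper = h$breaks[-1], count = h$counts))
}
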