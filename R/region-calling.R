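# SICER-parameterized island calling of essDNA regions from 3'-OH terminus
# coordinates, treated versus untreated control. The genome is tiled with
# non-overlapping windows of w bp; windows holding at least l0 termini are
# "eligible"; maximal runs of eligible windows separated by at most g/w
# ineligible windows form candidate islands scored against a Poisson
# background; the score threshold is chosen so that the expected number of
# random-background islands at or above it across the effective genome is at
# most the E-value. Retained candidates are then tested against the scaled
# control with an upper-tail Poisson test and BH-FDR.

#' Island caller configuration
#'
#' Defaults are the published run parameters of the essDNA analysis:
#' redundancy threshold 1, window 10 bp, fragment size 1 bp (a terminus
#' contributes to exactly one window), effective genome fraction 0.8, gap
#' 30 bp and E-value 0.01. The window eligibility probability `window_p0`
#' (0.2) and the control comparison (Poisson test at BH-FDR 0.01 against the
#' library-size-scaled control) fill in stages the published parameter list
#' leaves implicit; both are configurable, and `use_control = FALSE`
#' reproduces pure random-background calling.
#'
#' @param window_size Window width w in bp.
#' @param gap_size Maximum gap g in bp between eligible windows of one
#'   island; must be a non-negative multiple of `window_size`.
#' @param fragment_size Fragment size in bp (termini are single bases).
#' @param redundancy_threshold Per-site count cap applied before calling.
#' @param effective_genome_fraction Mappable fraction of the genome used in
#'   the background mean.
#' @param e_value Expected number of random-background islands tolerated
#'   genome-wide.
#' @param window_p0 Upper bound on the Poisson tail used for window
#'   eligibility.
#' @param control_fdr BH-FDR cutoff of the control comparison.
#' @param control_scaling Treated/control library-size ratio; `NULL` (the
#'   default) computes it from the deduplicated totals.
#' @param use_control Whether to run the control comparison at all.
#' @return A list of class `island_caller_config`.
#' @export
island_caller_config <- function(window_size = 10L, gap_size = 30L,
                                 fragment_size = 1L,
                                 redundancy_threshold = 1L,
                                 effective_genome_fraction = 0.8,
                                 e_value = 0.01, window_p0 = 0.2,
                                 control_fdr = 0.01,
                                 control_scaling = NULL,
                                 use_control = TRUE) {
  stopifnot(window_size >= 1, gap_size >= 0,
            effective_genome_fraction > 0, effective_genome_fraction <= 1,
            e_value > 0, window_p0 > 0, redundancy_threshold >= 1)
  if (gap_size %% window_size != 0) {
    stop("gap_size must be a non-negative multiple of window_size")
  }
  structure(list(window_size = as.integer(window_size),
                 gap_size = as.integer(gap_size),
                 fragment_size = as.integer(fragment_size),
                 redundancy_threshold = as.integer(redundancy_threshold),
                 effective_genome_fraction = effective_genome_fraction,
                 e_value = e_value, window_p0 = window_p0,
                 control_fdr = control_fdr,
                 control_scaling = control_scaling,
                 use_control = use_control),
            class = "island_caller_config")
}

#' Cap per-site terminus redundancy
#'
#' @param table A [terminus_table].
#' @param redundancy Maximum count retained per (contig, position, strand).
#' @return The capped table.
#' @export
deduplicate_sites <- function(table, redundancy = 1L) {
  stopifnot(redundancy >= 1)
  table$count <- pmin(table$count, redundancy)
  table
}

#' Per-window terminus counts
#'
#' Window `i` of a contig covers `[i*w, (i+1)*w)`; a terminus contributes to
#' exactly one window and strands are pooled. Only non-empty windows are
#' returned.
#'
#' @param table A [terminus_table] (deduplicate first for calling).
#' @param w Window size in bp.
#' @param genome Named contig-length vector (validates positions).
#' @return A data.frame with `contig`, `window` (0-based index), `count`.
#' @export
window_histogram <- function(table, w, genome = NULL) {
  if (!is.null(genome)) {
    bad <- table$position >= genome[table$contig]
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      stop("terminus positions outside the genome table")
    }
  }
  if (nrow(table) == 0) {
    return(data.frame(contig = character(), window = integer(),
                      count = numeric()))
  }
  win <- floor(table$position / w)
  key <- paste(table$contig, win, sep = "\r")
  agg <- rowsum(table$count, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(contig = vapply(parts, `[[`, "", 1),
                    window = as.integer(vapply(parts, `[[`, "", 2)),
                    count = agg[, 1], stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$window), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Window eligibility threshold
#'
#' Smallest integer `l0 >= 1` whose upper-tail Poisson probability
#' `P(X >= l0; lambda)` is below `p0`.
#'
#' @param lambda Background mean terminus count per window,
#'   `N * w / (EGF * L)`.
#' @param p0 Tail probability bound.
#' @return Integer threshold `l0`.
#' @export
window_eligibility_threshold <- function(lambda, p0 = 0.2) {
  stopifnot(lambda > 0)
  l0 <- 1L
  while (ppois(l0 - 1, lambda, lower.tail = FALSE) >= p0) {
    l0 <- l0 + 1L
    if (l0 > 1e6) stop("eligibility threshold did not converge")
  }
  l0
}

#' Candidate islands from a window histogram
#'
#' Maximal runs of eligible windows (count >= `l0`) in which consecutive
#' eligible windows are separated by at most `gap_windows` ineligible
#' windows. The island interval spans the first through last eligible
#' window only; the score is the sum over eligible windows of
#' `-log` Poisson pmf of the window count at `lambda`.
#'
#' @param windows Data.frame from [window_histogram()].
#' @param l0 Eligibility threshold.
#' @param gap_windows Allowed ineligible windows between eligible ones
#'   (`g / w`).
#' @param lambda Background mean per window.
#' @param w Window size in bp.
#' @return Data.frame with `contig`, `start`, `end` (0-based half-open bp),
#'   `n_eligible`, `span_windows`, `score`.
#' @export
find_candidate_islands <- function(windows, l0, gap_windows, lambda, w) {
  elig <- windows[windows$count >= l0, , drop = FALSE]
  if (nrow(elig) == 0) {
    return(data.frame(contig = character(), start = numeric(),
                      end = numeric(), n_eligible = integer(),
                      span_windows = integer(), score = numeric()))
  }
  elig$score <- -dpois(elig$count, lambda, log = TRUE)
  res <- lapply(split(elig, elig$contig), function(e) {
    e <- e[order(e$window), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(e$window) > gap_windows + 1L)))
    first <- tapply(e$window, grp, min)
    last <- tapply(e$window, grp, max)
    data.frame(contig = e$contig[1],
               start = as.numeric(first) * w,
               end = (as.numeric(last) + 1) * w,
               n_eligible = as.integer(tapply(e$window, grp, length)),
               span_windows = as.integer(last - first + 1L),
               score = as.numeric(tapply(e$score, grp, sum)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Discretized distribution of the score of a single random-background
# island, plus the expected island count, under the renewal description of
# the eligible-window process: an island starts at an eligible window
# preceded by more than gap_windows ineligible ones; after each eligible
# window it continues iff another eligible window occurs within
# gap_windows + 1 positions.
island_null_model <- function(lambda, l0, gap_windows, effective_windows,
                              grid = 0.01, tail_weight = 1e-4) {
  q <- ppois(l0 - 1, lambda, lower.tail = FALSE)
  if (q <= 0) stop("eligible windows have probability zero")
  reach <- gap_windows + 1
  cont <- 1 - (1 - q)^reach
  n_starts <- effective_windows * q * (1 - q)^reach
  kmax <- max(l0 + 1, suppressWarnings(
    qpois(1e-15, lambda, lower.tail = FALSE)))
  k <- l0:kmax
  pk <- dpois(k, lambda)
  pk <- pk / sum(pk)
  sk <- -dpois(k, lambda, log = TRUE)
  # number of convolution terms needed before the geometric island-length
  # weight becomes negligible relative to the E-value resolution
  m_max <- 2L
  while (cont^m_max > tail_weight && m_max < 5000L) m_max <- m_max + 1L
  list(q = q, cont = cont, n_starts = n_starts, k = k, pk = pk, sk = sk,
       m_max = m_max, grid = grid)
}

#' Island score threshold for a target E-value
#'
#' Computes, by dynamic-programming convolution of the per-window score
#' distribution, the expected number of random-background islands with score
#' at or above each grid score across the effective genome, and returns the
#' smallest score whose expectation is at most `e_value`. A seeded Monte
#' Carlo estimator ([simulate_island_null()]) serves as an independent
#' cross-check and as a fallback if the DP fails to converge.
#'
#' @param lambda Background mean per window.
#' @param l0 Eligibility threshold (see [window_eligibility_threshold()]).
#' @param gap_windows Allowed gap in windows.
#' @param e_value Tolerated expected island count.
#' @param effective_windows Number of background windows
#'   (`EGF * L / w`).
#' @param grid Score discretization step.
#' @return The threshold score, with attributes `scores` (grid) and
#'   `expected_ge` (expected island count at or above each grid score).
#' @export
island_score_threshold <- function(lambda, l0, gap_windows, e_value,
                                   effective_windows, grid = 0.01) {
  if (!is.finite(e_value)) return(structure(0, scores = 0,
                                            expected_ge = Inf))
  key <- paste(signif(lambda, 12), l0, gap_windows, e_value,
               signif(effective_windows, 12), grid)
  cached <- .threshold_cache[[key]]
  if (!is.null(cached)) return(cached)
  mod <- island_null_model(lambda, l0, gap_windows, effective_windows,
                           grid = grid,
                           tail_weight = min(1e-4, e_value * 1e-3 /
                                               max(1, effective_windows)))
  if (mod$n_starts <= e_value) {
    # fewer islands than tolerated even before any score filtering
    return(structure(0, scores = 0, expected_ge = mod$n_starts))
  }
  idx <- pmax(1L, as.integer(round(mod$sk / grid)))
  m_bins <- max(idx) * mod$m_max + 1L
  if (m_bins > 5e7) stop("score grid too large; DP did not converge")
  atoms <- rowsum(mod$pk, idx)
  aidx <- as.integer(rownames(atoms))
  aval <- atoms[, 1]

  # dist[i] = P(score == (i-1)*grid), overflow lumped in the last bin
  dist <- numeric(m_bins)
  dist[pmin(aidx + 1L, m_bins)] <- aval
  acc_tail <- rev(cumsum(rev(dist))) * (1 - mod$cont)
  for (m in 2:mod$m_max) {
    new <- numeric(m_bins)
    for (j in seq_along(aidx)) {
      sh <- aidx[j]
      if (sh < m_bins - 1L) {
        new[(sh + 1L):m_bins] <- new[(sh + 1L):m_bins] +
          aval[j] * dist[1:(m_bins - sh)]
      }
      # mass shifted beyond the grid stays in the overflow bin
      over <- sum(dist[max(1L, m_bins - sh + 1L):m_bins]) * aval[j]
      if (sh >= 1L) new[m_bins] <- new[m_bins] + over
    }
    dist <- new
    acc_tail <- acc_tail + rev(cumsum(rev(dist))) * (1 - mod$cont) *
      mod$cont^(m - 1)
  }
  # unreached island lengths, counted conservatively as exceeding any score
  remainder <- mod$cont^mod$m_max
  expected <- mod$n_starts * (acc_tail + remainder)
  scores <- (seq_len(m_bins) - 1) * grid
  ok <- which(expected <= e_value)
  if (length(ok) == 0) stop("score threshold not attainable on the grid")
  out <- structure(scores[ok[1]], scores = scores, expected_ge = expected)
  .threshold_cache[[key]] <- out
  out
}

# memoized score thresholds (repeated calls with identical background
# parameters are common in null-replicate loops)
.threshold_cache <- new.env(parent = emptyenv())

#' Monte Carlo island null
#'
#' Simulates Poisson window counts over a background of `n_windows`
#' windows, forms islands under the gap rule and records their scores.
#'
#' @inheritParams island_score_threshold
#' @param n_windows Number of simulated windows per replicate.
#' @param reps Number of replicates.
#' @param seed RNG seed.
#' @return Numeric vector of island scores pooled across replicates, with
#'   attribute `reps`. The expected number of islands with score at least
#'   `s` is estimated by `sum(scores >= s) / reps`.
#' @export
simulate_island_null <- function(lambda, l0, gap_windows, n_windows,
                                 reps = 200L, seed = 1L) {
  scores <- with_seed_(seed, {
    out <- vector("list", reps)
    for (r in seq_len(reps)) {
      counts <- rpois(n_windows, lambda)
      idx <- which(counts >= l0)
      if (length(idx) == 0) next
      grp <- cumsum(c(1L, as.integer(diff(idx) > gap_windows + 1L)))
      sc <- -dpois(counts[idx], lambda, log = TRUE)
      out[[r]] <- as.numeric(tapply(sc, grp, sum))
    }
    unlist(out)
  })
  if (is.null(scores)) scores <- numeric()
  structure(scores, reps = reps)
}

count_in_spans <- function(table, islands) {
  if (nrow(islands) == 0 || nrow(table) == 0) {
    return(list(count = numeric(nrow(islands)),
                sites = integer(nrow(islands))))
  }
  igr <- GRanges(islands$contig, IRanges(islands$start + 1, islands$end))
  sgr <- sites_as_granges(table)
  hits <- findOverlaps(sgr, igr, ignore.strand = TRUE)
  cnt <- numeric(nrow(islands))
  nst <- integer(nrow(islands))
  if (length(hits) > 0) {
    agg <- rowsum(table$count[queryHits(hits)], subjectHits(hits))
    cnt[as.integer(rownames(agg))] <- agg[, 1]
    tb <- table(subjectHits(hits))
    nst[as.integer(names(tb))] <- as.integer(tb)
  }
  list(count = cnt, sites = nst)
}

#' Call essDNA regions from treated versus control terminus tables
#'
#' Runs the full island caller: redundancy capping, window histogram,
#' eligibility and score thresholds on the treated sample, then an
#' upper-tail Poisson test of each candidate island against
#' `max(scaled control count, lambda * island window span)` with BH
#' correction across islands. Termini of the treated sample located inside
#' retained regions are the clustered P1 cut sites.
#'
#' @param treated [terminus_table] of the P1-treated sample.
#' @param control [terminus_table] of the untreated control, or `NULL` for
#'   pure random-background calling.
#' @param cfg An [island_caller_config()].
#' @param genome Named contig-length vector.
#' @return A `call_result`: list with `regions` (GRanges with `score`, `p`,
#'   `q`, `site_count`), `clustered_sites` ([terminus_table]),
#'   `ratio_clustered`, `total_unique_sites`, `lambda`, `l0`,
#'   `score_threshold`.
#' @export
call_regions <- function(treated, control = NULL,
                         cfg = island_caller_config(), genome) {
  stopifnot(is_terminus_table(treated), !missing(genome))
  w <- cfg$window_size
  gap_windows <- cfg$gap_size %/% w
  td <- deduplicate_sites(treated, cfg$redundancy_threshold)
  n_total <- total_termini(td)
  empty <- function(lambda = NA_real_, l0 = NA_integer_, thr = NA_real_) {
    structure(list(regions = GRanges(),
                   clustered_sites = terminus_table(
                     sample_id = attr(treated, "sample_id"),
                     dose_label = attr(treated, "dose_label")),
                   ratio_clustered = if (unique_sites(td) > 0) 0 else
                     NA_real_,
                   total_unique_sites = unique_sites(td),
                   lambda = lambda, l0 = l0, score_threshold = thr,
                   config = cfg),
              class = "call_result")
  }
  if (n_total == 0) return(empty())
  gl <- sum(as.numeric(genome))
  lambda <- n_total * w / (cfg$effective_genome_fraction * gl)
  l0 <- window_eligibility_threshold(lambda, cfg$window_p0)
  windows <- window_histogram(td, w, genome)
  cand <- find_candidate_islands(windows, l0, gap_windows, lambda, w)
  effective_windows <- cfg$effective_genome_fraction * gl / w
  thr <- tryCatch(
    as.numeric(island_score_threshold(lambda, l0, gap_windows, cfg$e_value,
                                      effective_windows)),
    error = function(e) {
      warning("score-threshold DP failed (", conditionMessage(e),
              "); falling back to Monte Carlo")
      sc <- simulate_island_null(lambda, l0, gap_windows,
                                 n_windows = min(effective_windows, 2e6),
                                 reps = 200L, seed = 1L)
      reps <- attr(sc, "reps")
      scale <- effective_windows / min(effective_windows, 2e6)
      s_sorted <- sort(sc, decreasing = TRUE)
      exp_ge <- seq_along(s_sorted) / reps * scale
      ok <- which(exp_ge <= cfg$e_value)
      if (length(ok) == 0) 0 else s_sorted[max(ok)] + 1e-9
    })
  cand <- cand[cand$score >= thr, , drop = FALSE]
  if (nrow(cand) == 0) return(empty(lambda, l0, thr))

  p <- q <- rep(NA_real_, nrow(cand))
  tc <- count_in_spans(td, cand)
  if (cfg$use_control && !is.null(control)) {
    cd <- deduplicate_sites(control, cfg$redundancy_threshold)
    scale <- cfg$control_scaling
    if (is.null(scale)) {
      nc <- total_termini(cd)
      scale <- if (nc > 0) n_total / nc else 1
    }
    cc <- count_in_spans(cd, cand)
    mu <- pmax(cc$count * scale, lambda * cand$span_windows)
    p <- ppois(tc$count - 1, mu, lower.tail = FALSE)
    q <- p.adjust(p, method = "BH")
    keep <- q <= cfg$control_fdr
    cand <- cand[keep, , drop = FALSE]
    p <- p[keep]; q <- q[keep]
    tc <- lapply(tc, `[`, keep)
  }
  if (nrow(cand) == 0) return(empty(lambda, l0, thr))

  regions <- interval_set(cand$contig, cand$start, cand$end,
                          genome = genome)
  # interval_set sorts; carry metadata through the same order
  ord <- order(cand$contig, cand$start, cand$end)
  mcols(regions)$score <- cand$score[ord]
  mcols(regions)$p <- p[ord]
  mcols(regions)$q <- q[ord]
  mcols(regions)$site_count <- tc$sites[ord]

  sgr <- sites_as_granges(td)
  inside <- countOverlaps(sgr, regions, ignore.strand = TRUE) > 0
  clustered <- terminus_table(td$contig[inside], td$position[inside],
                              td$strand[inside], td$count[inside],
                              sample_id = attr(treated, "sample_id"),
                              dose_label = attr(treated, "dose_label"))
  structure(list(regions = regions, clustered_sites = clustered,
                 ratio_clustered = unique_sites(clustered) /
                   unique_sites(td),
                 total_unique_sites = unique_sites(td),
                 lambda = lambda, l0 = l0, score_threshold = thr,
                 config = cfg),
            class = "call_result")
}

#' @export
print.call_result <- function(x, ...) {
  cat(sprintf(paste0(
    "call_result: %d regions, %d clustered sites of %d unique",
    " (ratio %.4f)\n  lambda=%.4g l0=%d score_threshold=%.3f\n"),
    length(x$regions), unique_sites(x$clustered_sites),
    x$total_unique_sites,
    if (is.na(x$ratio_clustered)) NA else x$ratio_clustered,
    x$lambda, x$l0, x$score_threshold))
  invisible(x)
}

#' Merge region sets across replicates and doses
#'
#' Interval union (overlapping and bookended intervals joined) over the
#' concatenation of the input sets.
#'
#' @param sets List of `GRanges` on the same genome.
#' @return A merged `GRanges`.
#' @export
merge_region_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  merge_intervals(do.call(c, lapply(sets, function(g) {
    GRanges(seqnames(g), IRanges(start(g), end(g)))
  })))
}
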