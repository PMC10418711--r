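# Independent brute-force oracles used to cross-check the package's
# vectorized/DP implementations. These are deliberately naive and share no
# code with the implementation paths they verify.

# Position-by-position membership scan.
brute_count_sites <- function(table, elements) {
  if (nrow(table) == 0 || length(elements) == 0) return(0L)
  ec <- as.character(GenomicRanges::seqnames(elements))
  es <- BiocGenerics::start(elements) - 1
  ee <- BiocGenerics::end(elements)
  hits <- 0L
  for (i in seq_len(nrow(table))) {
    p <- table$position[i]
    ctg <- table$contig[i]
    inside <- FALSE
    for (j in seq_along(elements)) {
      if (ec[j] == ctg && es[j] <= p && p < ee[j]) {
        inside <- TRUE
        break
      }
    }
    if (inside) hits <- hits + 1L
  }
  hits
}

# Quadratic all-pairs interval overlap count.
brute_overlap_count <- function(a, b) {
  ac <- as.character(GenomicRanges::seqnames(a))
  as0 <- BiocGenerics::start(a) - 1
  ae0 <- BiocGenerics::end(a)
  bc <- as.character(GenomicRanges::seqnames(b))
  bs0 <- BiocGenerics::start(b) - 1
  be0 <- BiocGenerics::end(b)
  n <- 0L
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      if (ac[i] == bc[j] && as0[i] < be0[j] && bs0[j] < ae0[i]) {
        n <- n + 1L
        break
      }
    }
  }
  n
}

# Exhaustive enumeration of eligible-window clusterings on one contig: every
# (i, j) pair of eligible windows is tested for being a maximal valid island
# (internal gaps within reach, no extension possible on either side).
enumerate_islands <- function(counts, l0, gap_windows, lambda, w) {
  elig <- which(counts >= l0) - 1L  # 0-based window indices
  out <- NULL
  reach <- gap_windows + 1L
  for (i in seq_along(elig)) {
    for (j in i:length(elig)) {
      run <- elig[i:j]
      if (length(run) > 1 && any(diff(run) > reach)) next
      left_ok <- i == 1 || (run[1] - elig[i - 1]) > reach
      right_ok <- j == length(elig) || (elig[j + 1] - run[length(run)]) > reach
      if (!(left_ok && right_ok)) next
      score <- sum(-dpois(counts[run + 1L], lambda, log = TRUE))
      out <- rbind(out, data.frame(start = run[1] * w,
                                   end = (run[length(run)] + 1L) * w,
                                   n_eligible = length(run),
                                   score = score))
    }
  }
  out
}

# Brute-force nearest-TSS proximity scan.
brute_proximity <- function(promoters, tss, radius) {
  pc <- as.character(GenomicRanges::seqnames(promoters))
  ps0 <- BiocGenerics::start(promoters) - 1
  pe0 <- BiocGenerics::end(promoters)
  vapply(seq_along(promoters), function(i) {
    for (j in seq_len(nrow(tss))) {
      if (tss$contig[j] != pc[i]) next
      lo <- tss$position[j] - radius
      hi <- tss$position[j] + radius + 1
      if (ps0[i] < hi && lo < pe0[i]) return(TRUE)
    }
    FALSE
  }, logical(1))
}

site_key <- function(d) paste(d$contig, d$position, d$strand)
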