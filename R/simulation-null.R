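# Shuffle-based background simulation: the same number of termini as a real
# sample is placed uniformly at random across the genome (contigs chosen
# proportionally to length, mirroring the default behaviour of the standard
# interval-shuffling tools), the caller is re-run, and the simulated region
# and clustered-site counts summarize the background noise.

#' Place termini uniformly at random across a genome
#'
#' Each of `n` termini independently picks a contig with probability
#' proportional to its length, a position uniform on the contig and a strand
#' uniform on `+`/`-`. Deterministic given `seed`; colliding placements are
#' aggregated so the total terminus count is exactly `n`.
#'
#' @param n Number of termini.
#' @param genome Named contig-length vector.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @param sample_id,dose_label Metadata for the resulting table.
#' @return A [terminus_table] with `total_termini == n`.
#' @export
shuffle_sites <- function(n, genome, seed = NULL,
                          sample_id = "shuffled",
                          dose_label = NA_character_) {
  stopifnot(n >= 0, length(genome) > 0, all(genome > 0))
  draw <- function() {
    if (n == 0) {
      return(terminus_table(sample_id = sample_id,
                            dose_label = dose_label))
    }
    ci <- sample.int(length(genome), n, replace = TRUE,
                     prob = as.numeric(genome))
    len <- as.numeric(genome)[ci]
    pos <- floor(runif(n) * len)
    pos <- pmin(pos, len - 1)
    str <- sample(c("+", "-"), n, replace = TRUE)
    terminus_table(names(genome)[ci], pos, str,
                   sample_id = sample_id, dose_label = dose_label)
  }
  if (is.null(seed)) draw() else with_seed_(seed, draw())
}

#' Repeated shuffle-and-call null replicates
#'
#' For each replicate, treated and control terminus sets of the requested
#' sizes are shuffled across the genome, [call_regions()] is run with the
#' supplied configuration, and the simulated region count, clustered-site
#' count and clustered-site ratio are recorded. Replicate `i` is seeded
#' with `base_seed + i`, so the run is bit-reproducible.
#'
#' @param treated_n,control_n Terminus counts matching the real samples.
#' @param genome Named contig-length vector.
#' @param cfg An [island_caller_config()].
#' @param reps Number of replicates (the published analysis used 100).
#' @param base_seed Base RNG seed.
#' @return A data.frame with one row per replicate (`replicate`, `seed`,
#'   `region_count`, `clustered_sites`, `ratio`), with a `summary`
#'   attribute holding means and SDs.
#' @export
run_null_replicates <- function(treated_n, control_n, genome,
                                cfg = island_caller_config(), reps = 100L,
                                base_seed = 1L) {
  stopifnot(reps >= 1)
  rows <- vector("list", reps)
  for (i in seq_len(reps)) {
    seed <- base_seed + i
    res <- with_seed_(seed, {
      tr <- shuffle_sites(treated_n, genome, seed = NULL,
                          sample_id = "sim_treated")
      ct <- shuffle_sites(control_n, genome, seed = NULL,
                          sample_id = "sim_control")
      call_regions(tr, ct, cfg, genome)
    })
    ratio <- res$ratio_clustered
    rows[[i]] <- data.frame(
      replicate = i, seed = seed,
      region_count = length(res$regions),
      clustered_sites = unique_sites(res$clustered_sites),
      ratio = if (is.na(ratio)) 0 else ratio)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- data.frame(
    metric = c("region_count", "clustered_sites", "ratio"),
    mean = c(mean(out$region_count), mean(out$clustered_sites),
             mean(out$ratio)),
    sd = c(sd(out$region_count), sd(out$clustered_sites), sd(out$ratio)))
  out
}
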