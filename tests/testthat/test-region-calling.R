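test_that("redundancy capping keeps totals consistent", {
  tt <- terminus_table("c", c(1, 2, 3), "+", count = c(7, 1, 3))
  dd <- deduplicate_sites(tt, 1L)
  expect_equal(dd$count, c(1, 1, 1))
  expect_identical(deduplicate_sites(dd, 1L)$count, dd$count)
  dd2 <- deduplicate_sites(tt, 2L)
  expect_equal(total_termini(dd2), sum(pmin(tt$count, 2)))
})

test_that("window histogram bins half-open windows and conserves counts", {
  tt <- terminus_table("c", 0:9, "+")
  h <- window_histogram(tt, 10)
  expect_equal(h$window, 0L)
  expect_equal(h$count, 10)
  h <- window_histogram(terminus_table("c", 10, "+"), 10)
  expect_equal(h$window, 1L)
  set.seed(13)
  tt <- terminus_table(sample(c("a", "b"), 500, TRUE),
                       sample(0:5000, 500, TRUE),
                       sample(c("+", "-"), 500, TRUE))
  h <- window_histogram(tt, 10)
  expect_equal(sum(h$count), total_termini(tt))
})

test_that("window eligibility threshold matches direct tail summation", {
  expect_equal(window_eligibility_threshold(0.05, 0.2), 1L)
  expect_equal(window_eligibility_threshold(2, 0.2), 4L)
  expect_equal(window_eligibility_threshold(5, 1), 1L)
  for (lambda in c(0.01, 0.1, 0.5, 1, 2, 5, 10)) {
    for (p0 in c(0.01, 0.05, 0.2, 0.5)) {
      l0 <- window_eligibility_threshold(lambda, p0)
      # direct summation of the upper tail
      tail_at <- function(k) 1 - sum(dpois(0:(k - 1), lambda))
      expect_lt(tail_at(l0), p0)
      if (l0 > 1) expect_gte(tail_at(l0 - 1), p0)
    }
  }
})

test_that("island clustering follows the gap rule", {
  w <- 10; lambda <- 0.1
  win <- function(idx) data.frame(contig = "c", window = idx,
                                  count = rep(1L, length(idx)))
  # 4 intervening windows: two islands
  isl <- find_candidate_islands(win(c(0, 5)), 1, 3, lambda, w)
  expect_equal(nrow(isl), 2)
  # 3 intervening windows: one island spanning [0,50)
  isl <- find_candidate_islands(win(c(0, 4)), 1, 3, lambda, w)
  expect_equal(nrow(isl), 1)
  expect_equal(c(isl$start, isl$end), c(0, 50))
  # single eligible window scores -log pmf
  isl <- find_candidate_islands(win(7), 1, 3, lambda, w)
  expect_equal(isl$score, -dpois(1, lambda, log = TRUE))
  expect_equal(c(isl$start, isl$end), c(70, 80))
})

test_that("caller equals exhaustive enumeration on small instances", {
  w <- 10; gap_w <- 3
  set.seed(21)
  for (rep in 1:5) {
    counts <- rpois(200, 0.3)  # 2 kb contig
    lambda <- 0.3
    l0 <- window_eligibility_threshold(lambda, 0.2)
    idx <- which(counts > 0) - 1L
    windows <- data.frame(contig = "c", window = idx,
                          count = counts[idx + 1L])
    got <- find_candidate_islands(windows, l0, gap_w, lambda, w)
    want <- enumerate_islands(counts, l0, gap_w, lambda, w)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("score threshold DP is self-consistent and matches Monte Carlo", {
  expect_equal(as.numeric(island_score_threshold(0.05, 1, 3, Inf, 1e5)), 0)

  lambda <- 0.02; l0 <- 1; gap_w <- 3; nwin <- 10000
  thr <- island_score_threshold(lambda, l0, gap_w, 0.01, nwin)
  scores <- attr(thr, "scores")
  expected <- attr(thr, "expected_ge")
  i <- match(as.numeric(thr), scores)
  expect_lte(expected[i], 0.01)
  expect_gt(expected[i - 1], 0.01)

  mc <- simulate_island_null(lambda, l0, gap_w, nwin, reps = 1500, seed = 7)
  reps <- attr(mc, "reps")
  for (s in c(5, 10, 15)) {
    est <- sum(mc >= s) / reps
    se <- sqrt(est / reps)
    dp <- expected[findInterval(s, scores)]
    expect_lt(abs(dp - est), 4 * se + 1e-6)
  }
})

test_that("planted regions are recovered and pure noise yields nothing", {
  g <- c(chr1 = 1e6)
  truth <- plant_regions(g, n = 20, sizes = 200, seed = 11)
  sims <- simulate_titration_termini(truth, g, seed = 42)
  cfg <- island_caller_config()
  res <- call_regions(sims[["0.1U"]], sims$control, cfg, g)

  sens <- mean(countOverlaps(truth, res$regions) > 0)
  prec <- mean(countOverlaps(res$regions, truth) > 0)
  expect_gte(sens, 0.9)
  expect_gte(prec, 0.9)
  expect_true(res$ratio_clustered >= 0 && res$ratio_clustered <= 1)
  expect_lte(unique_sites(res$clustered_sites), res$total_unique_sites)

  # reported per-region site counts match an independent recount
  td <- deduplicate_sites(sims[["0.1U"]], 1L)
  for (k in head(seq_along(res$regions), 5)) {
    expect_equal(S4Vectors::mcols(res$regions)$site_count[k],
                 count_sites_in(td, res$regions[k]))
  }

  # a sample tested against itself never beats its own control
  self <- call_regions(sims[["0.1U"]], sims[["0.1U"]], cfg, g)
  expect_length(self$regions, 0)

  # empty treated table
  e <- call_regions(terminus_table(), NULL, cfg, g)
  expect_length(e$regions, 0)
})

test_that("recovered region count is monotone in planted enrichment", {
  g <- c(chr1 = 5e5)
  truth <- plant_regions(g, n = 10, sizes = 200, seed = 4)
  cfg <- island_caller_config()
  n_rec <- vapply(c(0.02, 0.06, 0.12), function(dens) {
    model <- titration_model(specific_density = list(
      essDNA = c(control = 0, "0.01U" = 0, "0.1U" = dens, "1U" = dens,
                 "10U" = dens)))
    sims <- simulate_titration_termini(truth, g, model, seed = 9)
    res <- call_regions(sims[["0.1U"]], sims$control, cfg, g)
    sum(countOverlaps(truth, res$regions) > 0)
  }, 0)
  expect_true(all(diff(n_rec) >= 0))
})

test_that("region sets merge across doses by interval union", {
  a <- interval_set("c", 0, 100)
  b <- interval_set("c", 50, 150)
  m <- merge_region_sets(list(a, b))
  expect_equal(c(start(m) - 1, end(m)), c(0, 150))
  d <- merge_region_sets(list(interval_set("c", 0, 10),
                              interval_set("c", 500, 510)))
  expect_length(d, 2)
  expect_lte(length(merge_region_sets(list(a, b, d))),
             length(a) + length(b) + length(d))
})
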