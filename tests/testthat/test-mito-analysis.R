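test_that("default annotation converts printed coordinates and tiles the genome", {
  anno <- mito_annotation()
  expect_equal(anno$regions$Q1[1, ], c(start = 10592, end = 16024))
  expect_equal(anno$regions$Q2[1, ], c(start = 5159, end = 10592))
  expect_equal(anno$regions$Q3[1, ], c(start = 2868, end = 5158))
  expect_equal(anno$regions$Q4[1, ], c(start = 578, end = 2868))
  expect_equal(anno$regions$OL[1, ], c(start = 5158, end = 5159))
  # NCR wraps the origin: two sub-intervals, one label
  expect_equal(nrow(anno$regions$NCR), 2)
  covered <- sum(vapply(anno$regions, function(m) {
    sum(m[, "end"] - m[, "start"])
  }, 0))
  expect_equal(covered, anno$genome_length)
})

test_that("annotation round-trips through the key=value config file", {
  f <- tempfile(fileext = ".cfg")
  writeLines(c("contig = MT", "genome_length = 16571", "h_strand = -",
               "# printed 1-based inclusive coordinates",
               "q1 = 10593, 16024", "q2 = 5160, 10592",
               "q3 = 2869, 5158", "q4 = 579, 2868"), f)
  anno <- read_mito_annotation(f)
  expect_equal(anno$contig, "MT")
  expect_equal(anno$regions$Q1[1, "start"], c(start = 10592))
})

test_that("wrapped NCR counting sees both sides of the origin", {
  anno <- mito_annotation()
  h <- anno$h_strand
  tt <- terminus_table("chrM", c(100, anno$genome_length - 50), h)
  expect_equal(strand_region_counts(tt, anno, "NCR", "H", "sites"), 2)
  expect_equal(strand_region_counts(tt, anno, "NCR", "L", "sites"), 0)
})

test_that("region/strand counts partition the totals and modes agree", {
  anno <- mito_annotation()
  set.seed(5)
  tt <- terminus_table("chrM",
                       sample(0:(anno$genome_length - 1), 3000, TRUE),
                       sample(c("+", "-"), 3000, TRUE))
  for (s in c("H", "L")) {
    tot <- sum(vapply(names(anno$regions), function(r) {
      strand_region_counts(tt, anno, r, s, "termini")
    }, 0))
    ref <- ssingleP1:::mito_ref_strand(anno, s)
    expect_equal(tot, sum(tt$count[tt$strand == ref]))
  }
  # depth = termini / sites, missing over empty regions
  h5 <- terminus_table("chrM", c(10600, 10600, 10700, 10800, 10800),
                       anno$h_strand)
  expect_equal(strand_region_counts(h5, anno, "Q1", "H", "termini"), 5)
  expect_equal(strand_region_counts(h5, anno, "Q1", "H", "sites"), 3)
  expect_equal(strand_region_counts(h5, anno, "Q1", "H", "depth"), 5 / 3)
  expect_true(is.na(strand_region_counts(h5, anno, "OL", "H", "depth")))
})

test_that("H/L ratios behave at identity, asymmetry and degeneracy", {
  anno <- mito_annotation()
  h <- anno$h_strand; l <- setdiff(c("+", "-"), h)
  tt <- terminus_table("chrM", c(10600:10609, 10700, 10701),
                       c(rep(h, 10), rep(l, 2)))
  expect_equal(hl_ratio(tt, anno, "Q1", "sites"), 5)
  sym <- terminus_table("chrM", c(10600, 10601), c(h, l))
  expect_equal(hl_ratio(sym, anno, "Q1", "sites"), 1)
  only_h <- terminus_table("chrM", 10600, h)
  expect_warning(r <- hl_ratio(only_h, anno, "Q1", "sites"), "infinite")
  expect_identical(r, Inf)
  expect_equal(normalized_hl_ratio(tt, sym, anno, "Q1", "sites"), 5)
})

test_that("a 7S-like redundant site inflates termini ratios but not site ratios", {
  anno <- mito_annotation()
  m7 <- mito_sim_model(seven_s_weight = 60000)
  sims <- simulate_mito_termini(m7, anno, n = 30000, seed = 8)
  ctl <- sims$control
  r_term <- hl_ratio(ctl, anno, "NCR", "termini")
  r_site <- hl_ratio(ctl, anno, "NCR", "sites")
  expect_gt(r_term, 50)
  expect_lt(r_site, 5)
  # the constant redundant signal dominates both samples under "termini",
  # compressing the normalized ratio toward 1; unique-site counting
  # recovers the genuine treated/control strand asymmetry
  tr <- sims[["0.1U"]]
  expect_gt(normalized_hl_ratio(tr, ctl, anno, "NCR", "sites"),
            normalized_hl_ratio(tr, ctl, anno, "NCR", "termini"))
})

test_that("essDNA index is 1 on identical samples and scale-invariant", {
  anno <- mito_annotation()
  set.seed(9)
  tt <- terminus_table("chrM",
                       sample(0:(anno$genome_length - 1), 2000, TRUE),
                       sample(c("+", "-"), 2000, TRUE))
  for (r in c("Q1", "Q3", "NCR")) {
    expect_equal(essdna_index(tt, tt, anno, r, "H"), 1)
  }
  doubled <- terminus_table(tt$contig, tt$position, tt$strand,
                            tt$count * 2)
  expect_equal(essdna_index(doubled, tt, anno, "Q1", "H"), 1)
})

test_that("the strand-displacement simulation recovers the exposure ordering", {
  anno <- mito_annotation()
  sims <- simulate_mito_termini(mito_sim_model(), anno, n = 50000, seed = 2)
  tr <- sims[["0.1U"]]; ctl <- sims$control
  i <- function(r, s) essdna_index(tr, ctl, anno, r, s)
  expect_gt(i("Q1", "H"), i("Q2", "H"))
  expect_gt(i("Q3", "H"), i("Q4", "H"))
  for (r in c("Q1", "Q2", "Q3", "Q4")) {
    expect_gt(i(r, "L"), 0.7)
    expect_lt(i(r, "L"), 1.3)
  }
  # uniform exposure is the null: H/L ratio near 1
  uni <- mito_sim_model(h_exposure = c(Q1 = 0.02, Q2 = 0.02, Q3 = 0.02,
                                       Q4 = 0.02, NCR = 0.02, OL = 0.02),
                        l_exposure = 0.02)
  usim <- simulate_mito_termini(uni, anno, n = 50000, seed = 3)
  r <- hl_ratio(usim[["1U"]], anno, "Q1", "sites")
  expect_gt(r, 0.9)
  expect_lt(r, 1.1)
})

test_that("paired t-test matches the closed form and flags degeneracy", {
  r <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_true(r$degenerate)

  r <- paired_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_true(r$degenerate)
  expect_true(is.na(r$p))

  a <- c(1.1, 2.0, 3.2); b <- c(0.9, 1.7, 2.8)
  r <- paired_t_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(abs(t_hand), df = length(d) - 1, lower.tail = FALSE)
  expect_equal(r$t, t_hand)
  expect_equal(r$p, p_hand)
  expect_false(r$degenerate)
})

test_that("mito_strand_summary tabulates every region x strand x mode", {
  anno <- mito_annotation()
  tt <- terminus_table("chrM", c(100, 700, 3000), c("-", "-", "+"))
  s <- mito_strand_summary(list(s1 = tt), anno)
  expect_equal(nrow(s), length(anno$regions) * 2 * 3)
  expect_equal(s$value[s$region == "NCR" & s$strand == "H" &
                         s$mode == "sites"], 1)
})
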