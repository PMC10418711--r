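test_that("toy genomes are deterministic with exact lengths and tracts", {
  sizes <- c(big = 10000, chrM = 16571)
  g1 <- make_toy_genome(sizes, seed = 3)
  g2 <- make_toy_genome(sizes, seed = 3)
  expect_equal(genome_of(g1), sizes)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- make_toy_genome(sizes, seed = 4)
  expect_false(identical(as.character(g1), as.character(g3)))
  gt <- make_toy_genome(sizes, seed = 3,
                        tracts = data.frame(contig = "big", start = 500,
                                            length = 20, base = "T"))
  expect_equal(as.character(subseq(gt[["big"]], 501, 520)), strrep("T", 20))
})

test_that("planted regions are disjoint, BED-round-trippable and sized", {
  g <- c(chr1 = 1e6)
  tr <- plant_regions(g, n = 20, sizes = 200, seed = 1)
  expect_length(tr, 20)
  expect_true(all(width(tr) == 200))
  expect_equal(sum(countOverlaps(tr, tr) > 1), 0)
  f <- tempfile(fileext = ".bed")
  save_intervals(tr, f)
  back <- load_intervals(f, genome = g)
  expect_equal(start(back), start(tr))
  expect_equal(S4Vectors::mcols(back)$name, S4Vectors::mcols(tr)$name)

  lnorm_sizes <- function(n) rlnorm(n, meanlog = log(45), sdlog = 0.5)
  tr2 <- plant_regions(c(chr1 = 5e7), n = 500, sizes = lnorm_sizes,
                       seed = 2, min_gap = 100)
  med <- sort(width(tr2))[250]
  expect_gte(med, 30)
  expect_lte(med, 60)
})

test_that("titration termini follow the configured rate structure", {
  g <- c(chr1 = 1e6)
  truth <- plant_regions(g, n = 20, sizes = 200, seed = 11)
  sims <- simulate_titration_termini(truth, g, seed = 7)
  expect_named(sims, titration_doses())

  in_truth <- function(tt) count_sites_in(tt, truth)
  area <- sum(width(truth)) / sum(g)

  # control carries no in-region excess beyond background
  ctl_in <- in_truth(sims$control)
  expect_lt(abs(ctl_in - unique_sites(sims$control) * area),
            3 * sqrt(unique_sites(sims$control) * area) + 3)

  # 0.1U in-region density is background + configured specific density
  m <- titration_model()
  dens_01 <- m$background_rate + m$specific_density$essDNA[["0.1U"]]
  got <- total_termini(sims[["0.1U"]]) - total_termini(sims$control)
  expect_lt(abs(in_truth(sims[["0.1U"]]) -
                  dens_01 * sum(width(truth))),
            4 * sqrt(dens_01 * sum(width(truth))))

  # reproducibility
  sims2 <- simulate_titration_termini(truth, g, seed = 7)
  expect_identical(as.data.frame(sims[["1U"]]),
                   as.data.frame(sims2[["1U"]]))
})

test_that("emitted reads pass the classifier and round-trip exactly", {
  gseq <- make_toy_genome(c(chrA = 30000), seed = 2)
  g <- genome_of(gseq)
  raw <- shuffle_sites(200, g, seed = 9)
  keepable <- raw$position > 150 & raw$position < g[raw$contig] - 150
  truth <- terminus_table(raw$contig[keepable], raw$position[keepable],
                          raw$strand[keepable])
  fq1 <- tempfile(fileext = ".fq"); fq2 <- tempfile(fileext = ".fq")
  sam <- tempfile(fileext = ".sam")
  expected <- emit_reads(truth, gseq, fq1, fq2, sam, seed = 3)
  emitted <- expected[expected$emitted, ]
  expect_gt(nrow(emitted), 0)

  # every emitted pair passes the structural filter; T runs are in range
  r2 <- ssingleP1:::read_fastq_(fq2)
  runs <- attr(regexpr("^T+", r2$seq), "match.length")
  expect_true(all(runs >= 11 & runs <= 13))
  rep <- process_fastq_pair(fq1, fq2, tempfile(fileext = ".fq"),
                            tempfile(fileext = ".fq"))
  expect_equal(rep$kept, nrow(emitted))
  expect_equal(sum(rep$counters), 0)

  # extraction recovers every emitted terminus exactly
  tab <- extract_termini(sam)
  expect_setequal(site_key(tab), site_key(emitted))

  # reads planted over an A-rich tract are removed by the priming filter
  gA <- make_toy_genome(c(chrA = 30000), seed = 2,
                        tracts = data.frame(contig = "chrA", start = 1000,
                                            length = 20, base = "T"))
  ttA <- terminus_table("chrA", c(1020, 20000), "-")
  samA <- tempfile(fileext = ".sam")
  expected_a <- emit_reads(ttA, gA, sam = samA, seed = 4)
  tabA <- extract_termini(samA, genome = gA)
  expect_false(1020 %in% tabA$position)
})

test_that("tower fixtures reproduce prescribed unique and overlap counts", {
  fx <- make_overlap_towers(
    patterns = data.frame(pattern = c("X&Y", "X&Z"), count = c(7, 3)),
    unique_counts = c(X = 10, Y = 4, Z = 6))
  mm <- multiset_membership(fx$sets)
  s <- mm$summary
  expect_equal(s$n[s$set == "X"], 20)
  expect_equal(s$n_unique, c(10, 4, 6))
  expect_equal(s$pct_unique[s$set == "X"], 50)
})

test_that("promoter fixtures encode exact proximity fractions", {
  prox <- rep(c(TRUE, FALSE), c(30, 70))
  cage <- rep(c(TRUE, FALSE), c(12, 88))
  fx <- make_promoter_tss_fixture(prox, cage)
  got <- classify_promoter_proximity(fx$promoters, fx$tss)
  expect_equal(got$proximal, 30)
  expect_equal(got$percent, 30.0)
  cg <- classify_promoter_proximity(fx$promoters,
                                    cage_supported_tss(fx$tss, fx$cage))
  expect_equal(cg$proximal, 12)
})
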