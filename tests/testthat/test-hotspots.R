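toy_genome_100k <- function()
  genome_model(data.frame(name = "c1", length = 100000L),
               data.frame(name = "c1", start = 50000L, end = 50200L))

test_that("occupancy counts overlapping tracts per position", {
  g <- toy_genome_100k()
  tracts <- data.frame(line = c("L1", "L2", "L3"), chrom = "c1",
                       start = c(100L, 150L, 180L), end = c(200L, 300L, 190L),
                       haplotype = "P1", support = 3L)
  occ <- build_occupancy(tracts, g)
  expect_equal(occupancy_at(occ, "c1", 185), 3L)
  expect_equal(occupancy_at(occ, "c1", 250), 1L)
  expect_equal(occupancy_at(occ, "c1", 50), 0L)
  # counts change only at tract boundaries: piecewise constant segments
  seg <- occ$segments
  expect_true(all(seg$start[-1] == seg$end[-nrow(seg)] + 1))
  expect_equal(seg$start[1], 1)
  expect_equal(seg$end[nrow(seg)], 100000)
})

test_that("occupancy equals naive per-position counting on a toy
           chromosome", {
  g <- toy_genome_100k()
  set.seed(31)
  tracts <- data.frame(line = sample(paste0("L", 1:8), 60, replace = TRUE),
                       chrom = "c1", start = sample.int(90000L, 60),
                       haplotype = sample(c("P1", "P2"), 60, replace = TRUE),
                       support = 2L)
  tracts$end <- pmin(100000L, tracts$start + sample.int(20000L, 60))
  for (dedup in c(TRUE, FALSE)) {
    occ <- build_occupancy(tracts, g, dedup_lines = dedup)
    dense <- oracle_occupancy(tracts, "c1", 100000L, dedup_lines = dedup)
    expect_equal(occupancy_at(occ, "c1", 1:100000), dense)
  }
  # haplotype restriction drops the other parent's tracts
  occ_p1 <- build_occupancy(tracts, g, restrict_haplotype = "P1",
                            dedup_lines = FALSE)
  dense_p1 <- oracle_occupancy(tracts[tracts$haplotype == "P1", ], "c1",
                               100000L, dedup_lines = FALSE)
  expect_equal(occupancy_at(occ_p1, "c1", 1:100000), dense_p1)
})

test_that("segment sums conserve total covered tract length", {
  g <- toy_genome_100k()
  set.seed(17)
  tracts <- data.frame(line = paste0("L", 1:40), chrom = "c1",
                       start = sample.int(80000L, 40),
                       haplotype = "P1", support = 2L)
  tracts$end <- pmin(100000L, tracts$start + sample.int(15000L, 40))
  occ <- build_occupancy(tracts, g, dedup_lines = FALSE)
  seg <- occ$segments
  # sum(count x segment span) = total inclusive span of all tracts, exactly
  expect_identical(sum(as.numeric(seg$count) * (seg$end - seg$start + 1)),
                   sum(as.numeric(tracts$end - tracts$start + 1)))
})

test_that("hotspot calling returns maximal merged intervals above the
           threshold", {
  g <- toy_genome_100k()
  tracts <- data.frame(line = c("L1", "L2", "L3"), chrom = "c1",
                       start = c(100L, 150L, 180L), end = c(200L, 300L, 190L),
                       haplotype = "P1", support = 3L)
  occ <- build_occupancy(tracts, g)
  hot3 <- call_hotspots(occ, min_count = 3)
  expect_equal(nrow(hot3), 1L)
  expect_equal(c(hot3$start, hot3$end, hot3$peak_count), c(180, 190, 3))
  expect_equal(nrow(call_hotspots(occ, min_count = 4)), 0L)
  # empty tract set -> all-zero occupancy
  occ0 <- build_occupancy(tracts[0, ], g)
  expect_true(all(occ0$segments$count == 0))
})

test_that("adjacent qualifying segments merge into one hotspot with feature
           annotation", {
  g <- genome_model(data.frame(name = "c1", length = 100000L),
                    data.frame(name = "c1", start = 50000L, end = 50200L),
                    features = list(LTR = data.frame(chrom = "c1",
                                                     start = 900L, end = 950L,
                                                     name = "YLT1")))
  # two tract stacks meeting end-to-start: one merged hotspot
  tracts <- data.frame(line = paste0("L", 1:4), chrom = "c1",
                       start = c(1000L, 1000L, 1501L, 1501L),
                       end = c(1500L, 1500L, 2000L, 2000L),
                       haplotype = "P1", support = 2L)
  occ <- build_occupancy(tracts, g)
  hot <- call_hotspots(occ, min_count = 2)
  expect_equal(nrow(hot), 1L)
  expect_equal(c(hot$start, hot$end), c(1000, 2000))
  expect_equal(hot$nearest_feature, "YLT1")
  expect_equal(hot$feature_dist, 1000 - 950)
})

test_that("a line with overlapping tracts counts once when deduplicated", {
  g <- toy_genome_100k()
  tracts <- data.frame(line = "L1", chrom = "c1",
                       start = c(100L, 150L), end = c(200L, 250L),
                       haplotype = "P1", support = 2L)
  occ_d <- build_occupancy(tracts, g, dedup_lines = TRUE)
  occ_n <- build_occupancy(tracts, g, dedup_lines = FALSE)
  expect_equal(occupancy_at(occ_d, "c1", 175), 1L)
  expect_equal(occupancy_at(occ_n, "c1", 175), 2L)
})
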