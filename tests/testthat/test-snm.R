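mk_map <- function() {
  map <- data.frame(chrom = "c1", pos = c(100L, 300L, 500L),
                    p1 = "A", p2 = "G")
  class(map) <- c("snp_map", "data.frame")
  map
}
parent_rec <- function() data.frame(
  chrom = "c1", pos = c(100L, 300L, 500L, 1000L, 2000L),
  ref = c("A", "A", "A", "C", "T"), alt = c("G", "G", "G", ".", "A"),
  gt = c("0/1", "0/1", "0/1", "0/0", "0/1"), dp = 70, mq = 60)
line_rec <- function(pos = 1000L, alt = "T", gt = "0/1", dp = 60, mq = 50)
  data.frame(chrom = "c1", pos = pos, ref = "C", alt = alt, gt = gt,
             dp = dp, mq = mq)

test_that("de novo candidates pass the parent-comparison and DP/MQ filters", {
  # clean heterozygous novelty at a non-marker position
  m <- detect_snms(line_rec(), parent_rec(), mk_map())
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos, 1000L)
  expect_equal(m$genotype, "0/1")
  # depth 30 < 40: filtered
  m2 <- detect_snms(line_rec(dp = 30), parent_rec(), mk_map())
  expect_equal(nrow(m2), 0L)
  expect_equal(attr(m2, "dropped")[["low_depth"]], 1L)
  # mapping quality 35 < 40: filtered
  m3 <- detect_snms(line_rec(mq = 35), parent_rec(), mk_map())
  expect_equal(nrow(m3), 0L)
  expect_equal(attr(m3, "dropped")[["low_mapq"]], 1L)
})

test_that("parental markers, homozygous calls and parent-shared alleles are
           never emitted", {
  map <- mk_map()
  # a homozygous transition at a marker position is LOH, not a mutation
  r1 <- data.frame(chrom = "c1", pos = 300L, ref = "A", alt = "G",
                   gt = "1/1", dp = 70, mq = 60)
  expect_equal(nrow(detect_snms(r1, parent_rec(), map)), 0L)
  # even a heterozygous odd call at a marker position is excluded
  r2 <- data.frame(chrom = "c1", pos = 300L, ref = "A", alt = "T",
                   gt = "0/1", dp = 70, mq = 60)
  m2 <- detect_snms(r2, parent_rec(), map)
  expect_equal(nrow(m2), 0L)
  expect_equal(attr(m2, "dropped")[["parental_snp"]], 1L)
  # allele already present in the parent record: not de novo
  m3 <- detect_snms(line_rec(pos = 2000L, alt = "A"), parent_rec(), map)
  expect_equal(nrow(m3), 0L)
  expect_equal(attr(m3, "dropped")[["allele_in_parent"]], 1L)
  # no parent record at the candidate: dropped with its reason
  m4 <- detect_snms(line_rec(pos = 3000L), parent_rec(), map)
  expect_equal(nrow(m4), 0L)
  expect_equal(attr(m4, "dropped")[["no_parent_evidence"]], 1L)
  # homozygous novel call: not an SNM (expected heterozygous)
  m5 <- detect_snms(line_rec(gt = "1/1"), parent_rec(), map)
  expect_equal(nrow(m5), 0L)
})

test_that("candidates inside called LOH tracts are flagged, not dropped", {
  tracts <- data.frame(line = "L1", chrom = "c1", start = 900L, end = 1100L,
                       haplotype = "P1", support = 5L)
  m <- detect_snms(line_rec(), parent_rec(), mk_map(), line_name = "L1",
                   loh_tracts = tracts)
  expect_equal(nrow(m), 1L)
  expect_true(m$in_loh)
})

test_that("the rate estimator reproduces published-scale arithmetic", {
  r <- estimate_rate(47, 10, g = 2000, G = 2.404e7)
  expect_equal(r$mu_e10, 0.98)
  expect_equal(estimate_rate(13, 5, g = 2000, G = 2.404e7)$mu_e10, 0.54)
  expect_equal(estimate_rate(0, 10, g = 2000, G = 2.404e7)$mu, 0)
  expect_error(estimate_rate(5, 0, 2000, 2.404e7), "positive")
  expect_error(estimate_rate(-1, 10, 2000, 2.404e7), ">= 0")
  # per-line counts must be consistent and give a between-line SE
  r2 <- estimate_rate(10, 5, g = 2000, G = 2.404e7,
                      per_line_m = c(1, 2, 3, 0, 4))
  expect_equal(length(r2$per_line_mu), 5L)
  expect_equal(mean(r2$per_line_mu), r2$mu)
  expect_error(estimate_rate(10, 5, per_line_m = c(1, 2)), "summing to m")
})

test_that("rate pooling is invariant to splitting lines into batches", {
  m1 <- 12; n1 <- 4; m2 <- 8; n2 <- 6
  pooled <- estimate_rate(m1 + m2, n1 + n2, g = 2000, G = 2.404e7)
  # the pooled rate is the line-weighted mean of batch rates
  mu_batch <- (n1 * estimate_rate(m1, n1, 2000, 2.404e7)$mu +
                 n2 * estimate_rate(m2, n2, 2000, 2.404e7)$mu) / (n1 + n2)
  expect_equal(pooled$mu, mu_batch)
})

test_that("rate comparison reports Welch p-values and both fold forms", {
  a <- c(1.1, 0.9, 1.0, 1.2, 0.8) * 1e-10
  r_same <- compare_rates(a, a)
  expect_equal(r_same$fold, 1)
  expect_gt(r_same$p_value, 0.99)
  # rounded-summary fold mirrors the printed-rate convention
  b <- a * 0.17 / mean(a * 1e10)
  r <- compare_rates(a * 0.98 / mean(a * 1e10), b)
  expect_equal(r$fold_rounded, round(0.98 / 0.17, 2))
  # degenerate zero-variance identical groups: p = 1 by convention, flagged
  r_deg <- compare_rates(rep(1e-10, 3), rep(1e-10, 3))
  expect_equal(r_deg$p_value, 1)
  expect_true(r_deg$degenerate)
  expect_error(compare_rates(1e-10, a), ">= 2")
})

test_that("coding annotation uses 1-based inclusive interval overlap", {
  muts <- data.frame(line = "L1", chrom = "c1", pos = c(150L, 250L, 300L),
                     ref = "A", alt = "T", depth = 50, mapq = 60,
                     genotype = "0/1", in_loh = FALSE)
  feats <- data.frame(chrom = "c1", start = 100L, end = 300L)
  ann <- annotate_coding(muts, feats)
  # boundary position (interval end) is inside
  expect_equal(ann$in_coding, c(TRUE, TRUE, TRUE))
  ann2 <- annotate_coding(transform(muts, pos = c(99L, 301L, 500L)), feats)
  expect_equal(ann2$in_coding, c(FALSE, FALSE, FALSE))
})
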