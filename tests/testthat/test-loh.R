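test_that("fixed-SNP identification applies the strict shared-homozygosity
           rule", {
  # 5 lines: one homozygous line at a position is fixed for that line
  t1 <- toy_gm(list(L1 = "HOM_P1", L2 = "HET", L3 = "HET", L4 = "HET",
                    L5 = "HET"))
  f1 <- identify_fixed_snps(t1$gm)
  expect_true(f1$fixed[1, "L1"])
  expect_false(f1$excluded[1])

  # 3 of 5 homozygous (60% > 50%): excluded for all lines
  t2 <- toy_gm(list(L1 = "HOM_P1", L2 = "HOM_P2", L3 = "HOM_P1", L4 = "HET",
                    L5 = "HET"))
  f2 <- identify_fixed_snps(t2$gm)
  expect_true(f2$excluded[1])
  expect_equal(f2$reason[1], "shared_homozygous")
  expect_false(any(f2$fixed[1, ]))

  # exactly 50% of 10 lines homozygous: NOT excluded (rule is strictly >50%)
  st10 <- as.list(c(rep("HOM_P1", 5), rep("HET", 5)))
  names(st10) <- paste0("L", 1:10)
  f3 <- identify_fixed_snps(toy_gm(st10)$gm)
  expect_false(f3$excluded[1])
  expect_true(all(f3$fixed[1, 1:5]))

  # the share is over non-missing lines; all-missing gets its own reason
  t4 <- toy_gm(list(L1 = "MISSING", L2 = "MISSING", L3 = "MISSING",
                    L4 = "MISSING", L5 = "MISSING"))
  f4 <- identify_fixed_snps(t4$gm)
  expect_equal(f4$reason[1], "all_missing")
  expect_error(identify_fixed_snps(toy_gm(list(L1 = "HET"))$gm), ">= 2")
})

test_that("tract calling finds maximal same-haplotype runs at both support
           levels", {
  mk <- function(states) {
    # neighbour line of all HET keeps positions below the exclusion fraction
    toy <- toy_gm(list(A = states, B = rep("HET", length(states)),
                       C = rep("HET", length(states))))
    list(tr2 = call_tracts(toy$gm, toy$genome, min_support = 2),
         tr10 = call_tracts(toy$gm, toy$genome, min_support = 10))
  }
  r1 <- mk(c("HET", "HOM_P1", "HOM_P1", "HOM_P1", "HET"))
  a1 <- r1$tr2[r1$tr2$line == "A", ]
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$support, 3L)
  expect_equal(a1$haplotype, "P1")

  # isolated single fixed SNP: no tract at min_support 2
  r2 <- mk(c("HET", "HOM_P1", "HET"))
  expect_equal(nrow(r2$tr2[r2$tr2$line == "A", ]), 0L)

  # two runs of opposite haplotype; none survives min_support 10
  r3 <- mk(c("HET", "HOM_P1", "HOM_P1", "HET", "HOM_P2", "HOM_P2", "HOM_P2",
             "HET"))
  a3 <- r3$tr2[r3$tr2$line == "A", ]
  expect_equal(nrow(a3), 2L)
  expect_equal(sort(a3$support), c(2L, 3L))
  expect_equal(a3$haplotype[order(a3$first_snp)], c("P1", "P2"))
  expect_equal(nrow(r3$tr10[r3$tr10$line == "A", ]), 0L)

  # MISSING inside a run neither breaks nor supports it
  r4 <- mk(c("HET", "HOM_P1", "HOM_P1", "MISSING", "HOM_P1", "HET"))
  a4 <- r4$tr2[r4$tr2$line == "A", ]
  expect_equal(nrow(a4), 1L)
  expect_equal(a4$support, 3L)
})

test_that("tract size follows the flanking-marker midpoint convention", {
  expect_equal(measure_tract(1000, 1200, left = 900, right = 1350,
                             chrom_length = 10000),
               c(start = 950, end = 1275, length = 325))
  expect_equal(measure_tract(500, 600, left = 400, right = 700,
                             chrom_length = 10000),
               c(start = 450, end = 650, length = 200))
  # no flanking marker on the left: boundary snaps to the chromosome start
  expect_equal(measure_tract(100, 200, left = NA, right = 260,
                             chrom_length = 10000),
               c(start = 1, end = 230, length = 229))
  # no flanking marker on the right: boundary snaps to the chromosome end
  expect_equal(measure_tract(9000, 9500, left = 8000, right = NA,
                             chrom_length = 10000),
               c(start = 8500, end = 10000, length = 1500))
})

test_that("classification separates terminal, interstitial and
           centromere-spanning tracts", {
  g <- genome_model(data.frame(name = "chrA", length = 200000L),
                    data.frame(name = "chrA", start = 100000L, end = 100500L))
  tr <- function(s, e) data.frame(chrom = "chrA", start = s, end = e)
  # within 100 bp of the chromosome end -> terminal
  expect_true(classify_tract(tr(150000, 199950), g)$terminal)
  expect_true(classify_tract(tr(50, 500), g)$terminal)
  t2 <- classify_tract(tr(50000, 60000), g)
  expect_false(t2$terminal)
  expect_false(t2$centromere_spanning)
  t3 <- classify_tract(tr(99000, 101000), g)
  expect_true(t3$centromere_spanning)
  expect_equal(t3$dist_cen, 0)
})

test_that("haplotype switches are adjacent opposite-haplotype tract pairs", {
  mk <- function(states, max_gap = 2L) {
    toy <- toy_gm(list(A = states, B = rep("HET", length(states)),
                       C = rep("HET", length(states))))
    tr <- call_tracts(toy$gm, toy$genome, min_support = 2)
    detect_haplotype_switches(tr, toy$gm, max_gap_snps = max_gap)
  }
  # opposite runs with 0 intervening het markers -> one pair
  s1 <- mk(c("HOM_P1", "HOM_P1", "HOM_P2", "HOM_P2"))
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$n_het_between, 0L)
  # 3 intervening het markers at max_gap 2 -> no pair
  s2 <- mk(c("HOM_P1", "HOM_P1", "HET", "HET", "HET", "HOM_P2", "HOM_P2"))
  expect_equal(nrow(s2), 0L)
  # P1, P2, P1 alternation with small gaps -> two pairs
  s3 <- mk(c("HOM_P1", "HOM_P1", "HET", "HOM_P2", "HOM_P2", "HET",
             "HOM_P1", "HOM_P1"))
  expect_equal(nrow(s3), 2L)
  # same-haplotype adjacency is not a switch
  s4 <- mk(c("HOM_P1", "HOM_P1", "HET", "HOM_P1", "HOM_P1"))
  expect_equal(nrow(s4), 0L)
})

test_that("fixation summary percentages are per-line arithmetic", {
  states <- c(rep("HOM_P1", 4), rep("HET", 46))
  toy <- toy_gm(list(A = states, B = rep("HET", 50), C = rep("HET", 50)),
                pos = seq(100, by = 100, length.out = 50))
  tracts <- call_tracts(toy$gm, toy$genome, min_support = 2)
  fs <- summarize_fixation(toy$gm, tracts, toy$genome)
  a <- fs[fs$line == "A", ]
  expect_equal(a$n_genotyped, 50L)
  expect_equal(a$n_fixed, 4L)
  expect_equal(a$pct_snps_fixed, 8.0)
  # one tract: markers 100..400, flanking het 500 -> end 450, length 449
  expect_equal(a$genome_fixed_bp, 449)
  expect_equal(a$pct_genome_fixed, 100 * 449 / 10000)
  b <- fs[fs$line == "B", ]
  expect_equal(b$n_fixed, 0L)
  expect_equal(b$pct_snps_fixed, 0)
})

test_that("strict-support tracts are a subset of loose-support tracts", {
  x <- full_scale_sim("SY")
  strict <- call_tracts(x$sim$genotypes, x$cfg$genome, min_support = 10)
  key <- function(t) paste(t$line, t$chrom, t$first_snp, t$last_snp)
  expect_true(all(key(strict) %in% key(x$tracts)))
  expect_true(all(strict$support >= 10))
})

test_that("tract length comparison is a rank-sum test with group summaries", {
  set.seed(7)
  a <- rlnorm(200, log(1700), 1)
  r_same <- compare_tract_lengths(a, sample(a))
  expect_gt(r_same$p_value, 0.9)
  expect_equal(r_same$median_a, r_same$median_b)
  # permutation invariance of the statistic
  r_perm <- compare_tract_lengths(sample(a), a)
  expect_equal(r_perm$statistic + r_same$statistic, 2 * r_same$statistic)
  expect_error(compare_tract_lengths(a, numeric(0)), "non-empty")
})
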