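test_that("snp map generation is deterministic, exact in count, and matches
           the spacing model", {
  cfg <- sim_config(seed = 5, n_snps = 50000L)
  map1 <- simulate_snp_map(cfg)
  map2 <- simulate_snp_map(cfg)
  expect_identical(map1, map2)
  expect_equal(nrow(map1), 50000L)
  # strictly increasing per chromosome, inside bounds
  for (ch in unique(map1$chrom)) {
    p <- map1$pos[map1$chrom == ch]
    expect_true(!is.unsorted(p, strictly = TRUE))
    expect_true(min(p) >= 1 && max(p) <= chrom_length(cfg$genome, ch))
  }
  # observed median gap within 10% of the configured 100 bp median
  gaps <- unlist(tapply(map1$pos, map1$chrom, diff))
  expect_lte(abs(median(gaps) - 100) / 100, 0.10)
  # alleles are distinct single bases
  expect_true(all(map1$p1 != map1$p2))
  expect_true(all(c(map1$p1, map1$p2) %in% c("A", "C", "G", "T")))
})

test_that("a too-dense marker request is a config error", {
  tiny <- genome_model(data.frame(name = "c1", length = 500L),
                       data.frame(name = "c1", start = 200L, end = 210L))
  expect_error(sim_config(seed = 1, genome = tiny, n_snps = 1000L),
               "too small")
})

test_that("with all event rates zero the lines are the parent", {
  cfg <- sim_config(seed = 3, n_lines = 4, n_snps = 2000,
                    loh = loh_regime("none"), snm_rate = 0,
                    trisomy_prob = 0, segmental_cnv_prob = 0,
                    genotype_error_prob = 0, missing_prob = 0)
  sim <- simulate_lines(cfg)
  expect_true(all(sim$genotypes$state == "HET"))
  expect_equal(nrow(sim$truth$loh), 0L)
  expect_equal(nrow(sim$truth$snm), 0L)
  expect_equal(nrow(sim$truth$cnv), 0L)
  expect_equal(nrow(sim$truth$aneuploidy), 0L)
})

test_that("planted events flip exactly the covered markers", {
  cfg <- sim_config(seed = 8, n_lines = 3, n_snps = 2000,
                    loh = loh_regime("SY"), snm_rate = 0,
                    trisomy_prob = 0, segmental_cnv_prob = 0,
                    genotype_error_prob = 0, missing_prob = 0)
  sim <- simulate_lines(cfg)
  truth <- sim$truth$loh
  expect_gt(nrow(truth), 0)
  for (r in seq_len(nrow(truth))) {
    li <- match(truth$line[r], sim$lines)
    inside <- sim$snp_map$chrom == truth$chrom[r] &
      sim$snp_map$pos >= truth$start[r] & sim$snp_map$pos <= truth$end[r]
    if (!any(inside)) next
    expect_true(all(sim$genotypes$state[inside, li] ==
                      paste0("HOM_", truth$haplotype[r])))
  }
  # markers covered by no event remain heterozygous
  for (li in seq_along(sim$lines)) {
    tt <- truth[truth$line == sim$lines[li], ]
    covered <- rep(FALSE, nrow(sim$snp_map))
    for (r in seq_len(nrow(tt)))
      covered <- covered | (sim$snp_map$chrom == tt$chrom[r] &
        sim$snp_map$pos >= tt$start[r] & sim$snp_map$pos <= tt$end[r])
    expect_true(all(sim$genotypes$state[!covered, li] == "HET"))
  }
})

test_that("per-line event counts follow the configured Poisson intensity", {
  lam <- 3; n_lines <- 10
  cfg <- sim_config(seed = 13, n_lines = n_lines, n_snps = 2000,
                    loh = loh_regime("SY", lambda = lam, whole_chrom_prob = 0,
                                     terminal_frac = 0,
                                     median_bp = 500, mean_bp = 600),
                    snm_rate = 0, trisomy_prob = 0, segmental_cnv_prob = 0)
  sim <- simulate_lines(cfg)
  total <- sum(sim$truth$loh$n_merged)   # merged events keep their multiplicity
  expect_lt(abs(total - lam * n_lines), 3 * sqrt(lam * n_lines))
})

test_that("truth events respect chromosome bounds and per-line events do not
           overlap", {
  cfg <- sim_config(seed = 21, n_lines = 6, n_snps = 2000,
                    loh = loh_regime("SR"))
  sim <- simulate_lines(cfg)
  t <- sim$truth$loh
  L <- chrom_length(cfg$genome, t$chrom)
  expect_true(all(t$start >= 1 & t$end <= L & t$start <= t$end))
  parts <- split(t, list(t$line, t$chrom), drop = TRUE)
  for (p in parts) {
    if (nrow(p) < 2) next
    p <- p[order(p$start), ]
    expect_true(all(p$start[-1] > p$end[-nrow(p)]))
  }
})

test_that("state bookkeeping: counts per line always sum to the map size", {
  cfg <- sim_config(seed = 2, n_lines = 5, n_snps = 3000,
                    loh = loh_regime("SR"))
  sim <- simulate_lines(cfg)
  for (li in seq_along(sim$lines)) {
    tab <- table(factor(sim$genotypes$state[, li],
                        levels = c("HET", "HOM_P1", "HOM_P2", "MISSING")))
    expect_equal(sum(tab), nrow(sim$snp_map))
  }
})

test_that("identical seeds reproduce the full simulation byte for byte", {
  cfg <- sim_config(seed = 99, n_lines = 3, n_snps = 1500)
  s1 <- simulate_lines(cfg)
  s2 <- simulate_lines(cfg)
  expect_identical(s1$genotypes$state, s2$genotypes$state)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$coverage, s2$coverage)
})
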