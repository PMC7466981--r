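# Synthetic MA-line generator. The simulator plants already-fixed events per
# line (the analysis only ever sees outcomes after ~100 bottlenecks, so
# lineage-level drift is not modelled) and records everything it planted in a
# truth table, so each caller can be scored against known events.

#' LOH event regime for the simulator
#'
#' Presets mirror the two hybrid backgrounds the package is designed around:
#' `"SY"`-like lines carry fewer, longer tracts (median ~1.73 kb, mean
#' ~28.4 kb, more terminal events), `"SR"`-like lines many short tracts
#' (median ~247 bp, mean ~4.03 kb). Tract lengths are log-normal with
#' `meanlog = log(median_bp)` and `sdlog = sqrt(2 log(mean/median))`, which
#' reproduces both the median and the heavy upper tail.
#'
#' @param preset `"SY"`, `"SR"`, or `"none"` (no LOH); ignored when the
#'   explicit parameters are all supplied.
#' @param lambda expected number of fixed LOH events per line (Poisson).
#' @param median_bp,mean_bp tract-length log-normal calibration.
#' @param terminal_frac fraction of events modelled as terminal crossovers
#'   (breakpoint to a chromosome end).
#' @param whole_chrom_prob per-line probability of one whole-chromosome LOH
#'   (chromosome loss + reduplication analogue).
#' @param switch_pair_prob per-line probability of planting one pair of
#'   adjacent opposite-haplotype tracts (exercises switch detection; the data
#'   cannot distinguish one repair event from two, so no mechanism is
#'   implied). Default 0.
#' @return list of regime parameters, class `loh_regime`.
#' @export
loh_regime <- function(preset = c("SY", "SR", "none"), lambda = NULL,
                       median_bp = NULL, mean_bp = NULL,
                       terminal_frac = NULL, whole_chrom_prob = NULL,
                       switch_pair_prob = 0) {
  preset <- match.arg(preset)
  def <- switch(preset,
    SY   = list(lambda = 30, median_bp = 1730, mean_bp = 28400,
                terminal_frac = 0.20, whole_chrom_prob = 0.05),
    SR   = list(lambda = 90, median_bp = 247, mean_bp = 4030,
                terminal_frac = 0.05, whole_chrom_prob = 0.02),
    none = list(lambda = 0, median_bp = 1000, mean_bp = 2000,
                terminal_frac = 0, whole_chrom_prob = 0))
  r <- list(lambda = lambda %||% def$lambda,
            median_bp = median_bp %||% def$median_bp,
            mean_bp = mean_bp %||% def$mean_bp,
            terminal_frac = terminal_frac %||% def$terminal_frac,
            whole_chrom_prob = whole_chrom_prob %||% def$whole_chrom_prob,
            switch_pair_prob = switch_pair_prob)
  stopifnot(r$lambda >= 0, r$median_bp >= 1, r$mean_bp >= r$median_bp,
            r$terminal_frac >= 0, r$terminal_frac <= 1,
            r$whole_chrom_prob >= 0, r$whole_chrom_prob <= 1,
            r$switch_pair_prob >= 0, r$switch_pair_prob <= 1)
  r$meanlog <- log(r$median_bp)
  r$sdlog <- sqrt(2 * log(r$mean_bp / r$median_bp))
  class(r) <- "loh_regime"
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulator configuration
#'
#' Defaults describe one MA experiment arm as the package models it: a
#' ~12 Mb, 16-chromosome diploid hybrid with ~50,000 heterozygous markers
#' (median inter-marker spacing ~100 bp), 10 lines propagated for 2000
#' generations, de novo single-nucleotide mutations at 1e-10 per base per
#' generation over the diploid genome, ~70X sequencing depth, and occasional
#' trisomy / segmental copy-number changes.
#'
#' @param seed integer; the single source of randomness for everything the
#'   simulator emits (identical seed, identical output).
#' @param n_lines number of MA lines.
#' @param genome a [genome_model()]; default [yeast_genome()].
#' @param n_snps target heterozygous marker count (realised count is exact).
#' @param snp_median_spacing median inter-marker gap in bp; gaps are
#'   exponential with this median, with ~5% of gaps inflated so the markers
#'   span each chromosome (clustered-marker structure).
#' @param loh an [loh_regime()].
#' @param snm_rate true single-nucleotide mutation rate, per base per
#'   generation (diploid base count).
#' @param generations mitotic generations of propagation.
#' @param trisomy_prob,segmental_cnv_prob per-line event probabilities.
#' @param segmental_bins_range integer range (bins of `coverage_bin` bp) for
#'   segmental CNV spans.
#' @param segmental_kind `"both"` (default), `"dup"` or `"del"`: which
#'   segmental event kinds the generator plants.
#' @param depth_mean,depth_size negative-binomial per-site read depth model.
#' @param mapq_mean,mapq_outlier_prob mapping quality is `mapq_mean` except
#'   at a small fraction of sites drawn uniformly in 10..39 (exercises the
#'   MQ filter).
#' @param genotype_error_prob probability a truly heterozygous marker is
#'   miscalled homozygous (justifies the >=2-SNP tract support rule).
#' @param missing_prob probability a marker genotype is missing in a line.
#' @param coverage_bin coverage bin size in bp (default 5000).
#' @param coverage_size negative-binomial size for binned counts.
#' @return list of validated parameters, class `sim_config`.
#' @export
sim_config <- function(seed, n_lines = 10L, genome = yeast_genome(),
                       n_snps = 50000L, snp_median_spacing = 100,
                       loh = loh_regime("SY"), snm_rate = 1e-10,
                       generations = 2000L, trisomy_prob = 0.05,
                       segmental_cnv_prob = 0.05,
                       segmental_bins_range = c(20L, 40L),
                       segmental_kind = c("both", "dup", "del"),
                       depth_mean = 70, depth_size = 80,
                       mapq_mean = 60, mapq_outlier_prob = 0.01,
                       genotype_error_prob = 1e-4, missing_prob = 0.002,
                       coverage_bin = 5000L, coverage_size = 60) {
  stopifnot(is.numeric(seed), length(seed) == 1L, inherits(genome, "genome_model"),
            n_lines >= 1, n_snps >= 1, snp_median_spacing >= 1,
            inherits(loh, "loh_regime"), snm_rate >= 0, generations >= 1,
            trisomy_prob >= 0, trisomy_prob <= 1,
            segmental_cnv_prob >= 0, segmental_cnv_prob <= 1,
            length(segmental_bins_range) == 2L,
            segmental_bins_range[1] >= 1,
            segmental_bins_range[2] >= segmental_bins_range[1],
            depth_mean > 0, depth_size > 0, mapq_mean > 0,
            mapq_outlier_prob >= 0, mapq_outlier_prob <= 1,
            genotype_error_prob >= 0, genotype_error_prob <= 1,
            missing_prob >= 0, missing_prob <= 1,
            coverage_bin >= 1, coverage_size > 0)
  segmental_kind <- match.arg(segmental_kind)
  if (n_snps > sum(genome$chromosomes$length))
    stop("genome too small for n_snps at minimum spacing 1")
  structure(list(seed = as.integer(seed), n_lines = as.integer(n_lines),
                 genome = genome, n_snps = as.integer(n_snps),
                 snp_median_spacing = snp_median_spacing, loh = loh,
                 snm_rate = snm_rate, generations = as.integer(generations),
                 trisomy_prob = trisomy_prob,
                 segmental_cnv_prob = segmental_cnv_prob,
                 segmental_bins_range = as.integer(segmental_bins_range),
                 segmental_kind = segmental_kind,
                 depth_mean = depth_mean, depth_size = depth_size,
                 mapq_mean = mapq_mean, mapq_outlier_prob = mapq_outlier_prob,
                 genotype_error_prob = genotype_error_prob,
                 missing_prob = missing_prob,
                 coverage_bin = as.integer(coverage_bin),
                 coverage_size = coverage_size),
            class = "sim_config")
}

#' Simulate a parental heterozygous SNP map
#'
#' Markers are placed per chromosome (counts proportional to chromosome
#' length, summing exactly to `n_snps`). Inter-marker gaps are exponential
#' with the configured median; a random ~5% of gaps absorb the remaining
#' chromosome length so markers span the chromosome while the median gap
#' stays near the configured value — mimicking the clustered marker density
#' of real hybrid genomes.
#'
#' @param config a [sim_config()].
#' @return A `snp_map`: data.frame (`chrom`, `pos`, `p1`, `p2`) with
#'   strictly increasing positions per chromosome and distinct single-base
#'   parental alleles.
#' @export
simulate_snp_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    g <- config$genome$chromosomes
    n_k <- largest_remainder(config$n_snps, g$length)
    rate <- log(2) / config$snp_median_spacing
    maps <- lapply(seq_len(nrow(g)), function(k) {
      n <- n_k[k]
      if (n == 0L) return(NULL)
      if (n > g$length[k])
        stop("genome too small for n_snps at minimum spacing 1")
      gaps <- pmax(1, round(stats::rexp(n, rate)))
      slack <- g$length[k] - sum(gaps) - 1
      if (slack > 0) {
        n_inf <- max(1L, ceiling(0.05 * n))
        idx <- sample.int(n, n_inf)
        w <- stats::runif(n_inf)
        gaps[idx] <- gaps[idx] + floor(slack * w / sum(w))
      } else if (slack < 0) {
        gaps <- pmax(1, floor(gaps * (g$length[k] - 1) / sum(gaps)))
      }
      pos <- cumsum(gaps)
      pos <- pmin(pos, g$length[k])
      pos <- make_strictly_increasing(pos, g$length[k])
      data.frame(chrom = g$name[k], pos = pos)
    })
    map <- do.call(rbind, maps)
    bases <- c("A", "C", "G", "T")
    map$p1 <- sample(bases, nrow(map), replace = TRUE)
    map$p2 <- vapply(map$p1, function(b) sample(setdiff(bases, b), 1L), "")
    rownames(map) <- NULL
    class(map) <- c("snp_map", "data.frame")
    map
  })
}

# Apportion n proportionally to weights, summing exactly to n.
largest_remainder <- function(n, weights) {
  raw <- as.numeric(n) * as.numeric(weights) / sum(as.numeric(weights))
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

make_strictly_increasing <- function(pos, len) {
  if (length(pos) > 1L)
    for (i in 2:length(pos))
      if (pos[i] <= pos[i - 1L]) pos[i] <- pos[i - 1L] + 1L
  if (pos[length(pos)] > len) {
    # fall back: evenly squeeze the tail inside the chromosome
    over <- which(pos > len - (length(pos) - seq_along(pos)))
    pos[over] <- len - (length(pos) - over)
  }
  pos
}

#' Simulate MA lines: genotypes, coverage and a planted-event truth table
#'
#' Plants per line: Poisson LOH events (conversions, terminal crossovers,
#' whole-chromosome events) that flip all covered markers to one parental
#' haplotype; Poisson de novo mutations at non-marker positions, recorded
#' heterozygous with their own depth/quality draws; occasional trisomy and
#' segmental copy-number events that scale binned coverage. Overlapping
#' same-haplotype LOH events are merged at generation time and recorded
#' merged; a later event overlapping an opposite-haplotype one is discarded
#' (a fixed region cannot re-fix to the other haplotype).
#'
#' @param config a [sim_config()].
#' @param snp_map from [simulate_snp_map()]; simulated from `config` when
#'   omitted.
#' @return list of class `ma_sim` with elements `config`, `snp_map`,
#'   `genotypes` (a `genotype_matrix`), `coverage` (data.frame: line, chrom,
#'   start, end, count), `truth` (list `loh`, `snm`, `cnv`, `aneuploidy`),
#'   and `lines` (line names).
#' @export
simulate_lines <- function(config, snp_map = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(snp_map)) snp_map <- simulate_snp_map(config)
  withr::with_seed(config$seed + 1L, {
    g <- config$genome$chromosomes
    lines <- sprintf("MA_%02d", seq_len(config$n_lines))
    n_snp <- nrow(snp_map)

    state <- matrix("HET", nrow = n_snp, ncol = config$n_lines,
                    dimnames = list(NULL, lines))
    truth_loh <- list(); truth_snm <- list()
    truth_cnv <- list(); truth_aneu <- list()

    for (li in seq_along(lines)) {
      ev <- plant_loh_events(config, g)
      if (nrow(ev)) {
        ev$line <- lines[li]
        truth_loh[[length(truth_loh) + 1L]] <- ev
        for (r in seq_len(nrow(ev))) {
          cover <- snp_map$chrom == ev$chrom[r] &
            snp_map$pos >= ev$start[r] & snp_map$pos <= ev$end[r]
          state[cover, li] <- paste0("HOM_", ev$haplotype[r])
        }
      }

      # de novo SNMs: Poisson over diploid base count x generations
      G_dip <- 2 * sum(g$length)
      m <- stats::rpois(1L, config$snm_rate * config$generations * G_dip)
      if (m > 0) {
        snm <- draw_snm_positions(m, g, snp_map)
        snm$line <- lines[li]
        snm$dp <- stats::rnbinom(m, size = config$depth_size,
                                 mu = config$depth_mean)
        snm$mq <- draw_mapq(m, config)
        snm$parent_dp <- stats::rnbinom(m, size = config$depth_size,
                                        mu = config$depth_mean)
        truth_snm[[length(truth_snm) + 1L]] <- snm
      }

      aneu_chrom <- NA_character_
      if (stats::runif(1) < config$trisomy_prob) {
        aneu_chrom <- sample(g$name, 1L, prob = g$length)
        truth_aneu[[length(truth_aneu) + 1L]] <-
          data.frame(line = lines[li], chrom = aneu_chrom, copy_number = 3L)
      }
      if (stats::runif(1) < config$segmental_cnv_prob) {
        cn <- plant_segmental(config, g, exclude = aneu_chrom)
        cn$line <- lines[li]
        truth_cnv[[length(truth_cnv) + 1L]] <- cn
      }
    }

    truth <- list(loh = rbind_or_empty(truth_loh,
                    c("line", "chrom", "start", "end", "haplotype", "kind",
                      "n_merged")),
                  snm = rbind_or_empty(truth_snm,
                    c("line", "chrom", "pos", "ref", "alt", "dp", "mq",
                      "parent_dp")),
                  cnv = rbind_or_empty(truth_cnv,
                    c("line", "chrom", "start", "end", "copy_ratio", "kind")),
                  aneuploidy = rbind_or_empty(truth_aneu,
                    c("line", "chrom", "copy_number")))

    # genotyping noise: rare het->hom miscalls, then missingness
    n_cell <- n_snp * config$n_lines
    err <- which(stats::runif(n_cell) < config$genotype_error_prob &
                   state == "HET")
    if (length(err))
      state[err] <- sample(c("HOM_P1", "HOM_P2"), length(err), replace = TRUE)
    miss <- which(stats::runif(n_cell) < config$missing_prob)
    if (length(miss)) state[miss] <- "MISSING"

    depth <- matrix(stats::rnbinom(n_cell, size = config$depth_size,
                                   mu = config$depth_mean),
                    nrow = n_snp, dimnames = list(NULL, lines))
    mapq <- matrix(draw_mapq(n_cell, config), nrow = n_snp,
                   dimnames = list(NULL, lines))

    gm <- genotype_matrix(snp_map, state, depth, mapq)
    cov <- simulate_coverage(config, g, lines, truth)

    structure(list(config = config, snp_map = snp_map, genotypes = gm,
                   coverage = cov, truth = truth, lines = lines),
              class = "ma_sim")
  })
}

rbind_or_empty <- function(lst, cols) {
  if (length(lst)) {
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out[, cols]
  } else {
    out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                         cols))
    out
  }
}

# Uniform non-marker genomic positions with random ref/alt base pairs.
draw_snm_positions <- function(m, g, snp_map) {
  bases <- c("A", "C", "G", "T")
  taken <- paste(snp_map$chrom, snp_map$pos)
  out <- vector("list", m)
  for (i in seq_len(m)) {
    repeat {
      k <- sample(nrow(g), 1L, prob = g$length)
      pos <- sample.int(g$length[k], 1L)
      key <- paste(g$name[k], pos)
      if (!key %in% taken) { taken <- c(taken, key); break }
    }
    ref <- sample(bases, 1L)
    out[[i]] <- data.frame(chrom = g$name[k], pos = pos, ref = ref,
                           alt = sample(setdiff(bases, ref), 1L))
  }
  do.call(rbind, out)
}

draw_mapq <- function(n, config) {
  mq <- rep(config$mapq_mean, n)
  low <- stats::runif(n) < config$mapq_outlier_prob
  mq[low] <- sample(10:39, sum(low), replace = TRUE)
  mq
}

# Draw, merge and record one line's LOH events.
plant_loh_events <- function(config, g) {
  r <- config$loh
  ev <- list()
  add <- function(chrom, start, end, hap, kind)
    data.frame(chrom = chrom, start = start, end = end, haplotype = hap,
               kind = kind, n_merged = 1L)
  if (stats::runif(1) < r$whole_chrom_prob) {
    k <- sample(nrow(g), 1L)
    ev[[1L]] <- add(g$name[k], 1, g$length[k],
                    sample(c("P1", "P2"), 1L), "whole-chromosome")
  }
  n_ev <- stats::rpois(1L, r$lambda)
  drawn <- if (n_ev > 0) draw_interstitial(n_ev, r, g) else NULL
  if (r$switch_pair_prob > 0 && stats::runif(1) < r$switch_pair_prob) {
    # adjacent opposite-haplotype pair on one chromosome
    k <- sample(nrow(g), 1L, prob = g$length)
    len <- pmax(1, round(stats::rlnorm(2, r$meanlog, min(r$sdlog, 1))))
    s1 <- sample.int(max(1, g$length[k] - sum(len) - 200L), 1L)
    pair <- rbind(
      add(g$name[k], s1, min(g$length[k], s1 + len[1] - 1), "P1", "conversion"),
      add(g$name[k], min(g$length[k], s1 + len[1] + 100L),
          min(g$length[k], s1 + len[1] + 100L + len[2] - 1), "P2", "conversion"))
    drawn <- rbind(pair, drawn)
  }
  if (!is.null(drawn))
    for (i in seq_len(nrow(drawn))) ev <- merge_event(ev, drawn[i, ])
  if (length(ev)) do.call(rbind, ev) else
    rbind_or_empty(list(), c("chrom", "start", "end", "haplotype", "kind",
                             "n_merged"))
}

draw_interstitial <- function(n, r, g) {
  k <- sample(nrow(g), n, replace = TRUE, prob = g$length)
  len <- pmax(1, round(stats::rlnorm(n, r$meanlog, r$sdlog)))
  terminal <- stats::runif(n) < r$terminal_frac
  start <- end <- integer(n)
  for (i in seq_len(n)) {
    L <- g$length[k[i]]
    li <- min(len[i], L)
    if (terminal[i]) {
      if (stats::runif(1) < 0.5) { start[i] <- 1L; end[i] <- li }
      else { start[i] <- L - li + 1L; end[i] <- L }
    } else {
      start[i] <- sample.int(L, 1L)
      end[i] <- min(L, start[i] + li - 1L)
    }
  }
  data.frame(chrom = g$name[k], start = start, end = end,
             haplotype = sample(c("P1", "P2"), n, replace = TRUE),
             kind = ifelse(terminal, "crossover-terminal", "conversion"),
             n_merged = 1L)
}

# Same-haplotype overlaps merge to their union; an event overlapping an
# already-fixed opposite-haplotype region is discarded.
merge_event <- function(ev, new) {
  if (length(ev)) {
    for (j in seq_along(ev)) {
      e <- ev[[j]]
      if (e$chrom == new$chrom && new$start <= e$end && new$end >= e$start) {
        if (e$haplotype == new$haplotype) {
          e$start <- min(e$start, new$start)
          e$end <- max(e$end, new$end)
          e$n_merged <- e$n_merged + new$n_merged
          if (e$kind != new$kind && e$kind != "whole-chromosome")
            e$kind <- "merged"
          ev[[j]] <- e
          # the grown event may now touch others; re-merge once
          rest <- ev[-j]
          ev <- list()
          for (x in rest) ev <- merge_event(ev, x)
          return(merge_event(ev, e))
        }
        return(ev)   # opposite haplotype: drop the new event
      }
    }
  }
  c(ev, list(new))
}

# sample() treats a scalar first argument as 1:x; always index explicitly
sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]

plant_segmental <- function(config, g, exclude = NA_character_) {
  bin <- config$coverage_bin
  span <- sample1(seq(config$segmental_bins_range[1],
                      config$segmental_bins_range[2]))
  # segmental means sub-chromosomal: keep the event under ~40% of the
  # chromosome so it cannot read as a whole-chromosome change
  n_bins <- ceiling(g$length / bin)
  ok <- which(!(g$name %in% exclude) & n_bins >= 2.5 * span)
  if (!length(ok)) { ok <- which(!(g$name %in% exclude))
                     span <- max(1L, floor(0.4 * max(n_bins[ok])))
                     ok <- ok[n_bins[ok] >= 2.5 * span] }
  k <- sample1(ok, prob = g$length[ok])
  n_bins_chr <- n_bins[k]
  b0 <- sample.int(max(1L, n_bins_chr - span + 1L), 1L)
  kind <- switch(config$segmental_kind,
                 both = sample(c("segmental_dup", "segmental_del"), 1L),
                 dup = "segmental_dup", del = "segmental_del")
  data.frame(chrom = g$name[k],
             start = (b0 - 1L) * bin + 1L,
             end = min(g$length[k], (b0 + span - 1L) * bin),
             copy_ratio = if (kind == "segmental_dup") 1.5 else 0.5,
             kind = kind)
}

simulate_coverage <- function(config, g, lines, truth) {
  bin <- config$coverage_bin
  base_mu <- config$depth_mean * bin / 100   # ~reads per bin at 100 bp reads
  out <- vector("list", length(lines) * nrow(g))
  i <- 0L
  for (li in lines) {
    for (k in seq_len(nrow(g))) {
      starts <- seq(1L, g$length[k], by = bin)
      ends <- pmin(starts + bin - 1L, g$length[k])
      mult <- rep(1, length(starts))
      an <- truth$aneuploidy
      if (nrow(an) && any(an$line == li & an$chrom == g$name[k])) {
        cn <- an$copy_number[an$line == li & an$chrom == g$name[k]][1]
        mult[] <- cn / 2
      }
      cv <- truth$cnv
      if (nrow(cv)) {
        sel <- cv$line == li & cv$chrom == g$name[k]
        for (r in which(sel)) {
          hit <- starts <= cv$end[r] & ends >= cv$start[r]
          mult[hit] <- cv$copy_ratio[r]
        }
      }
      mu <- base_mu * mult * (ends - starts + 1L) / bin
      cnt <- stats::rnbinom(length(starts), size = config$coverage_size,
                            mu = mu)
      i <- i + 1L
      out[[i]] <- data.frame(line = li, chrom = g$name[k], start = starts,
                             end = ends, count = cnt)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
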