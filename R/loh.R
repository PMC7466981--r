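# LOH tract calling. A tract is a maximal run of consecutive markers (per
# line, per chromosome) fixed to the same parental haplotype, uninterrupted
# by heterozygous markers; missing genotypes neither break nor support a run.
# Tract size follows the flanking-marker midpoint convention: each boundary
# is the midpoint between the outermost fixed marker and the first
# heterozygous marker beyond it (chromosome end if there is none).

#' Identify fixed SNPs and artifact-excluded positions
#'
#' A marker is *fixed* for a line iff that line is homozygous there and the
#' position passes the shared-homozygosity filter: positions homozygous (for
#' either haplotype) in strictly more than `fixed_share_fraction` of the
#' non-missing lines are excluded for all lines — recurrent homozygosity
#' across independent lines indicates a systematic artifact or parental
#' homozygosity rather than independent LOH. All-missing positions are
#' excluded with their own reason code.
#'
#' @param gm a `genotype_matrix` (>= 2 lines).
#' @param thresholds a [thresholds()].
#' @return list: `fixed` (logical matrix, SNPs x lines), `excluded` (logical
#'   vector), `reason` (character: `""`, `"shared_homozygous"` or
#'   `"all_missing"`), `share` (numeric homozygous fraction).
#' @export
identify_fixed_snps <- function(gm, thresholds = lohma::thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$lines) < 2L)
    stop("need >= 2 lines to apply the shared-homozygosity filter")
  hom <- gm$state == "HOM_P1" | gm$state == "HOM_P2"
  nonmiss <- gm$state != "MISSING"
  n_hom <- rowSums(hom)
  n_nm <- rowSums(nonmiss)
  share <- ifelse(n_nm > 0, n_hom / n_nm, NA_real_)
  reason <- rep("", nrow(hom))
  reason[n_nm == 0L] <- "all_missing"
  reason[n_nm > 0L & share > thresholds$fixed_share_fraction] <-
    "shared_homozygous"
  excluded <- reason != ""
  fixed <- hom & !excluded
  list(fixed = fixed, excluded = excluded, reason = reason, share = share)
}

#' Call LOH tracts from fixed-SNP flags
#'
#' Scans each line and chromosome for maximal runs of consecutive markers
#' fixed to the same haplotype. Heterozygous markers (and fixed markers of
#' the opposite haplotype) break runs; missing markers and excluded
#' positions neither break nor support them. Runs with at least
#' `min_support` fixed markers become tracts, measured by
#' [measure_tract()] and classified by [classify_tract()].
#'
#' @param gm a `genotype_matrix`.
#' @param fixed result of [identify_fixed_snps()] (computed when `NULL`).
#' @param genome a `genome_model`.
#' @param min_support minimum fixed markers per tract (default 2; 10 is the
#'   conservative call level).
#' @param thresholds a [thresholds()] used when `fixed` is `NULL`.
#' @return data.frame with one row per tract: `line`, `chrom`, `first_snp`,
#'   `last_snp`, `start`, `end`, `length`, `support`, `haplotype`,
#'   `terminal`, `centromere_spanning`, `dist_cen`, `dist_tel`.
#' @export
call_tracts <- function(gm, genome, fixed = NULL, min_support = 2L,
                        thresholds = lohma::thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(genome, "genome_model"))
  if (is.null(fixed)) fixed <- identify_fixed_snps(gm, thresholds)
  keep <- !fixed$excluded
  out <- list()
  for (li in seq_along(gm$lines)) {
    for (ch in unique(gm$snp_map$chrom)) {
      sel <- which(gm$snp_map$chrom == ch & keep)
      if (!length(sel)) next
      pos <- gm$snp_map$pos[sel]
      st <- gm$state[sel, li]
      runs <- scan_runs(st, pos)
      if (is.null(runs)) next
      L <- chrom_length(genome, ch)
      for (r in seq_len(nrow(runs))) {
        if (runs$support[r] < min_support) next
        m <- measure_tract(runs$first[r], runs$last[r],
                           left = runs$left[r], right = runs$right[r],
                           chrom_length = L)
        tr <- data.frame(line = gm$lines[li], chrom = ch,
                         first_snp = runs$first[r], last_snp = runs$last[r],
                         start = m[["start"]], end = m[["end"]],
                         length = m[["length"]], support = runs$support[r],
                         haplotype = runs$hap[r])
        out[[length(out) + 1L]] <- classify_tract(tr, genome)
      }
    }
  }
  if (!length(out))
    return(data.frame(line = character(), chrom = character(),
                      first_snp = integer(), last_snp = integer(),
                      start = integer(), end = integer(), length = integer(),
                      support = integer(), haplotype = character(),
                      terminal = logical(), centromere_spanning = logical(),
                      dist_cen = numeric(), dist_tel = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Run-length scan over one line/chromosome state vector. Missing entries are
# dropped (they neither break nor support); the flanking anchors are the
# nearest retained non-missing neighbours of each run (NA at chromosome
# ends). Anchors are usually heterozygous markers; where two opposite-
# haplotype runs are directly adjacent the anchor is the neighbouring run's
# outermost fixed marker, which keeps measured tracts non-overlapping.
scan_runs <- function(st, pos) {
  nm <- st != "MISSING"
  st <- st[nm]; pos <- pos[nm]
  if (!length(st)) return(NULL)
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  isrun <- r$values %in% c("HOM_P1", "HOM_P2")
  if (!any(isrun)) return(NULL)
  i <- which(isrun)
  left_i <- starts[i] - 1L; right_i <- ends[i] + 1L
  left <- rep(NA_real_, length(i)); right <- rep(NA_real_, length(i))
  left[left_i >= 1L] <- pos[left_i[left_i >= 1L]]
  right[right_i <= length(pos)] <- pos[right_i[right_i <= length(pos)]]
  data.frame(first = pos[starts[i]], last = pos[ends[i]],
             support = r$lengths[i],
             hap = sub("HOM_", "", r$values[i]),
             left = left, right = right)
}

#' Measure a tract by the flanking-marker midpoint convention
#'
#' `start = floor((left + first) / 2)`, `end = floor((last + right) / 2)`;
#' a side with no flanking marker (the run reaches a chromosome end) takes
#' boundary 1 or the chromosome length. `length = end - start`.
#'
#' @param first,last outermost fixed marker positions of the run.
#' @param left,right nearest flanking marker positions (`NA` at a chromosome
#'   end).
#' @param chrom_length chromosome length in bp.
#' @return named numeric vector `c(start, end, length)`.
#' @export
measure_tract <- function(first, last, left = NA, right = NA, chrom_length) {
  stopifnot(first <= last, chrom_length >= last)
  start <- if (is.na(left)) 1 else floor((left + first) / 2)
  end <- if (is.na(right)) chrom_length else floor((last + right) / 2)
  c(start = start, end = end, length = end - start)
}

#' Classify a measured tract against the genome
#'
#' Terminal iff a boundary lies within the telomere window of a chromosome
#' end; centromere-spanning iff the tract interval overlaps the centromere
#' interval; centromere/telomere distances via [distance_to_features()].
#'
#' @param tract one-row data.frame with `chrom`, `start`, `end`.
#' @param genome a `genome_model`.
#' @param mode distance convention, see [distance_to_features()].
#' @return the tract with `terminal`, `centromere_spanning`, `dist_cen`,
#'   `dist_tel` columns added or overwritten.
#' @export
classify_tract <- function(tract, genome, mode = "edge") {
  L <- chrom_length(genome, tract$chrom)
  w <- genome$telomere_window
  d <- distance_to_features(tract$chrom, tract$start, tract$end, genome,
                            mode = mode)
  tract$terminal <- tract$end >= L - w | tract$start <= 1 + w
  tract$centromere_spanning <- d[["dist_cen"]] == 0
  tract$dist_cen <- d[["dist_cen"]]
  tract$dist_tel <- d[["dist_tel"]]
  tract
}

#' Detect haplotype switching between adjacent tracts
#'
#' Reports ordered pairs of same-line, same-chromosome tracts with opposite
#' haplotypes separated by at most `max_gap_snps` heterozygous markers.
#' Whether such a pair arose from one double-strand-break repair event or
#' two cannot be resolved from end-point data; the pairs are reported
#' without mechanistic claims.
#'
#' @param tracts tract table from [call_tracts()].
#' @param gm the `genotype_matrix` the tracts were called from.
#' @param fixed result of [identify_fixed_snps()] (recomputed when `NULL`);
#'   used to ignore excluded positions when counting intervening markers.
#' @param max_gap_snps maximum intervening heterozygous markers (default 2).
#' @param thresholds used when `fixed` is `NULL`.
#' @return data.frame: `line`, `chrom`, `first_end`, `second_start`,
#'   `hap_first`, `hap_second`, `n_het_between`.
#' @export
detect_haplotype_switches <- function(tracts, gm, fixed = NULL,
                                      max_gap_snps = 2L,
                                      thresholds = lohma::thresholds()) {
  if (is.null(fixed)) fixed <- identify_fixed_snps(gm, thresholds)
  out <- list()
  if (nrow(tracts)) {
    keys <- unique(tracts[c("line", "chrom")])
    for (k in seq_len(nrow(keys))) {
      tt <- tracts[tracts$line == keys$line[k] & tracts$chrom == keys$chrom[k], ]
      tt <- tt[order(tt$first_snp), ]
      if (nrow(tt) < 2L) next
      li <- match(keys$line[k], gm$lines)
      sel <- gm$snp_map$chrom == keys$chrom[k] & !fixed$excluded
      pos <- gm$snp_map$pos[sel]
      het <- gm$state[sel, li] == "HET"
      for (j in seq_len(nrow(tt) - 1L)) {
        if (tt$haplotype[j] == tt$haplotype[j + 1L]) next
        between <- pos > tt$last_snp[j] & pos < tt$first_snp[j + 1L]
        n_het <- sum(het & between)
        if (n_het <= max_gap_snps)
          out[[length(out) + 1L]] <- data.frame(
            line = keys$line[k], chrom = keys$chrom[k],
            first_end = tt$end[j], second_start = tt$start[j + 1L],
            hap_first = tt$haplotype[j], hap_second = tt$haplotype[j + 1L],
            n_het_between = n_het)
      }
    }
  }
  if (!length(out))
    return(data.frame(line = character(), chrom = character(),
                      first_end = integer(), second_start = integer(),
                      hap_first = character(), hap_second = character(),
                      n_het_between = integer()))
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Per-line fixation summary
#'
#' Percentage of genotyped markers fixed (`100 * n_fixed / n_genotyped`,
#' over non-missing non-excluded positions) and percentage of the genome
#' fixed (`100 * sum(tract length) / sum(chromosome lengths)`, using tracts
#' from the loose support call). Lines with zero genotyped markers report
#' `NA` percentages.
#'
#' @param gm a `genotype_matrix`.
#' @param tracts tract table from the `min_support_loose` call.
#' @param genome a `genome_model`.
#' @param fixed result of [identify_fixed_snps()] (recomputed when `NULL`).
#' @param thresholds used when `fixed` is `NULL`.
#' @return data.frame: `line`, `n_genotyped`, `n_fixed`, `pct_snps_fixed`,
#'   `genome_fixed_bp`, `pct_genome_fixed`.
#' @export
summarize_fixation <- function(gm, tracts, genome, fixed = NULL,
                               thresholds = lohma::thresholds()) {
  if (is.null(fixed)) fixed <- identify_fixed_snps(gm, thresholds)
  G <- sum(genome$chromosomes$length)
  keep <- !fixed$excluded
  out <- lapply(seq_along(gm$lines), function(li) {
    st <- gm$state[keep, li]
    n_gt <- sum(st != "MISSING")
    n_fx <- sum(fixed$fixed[keep, li])
    bp <- sum(tracts$length[tracts$line == gm$lines[li]])
    data.frame(line = gm$lines[li], n_genotyped = n_gt, n_fixed = n_fx,
               pct_snps_fixed = if (n_gt > 0) 100 * n_fx / n_gt else NA_real_,
               genome_fixed_bp = bp, pct_genome_fixed = 100 * bp / G)
  })
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Compare tract lengths between two groups
#'
#' Wilcoxon rank-sum test on tract lengths (normal approximation with
#' continuity correction for the tied, large samples typical here), with
#' per-group medians and means.
#'
#' @param tracts_a,tracts_b tract tables from [call_tracts()], or numeric
#'   length vectors.
#' @return list: `statistic`, `p_value`, `median_a`, `median_b`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
compare_tract_lengths <- function(tracts_a, tracts_b) {
  a <- if (is.data.frame(tracts_a)) tracts_a$length else as.numeric(tracts_a)
  b <- if (is.data.frame(tracts_b)) tracts_b$length else as.numeric(tracts_b)
  if (!length(a) || !length(b)) stop("both tract groups must be non-empty")
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_a = stats::median(a), median_b = stats::median(b),
       mean_a = mean(a), mean_b = mean(b), n_a = length(a), n_b = length(b))
}
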