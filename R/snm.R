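# De novo single-nucleotide mutation (SNM) detection and rate estimation.
# A candidate is a heterozygous call in an MA line, at a position that is
# not a parental heterozygous marker, carrying an allele absent from the
# parent, with record-level mapping quality >= 40 and depth >= 40 reads.
# The rate estimator is mu = m / (n_lines * generations * callable bases),
# with the callable denominator defaulting to the full diploid genome.

#' Detect de novo single-nucleotide mutations against the parent
#'
#' @param line_variants record table for one MA line ([read_vcf_records()]
#'   or a path to its VCF).
#' @param parent_variants record table for the parent (or a VCF path).
#'   Candidates without a parent record are dropped with reason
#'   `no_parent_evidence`.
#' @param snp_map parental heterozygous `snp_map`; candidates at map
#'   positions are never emitted (changes there are LOH, not new mutation).
#' @param thresholds a [thresholds()]; supplies `min_depth` and `min_mapq`.
#' @param line_name carried into the output.
#' @param loh_tracts optional tract table; candidates inside a called tract
#'   of the same line are retained but flagged `in_loh` for auditability.
#' @return data.frame of class-invariant mutation records: `line`, `chrom`,
#'   `pos`, `ref`, `alt`, `depth`, `mapq`, `genotype`, `in_loh`; attribute
#'   `dropped` tabulates exclusion reasons.
#' @export
detect_snms <- function(line_variants, parent_variants, snp_map,
                        thresholds = lohma::thresholds(),
                        line_name = "line", loh_tracts = NULL) {
  lv <- if (is.character(line_variants)) read_vcf_records(line_variants)
        else line_variants
  pv <- if (is.character(parent_variants)) read_vcf_records(parent_variants)
        else parent_variants
  dropped <- c(not_het = 0L, parental_snp = 0L, no_parent_evidence = 0L,
               allele_in_parent = 0L, low_depth = 0L, low_mapq = 0L)
  gt <- gsub("\\|", "/", lv$gt)
  het <- gt %in% c("0/1", "1/0") & !grepl(",", lv$alt)
  dropped[["not_het"]] <- sum(!het, na.rm = TRUE)
  cand <- lv[which(het), , drop = FALSE]

  in_map <- paste(cand$chrom, cand$pos) %in% paste(snp_map$chrom, snp_map$pos)
  dropped[["parental_snp"]] <- sum(in_map)
  cand <- cand[!in_map, , drop = FALSE]

  key_p <- paste(pv$chrom, pv$pos)
  pi <- match(paste(cand$chrom, cand$pos), key_p)
  dropped[["no_parent_evidence"]] <- sum(is.na(pi))
  cand <- cand[!is.na(pi), , drop = FALSE]
  pr <- pv[pi[!is.na(pi)], , drop = FALSE]

  # the new allele must be absent from the parent record's alleles
  pgt <- gsub("\\|", "/", pr$gt)
  p_alleles <- mapply(function(g, ref, alt) {
    idx <- suppressWarnings(as.integer(strsplit(g, "/")[[1]]))
    al <- c(ref, strsplit(alt, ",")[[1]])
    unique(al[idx + 1L])
  }, pgt, pr$ref, pr$alt, SIMPLIFY = FALSE)
  novel <- !mapply(function(a, pa) a %in% pa, cand$alt, p_alleles)
  dropped[["allele_in_parent"]] <- sum(!novel)
  cand <- cand[novel, , drop = FALSE]

  lo_dp <- !is.na(cand$dp) & cand$dp < thresholds$min_depth
  lo_dp[is.na(cand$dp)] <- TRUE
  dropped[["low_depth"]] <- sum(lo_dp)
  cand <- cand[!lo_dp, , drop = FALSE]
  lo_mq <- is.na(cand$mq) | cand$mq < thresholds$min_mapq
  dropped[["low_mapq"]] <- sum(lo_mq)
  cand <- cand[!lo_mq, , drop = FALSE]

  out <- data.frame(line = rep(line_name, nrow(cand)), chrom = cand$chrom,
                    pos = cand$pos, ref = cand$ref, alt = cand$alt,
                    depth = cand$dp, mapq = cand$mq,
                    genotype = rep("0/1", nrow(cand)),
                    in_loh = rep(FALSE, nrow(cand)))
  if (!is.null(loh_tracts) && nrow(out) && nrow(loh_tracts)) {
    tt <- loh_tracts[loh_tracts$line == line_name, , drop = FALSE]
    for (r in seq_len(nrow(tt)))
      out$in_loh <- out$in_loh | (out$chrom == tt$chrom[r] &
        out$pos >= tt$start[r] & out$pos <= tt$end[r])
  }
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Estimate a per-base per-generation mutation rate
#'
#' `mu = m / (n_lines * g * G)`. Summaries report the rate on the 1e-10
#' scale rounded to two decimals, the convention for yeast MA studies.
#'
#' @param m total mutation count across lines (>= 0).
#' @param n_lines number of MA lines.
#' @param g generations per line (default 2000: 100 bottlenecks of ~20
#'   generations).
#' @param G callable bases per line; defaults to the full diploid genome,
#'   24.04e6 for a ~12 Mb haploid assembly.
#' @param background label carried into the result.
#' @param per_line_m optional per-line mutation counts (must sum to `m`);
#'   enables the per-line rate list and its standard error.
#' @return object of class `rate_estimate`: `background`, `m`, `n_lines`,
#'   `g`, `G`, `mu`, `mu_e10` (rate x 1e10, rounded to 2 decimals),
#'   `per_line_mu`, `se` (across lines, `NA` without per-line counts).
#' @export
estimate_rate <- function(m, n_lines, g = 2000, G = 24.04e6,
                          background = "background", per_line_m = NULL) {
  if (n_lines <= 0 || g <= 0 || G <= 0)
    stop("n_lines, g and G must all be positive")
  if (m < 0) stop("m must be >= 0")
  mu <- m / (n_lines * g * G)
  per_line_mu <- NULL; se <- NA_real_
  if (!is.null(per_line_m)) {
    if (length(per_line_m) != n_lines || sum(per_line_m) != m)
      stop("per_line_m must have n_lines entries summing to m")
    per_line_mu <- per_line_m / (g * G)
    se <- stats::sd(per_line_mu) / sqrt(n_lines)
  }
  structure(list(background = background, m = m, n_lines = n_lines, g = g,
                 G = G, mu = mu, mu_e10 = round(mu * 1e10, 2),
                 per_line_mu = per_line_mu, se = se),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s: %d SNMs / (%d lines x %g gen x %.4g bp) = %.2f x 10^-10 per base per generation\n",
              x$background, x$m, x$n_lines, x$g, x$G, x$mu_e10))
  if (!is.na(x$se))
    cat(sprintf("  between-line SE: %.2f x 10^-10\n", x$se * 1e10))
  invisible(x)
}

#' Compare per-line mutation rates between two backgrounds
#'
#' Welch two-sample t-test on per-line rates. The fold change is reported
#' twice: from the raw means and from the 2-decimal rounded summary rates
#' (the form quoted in publication-style summaries). Identical
#' zero-variance groups get `p = 1` by convention, flagged.
#'
#' @param mu_a,mu_b numeric vectors of per-line rates (>= 2 each), or
#'   `rate_estimate` objects carrying `per_line_mu`.
#' @return list: `statistic`, `p_value`, `fold` (mean_a / mean_b),
#'   `fold_rounded` (ratio of rounded 1e-10-scale summary rates, rounded to
#'   2 decimals), `mean_a`, `mean_b`, `degenerate`.
#' @export
compare_rates <- function(mu_a, mu_b) {
  if (inherits(mu_a, "rate_estimate")) mu_a <- mu_a$per_line_mu
  if (inherits(mu_b, "rate_estimate")) mu_b <- mu_b$per_line_mu
  if (length(mu_a) < 2L || length(mu_b) < 2L)
    stop("need >= 2 per-line rates per group")
  degenerate <- stats::sd(mu_a) == 0 && stats::sd(mu_b) == 0
  if (degenerate && isTRUE(all.equal(mean(mu_a), mean(mu_b)))) {
    statistic <- 0; p_value <- 1
  } else if (degenerate) {
    statistic <- Inf * sign(mean(mu_a) - mean(mu_b)); p_value <- 0
  } else {
    tt <- stats::t.test(mu_a, mu_b)
    statistic <- unname(tt$statistic); p_value <- tt$p.value
  }
  ra <- round(mean(mu_a) * 1e10, 2); rb <- round(mean(mu_b) * 1e10, 2)
  list(statistic = statistic, p_value = p_value,
       fold = mean(mu_a) / mean(mu_b),
       fold_rounded = if (rb > 0) round(ra / rb, 2) else NA_real_,
       mean_a = mean(mu_a), mean_b = mean(mu_b), degenerate = degenerate)
}

#' Flag mutations falling in coding intervals
#'
#' @param muts mutation table from [detect_snms()].
#' @param features data.frame of coding intervals (`chrom`, `start`, `end`),
#'   1-based inclusive; a mutation on an interval boundary is inside.
#' @return `muts` with an `in_coding` logical column.
#' @export
annotate_coding <- function(muts, features) {
  muts$in_coding <- FALSE
  for (ch in unique(muts$chrom)) {
    f <- features[features$chrom == ch, , drop = FALSE]
    if (!nrow(f)) next
    i <- which(muts$chrom == ch)
    muts$in_coding[i] <- vapply(muts$pos[i], function(p)
      any(p >= f$start & p <= f$end), logical(1))
  }
  muts
}
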