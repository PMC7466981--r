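# Scoring called events against a simulator truth table. The simulator's
# reason to exist is the round trip: every planted event that the genotype
# data can support should come back out of the callers.

#' Score LOH tract calls against the planted truth
#'
#' A truth event is *recoverable* when it covers at least `min_support`
#' markers. Same-line, same-chromosome, same-haplotype truth events whose
#' marker runs touch (no marker strictly between them) are merged before
#' matching, since the genotype data cannot distinguish them from one
#' event. A recoverable event is *recovered* when a called tract of the
#' same line/chromosome/haplotype overlaps its marker run and both tract
#' boundaries fall within the local flanking inter-marker gap of the true
#' boundaries. Precision counts called tracts that overlap any truth event
#' of the same haplotype.
#'
#' @param sim an `ma_sim` from [simulate_lines()].
#' @param tracts tract table from [call_tracts()] on `sim$genotypes`.
#' @param min_support marker-coverage threshold defining recoverable events
#'   (default 2).
#' @return list: `sensitivity`, `precision`, `n_truth` (recoverable after
#'   merging), `n_recovered`, `n_called`, `n_matched_calls`, and the
#'   per-event table `events` (`covered`, `recovered`, `boundary_ok`).
#' @export
evaluate_loh_recovery <- function(sim, tracts, min_support = 2L) {
  stopifnot(inherits(sim, "ma_sim"))
  map <- sim$snp_map
  truth <- sim$truth$loh
  if (!nrow(truth))
    return(list(sensitivity = NA_real_, precision = NA_real_, n_truth = 0L,
                n_recovered = 0L, n_called = nrow(tracts),
                n_matched_calls = 0L, events = truth))

  # marker run covered by each truth event
  cover <- lapply(seq_len(nrow(truth)), function(r) {
    i <- which(map$chrom == truth$chrom[r] & map$pos >= truth$start[r] &
                 map$pos <= truth$end[r])
    if (length(i)) c(min(i), max(i)) else c(NA_integer_, NA_integer_)
  })
  truth$first_idx <- vapply(cover, `[`, 0L, 1L)
  truth$last_idx <- vapply(cover, `[`, 0L, 2L)
  truth$covered <- ifelse(is.na(truth$first_idx), 0L,
                          truth$last_idx - truth$first_idx + 1L)

  # merge truth events indistinguishable in marker space
  truth <- truth[!is.na(truth$first_idx), , drop = FALSE]
  truth <- truth[order(truth$line, truth$chrom, truth$first_idx), ]
  merged <- list()
  for (r in seq_len(nrow(truth))) {
    e <- truth[r, ]
    n <- length(merged)
    if (n > 0L) {
      p <- merged[[n]]
      if (p$line == e$line && p$chrom == e$chrom &&
          p$haplotype == e$haplotype && e$first_idx <= p$last_idx + 1L) {
        p$last_idx <- max(p$last_idx, e$last_idx)
        p$end <- max(p$end, e$end)
        p$start <- min(p$start, e$start)
        p$covered <- p$last_idx - p$first_idx + 1L
        merged[[n]] <- p
        next
      }
    }
    merged[[n + 1L]] <- e
  }
  truth <- do.call(rbind, merged)
  truth <- truth[truth$covered >= min_support, , drop = FALSE]

  truth$recovered <- FALSE
  truth$boundary_ok <- FALSE
  match_call <- rep(FALSE, nrow(tracts))
  map_idx_first <- match(paste(tracts$chrom, tracts$first_snp),
                         paste(map$chrom, map$pos))
  map_idx_last <- match(paste(tracts$chrom, tracts$last_snp),
                        paste(map$chrom, map$pos))
  for (r in seq_len(nrow(truth))) {
    cand <- which(tracts$line == truth$line[r] &
                    tracts$chrom == truth$chrom[r] &
                    tracts$haplotype == truth$haplotype[r] &
                    map_idx_first <= truth$last_idx[r] &
                    map_idx_last >= truth$first_idx[r])
    if (!length(cand)) next
    truth$recovered[r] <- TRUE
    match_call[cand] <- TRUE
    # boundary tolerance: the inter-marker gap flanking each true boundary
    fi <- truth$first_idx[r]; la <- truth$last_idx[r]
    chrom_first <- which(map$chrom == truth$chrom[r])[1]
    left_tol <- if (fi > chrom_first) map$pos[fi] - map$pos[fi - 1L]
                else map$pos[fi]
    chrom_last <- max(which(map$chrom == truth$chrom[r]))
    right_tol <- if (la < chrom_last) map$pos[la + 1L] - map$pos[la]
                 else chrom_length(sim$config$genome, truth$chrom[r]) -
                   map$pos[la]
    ok <- any(abs(tracts$start[cand] - truth$start[r]) <= left_tol &
                abs(tracts$end[cand] - truth$end[r]) <= right_tol)
    truth$boundary_ok[r] <- ok
  }
  # precision: any-haplotype-correct overlap with any truth event
  list(sensitivity = mean(truth$recovered & truth$boundary_ok),
       precision = if (nrow(tracts)) mean(match_call) else NA_real_,
       n_truth = nrow(truth),
       n_recovered = sum(truth$recovered & truth$boundary_ok),
       n_called = nrow(tracts), n_matched_calls = sum(match_call),
       events = truth)
}

#' Score CNV and aneuploidy calls against the planted truth
#'
#' @param sim an `ma_sim`.
#' @param aneu_calls result of [call_aneuploidy()].
#' @param seg_calls result of [call_segmental()].
#' @return list: `aneuploidy_recovered`, `aneuploidy_truth`,
#'   `segmental_recovered`, `segmental_truth`,
#'   `false_whole_chromosome_calls` (trisomy/monosomy calls on line-
#'   chromosome pairs with no planted aneuploidy).
#' @export
evaluate_cnv_recovery <- function(sim, aneu_calls, seg_calls) {
  ta <- sim$truth$aneuploidy
  tc <- sim$truth$cnv
  aneu_hit <- if (nrow(ta)) vapply(seq_len(nrow(ta)), function(r)
    any(aneu_calls$line == ta$line[r] & aneu_calls$chrom == ta$chrom[r] &
          aneu_calls$kind == "trisomy"), logical(1)) else logical(0)
  seg_hit <- if (nrow(tc)) vapply(seq_len(nrow(tc)), function(r)
    any(seg_calls$line == tc$line[r] & seg_calls$chrom == tc$chrom[r] &
          seg_calls$kind == tc$kind[r] &
          seg_calls$start <= tc$end[r] & seg_calls$end >= tc$start[r]),
    logical(1)) else logical(0)
  whole <- aneu_calls[aneu_calls$kind %in% c("trisomy", "monosomy"), ,
                      drop = FALSE]
  false_whole <- if (nrow(whole)) sum(!vapply(seq_len(nrow(whole)),
    function(r) nrow(ta) > 0 && any(ta$line == whole$line[r] &
                                      ta$chrom == whole$chrom[r]),
    logical(1))) else 0L
  list(aneuploidy_recovered = sum(aneu_hit), aneuploidy_truth = nrow(ta),
       segmental_recovered = sum(seg_hit), segmental_truth = nrow(tc),
       false_whole_chromosome_calls = false_whole)
}
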