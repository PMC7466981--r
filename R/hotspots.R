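# Cross-line LOH occupancy at 1 bp resolution. Counts are stored as
# piecewise-constant segments (boundary difference accumulation), which is
# exactly equivalent to dense 1 bp bins at a fraction of the memory.

#' Build the cross-line LOH occupancy map
#'
#' For every genomic position, the count of tracts whose `[start, end]`
#' interval (1-based inclusive) contains it. With `restrict_haplotype` the
#' count is limited to tracts fixed for that parental haplotype (the
#' shared-parent haplotype when pooling two hybrids that share one parent).
#' With `dedup_lines` (default) a line contributes at most 1 at any
#' position, so counts read directly as "number of lines with LOH here".
#'
#' @param tracts tract table from [call_tracts()].
#' @param genome a `genome_model`.
#' @param restrict_haplotype `NULL`, `"P1"` or `"P2"`.
#' @param dedup_lines merge each line's tracts before counting (default
#'   `TRUE`).
#' @return object of class `loh_occupancy`: `segments` data.frame (`chrom`,
#'   `start`, `end`, `count`; inclusive coordinates, piecewise constant,
#'   tiling every chromosome), `n_lines_total`, `dedup_lines`,
#'   `restrict_haplotype`.
#' @export
build_occupancy <- function(tracts, genome, restrict_haplotype = NULL,
                            dedup_lines = TRUE) {
  stopifnot(inherits(genome, "genome_model"))
  tr <- tracts
  if (!is.null(restrict_haplotype)) {
    stopifnot(restrict_haplotype %in% c("P1", "P2"))
    tr <- tr[tr$haplotype == restrict_haplotype, , drop = FALSE]
  }
  if (nrow(tr)) {
    L <- chrom_length(genome, tr$chrom)
    if (any(tr$start < 1 | tr$end > L))
      stop("tract outside chromosome bounds")
    if (dedup_lines) tr <- merge_per_line(tr)
  }
  segs <- lapply(seq_len(nrow(genome$chromosomes)), function(k) {
    ch <- genome$chromosomes$name[k]
    L <- genome$chromosomes$length[k]
    tt <- tr[tr$chrom == ch, , drop = FALSE]
    if (!nrow(tt))
      return(data.frame(chrom = ch, start = 1, end = L, count = 0L))
    # +1 at start, -1 just past end; cut points delimit constant segments
    bp <- sort(unique(c(1, tt$start, tt$end + 1, L + 1)))
    bp <- bp[bp >= 1 & bp <= L + 1]
    delta <- rep(0L, length(bp))
    add <- tapply(rep(1L, nrow(tt)), match(tt$start, bp), sum)
    sub <- tapply(rep(1L, nrow(tt)), match(tt$end + 1, bp), sum)
    delta[as.integer(names(add))] <- delta[as.integer(names(add))] + add
    idx <- as.integer(names(sub))
    ok <- !is.na(idx)
    delta[idx[ok]] <- delta[idx[ok]] - sub[ok]
    count <- cumsum(delta)
    n_seg <- length(bp) - 1L
    data.frame(chrom = ch, start = bp[seq_len(n_seg)],
               end = bp[seq_len(n_seg) + 1L] - 1,
               count = as.integer(count[seq_len(n_seg)]))
  })
  structure(list(segments = do.call(rbind, segs),
                 n_lines_total = length(unique(tracts$line)),
                 dedup_lines = dedup_lines,
                 restrict_haplotype = restrict_haplotype,
                 genome = genome),
            class = "loh_occupancy")
}

# Union of each line's intervals per chromosome (so one line counts once).
merge_per_line <- function(tr) {
  parts <- split(tr, list(tr$line, tr$chrom), drop = TRUE)
  out <- lapply(parts, function(p) {
    p <- p[order(p$start), ]
    s <- p$start[1]; e <- p$end[1]
    res <- list()
    if (nrow(p) > 1L) for (i in 2:nrow(p)) {
      if (p$start[i] <= e + 1) e <- max(e, p$end[i])
      else { res[[length(res) + 1L]] <- c(s, e); s <- p$start[i]; e <- p$end[i] }
    }
    res[[length(res) + 1L]] <- c(s, e)
    m <- do.call(rbind, res)
    data.frame(line = p$line[1], chrom = p$chrom[1], start = m[, 1],
               end = m[, 2])
  })
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Occupancy counts at given positions
#' @param occ an `loh_occupancy`.
#' @param chrom chromosome name.
#' @param pos positions (bp).
#' @return integer vector of counts.
#' @export
occupancy_at <- function(occ, chrom, pos) {
  seg <- occ$segments[occ$segments$chrom == chrom, ]
  if (!nrow(seg)) stop("unknown chromosome: ", chrom)
  i <- findInterval(pos, seg$start)
  if (any(i < 1L | pos > seg$end[i]))
    stop("position outside chromosome ", chrom)
  seg$count[i]
}

#' Call LOH hotspots from an occupancy map
#'
#' Maximal intervals where the occupancy count is at least `min_count`
#' (default 5 lines, i.e. 20% of a 25-line panel). When the genome model
#' carries feature intervals (e.g. LTR retrotransposons), each hotspot is
#' annotated with the nearest feature and its distance.
#'
#' @param occ an `loh_occupancy`.
#' @param min_count minimum line count (default 5).
#' @param feature_set name of a feature set in the genome model to annotate
#'   against; defaults to the first one, if any.
#' @return data.frame: `chrom`, `start`, `end`, `peak_count`, and when
#'   features are available `nearest_feature`, `feature_dist`.
#' @export
call_hotspots <- function(occ, min_count = 5L, feature_set = NULL) {
  seg <- occ$segments
  hot <- seg[seg$count >= min_count, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_count = integer())
  if (!nrow(hot)) return(empty)
  out <- list()
  for (ch in unique(hot$chrom)) {
    h <- hot[hot$chrom == ch, ]
    h <- h[order(h$start), ]
    s <- h$start[1]; e <- h$end[1]; pk <- h$count[1]
    flush <- function(s, e, pk)
      data.frame(chrom = ch, start = s, end = e, peak_count = pk)
    if (nrow(h) > 1L) for (i in 2:nrow(h)) {
      if (h$start[i] == e + 1) { e <- h$end[i]; pk <- max(pk, h$count[i]) }
      else { out[[length(out) + 1L]] <- flush(s, e, pk)
             s <- h$start[i]; e <- h$end[i]; pk <- h$count[i] }
    }
    out[[length(out) + 1L]] <- flush(s, e, pk)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  genome <- occ$genome
  if (length(genome$features)) {
    if (is.null(feature_set)) feature_set <- names(genome$features)[1]
    fx <- genome$features[[feature_set]]
    res$nearest_feature <- NA_character_
    res$feature_dist <- NA_real_
    for (i in seq_len(nrow(res))) {
      f <- fx[fx$chrom == res$chrom[i], ]
      if (!nrow(f)) next
      d <- pmax(0, pmax(f$start - res$end[i], res$start[i] - f$end))
      j <- which.min(d)
      res$nearest_feature[i] <- if (!is.na(f$name[j])) f$name[j]
                                else sprintf("%s:%d-%d", f$chrom[j],
                                             f$start[j], f$end[j])
      res$feature_dist[i] <- d[j]
    }
  }
  res
}

#' Step plot of LOH occupancy for one chromosome
#'
#' Mirrors the chromosome panels of a genome-wide LOH map: a step line of
#' per-position tract counts, the hotspot threshold as a dashed line, the
#' centromere as a black dot and optional feature positions (e.g. LTRs) as
#' orange dots.
#'
#' @param occ an `loh_occupancy`.
#' @param chrom chromosome to draw.
#' @param min_count hotspot threshold line (default 5).
#' @param feature_set feature set to mark, if present in the genome model.
#' @return invisibly, the segment table drawn.
#' @export
plot_occupancy <- function(occ, chrom, min_count = 5L, feature_set = NULL) {
  seg <- occ$segments[occ$segments$chrom == chrom, ]
  if (!nrow(seg)) stop("unknown chromosome: ", chrom)
  x <- c(rbind(seg$start, seg$end)) / 1e3
  y <- c(rbind(seg$count, seg$count))
  plot(x, y, type = "l", xlab = sprintf("%s position (kb)", chrom),
       ylab = "LOH tract count", main = sprintf("LOH occupancy, %s", chrom))
  graphics::abline(h = min_count, col = "red", lty = 2)
  genome <- occ$genome
  cen <- genome$centromeres[genome$centromeres$name == chrom, ]
  if (nrow(cen))
    graphics::points(mean(c(cen$start, cen$end)) / 1e3, 0, pch = 19)
  if (length(genome$features)) {
    if (is.null(feature_set)) feature_set <- names(genome$features)[1]
    f <- genome$features[[feature_set]]
    f <- f[f$chrom == chrom, ]
    if (nrow(f))
      graphics::points((f$start + f$end) / 2e3, rep(0, nrow(f)),
                       pch = 19, col = "orange")
  }
  invisible(seg)
}
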