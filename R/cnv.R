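# Copy-number analysis from 5 kb binned read counts. The diploid baseline
# normalises each bin to the genome-wide median; a single chromosome gain in
# a diploid sits near ratio 1.5 and a single loss near 0.5, so the default
# call thresholds (1.4 / 0.6) lie midway between baseline and the expected
# one-copy change.

#' Normalize a binned coverage profile
#'
#' Adds `ratio = count / genome-wide median count` per line. By construction
#' the genome-wide median ratio of each line is 1.
#'
#' @param coverage data.frame (`line`, `chrom`, `start`, `end`, `count`).
#' @return the same data.frame with a `ratio` column.
#' @export
normalize_profile <- function(coverage) {
  if (!nrow(coverage)) stop("empty coverage profile")
  med <- tapply(coverage$count, coverage$line, stats::median)
  if (any(med == 0)) stop("zero median coverage for line(s): ",
                          paste(names(med)[med == 0], collapse = ", "))
  coverage$ratio <- coverage$count / as.numeric(med[coverage$line])
  coverage
}

#' Call whole-chromosome aneuploidy from normalized coverage
#'
#' A chromosome is called trisomic when its median normalized ratio is at
#' least `gain_threshold`, monosomic when at most `loss_threshold`.
#' Chromosomes in the intermediate band `mosaic_band` are reported as
#' `possible_mosaic` — flagged, not called — covering the case of a
#' sub-population of aneuploid cells in the colony.
#'
#' @param profile output of [normalize_profile()].
#' @param gain_threshold default 1.4 (single gain in a diploid is ~1.5).
#' @param loss_threshold default 0.6 (single loss is ~0.5).
#' @param mosaic_band numeric length-2 band for the mosaic flag, default
#'   `c(1.15, 1.4)`.
#' @return data.frame: `line`, `chrom`, `start`, `end`, `kind`
#'   (`trisomy`, `monosomy`, `possible_mosaic`), `mean_ratio` (chromosome
#'   median ratio), `n_bins`.
#' @export
call_aneuploidy <- function(profile, gain_threshold = 1.4,
                            loss_threshold = 0.6,
                            mosaic_band = c(1.15, 1.4)) {
  stopifnot("ratio" %in% names(profile))
  out <- list()
  for (li in unique(profile$line)) {
    p <- profile[profile$line == li, ]
    med <- tapply(p$ratio, p$chrom, stats::median)
    nb <- tapply(p$ratio, p$chrom, length)
    for (ch in names(med)) {
      kind <- if (med[[ch]] >= gain_threshold) "trisomy"
              else if (med[[ch]] <= loss_threshold) "monosomy"
              else if (med[[ch]] >= mosaic_band[1] &&
                       med[[ch]] < mosaic_band[2]) "possible_mosaic"
              else NA_character_
      if (is.na(kind)) next
      b <- p[p$chrom == ch, ]
      out[[length(out) + 1L]] <- data.frame(
        line = li, chrom = ch, start = min(b$start), end = max(b$end),
        kind = kind, mean_ratio = unname(med[[ch]]),
        n_bins = unname(nb[[ch]]))
    }
  }
  if (!length(out))
    return(data.frame(line = character(), chrom = character(),
                      start = integer(), end = integer(), kind = character(),
                      mean_ratio = numeric(), n_bins = integer()))
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Call segmental duplications and deletions
#'
#' Scans chromosomes not already carrying a whole-chromosome call for
#' maximal runs of consecutive bins beyond threshold. Runs separated by a
#' single in-range bin are merged (one noisy bin does not split an event);
#' runs spanning at least `min_run` bins become calls.
#'
#' @param profile output of [normalize_profile()].
#' @param dup_threshold,del_threshold bin ratio thresholds (defaults
#'   1.4 / 0.6).
#' @param min_run minimum bins per call (default 4, i.e. 20 kb at 5 kb
#'   bins — small enough for the tens-of-kb events seen in practice, large
#'   enough to suppress count noise).
#' @param whole_calls optional result of [call_aneuploidy()]; chromosomes
#'   with a trisomy/monosomy call there are skipped.
#' @return data.frame: `line`, `chrom`, `start`, `end`, `kind`
#'   (`segmental_dup` / `segmental_del`), `mean_ratio`, `n_bins`.
#' @export
call_segmental <- function(profile, dup_threshold = 1.4,
                           del_threshold = 0.6, min_run = 4L,
                           whole_calls = NULL) {
  stopifnot("ratio" %in% names(profile))
  out <- list()
  for (li in unique(profile$line)) {
    p <- profile[profile$line == li, ]
    for (ch in unique(p$chrom)) {
      if (!is.null(whole_calls) &&
          any(whole_calls$line == li & whole_calls$chrom == ch &
              whole_calls$kind %in% c("trisomy", "monosomy"))) next
      b <- p[p$chrom == ch, ]
      b <- b[order(b$start), ]
      for (kind in c("segmental_dup", "segmental_del")) {
        flag <- if (kind == "segmental_dup") b$ratio >= dup_threshold
                else b$ratio <= del_threshold
        runs <- flag_runs(flag, bridge = 1L)
        for (r in runs) {
          if (r[2] - r[1] + 1L < min_run) next
          out[[length(out) + 1L]] <- data.frame(
            line = li, chrom = ch, start = b$start[r[1]], end = b$end[r[2]],
            kind = kind, mean_ratio = mean(b$ratio[r[1]:r[2]]),
            n_bins = r[2] - r[1] + 1L)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(line = character(), chrom = character(),
                      start = integer(), end = integer(), kind = character(),
                      mean_ratio = numeric(), n_bins = integer()))
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

# Maximal TRUE runs, bridging interruptions of up to `bridge` FALSE bins
# that are flanked by TRUE on both sides. Returns list of c(first, last).
flag_runs <- function(flag, bridge = 1L) {
  if (!any(flag)) return(list())
  r <- rle(flag)
  if (bridge > 0L && length(r$lengths) >= 3L) {
    interior <- which(!r$values & r$lengths <= bridge)
    interior <- interior[interior > 1L & interior < length(r$values)]
    if (length(interior)) {
      r$values[interior] <- TRUE
      flag2 <- inverse.rle(r)
      r <- rle(flag2)
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  lapply(i, function(j) c(starts[j], ends[j]))
}

#' Per-line coverage plot
#'
#' Draws binned read counts across the genome with chromosome boundaries,
#' the genome-wide median and twice the median as horizontal lines —
#' the visual used to spot aneuploidies and half-aneuploidies.
#'
#' @param coverage data.frame for one line (`chrom`, `start`, `end`,
#'   `count`).
#' @param genome a `genome_model`.
#' @param line_name title label.
#' @return invisibly, the cumulative-coordinate data drawn.
#' @export
plot_coverage <- function(coverage, genome, line_name = "") {
  offs <- c(0, cumsum(as.numeric(genome$chromosomes$length)))
  names(offs) <- c(genome$chromosomes$name, "END")
  x <- (coverage$start + coverage$end) / 2 +
    offs[as.character(coverage$chrom)]
  med <- stats::median(coverage$count)
  plot(x / 1e6, coverage$count, pch = ".", xlab = "genome position (Mb)",
       ylab = "reads per bin", main = line_name,
       ylim = c(0, max(coverage$count, 2.5 * med)))
  graphics::abline(v = offs[-1] / 1e6, col = "grey", lty = 3)
  graphics::abline(h = med, col = "blue")
  graphics::abline(h = 2 * med, col = "red")
  invisible(data.frame(x = x, count = coverage$count))
}
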