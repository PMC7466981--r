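# Genome coordinate frame. All point positions and interval endpoints are
# 1-based inclusive (VCF convention); coverage bins are half-open on read
# and converted to inclusive endpoints internally.

#' Construct a genome model
#'
#' A `genome_model` is the shared coordinate frame for every caller in the
#' package: ordered chromosomes with lengths, per-chromosome centromere
#' intervals, a telomere proximity window and optional named feature interval
#' sets (e.g. LTR retrotransposon positions).
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp). Order is
#'   preserved and used for all outputs.
#' @param centromeres data.frame with columns `name`, `start`, `end`
#'   (1-based inclusive). Every chromosome must have exactly one interval.
#' @param telomere_window bp; a tract whose boundary comes within this many
#'   bases of a chromosome end is classified terminal. Default 100.
#' @param features optional named list of data.frames (`chrom`, `start`,
#'   `end`, optionally `name`), e.g. `list(LTR = ...)`.
#' @return An object of class `genome_model`.
#' @seealso [yeast_genome()], [load_genome()], [distance_to_features()]
#' @export
genome_model <- function(chromosomes, centromeres, telomere_window = 100,
                         features = list()) {
  chromosomes <- as.data.frame(chromosomes)
  centromeres <- as.data.frame(centromeres)
  stopifnot(all(c("name", "length") %in% names(chromosomes)),
            all(c("name", "start", "end") %in% names(centromeres)))
  chromosomes$name <- as.character(chromosomes$name)
  centromeres$name <- as.character(centromeres$name)
  if (nrow(chromosomes) == 0L) stop("no chromosomes")
  if (anyDuplicated(chromosomes$name))
    stop("chromosome names must be unique")
  if (any(chromosomes$length < 1))
    stop("chromosome lengths must be >= 1")
  if (!is.numeric(telomere_window) || telomere_window < 0)
    stop("telomere_window must be >= 0")
  m <- match(centromeres$name, chromosomes$name)
  if (anyNA(m))
    stop("centromere for unknown chromosome: ",
         paste(centromeres$name[is.na(m)], collapse = ", "))
  len <- chromosomes$length[m]
  bad <- centromeres$start < 1 | centromeres$end > len |
    centromeres$start > centromeres$end
  if (any(bad))
    stop("centromere interval outside chromosome bounds: ",
         paste(centromeres$name[bad], collapse = ", "))
  features <- lapply(features, function(f) {
    f <- as.data.frame(f)
    stopifnot(all(c("chrom", "start", "end") %in% names(f)))
    f$chrom <- as.character(f$chrom)
    fl <- chromosomes$length[match(f$chrom, chromosomes$name)]
    if (anyNA(fl) || any(f$start < 1) || any(f$end > fl))
      stop("feature interval outside chromosome bounds")
    f
  })
  structure(list(chromosomes = chromosomes,
                 centromeres = centromeres[order(m), , drop = FALSE],
                 telomere_window = telomere_window,
                 features = features),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %s bp total, telomere window %d bp\n",
              nrow(x$chromosomes),
              format(sum(x$chromosomes$length), big.mark = ","),
              as.integer(x$telomere_window)))
  if (length(x$features))
    cat("features:", paste(names(x$features), collapse = ", "), "\n")
  invisible(x)
}

#' Length of one chromosome
#' @param genome a `genome_model`
#' @param chrom chromosome name
#' @return length in bp
#' @export
chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome: ", chrom[is.na(i)][1])
  genome$chromosomes$length[i]
}

#' Built-in budding-yeast genome frame
#'
#' A 16-chromosome, ~12.07 Mb diploid-reference frame with sacCer3-like
#' chromosome lengths and centromere intervals. This is the default
#' coordinate frame for the simulator; real analyses should load their own
#' annotation with [load_genome()].
#'
#' @param telomere_window bp, see [genome_model()]. Default 100.
#' @return A `genome_model`.
#' @export
yeast_genome <- function(telomere_window = 100) {
  chroms <- data.frame(
    name = c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrVI", "chrVII",
             "chrVIII", "chrIX", "chrX", "chrXI", "chrXII", "chrXIII",
             "chrXIV", "chrXV", "chrXVI"),
    length = c(230218L, 813184L, 316620L, 1531933L, 576874L, 270161L,
               1090940L, 562643L, 439888L, 745751L, 666816L, 1078177L,
               924431L, 784333L, 1091291L, 948066L))
  cens <- data.frame(
    name = chroms$name,
    start = c(151465L, 238207L, 114385L, 449711L, 151987L, 148510L,
              496920L, 105586L, 355629L, 436307L, 440129L, 150828L,
              268031L, 628758L, 326584L, 555957L),
    end = c(151582L, 238323L, 114501L, 449821L, 152104L, 148627L,
            497038L, 105703L, 355745L, 436425L, 440246L, 150947L,
            268149L, 628875L, 326702L, 556073L))
  genome_model(chroms, cens, telomere_window = telomere_window)
}

#' Load a genome model from annotation files
#'
#' Reads a chromosome-length table plus optional centromere and feature
#' interval files. Two dialects are accepted for interval files: a 1-based
#' inclusive TSV (`chrom  start  end`) or BED (0-based half-open, detected by
#' a `.bed` extension and converted on read).
#'
#' @param chrom_file TSV with two columns: chromosome name, length (bp).
#' @param centromere_file interval file (TSV or BED) with one centromere per
#'   chromosome. Required unless `centromeres` intervals are irrelevant to the
#'   downstream analysis, in which case zero-width placeholders at position 1
#'   are used.
#' @param feature_files optional named character vector of interval files;
#'   names become feature-set names (e.g. `c(LTR = "ltr.bed")`).
#' @param telomere_window bp, see [genome_model()].
#' @return A `genome_model`.
#' @export
load_genome <- function(chrom_file, centromere_file = NULL,
                        feature_files = NULL, telomere_window = 100) {
  chroms <- read_two_col(chrom_file)
  if (nrow(chroms) == 0L) stop("no chromosomes in ", chrom_file)
  if (is.null(centromere_file)) {
    cens <- data.frame(name = chroms$name, start = 1L, end = 1L)
  } else {
    iv <- read_intervals(centromere_file)
    cens <- data.frame(name = iv$chrom, start = iv$start, end = iv$end)
  }
  features <- list()
  if (!is.null(feature_files)) {
    if (is.null(names(feature_files)) || any(names(feature_files) == ""))
      stop("feature_files must be a named character vector")
    features <- lapply(feature_files, read_intervals)
  }
  genome_model(chroms, cens, telomere_window = telomere_window,
               features = features)
}

read_two_col <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("no chromosomes in ", path)
  parts <- strsplit(lines, "\t| +")
  out <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 2L || is.na(suppressWarnings(as.numeric(p[2]))))
      stop("malformed chromosome line ", i, " in ", path, ": ", lines[i])
    data.frame(name = p[1], length = as.numeric(p[2]))
  })
  do.call(rbind, out)
}

# Interval files: BED (0-based half-open) if extension .bed, else 1-based
# inclusive TSV chrom/start/end[/name].
read_intervals <- function(path) {
  is_bed <- grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track|browser|$)", lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  parts <- strsplit(lines, "\t")
  out <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    s <- suppressWarnings(as.numeric(p[2])); e <- suppressWarnings(as.numeric(p[3]))
    if (length(p) < 3L || is.na(s) || is.na(e))
      stop("malformed interval line ", i, " in ", path, ": ", lines[i])
    data.frame(chrom = p[1], start = s, end = e,
               name = if (length(p) >= 4L) p[4] else NA_character_)
  })
  iv <- do.call(rbind, out)
  if (is_bed) iv$start <- iv$start + 1    # 0-based half-open -> 1-based incl.
  if (any(iv$end < iv$start)) stop("interval with end < start in ", path)
  iv
}

#' Distance from an interval to the centromere and the nearest telomere
#'
#' Centromere distance is the gap between the interval and the centromere
#' interval (0 if they overlap, i.e. the interval spans the centromere).
#' Telomeres are operationalised as the chromosome ends (positions 1 and
#' length); telomere distance is `min(start - 1, length - end)`. With
#' `mode = "midpoint"` both distances are measured from the interval
#' midpoint instead of its nearest edge.
#'
#' @param chrom chromosome name
#' @param start,end interval, 1-based inclusive
#' @param genome a `genome_model`
#' @param mode `"edge"` (default) or `"midpoint"`
#' @return named numeric vector `c(dist_cen, dist_tel)` in bp
#' @export
distance_to_features <- function(chrom, start, end, genome,
                                 mode = c("edge", "midpoint")) {
  mode <- match.arg(mode)
  i <- match(chrom, genome$chromosomes$name)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  L <- genome$chromosomes$length[i]
  if (start < 1 || end > L || start > end)
    stop("interval outside chromosome ", chrom)
  cen <- genome$centromeres[genome$centromeres$name == chrom, ]
  if (mode == "midpoint") {
    mid <- floor((start + end) / 2)
    start <- end <- mid
  }
  dist_cen <- if (end < cen$start) cen$start - end
              else if (start > cen$end) start - cen$end
              else 0
  dist_tel <- min(start - 1, L - end)
  c(dist_cen = as.numeric(dist_cen), dist_tel = as.numeric(dist_tel))
}

#' Global analysis thresholds
#'
#' Bundles the numeric rules used across the pipeline: LOH tract support at
#' two levels (2 loose, 10 strict), the shared-homozygosity exclusion
#' fraction (>50% of non-missing lines), de novo mutation filters (depth >=
#' 40 reads, mapping quality >= 40), the 1 bp hotspot and 5 kb coverage bin
#' sizes, the 5-line hotspot count, and the propagation design (100
#' single-colony bottlenecks of ~20 generations each, i.e. ~2000
#' generations).
#'
#' @param min_support_loose,min_support_strict minimum number of consecutive
#'   fixed SNPs supporting an LOH tract (defaults 2 and 10)
#' @param fixed_share_fraction positions homozygous in strictly more than
#'   this fraction of non-missing lines are excluded as putative artifacts
#'   (default 0.5)
#' @param min_depth,min_mapq read-depth and mapping-quality filters for de
#'   novo mutation calls (defaults 40, 40)
#' @param hotspot_bin,coverage_bin bin sizes in bp (defaults 1, 5000)
#' @param hotspot_min_count minimum cross-line tract count for a hotspot
#'   (default 5)
#' @param generations_per_bottleneck,bottlenecks propagation design; the
#'   generation total is their product (default 20 x 100 = 2000)
#' @return An object of class `lohma_thresholds` (a validated list with an
#'   additional `generations` element).
#' @export
thresholds <- function(min_support_loose = 2L, min_support_strict = 10L,
                       fixed_share_fraction = 0.5, min_depth = 40L,
                       min_mapq = 40L, hotspot_bin = 1L,
                       coverage_bin = 5000L, hotspot_min_count = 5L,
                       generations_per_bottleneck = 20L, bottlenecks = 100L) {
  if (min_support_loose < 2L)
    stop("min_support_loose must be >= 2 (single-SNP LOH is not called)")
  if (min_support_strict < min_support_loose)
    stop("min_support_strict must be >= min_support_loose")
  if (fixed_share_fraction <= 0 || fixed_share_fraction >= 1)
    stop("fixed_share_fraction must lie in (0, 1)")
  stopifnot(min_depth >= 0, min_mapq >= 0, hotspot_bin >= 1,
            coverage_bin >= 1, hotspot_min_count >= 1,
            generations_per_bottleneck >= 1, bottlenecks >= 1)
  structure(list(min_support_loose = as.integer(min_support_loose),
                 min_support_strict = as.integer(min_support_strict),
                 fixed_share_fraction = fixed_share_fraction,
                 min_depth = as.integer(min_depth),
                 min_mapq = as.integer(min_mapq),
                 hotspot_bin = as.integer(hotspot_bin),
                 coverage_bin = as.integer(coverage_bin),
                 hotspot_min_count = as.integer(hotspot_min_count),
                 generations_per_bottleneck = as.integer(generations_per_bottleneck),
                 bottlenecks = as.integer(bottlenecks),
                 generations = as.integer(generations_per_bottleneck) *
                   as.integer(bottlenecks)),
            class = "lohma_thresholds")
}
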