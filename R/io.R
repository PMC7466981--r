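# On-disk formats. The VCF dialect is deliberately minimal (VCFv4.2, FORMAT
# GT:DP:MQ): genotype, depth and mapping quality are the only per-site values
# any rule in the pipeline consumes. Reading goes through vcfR; the writers
# emit the same dialect so that write -> read is an exact round trip.

GT_STATES <- c("HET", "HOM_P1", "HOM_P2", "MISSING")

#' Construct a genotype matrix over a SNP map
#'
#' @param snp_map data.frame (`chrom`, `pos`, `p1`, `p2`), positions strictly
#'   increasing within chromosome.
#' @param state character matrix (`n_snps` x `n_lines`) with entries from
#'   `HET`, `HOM_P1`, `HOM_P2`, `MISSING`; column names are line names.
#' @param depth,mapq numeric matrices of the same shape.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(snp_map, state, depth, mapq) {
  stopifnot(is.matrix(state), nrow(state) == nrow(snp_map),
            identical(dim(depth), dim(state)),
            identical(dim(mapq), dim(state)),
            !is.null(colnames(state)))
  if (!all(state %in% GT_STATES))
    stop("genotype states must be one of ", paste(GT_STATES, collapse = ", "))
  ord <- order(match(snp_map$chrom, unique(snp_map$chrom)), snp_map$pos)
  if (is.unsorted(ord)) {
    snp_map <- snp_map[ord, ]; state <- state[ord, , drop = FALSE]
    depth <- depth[ord, , drop = FALSE]; mapq <- mapq[ord, , drop = FALSE]
  }
  bad <- tapply(snp_map$pos, snp_map$chrom, function(p) any(diff(p) <= 0))
  if (any(unlist(bad))) stop("snp_map positions must be strictly increasing")
  structure(list(snp_map = snp_map, lines = colnames(state), state = state,
                 depth = depth, mapq = mapq),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d lines (%s)\n",
              nrow(x$snp_map), length(x$lines),
              paste(utils::head(x$lines, 4), collapse = ", ")))
  tab <- table(factor(x$state, levels = GT_STATES))
  cat("  states:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Per-line variant records from a simulation
#'
#' Assembles the VCF-like record table for one simulated line: a record at
#' every marker position (REF = P1 allele, ALT = P2 allele, genotype from the
#' line's state) plus the line's planted de novo mutations as heterozygous
#' records at non-marker positions.
#'
#' @param sim an `ma_sim` from [simulate_lines()].
#' @param line line name.
#' @return data.frame (`chrom`, `pos`, `ref`, `alt`, `gt`, `dp`, `mq`).
#' @export
sim_line_variants <- function(sim, line) {
  li <- match(line, sim$lines)
  if (is.na(li)) stop("unknown line: ", line)
  map <- sim$snp_map
  st <- sim$genotypes$state[, li]
  gt <- c(HET = "0/1", HOM_P1 = "0/0", HOM_P2 = "1/1", MISSING = "./.")[st]
  rec <- data.frame(chrom = map$chrom, pos = map$pos, ref = map$p1,
                    alt = map$p2, gt = unname(gt),
                    dp = sim$genotypes$depth[, li],
                    mq = sim$genotypes$mapq[, li])
  rec <- rec[st != "MISSING", ]   # missing markers are absent from the VCF
  snm <- sim$truth$snm
  if (nrow(snm)) {
    snm <- snm[snm$line == line, ]
    if (nrow(snm))
      rec <- rbind(rec, data.frame(chrom = snm$chrom, pos = snm$pos,
                                   ref = snm$ref, alt = snm$alt, gt = "0/1",
                                   dp = snm$dp, mq = snm$mq))
  }
  order_records(rec, sim$config$genome)
}

#' Parent variant records from a simulation
#'
#' Heterozygous records at every marker position plus homozygous-reference
#' evidence records at every planted de novo mutation position (the
#' joint-genotyping analogue: parent evidence extracted at candidate sites).
#'
#' @inheritParams sim_line_variants
#' @return data.frame as in [sim_line_variants()].
#' @export
sim_parent_variants <- function(sim) {
  map <- sim$snp_map
  rec <- data.frame(chrom = map$chrom, pos = map$pos, ref = map$p1,
                    alt = map$p2, gt = "0/1",
                    dp = round(sim$config$depth_mean),
                    mq = sim$config$mapq_mean)
  snm <- sim$truth$snm
  if (nrow(snm)) {
    u <- !duplicated(snm[c("chrom", "pos")])
    rec <- rbind(rec, data.frame(chrom = snm$chrom[u], pos = snm$pos[u],
                                 ref = snm$ref[u], alt = ".", gt = "0/0",
                                 dp = snm$parent_dp[u],
                                 mq = sim$config$mapq_mean))
  }
  order_records(rec, sim$config$genome)
}

order_records <- function(rec, genome) {
  ord <- order(match(rec$chrom, genome$chromosomes$name), rec$pos)
  rec <- rec[ord, ]
  rownames(rec) <- NULL
  rec
}

#' Write variant records as a minimal VCF
#'
#' VCFv4.2, one sample, FORMAT `GT:DP:MQ`. Suitable for re-reading with
#' [read_vcf_records()] / [read_vcf_genotypes()] (or any VCF reader).
#'
#' @param records data.frame (`chrom`, `pos`, `ref`, `alt`, `gt`, `dp`, `mq`).
#' @param path output path; `.gz` suffix writes gzip.
#' @param sample_name sample column header.
#' @param genome optional `genome_model`; adds contig headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_name = "sample", genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lohma",
           if (!is.null(genome))
             sprintf("##contig=<ID=%s,length=%d>",
                     genome$chromosomes$name, genome$chromosomes$length),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=MQ,Number=1,Type=Integer,Description=\"Mapping quality\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_name))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:MQ\t%s:%d:%d",
                  records$chrom, as.integer(records$pos), records$ref,
                  records$alt, records$gt, as.integer(records$dp),
                  as.integer(records$mq))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a single-sample VCF into a flat record table
#'
#' @param path VCF path (plain or gzip).
#' @return data.frame (`chrom`, `pos`, `ref`, `alt`, `gt`, `dp`, `mq`);
#'   missing DP/MQ become `NA`.
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF has no sample column: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  dp <- suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "DP")[, 1]))
  mq <- suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "MQ")[, 1]))
  data.frame(chrom = as.character(v@fix[, "CHROM"]),
             pos = as.integer(v@fix[, "POS"]),
             ref = as.character(v@fix[, "REF"]),
             alt = as.character(v@fix[, "ALT"]),
             gt = unname(as.character(gt)), dp = unname(dp), mq = unname(mq),
             row.names = NULL)
}

#' Project one line's VCF onto the parental SNP map
#'
#' Every map position receives a state: `0/1` records become `HET`;
#' homozygous records become `HOM_P1`/`HOM_P2` according to which parental
#' allele they carry; positions absent from the VCF, with missing genotypes,
#' with multi-allelic ALT, or whose alleles match neither parent become
#' `MISSING` (the last case is counted in a warning summary, not fatal).
#' Depth and mapping quality are carried along unfiltered; depth/quality
#' thresholds are applied by the de novo mutation caller, not here.
#'
#' @param vcf_source path to a VCF or a record table from
#'   [read_vcf_records()].
#' @param snp_map the parental `snp_map`.
#' @param thresholds a [thresholds()] (reserved for dialect options; the
#'   genotype projection itself applies no depth/quality filter).
#' @return list with `state`, `depth`, `mapq` vectors aligned to `snp_map`
#'   rows, and `n_allele_mismatch`.
#' @export
read_vcf_genotypes <- function(vcf_source, snp_map, thresholds = NULL) {
  rec <- if (is.character(vcf_source)) read_vcf_records(vcf_source)
         else vcf_source
  key_map <- paste(snp_map$chrom, snp_map$pos)
  key_rec <- paste(rec$chrom, rec$pos)
  idx <- match(key_map, key_rec)
  n <- nrow(snp_map)
  state <- rep("MISSING", n)
  depth <- rep(NA_real_, n); mapq <- rep(NA_real_, n)
  hit <- which(!is.na(idx))
  r <- rec[idx[hit], ]
  depth[hit] <- r$dp; mapq[hit] <- r$mq
  gt <- gsub("\\|", "/", r$gt)
  p1 <- snp_map$p1[hit]; p2 <- snp_map$p2[hit]
  multi <- grepl(",", r$alt)
  st <- rep("MISSING", length(hit))
  het <- gt %in% c("0/1", "1/0") & !multi
  st[het & r$ref == p1 & r$alt == p2] <- "HET"
  hom_ref <- gt == "0/0" & !multi
  hom_alt <- gt == "1/1" & !multi
  st[hom_ref & r$ref == p1] <- "HOM_P1"
  st[hom_ref & r$ref == p2] <- "HOM_P2"
  st[hom_alt & r$alt == p1] <- "HOM_P1"
  st[hom_alt & r$alt == p2] <- "HOM_P2"
  mismatch <- sum(st == "MISSING" & !gt %in% c("./.", ".") & !is.na(gt))
  state[hit] <- st
  if (mismatch > 0)
    warning(mismatch, " record(s) at map positions matched neither parental",
            " allele; set to MISSING")
  list(state = state, depth = depth, mapq = mapq,
       n_allele_mismatch = mismatch)
}

#' Build a genotype matrix from per-line VCFs
#'
#' @param vcf_paths named character vector (names are line names).
#' @param snp_map parental `snp_map`.
#' @param thresholds passed to [read_vcf_genotypes()].
#' @return a `genotype_matrix`.
#' @export
read_genotype_matrix <- function(vcf_paths, snp_map, thresholds = NULL) {
  if (is.null(names(vcf_paths)) || any(names(vcf_paths) == ""))
    stop("vcf_paths must be a named character vector of line VCFs")
  cols <- lapply(vcf_paths, read_vcf_genotypes, snp_map = snp_map,
                 thresholds = thresholds)
  mk <- function(el, default) {
    m <- do.call(cbind, lapply(cols, `[[`, el))
    colnames(m) <- names(vcf_paths)
    m[is.na(m)] <- default
    m
  }
  state <- do.call(cbind, lapply(cols, `[[`, "state"))
  colnames(state) <- names(vcf_paths)
  genotype_matrix(snp_map, state, mk("depth", 0), mk("mapq", 0))
}

#' Write LOH tracts as BED6
#'
#' 1-based inclusive tract coordinates are converted to BED's 0-based
#' half-open convention. The name field encodes `line:haplotype:support`;
#' score is the support count; strand is `.`.
#'
#' @param tracts tract table from [call_tracts()].
#' @param path output path.
#' @param genome a `genome_model`; tracts outside their chromosome are
#'   refused.
#' @return `path`, invisibly.
#' @export
write_tracts_bed <- function(tracts, path, genome) {
  hdr <- "#chrom\tstart\tend\tname\tscore\tstrand"
  if (nrow(tracts)) {
    L <- chrom_length(genome, tracts$chrom)
    if (any(tracts$start < 1 | tracts$end > L))
      stop("tract outside chromosome bounds; refusing to write")
    body <- sprintf("%s\t%d\t%d\t%s:%s:%d\t%d\t.", tracts$chrom,
                    as.integer(tracts$start) - 1L, as.integer(tracts$end),
                    tracts$line, tracts$haplotype, as.integer(tracts$support),
                    as.integer(tracts$support))
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a tracts BED6 written by [write_tracts_bed()]
#' @param path BED path.
#' @return data.frame (`line`, `chrom`, `start`, `end`, `haplotype`,
#'   `support`) in 1-based inclusive coordinates.
#' @export
read_tracts_bed <- function(path) {
  iv <- read_intervals(path)
  if (nrow(iv) == 0L)
    return(data.frame(line = character(), chrom = character(),
                      start = integer(), end = integer(),
                      haplotype = character(), support = integer()))
  parts <- strsplit(iv$name, ":", fixed = TRUE)
  data.frame(line = vapply(parts, `[`, "", 1L), chrom = iv$chrom,
             start = as.integer(iv$start), end = as.integer(iv$end),
             haplotype = vapply(parts, `[`, "", 2L),
             support = as.integer(vapply(parts, `[`, "", 3L)))
}

#' Write binned coverage as TSV
#' @param coverage data.frame (`line`, `chrom`, `start`, `end`, `count`).
#' @param path output path; `.gz` writes gzip.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  utils::write.table(coverage, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read binned coverage and validate the tiling
#'
#' Bins must tile each chromosome completely at the stated bin size (the
#' last bin may be short); gaps, overlaps or mis-sized bins are format
#' errors — coverage must be complete for copy-number calling.
#'
#' @param tsv_source TSV path from [write_coverage()] (columns `line`,
#'   `chrom`, `start`, `end`, `count`).
#' @param genome a `genome_model`.
#' @param bin bin size in bp.
#' @return the validated coverage data.frame.
#' @export
read_coverage <- function(tsv_source, genome, bin = 5000L) {
  cov <- utils::read.table(tsv_source, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("line", "chrom", "start", "end", "count")
  if (!all(need %in% names(cov)))
    stop("coverage file must have columns ", paste(need, collapse = ", "))
  validate_coverage(cov, genome, bin)
  cov
}

validate_coverage <- function(cov, genome, bin) {
  for (li in unique(cov$line)) {
    for (ch in genome$chromosomes$name) {
      b <- cov[cov$line == li & cov$chrom == ch, ]
      L <- chrom_length(genome, ch)
      exp_starts <- seq(1L, L, by = bin)
      if (nrow(b) != length(exp_starts) ||
          !all(sort(b$start) == exp_starts) ||
          !all(b$end[order(b$start)] == pmin(exp_starts + bin - 1L, L)))
        stop("coverage bins for ", li, " on ", ch,
             " do not tile the chromosome at bin size ", bin)
    }
  }
  invisible(TRUE)
}

#' Write piecewise-constant LOH occupancy as bedGraph
#' @param occ an `loh_occupancy` from [build_occupancy()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_occupancy_bedgraph <- function(occ, path) {
  seg <- occ$segments
  lines <- c("track type=bedGraph name=loh_occupancy",
             sprintf("%s\t%d\t%d\t%d", seg$chrom,
                     as.integer(seg$start) - 1L, as.integer(seg$end),
                     as.integer(seg$count)))
  writeLines(lines, path)
  invisible(path)
}
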