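# Independent brute-force oracles. These re-derive expected results by the
# most literal possible method (per-position loops), deliberately sharing no
# code with the package implementations they check.

# Exhaustive per-line run scanner over a raw state matrix. Recomputes the
# shared-homozygosity exclusion itself, walks positions one by one, and
# returns runs of >= min_support same-haplotype homozygous calls with
# missing positions skipped.
oracle_scan_tracts <- function(snp_map, state, min_support, share_frac = 0.5) {
  n <- nrow(state)
  hom <- state == "HOM_P1" | state == "HOM_P2"
  excluded <- logical(n)
  for (i in seq_len(n)) {
    nm <- sum(state[i, ] != "MISSING")
    excluded[i] <- nm == 0 || (sum(hom[i, ]) / nm) > share_frac
  }
  out <- list()
  for (li in seq_len(ncol(state))) {
    for (ch in unique(snp_map$chrom)) {
      idx <- which(snp_map$chrom == ch & !excluded)
      run_hap <- NULL; run_pos <- c()
      flush <- function() {
        if (!is.null(run_hap) && length(run_pos) >= min_support)
          out[[length(out) + 1L]] <<- data.frame(
            line = colnames(state)[li], chrom = ch,
            first_snp = min(run_pos), last_snp = max(run_pos),
            support = length(run_pos), haplotype = run_hap)
      }
      for (i in idx) {
        s <- state[i, li]
        if (s == "MISSING") next
        if (s == "HET") { flush(); run_hap <- NULL; run_pos <- c() }
        else {
          hap <- sub("HOM_", "", s)
          if (is.null(run_hap) || hap != run_hap) {
            flush(); run_hap <- hap; run_pos <- c()
          }
          run_pos <- c(run_pos, snp_map$pos[i])
        }
      }
      flush()
    }
  }
  if (!length(out))
    return(data.frame(line = character(), chrom = character(),
                      first_snp = integer(), last_snp = integer(),
                      support = integer(), haplotype = character()))
  res <- do.call(rbind, out)
  res[order(res$line, res$chrom, res$first_snp), ]
}

# Dense per-position tract counting for small chromosomes.
oracle_occupancy <- function(tracts, chrom, chrom_len, dedup_lines = TRUE) {
  counts <- integer(chrom_len)
  tt <- tracts[tracts$chrom == chrom, , drop = FALSE]
  if (dedup_lines) {
    for (li in unique(tt$line)) {
      covered <- logical(chrom_len)
      p <- tt[tt$line == li, ]
      for (r in seq_len(nrow(p))) covered[p$start[r]:p$end[r]] <- TRUE
      counts <- counts + covered
    }
  } else {
    for (r in seq_len(nrow(tt))) {
      counts[tt$start[r]:tt$end[r]] <- counts[tt$start[r]:tt$end[r]] + 1L
    }
  }
  counts
}

# Random small genotype matrix over a toy genome, for property tests.
random_genotype_matrix <- function(n_snps, n_lines, n_chrom = 1L) {
  chroms <- paste0("c", seq_len(n_chrom))
  per <- tabulate(sample.int(n_chrom, n_snps, replace = TRUE), n_chrom)
  per <- pmax(per, 1L)
  map <- do.call(rbind, lapply(seq_len(n_chrom), function(k)
    data.frame(chrom = chroms[k], pos = sort(sample.int(10000L, per[k])))))
  map$p1 <- "A"; map$p2 <- "G"
  st <- matrix(sample(c("HET", "HOM_P1", "HOM_P2", "MISSING"),
                      nrow(map) * n_lines, replace = TRUE,
                      prob = c(0.55, 0.17, 0.17, 0.11)),
               nrow = nrow(map),
               dimnames = list(NULL, paste0("L", seq_len(n_lines))))
  toy_genome <- genome_model(
    data.frame(name = chroms, length = 10000L),
    data.frame(name = chroms, start = 5000L, end = 5100L))
  gm <- genotype_matrix(map, st,
                        matrix(50, nrow(map), n_lines,
                               dimnames = list(NULL, colnames(st))),
                        matrix(60, nrow(map), n_lines,
                               dimnames = list(NULL, colnames(st))))
  list(gm = gm, genome = toy_genome, map = map, state = st)
}

# Tiny genotype matrix straight from state vectors (one chromosome).
toy_gm <- function(states, pos = NULL, chrom_len = 10000L) {
  state <- do.call(cbind, states)
  colnames(state) <- names(states)
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = nrow(state))
  map <- data.frame(chrom = "c1", pos = pos, p1 = "A", p2 = "G")
  genome <- genome_model(data.frame(name = "c1", length = chrom_len),
                         data.frame(name = "c1",
                                    start = chrom_len - 100L,
                                    end = chrom_len - 50L))
  list(gm = genotype_matrix(map, state,
                            matrix(50, nrow(map), ncol(state),
                                   dimnames = list(NULL, colnames(state))),
                            matrix(60, nrow(map), ncol(state),
                                   dimnames = list(NULL, colnames(state)))),
       genome = genome)
}
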