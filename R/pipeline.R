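# End-to-end orchestration. The package's function surface is the
# interface; run_pipeline() composes the stages over a config (an R list or
# a YAML file) and writes every stage output plus a manifest recording the
# seed and thresholds, so that two runs with the same config are
# byte-identical.

#' Run the MA-line analysis pipeline
#'
#' Stages: `simulate` (or load inputs), `loh` (fixed SNPs, tracts at loose
#' and strict support, switches, fixation summary), `hotspots` (occupancy
#' bedGraph + hotspot BED), `cnv` (aneuploidy + segmental calls), `snm`
#' (mutation table + per-background rate). All outputs are TSV/BED/
#' bedGraph/VCF under `out_dir`, plus `manifest.yaml`.
#'
#' @param config a list or path to a YAML file. Recognised fields:
#'   `seed` (required), `out_dir` (required), `simulate` (list of
#'   [sim_config()] overrides; `loh_preset` selects the LOH regime),
#'   `thresholds` (list of [thresholds()] overrides), `stages` (character
#'   subset of `c("loh", "hotspots", "cnv", "snm")`; default all),
#'   `write_vcfs` (logical, default `FALSE`), `hotspot_haplotype`
#'   (default `"P1"`).
#' @return invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("loh", "hotspots", "cnv", "snm")

  th_args <- config$thresholds %||% list()
  th <- do.call(thresholds, th_args)

  sim_args <- config$simulate %||% list()
  preset <- sim_args$loh_preset %||% "SY"
  sim_args$loh_preset <- NULL
  sim_args$seed <- config$seed
  if (is.null(sim_args$loh)) sim_args$loh <- loh_regime(preset)
  cfg <- do.call(sim_config, sim_args)
  sim <- simulate_lines(cfg)
  genome <- cfg$genome

  utils::write.table(sim$truth$loh, file.path(out_dir, "truth_loh.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$snm, file.path(out_dir, "truth_snm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_coverage(sim$coverage, file.path(out_dir, "coverage.tsv"))
  if (isTRUE(config$write_vcfs)) {
    write_vcf(sim_parent_variants(sim), file.path(out_dir, "parent.vcf"),
              sample_name = "parent", genome = genome)
    for (li in sim$lines)
      write_vcf(sim_line_variants(sim, li),
                file.path(out_dir, paste0(li, ".vcf")),
                sample_name = li, genome = genome)
  }

  res <- list(out_dir = out_dir, sim = sim, thresholds = th)

  if ("loh" %in% stages) {
    fixed <- identify_fixed_snps(sim$genotypes, th)
    tracts <- call_tracts(sim$genotypes, genome, fixed,
                          min_support = th$min_support_loose)
    tracts_strict <- call_tracts(sim$genotypes, genome, fixed,
                                 min_support = th$min_support_strict)
    switches <- detect_haplotype_switches(tracts_strict, sim$genotypes, fixed)
    fixsum <- summarize_fixation(sim$genotypes, tracts, genome, fixed)
    utils::write.table(tracts, file.path(out_dir, "tracts_loose.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tracts_strict, file.path(out_dir, "tracts_strict.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_tracts_bed(tracts, file.path(out_dir, "tracts_loose.bed"), genome)
    utils::write.table(switches, file.path(out_dir, "haplotype_switches.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fixsum, file.path(out_dir, "fixation_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$fixed <- fixed; res$tracts <- tracts
    res$tracts_strict <- tracts_strict
    res$switches <- switches; res$fixation <- fixsum
  }

  if ("hotspots" %in% stages) {
    if (is.null(res$tracts)) stop("hotspots stage requires the loh stage")
    occ <- build_occupancy(res$tracts, genome,
                           restrict_haplotype = config$hotspot_haplotype %||% "P1")
    hot <- call_hotspots(occ, min_count = th$hotspot_min_count)
    write_occupancy_bedgraph(occ, file.path(out_dir, "occupancy.bedgraph"))
    utils::write.table(hot, file.path(out_dir, "hotspots.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$occupancy <- occ; res$hotspots <- hot
  }

  if ("cnv" %in% stages) {
    prof <- normalize_profile(sim$coverage)
    aneu <- call_aneuploidy(prof)
    seg <- call_segmental(prof, whole_calls = aneu)
    utils::write.table(rbind(aneu, seg), file.path(out_dir, "cnv_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$aneuploidy <- aneu; res$segmental <- seg
  }

  if ("snm" %in% stages) {
    parent <- sim_parent_variants(sim)
    muts <- do.call(rbind, lapply(sim$lines, function(li)
      detect_snms(sim_line_variants(sim, li), parent, sim$snp_map, th,
                  line_name = li, loh_tracts = res$tracts)))
    per_line_m <- vapply(sim$lines, function(li) sum(muts$line == li), 0L)
    G_dip <- 2 * sum(genome$chromosomes$length)
    rate <- estimate_rate(sum(per_line_m), length(sim$lines),
                          g = cfg$generations, G = G_dip,
                          background = "simulated", per_line_m = per_line_m)
    utils::write.table(muts, file.path(out_dir, "snm_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(background = rate$background, m = rate$m,
                 n_lines = rate$n_lines, g = rate$g, G = rate$G,
                 mu = rate$mu, mu_e10 = rate$mu_e10),
      file.path(out_dir, "snm_rate.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    res$mutations <- muts; res$rate <- rate
  }

  manifest <- list(package = "lohma",
                   version = as.character(utils::packageVersion("lohma")),
                   seed = config$seed, stages = stages,
                   thresholds = unclass(th)[names(unclass(th))],
                   n_lines = cfg$n_lines, n_snps = nrow(sim$snp_map),
                   loh_preset = preset)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(res)
}
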