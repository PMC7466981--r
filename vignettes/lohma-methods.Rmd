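---
title: "Methods: LOH, copy-number and mutation-rate analysis of MA lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LOH, copy-number and mutation-rate analysis of MA lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohma)
```

# The experimental design this package models

A mutation accumulation (MA) experiment propagates replicate lines from a
single ancestor through repeated single-colony bottlenecks, so that each
line's effective population size collapses to one cell at every transfer
and selection has almost no opportunity to filter mutations. The design
modelled here is a diploid budding-yeast panel: hybrid lines carrying tens
of thousands of heterozygous SNPs between two parental genomes, plus
homozygous diploid lines, propagated for ~100 bottlenecks (~20 generations
each, ~2000 mitotic generations total), then sequenced once alongside the
parents.

Three classes of events are read out per line against the parent, and each
has its own caller in this package:

1. **Loss of heterozygosity (LOH)** — mitotic recombination (gene
   conversion, crossover/BIR) or chromosome loss + reduplication converts
   heterozygous regions to homozygosity. Observable only in the hybrid
   lines, as runs of markers fixed to one parental haplotype.
2. **Gross chromosomal changes** — whole-chromosome aneuploidy and
   segmental duplications/deletions, visible as shifts in binned read
   depth.
3. **De novo single-nucleotide mutations (SNMs)** — new heterozygous
   variants at non-marker positions, the substrate for per-base
   per-generation rate estimates.

# Coordinates and the genome model

All point positions and interval endpoints are 1-based inclusive (the VCF
convention); BED input/output converts at the boundary, and coverage bins
are half-open on disk. A `genome_model` carries ordered chromosome
lengths, one centromere interval per chromosome, a telomere window, and
optional feature interval sets (e.g. LTR retrotransposons). Telomeres are
operationalised as the chromosome ends (positions 1 and length): no
telomere-repeat annotation is assumed, and a tract's telomere distance is
`min(start - 1, length - end)`. Distances of tracts to features are
measured from tract edges (nearest-edge gap, zero when overlapping); a
midpoint mode is available behind a flag since either convention is
defensible, but edges match the "reaching within *w* bp of the telomere"
terminal rule, with `telomere_window = 100` bp by default.

# Fixed SNPs and the shared-homozygosity exclusion

A marker is *fixed* for a line iff the line is homozygous there. Before
tract calling, positions homozygous — for either haplotype — in strictly
more than 50% of the non-missing lines are excluded for every line
(`fixed_share_fraction = 0.5`). Independent lines fix independent
regions; a position recurrently homozygous across most of a panel is far
more likely residual parental homozygosity or a systematic genotyping
artifact than seven independent LOH events. The rule is deliberately
allele-agnostic and uses a strict inequality (exactly half the lines does
not exclude), and the fraction is taken over non-missing lines so
low-coverage positions are not excluded by accident. All-missing
positions are excluded with their own reason code.

# Tract calling, measurement and classification

A tract is a maximal run of consecutive (non-excluded) markers fixed to
the same haplotype in one line, broken by heterozygous markers or by
fixed markers of the opposite haplotype. Two support levels are called:
`min_support = 2` (default; single-marker LOH is never emitted because
isolated homozygous calls are the dominant artifact class) and
`min_support = 10` (conservative; used for haplotype-switch reporting).

**Missing genotypes neither break nor support a run.** Missingness is
absence of evidence, not evidence of heterozygosity; a run of fixed
markers interrupted by a no-call remains one tract, but the no-call does
not count toward support. This choice is configurable by filtering the
genotype matrix beforehand, and the simulator's missingness lets the
round-trip tests quantify its effect.

Tract size uses the flanking-marker midpoint convention: each boundary is
`floor((outermost fixed marker + first heterozygous marker beyond it)/2)`,
and `length = end - start`. The true recombination breakpoint is only
known to lie between the outermost converted marker and the next
heterozygous one; the midpoint is the unbiased point estimate, and the
local inter-marker gap is the natural uncertainty (the recovery tests
score boundary error against exactly that gap). Where a run reaches a
chromosome end with no flanking marker, the boundary snaps to position 1
or the chromosome length — terminal crossover tracts span the telomere by
construction. Midpoints round down, so all coordinates stay integer.

Classification: *terminal* iff a boundary comes within the telomere
window of a chromosome end; *centromere-spanning* iff the tract interval
overlaps the centromere interval. Adjacent opposite-haplotype tracts in
one line separated by at most `max_gap_snps = 2` heterozygous markers are
reported as haplotype switches; end-point data cannot distinguish one
double-strand-break repair event from two independent ones, so the pairs
are reported without mechanistic claims (the threshold is exposed because
"contiguous" admits several operationalisations).

Per-line fixation is summarised two ways: `pct_snps_fixed` (fixed over
genotyped markers) and `pct_genome_fixed` (summed tract length over
genome length). The second corrects for marker-density differences when
comparing hybrids with different SNP maps. Percentages are computed per
line and then aggregated across lines, matching how MA panels are
reported. Group tract lengths are compared with the Wilcoxon rank-sum
test (normal approximation with continuity correction — tract lengths tie
heavily at marker-resolution).

# LOH occupancy and hotspots

The cross-line map counts, for every base pair, the tracts overlapping
that position. Counts are stored as piecewise-constant segments built by
boundary difference accumulation — exactly equivalent to dense 1 bp bins
(the oracle tests assert positionwise equality on toy chromosomes) at a
tiny fraction of the memory of a 12M-element vector. Two options reflect
how such maps are read:

- `dedup_lines` (default on): a line contributes at most 1 per position,
  so a count of 5 reads as "5 of *n* lines", and thresholds phrased as
  line fractions are meaningful even when one line has several
  overlapping tracts.
- `restrict_haplotype`: when pooling hybrids that share one parent, only
  tracts fixed to the shared parent's haplotype are counted, so the map
  is a map *of that genome*.

Hotspots are maximal intervals with count ≥ `hotspot_min_count` (default
5), merged across adjacent qualifying segments, annotated with the
nearest feature interval (e.g. LTR) when features are loaded. No
enrichment statistic is attached: the fixed count threshold mirrors how
such maps are drawn and read, and a proper null for mitotic LOH placement
is not part of this package's scope.

# Copy number from binned coverage

Read counts in 5 kb bins are normalised by the genome-wide median bin
count per line, so a euploid diploid sits at ratio 1, a single-chromosome
gain at 1.5, a single loss at 0.5. Calls use explicit thresholds halfway
between baseline and the one-copy expectation: chromosome median ratio
≥ 1.4 → trisomy, ≤ 0.6 → monosomy. The intermediate band [1.15, 1.4) is
flagged `possible_mosaic` rather than called: a colony in which only a
subset of cells carries an extra chromosome produces exactly such
intermediate coverage. Segmental events are runs of ≥ `min_run = 4` bins
(20 kb) beyond threshold, with single-bin interruptions bridged; 4 bins
suppresses negative-binomial count noise while remaining below the
tens-of-kb scale of observed segmental events. Published analyses of this
design typically call these events from coverage plots by eye; the
thresholds here are explicit, tested stand-ins for that judgement, and
all of them are arguments.

# SNM detection and rate estimation

A candidate SNM is a heterozygous record in a line at a position that is
not a parental heterozygous marker, whose alternate allele is absent from
the parent's record at that position. Candidates without parent evidence
are dropped (and counted) rather than assumed reference. Record-level
filters: mapping quality ≥ 40 and depth ≥ 40 reads. Homozygous novel
calls are not emitted — in a diploid propagated mitotically, a new
mutation is heterozygous, and fixed homozygous differences indicate
upstream problems. Candidates inside called LOH tracts are retained but
flagged, preserving auditability without silently coupling the two
callers. This package implements a single detection path with these
filters; published pipelines for this design have intersected several
independent callers, so counts from real data can only be more
conservative than this caller alone.

The estimator is the standard MA-design rate:
`mu = m / (n_lines * g * G)` with `g = 2000` generations and `G` the
callable bases per line, defaulting to the full diploid genome
(24.04 Mb). Summaries print on the 1e-10 scale rounded to two decimals.
Per-line counts give per-line rates, a between-line standard error, and
Welch *t*-tests between backgrounds; fold changes are reported both from
raw means and from the rounded summary rates, since published fold values
are conventionally quoted from the rounded pair. Using the whole diploid
genome as `G` slightly understates rates when per-line callable fractions
are below 1; with ~99.9% coverage the effect is below the reporting
precision, but analyses with per-line callable-site counts should pass
them as `G` — this is a known limitation, not a free parameter.

# The simulator: what it emulates, and what it does not

`simulate_lines()` generates the complete analysis substrate with a truth
table of everything planted. Defaults are the study conditions the
package is designed around: a 16-chromosome ~12.07 Mb genome with
realistic chromosome lengths and centromeres, 50,000 markers, 10 lines,
2000 generations, ~70X depth.

- **Markers.** Counts per chromosome are proportional to length (exact in
  total). Gaps are exponential with median 100 bp; because 50,000 markers
  over 12.07 Mb imply a mean gap of ~241 bp, a random ~5% of gaps are
  inflated to absorb the remaining length. The result is a clustered
  marker map — dense stretches punctuated by gaps, as in real hybrid
  genomes where diverged and repetitive regions carry few usable markers —
  whose observed median gap stays within ~10% of the configured median.
- **LOH.** Per line, a Poisson number of already-fixed events. Lineage
  drift within the 100 bottlenecks is deliberately *not* simulated: only
  fixed outcomes are observable at the endpoint, so planting fixed events
  is the correct generative model for the data the callers see, and
  cell-level simulation would add nothing testable. Two presets bracket
  the observed regimes: `"SY"` (λ = 30/line, lognormal lengths with
  median 1.73 kb and mean 28.4 kb, 20% terminal, 5% whole-chromosome) and
  `"SR"` (λ = 90/line, median 247 bp, mean 4.03 kb, 5% terminal, 2%
  whole-chromosome). `sdlog = sqrt(2 log(mean/median))` reproduces both
  calibration points of each heavy-tailed length distribution. Terminal
  events anchor a lognormal length at a random chromosome end; overlapping
  same-haplotype events merge (recorded merged); an event overlapping an
  opposite-haplotype one is discarded, since a fixed region cannot re-fix
  the other way. Note that *measured* tract medians exceed the planted
  medians: the midpoint convention adds about half a local gap per side,
  and events must cover ≥ 2 markers to be callable, which length-biases
  the recovered set. Tests therefore score recovery and regime
  separation, not equality of medians.
- **Noise.** Depth is negative-binomial (mean 70, size 80, so ~0.3% of
  sites fall under the 40-read filter); mapping quality is 60 with ~1%
  low-MQ outliers in 10..39; heterozygous markers are miscalled
  homozygous with probability 1e-4 (the artifact class that motivates the
  ≥ 2-marker support rule — singletons appear, tracts do not); genotypes
  go missing with probability 0.002.
- **SNMs** are Poisson over the diploid base count × generations at
  1e-10 per base per generation, placed at non-marker positions, always
  heterozygous, with their own depth/quality draws. The parent VCF
  carries homozygous-reference evidence records at candidate sites, the
  joint-genotyping analogue.
- **Copy number.** Binned counts are negative-binomial around a mean
  scaled by planted copy ratios (trisomy 1.5; segmental events 1.5/0.5
  over 20–40 bins, capped at 40% of a chromosome so that "segmental"
  stays sub-chromosomal).

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: read-level artifacts (mapping bias around
repeats, reference bias), the restriction to uniquely mapped reads that
makes repetitive regions systematically missing, GC-dependent coverage
waves, indels, correlated genotyping error along reads, and selection
during propagation. Real-data missingness is structured, not uniform;
the shared-homozygosity exclusion absorbs part of that structure but the
recovery percentages measured here are upper bounds for real data.

# Validation strategy and problem sizes

Every caller is tested three ways: frozen worked examples (hand-checked
arithmetic for the midpoint convention, distances, thresholds),
property-style oracle equivalence (the tract caller against a literal
per-position run scanner on 1000 random matrices; occupancy against dense
per-base counting on 100 kb chromosomes, with exact segment-sum
conservation), and end-to-end recovery on full-scale simulations (12 Mb /
50,000 markers / 10 lines per regime, ≥ 95% sensitivity and precision
with haplotype and boundary checks; 100-replicate rate recovery within
two standard errors of μ = 1e-10; planted trisomies and 20-bin deletions
recovered with no false whole-chromosome calls). These sizes keep the
default suite under about a minute while exercising the genome scale the
package targets; `scripts/acceptance.R` re-runs the same computations
from an installed copy and writes the headline numbers as JSON.

# Known limitations

- The callable-base denominator `G` defaults to the whole diploid genome;
  backgrounds with materially reduced callable fractions need explicit
  per-line denominators or their rates will be underestimated.
- The SNM caller is a single detection path; it quantifies the stated
  filters, not the consensus behaviour of multi-caller intersections.
- Hotspot calling is threshold-based; it identifies shared-overlap
  intervals, not statistically enriched ones.
- Tract boundaries are only as precise as the local marker density;
  deserts between markers make both lengths and terminal classification
  uncertain there, in the package as in any marker-based analysis.
- The mosaic coverage band flags, but cannot resolve, mixed-population
  aneuploidy; resolving it requires single-colony re-sequencing.
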