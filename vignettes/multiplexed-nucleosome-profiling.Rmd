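---
title: "Methods: multiplexed nucleosome profiling with nucleomux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed nucleosome profiling with nucleomux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

nucleomux analyses pooled, inline-barcoded ChIP-seq of MNase-derived
mono-nucleosomes: many biological samples are barcoded at the chromatin
stage, pooled, and immuno-precipitated together, so one sequencing lane
carries one IP assay for all samples at once. This vignette documents
the statistical models, the synthetic-data generator, and the numerical
choices — in particular every place where the design was genuinely open
and the package had to commit to a convention.

# From reads to nucleosome midpoints

**Demultiplexing.** A read pair is assigned to the unique barcode within
`max_mismatches` (default 0) of the 6-mer prefix of read 1. The default
of zero mismatches reflects the small Hamming slack of 6-mers; maps in
which two barcodes lie within `2 * max_mismatches` are rejected outright
so assignment is always unambiguous. Unassigned pairs are written to an
`undetermined` output for audit, and counts conserve totals
(assigned + unassigned = input). Whether real adapters carry the barcode
on both mates is not asserted; the package matches read 1 only, which is
also the simulator's dialect.

**Pooling-bias correction.** Because the barcoded chromatin samples are
pooled in only approximately equal amounts, the per-sample share of an
IP lane confounds IP recovery with pooling. The statistic reported by
`normalized_proportions()` divides each sample's IP-lane fraction by its
input-lane fraction; the input lane sees the same pool, so pooling
imbalance cancels. The renormalised values (summing to one) are the
pooling-corrected shares of the IP, and a sample whose strain cannot
carry the probed mark (e.g. an H3K4-methylation IP on a Set1 deletion)
shows up as the minimum share.

**Mono-nucleosome filtering.** Aligned pairs are retained when (i)
uniquely aligned — operationalised as: primary alignment, no
secondary-alignment records, mapping quality at least `min_mapq`
(default 30; the underlying aligner's notion of "unambiguous" is not
recoverable from output files, so a MAPQ floor stands in); (ii)
inward-facing (FR orientation); and (iii) of mono-nucleosomal length.
The length window is at most 220 bp everywhere; the lower bound is
130 bp for multiplexed IP lanes and 100 bp for inputs. The wider input
floor exists because some mutants' chromatin is more MNase-sensitive and
yields shorter protected fragments; censoring those from the
normalisation reference would bias every downstream ratio.

**Duplicates.** Fragments sharing both end coordinates beyond two copies
are treated as PCR duplicates. The rule "more than two identical copies"
is ambiguous between capping the stack at two and discarding it
entirely; `deduplicate()` caps by default (preserving one or two
observations of genuine signal) and offers `mode = "drop"` for the
stricter reading. Capping is idempotent.

**Midpoints.** Each fragment `[start, end)` (0-based half-open;
SAM input is converted from 1-based) is reduced to the midpoint
`floor((start + end - 1) / 2)`. The floor tie-break for even lengths is
a convention; it biases positions by at most half a base pair.

# Occupancy profiles

Midpoint counts per base form the occupancy track. TSS meta-profiles
collect, for every gene, the per-base counts over a window (default
−1000..+1500 bp) oriented in the direction of transcription:
minus-strand genes are flipped, a convention required for the downstream
part of the window to be meaningful even though the flip cannot be
verified against any external description. Counts are summed across all
genes — genes whose windows overlap both receive counts, with no
ownership resolution — and divided by the genome-wide total of observed
midpoints, so the profile is an occupancy distribution (its sum over the
window is the fraction of all midpoints that fall in some gene window).

Mark enrichment is the ratio of IP to input occupancy per position, with
a pseudocount added to both. The default pseudocount is
`1 / (total IP midpoints)`: scale-free, vanishing with depth, and just
large enough to keep positions with zero input occupancy finite.

**Peak spacing and the NDR.** Both estimators first smooth the profile
with a moving average of bandwidth 31 bp (partial windows at the edges,
no NA padding). The bandwidth suppresses per-base sampling noise while
remaining well below the 150 bp repeat it must not merge.
`profile_peak_spacing()` reports the median distance between successive
local maxima (plateaus — which arise when smoothing delta-like peaks —
resolve to their centres; maxima closer than 100 bp are merged,
strongest first). The median is used because the array is interrupted at
the nucleosome-depleted region: one inter-peak gap spans the NDR and
would corrupt a mean. `ndr_locator()` seeds at the smoothed minimum of
the search interval (default −400..0) and grows the contiguous stretch
whose occupancy stays below half (configurable) of the flanking peak
level; it reports the midpoint of that stretch as the centre and its
length as the width. Reporting the stretch midpoint rather than the raw
argmin is deliberate: on real-sized simulations the trough bottom is
flat and noisy and the argmin wanders by ±100 bp, while the stretch
edges are steep and stable. For a symmetric trough the two definitions
coincide.

# Differential occupancy

For two conditions with replicated IP and input lanes, counts are the
gene-summed midpoints at each TSS-relative position (integer sums — a
count model needs integers; the per-gene average is provided separately
as a reporting transform). Positions with zero counts in all samples are
dropped.

**Normalisation.** Each IP sample's paired input supplies per-position
factors: the input count, scaled by the IP/input total-coverage ratio,
zeros replaced by the position-wise minimum positive input count, and
the whole column rescaled to geometric mean one. Because of that final
rescaling, the direction of the coverage-ratio scaling (IP/input vs
input/IP) only changes factors by a per-sample constant and is
inconsequential — which is why the package does not agonise over the
choice. The factors absorb position-level technical structure (chromatin
solubility, MNase accessibility, PCR preference) shared between an IP
and its input.

**Test.** The per-position model is `K ~ NB(mu = factor * q(condition),
dispersion alpha)`. Dispersion is estimated by method of moments on
factor-normalised counts (`Var(K/f) = q * E(1/f) + alpha * q^2`), then
shrunk halfway towards a trend `a0 + a1/mu` fitted by robust regression
across positions, and floored at 1e-8. Halfway shrinkage is a stand-in
for the heavier machinery of dedicated count-model packages; it is the
declared design choice, not an optimised one. `q` per condition is
fitted by Newton iterations on the log scale (vectorised across
positions); a condition with all-zero counts takes the continuity value
`0.5 / sum(factors)` rather than an infinite fold change. The Wald
statistic is `log(qB/qA)` over its asymptotic standard error from the
expected Fisher information `sum(mu / (1 + alpha * mu))` per condition;
as `alpha -> 0` this reduces exactly to the Poisson Wald statistic,
which the tests verify against an independent Poisson GLM oracle.

**Local FDR.** The p-value distribution is modelled as a two-component
mixture. The null proportion `eta0` is the Storey estimator at
`lambda = 0.5`; the density is the Grenander estimator (left derivative
of the least concave majorant of the empirical CDF, computed by
pool-adjacent-violators), which is nonincreasing by construction, making
`lfdr(p) = min(1, eta0 / f(p))` nondecreasing in p. At least 100
p-values are required; below that the density estimate is meaningless
and the function says so rather than guessing.

**Calling.** A position is significant iff `|log2FC| > 0.05` and
`lfdr < 0.2`, both strict. The 0.05 fold-change threshold is a
calibration: comparing two replicate groups of the same condition must
produce no calls, and the acceptance suite re-enacts exactly that
self-comparison on simulated data. Per-replicate summaries of normalised
counts use the Huber M-estimator of location (tuning constant 1.345 on
the MAD scale), which equals the arithmetic mean when nothing is
downweighted.

# Cryptic initiation calling

5′-end tags are kept when uniquely aligned, with no 5′ soft-clipping and
at most 10% of the read soft-clipped in total. A tag supports internal
initiation of a gene when its 5′ end lies in the gene body on the
matching strand at a gene-relative offset of at least 200 bp; offsets
are measured from the TSS in the direction of transcription, and the
boundary is inclusive (a tag exactly at +200 counts — the source rule
only says "exclusion of the first 200 bp", so offsets 0..199 are
excluded). Strand-matching is this package's convention; requiring it is
the conservative choice for sense-strand internal initiation. Gene
counts are tested mutant vs reference with median-of-ratios size
factors, the NB Wald test above, and Benjamini–Hochberg adjustment; a
gene is called when log2FC > 0 and padj < 0.1. The sign requirement
means strongly *depleted* genes are never called, however significant.

# The synthetic-data generator

The generator states a world with the following structure, chosen once:

* **Genome.** Genes placed without overlap along auto-sized
  chromosomes; lengths log-normal with arithmetic mean 1500 bp and
  log-sd 0.5 (the right tail supplies the long-gene minority), gaps
  exponential (mean 400 bp) plus a 200 bp spacer, 2 kb margins so TSS
  windows are never truncated.
* **Chromatin.** Per gene, a phased dyad array: NDR centred 100 bp
  upstream of the TSS, width 140 bp; first flanking dyads 105 bp
  outside the NDR edges (+1 at +75, −1 at −275 with defaults); repeat
  150 bp; per-nucleosome Gaussian jitter, sd 20 bp. Marks are drawn per
  nucleosome index from per-strain layouts (5′ marks on +1..+4, an
  elongation mark on 3′ nucleosomes, gene-body acetylation spread in
  the deacetylase-pathway mutants); marks a strain cannot deposit are
  structurally absent. These are presets that reproduce the
  *qualitative* geometry of yeast promoters, not measured quantities.
* **Sequencing.** Fragments sample truth dyads — uniformly for input,
  with weights `enrichment : background_rate` (defaults 20 : 0.05) for
  an IP — with truncated-normal lengths (mean 150, sd 10, bounds
  100–250 bp; per-strain mean shifts express MNase hypersensitivity).
  PCR duplication adds geometric extra copies. Reads are error-free by
  default (a substitution-rate option exists so mismatch-tolerant
  demultiplexing is testable) and sequence content beyond the barcode
  is random: no GC bias, no mappability structure, no real genome
  sequence.
* **5′-end tags.** Poisson tag counts per gene; tags at the TSS with
  10 bp jitter, except a baseline fraction (default 0.05) scattered
  uniformly in the gene body — pervasive low-level internal initiation,
  a parameter the source material does not constrain but without which
  "n-fold internal gain" is undefined — and, for cryptic genes, an
  additional fraction at the gene's internal initiation site (at least
  200 bp in). Cryptic status is assigned length-weighted by default,
  reproducing the observed long-gene bias of cryptic genes.

**Replicates.** A strain's truth table — its preferred dyad positions
and mark assignments — is a property of the strain: biological
replicates share it and differ by independent fragment sampling, PCR
duplication and depth. This matters for calibration. If each replicate
instead re-draws jittered dyads, per-base counts become single-gene
delta spikes that migrate between replicates (counts like 60/51/0
within one condition at one base), a variance structure no real strain
exhibits and one that no per-position dispersion estimate can rescue at
n = 3. Culture-to-culture biological variability is therefore *not*
emulated; a green null-calibration test establishes calibration under
sampling noise, not under biological replicate noise.

**What a green test does not establish.** The generator has no sequence
content, so alignment ambiguity, mappability and GC effects are outside
every test's reach; enrichment is a two-level weight rather than a
quantitative IP-efficiency model; and the NDR/array geometry is
identical across genes up to jitter, so heterogeneity of promoter
classes is not represented.

# Reproducibility and interfaces

Every stochastic operation takes an explicit seed and restores the
caller's RNG state (`withr::with_seed`); the pipeline expands one global
seed into per-stage seeds. Inter-stage interchange is headered TSV
(fragments and midpoints BED-like, 0-based half-open), occupancy tracks
export as bedGraph, and the pipeline writes a JSON manifest recording
the package version, the full config and every output file. Re-running
a config reproduces byte-identical TSVs. The run config is a single
JSON document with unknown keys rejected and thresholds validated
before any stage executes.

# Known limitations

* The Wald test is asymptotic; at very low counts (below a handful per
  condition) its p-values are approximate even when the dispersion is
  right. The local FDR stage inherits this.
* Dispersion shrinkage ("halfway to a robust trend") is deliberately
  simple; it is less efficient than Cox-Reid/empirical-Bayes machinery
  at small replicate numbers.
* `load_aligned_pairs()` derives reference widths from CIGAR M/D/N/=/X
  operations and assumes name-consistent primary mate pairs; exotic
  chimeric alignments are counted and skipped, not rescued.
* The CLI covers the pipeline and the main standalone stages; it is a
  convenience wrapper, not a workflow engine.
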