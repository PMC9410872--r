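---
title: "Methods: amplicon marker-panel design and F2 genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon marker-panel design and F2 genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconpanel)
```

## The problem this package addresses

Onion (*Allium cepa*) and crops like it combine a very large genome
(~16 Gb), obligate outcrossing and strong inbreeding depression. Parental
"lines" of a mapping cross are therefore not inbred: individuals of the
same line segregate at many loci, and any marker-design strategy that
assumes fixed parents will propose markers that fail downstream. At the
same time, array genotyping does not exist for the species and
single-marker assays (KASP, HRM) do not multiplex, so a few hundred
well-placed markers genotyped by multiplex amplicon sequencing are the
practical route to F2 linkage maps and marker-assisted selection.

`ampliconpanel` implements the complete desk side of that strategy:

1. **Polymorphism detection** from per-individual RNA-seq variant tables of
   the two parental lines, with within-line consensus rules that tolerate
   incomplete fixation.
2. **Liftover** of transcript (unigene) site positions onto genome
   scaffolds through best-hit alignments, so primers are designed on
   genomic sequence and never across splice sites.
3. **Primer-panel design**: repeat masking against a genome-wide k-mer
   blacklist, 120–160-bp amplicons over each site, specificity checks,
   common sequence tags, genome-covering panel selection and multiplex
   pooling.
4. **Amplicon genotyping**: genotype calls from per-sample allele depths at
   hotspot sites, parental consensus, five-class marker validation,
   A/H/B-coded F2 matrices and the missing/segregation-distortion filters.
5. **Two-point linkage QC**: EM recombination fractions, LOD grouping and
   Haldane distances.
6. A **simulator** that generates every input the pipeline consumes, with
   the statistical structure real data of this kind shows.

## Variant thresholds and the zygosity rule

An RNA-seq variant observation is kept when total depth ≥ 5 reads,
alternate count ≥ 2 reads and alternate frequency ≥ 20%. A kept call is
*homozygous* when the alternate frequency strictly exceeds 80% and
*heterozygous* otherwise. The cutoff itself (exactly 80%) is assigned to
the heterozygous side: the defining inequalities are strict on the
homozygous side, and an observation sitting exactly on the boundary is the
kind of evidence that should not assert fixation. All four thresholds are
fields of `pipeline_config()`.

A site is *fixed within a line* when at least *n − 1* of its *n* genotyped
individuals share the same homozygous call. The n − 1 default reproduces
the four-of-five and five-of-six consensus rules appropriate for small
per-line panels while tolerating one plant with residual heterozygosity or
poor coverage; it can be overridden with an absolute count or a fraction.
A site is an *inter-line polymorphism* when it is fixed in one line and no
individual of the other line has **any called variant** there. Raw reads
below the calling thresholds do not veto a site: detection is defined
entirely through the calling rules, so sub-threshold noise in the opposite
line (which is ubiquitous at 2–4% allele frequency) cannot silently remove
usable markers.

## Coordinate projection

Transcript-to-genome projection uses the best alignment per unigene
(highest bitscore; ties by identity, length, then subject id, with
equal-score multi-scaffold ties flagged `ambiguous-hit`). Projection
through a gapped alignment requires a per-base trace (`M`/`X` consume both
sequences, `I` a query base over a subject gap, `D` a subject base over a
query gap); gapped alignments without a trace are refused rather than
interpolated, because linear interpolation across an intron would place the
primer window on the wrong bases — exactly the failure the liftover exists
to avoid. Sites whose projection lands within one flank length (150 bp) of
either end of the aligned subject span are dropped as `near-junction`,
since a full design window there would cross into unaligned (likely
intronic or junction) sequence.

## Primer design parameters

The repeat blacklist collects canonical k-mers (k = 16) occurring more
than 10 times in the genome, both strands counted. Both parameters are
configurable; the defaults are chosen so that a planted repeat family of a
few dozen copies is caught while single-copy sequence stays clear.
Windows are 300 bp: 150 bp upstream, the site base, 149 bp downstream.
This honours the published total window length; whether the original
design used 150+1+149 or 150+1+150 is not stated, and one base at the far
window edge cannot change which primers are feasible.

Candidate primers are 18–25 nt with nearest-neighbour Tm in [57, 63] °C
(unified duplex parameters, 50 mM Na⁺, 500 nM primer), pair ΔTm ≤ 3 °C,
GC 30–70%, no homopolymer run of 5, and an unmasked 3′-terminal base.
Products must be 120–160 bp and contain the site strictly between the
primer intervals. Candidates are ranked by |Tm − 60| summed over the pair.
These thermodynamic constraints are standard panel-design practice rather
than published values, and every one of them is a `pipeline_config()`
field.

Specificity follows the published contract — count binding sites and
possible products — with a concrete rule: a binding site is an exact match
of a primer's 3′-terminal 15-mer on either strand, and a predicted product
is a facing pair of sites within 1 kb. Designs whose primers bind more
than once, or that predict more than one product, are rejected.

Panel selection divides each chromosome's anchored cM range into
equal-width bins (one per quota slot) and takes the candidate nearest each
bin centre; chromosome-only quotas are then filled preferring unseen
unigenes and scaffolds; no two panel members may lie within 1 kb on one
scaffold. The selection is deterministic after a (unigene, position)
pre-sort. This binning heuristic is this package's reconstruction: the
published goal is "markers covering the whole genome" with per-chromosome
counts reflecting candidate availability, not a stated allocation rule.
Pooling balances pool sizes to within one pair and greedily minimizes the
worst 3′-terminal-8-mer reverse-complement match against the pool.

## Genotyping and marker classes

Amplicon genotype calls reuse the RNA-seq thresholds (the production
caller's internals being unpublished): `no_call` below 5 reads, `alt_hom`
above 80% alternate frequency, `ref_hom` below 20%, `het` between provided
both alleles have ≥ 2 reads. Parental consensus across the three replicate
parent plants requires unanimity among non-missing calls; disagreement is
`unfixed`. The five marker classes follow the published footnotes: (1)
both parents fixed and different, (2) no variant, (3) neither parent
callable, (4) exactly one parent callable, (5) a parent unfixed. For
combinations the footnotes leave implicit (both parents fixed for the same
genotype while variants were seen elsewhere) the class-2 "no polymorphism
captured" reading applies. The A code is anchored to parent 1 — the study
never defines an orientation, so the package makes it explicit and
configurable by which line is supplied as parent 1.

F2 matrix filters are strict, as printed: a marker is removed when its
missing fraction exceeds 0.10, or when its (nA, nH, nB) counts reject
1:2:1 by chi-square (2 df) at p < 0.001. On 10,000 undistorted simulated
rows of 96 individuals the distortion filter removes about 0.1%,
consistent with its nominal level (the acceptance suite checks ≤ 0.3%).

## Two-point linkage

For each marker pair the recombination fraction is the maximum-likelihood
estimate under the codominant F2 model. The double-heterozygote cell mixes
the two phase classes (0 or 2 recombinant gametes); EM splits it at each
iteration by the current estimate, converging at |Δrf| < 1e−8 (≤ 200
iterations), clipped to [0, 0.5]. The estimate matches a 1e−4-step
grid-search of the likelihood to within 1e−3 on arbitrary tables (tested).
LOD is log10 L(rf) − log10 L(0.5). Grouping is single-linkage transitive
closure over edges with LOD above the threshold (default 4.0, the value
used for the first mapping population; 10.0 suits larger ones) **and**
rf < 0.45: the rf guard, not part of the published procedure, prevents
distorted marker pairs with high LOD at rf ≈ 0.5 from merging groups.
Distances use Haldane's function d = −50 ln(1 − 2rf), consistent with the
no-interference meiosis model. Marker ordering and multipoint mapping are
deliberately out of scope — those were done with dedicated mapping
software in the study this package emulates, and two-point grouping plus
pairwise distances are what the package's QC needs.

## What the simulator emulates — and what it does not

`sim_config()` defaults are the study conditions: two parental lines with
within-line fixation rate f = 0.8 (onion lines are far from inbred; at
this rate roughly a fifth to a third of true founder differences survive
the consensus and veto rules, matching the low recovery seen in real
transcriptome comparisons), 5 and 6 RNA-seq individuals per line, 3
replicate parent plants in the amplicon run, one F1, 63 F2 individuals,
eight 100-cM chromosomes, log-normal per-marker amplicon depths
(sdlog = 1, spanning more than tenfold between the 10th and 90th
percentile, as real per-marker read counts do), beta-binomial heterozygote
allele counts (ρ = 0.05) and a 4% per-marker-per-line chance of founder
allele dropout (producing the one-parent no-call class). Genes carry
introns, so unigene-to-genome projection must cross real gaps; repeat
families are planted at blacklist-triggering copy numbers; the anchor
table hides cM for a configurable share of unigenes.

Scale choices: simulated genomes are a few scaffolds of tens of kb with
~24–96 genes. These sizes exercise every code path (splicing, repeats,
masking, specificity, meiosis, depth heterogeneity) while keeping the full
suite fast; they are the package's chosen test sizes, not estimates of any
real genome.

The simulator does **not** model read-level errors, PCR chimeras,
barcode hopping, alignment artefacts, segregation distortion from
selection, or crossover interference (meioses are Poisson along the map —
the Haldane model, matching the mapping function used downstream). Passing
tests therefore demonstrate the correctness of the pipeline's logic and
statistics under the stated noise model, not robustness to every artefact
of a real sequencing run.

## Numerical choices and degenerate inputs

* Frequencies exactly at a strict boundary (80% zygosity, 10% missing,
  p = 0.001) go to the side the printed inequalities imply.
* `estimate_rf_em()` flags pairs with fewer than 10 informative
  individuals as `low_information` rather than refusing them.
* A diagonal pair table gives rf = 0 exactly; an empty table gives `NA`.
* `haldane_cm(0.5)` is an error (infinite distance), not `Inf`, so a bad
  rf cannot silently poison downstream sums.
* Zero-depth sites are `no_call`; depth arithmetic never divides by zero.
* Fully masked windows, sites near scaffold ends, unprojectable sites and
  non-specific designs are all dropped with machine-readable reasons, and
  the stage runners write those reasons into the run manifest.

## Reproducibility

Every generator takes an explicit seed and is byte-deterministic given it.
The file-based stage runners (`run_simulate()` … `run_linkage_qc()`,
`run_all()`) write a JSONL manifest entry per stage with input/output
paths, a configuration hash and the seed, so any output file is traceable
to the exact configuration that produced it.
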