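# ampliconpanel

Genome-wide marker design and target-amplicon-sequencing genotyping for
highly heterozygous, large-genome outcrossing crops — onion being the
archetype.

## Who this is for, and what it does

Breeders and mapping-population geneticists working in species where (i)
the genome is too large and fragmented for routine whole-genome
genotyping, (ii) no SNP array exists, and (iii) "parental lines" are not
inbred, so naive marker design against a single parental genotype fails.
The package covers the whole desk workflow around a multiplex amplicon
sequencing platform:

1. **Detect inter-line polymorphisms** from per-individual transcriptome
   variant tables of the two parents. A call is kept at depth ≥ 5 reads,
   alt count ≥ 2 and alt frequency ≥ 20%; a kept call is homozygous when
   the alt frequency exceeds 80%. A site is *fixed within a line* when at
   least n − 1 of its n individuals share the same homozygous call, and a
   *polymorphic site* when it is fixed in one line and no individual of
   the other line has any called variant there.
2. **Lift** unigene site positions onto genome scaffolds through best-hit
   alignments (per-base trace walking across intron gaps; no silent
   interpolation), so primers never straddle splice junctions.
3. **Design the panel**: repeat masking against a canonical k-mer
   blacklist (k = 16, count > 10 genome-wide on both strands), 300-bp
   windows, 18–25-nt primers (nearest-neighbour Tm 57–63 °C, pair
   ΔTm ≤ 3 °C, GC 30–70%), 120–160-bp amplicons containing the site,
   exact 3′-15-mer specificity checks, CS1/CS2 common tags, genome-covering
   selection by cM binning, and multiplex pools of 48 pairs.
4. **Genotype F2 populations** from per-sample allele depths at hotspot
   sites; determine parental consensus over replicate plants; classify
   markers into the five validation classes; convert F2 calls to A/H/B;
   filter markers with > 10% missing data or 1:2:1 segregation distortion
   at p < 0.001 (chi-square, 2 df).
5. **Two-point linkage QC**: per-pair recombination fraction by EM under
   the codominant F2 model (double-heterozygote phase resolved
   iteratively), LOD = log₁₀ L(r̂) − log₁₀ L(0.5), single-linkage grouping
   at a LOD threshold (default > 4.0), and Haldane distances
   d = −50 ln(1 − 2r̂) cM.
6. **Simulate** everything end to end — reference genome + spliced
   unigenes, incompletely fixed parental lines (fixation rate f), F1 and
   Poisson-crossover F2 meioses, and amplicon depths with log-normal
   per-marker means, beta-binomial heterozygote counts and one-parent
   dropout — so the pipeline is testable with no external data.

Everything is a tibble in, a tibble out; results chain with the pipe and
come with `tidy()`/`glance()`/`autoplot()` methods where that helps.

## A worked example

A complete run on a simulated study (two parental lines at within-line
fixation rate 0.9, 96 transcript loci on 8 chromosomes, 63 F2
individuals):

```r
library(ampliconpanel)
library(dplyr)

cfg <- pipeline_config()
sc  <- sim_config(n_genes = 96, fixation_rate = 0.9)

ref   <- simulate_reference(sc, seed = 20)
cross <- simulate_lines_and_cross(ref, sc, seed = 20)

sites <- detect_polymorphic_sites(cross$variants, cfg) |>
  categorize_sites(ref$anchors)
count(sites, category)
#>   category            n
#> 1 anchored           32
#> 2 chromosome_only     9
#> 3 no_information      4
```

Of the 96 true founder differences, 45 survive the consensus and veto
rules — within-line heterozygosity (f = 0.9 here, lower in real onion
lines) hides the rest. Liftover, masking and primer design:

```r
lifted <- lift_sites(sites, ref$alignments, flank = cfg$flank)
bl     <- build_kmer_blacklist(ref$genome, cfg$kmer_k, cfg$blacklist_cutoff)
bl
#> <kmer_blacklist> k = 16 , cutoff = 10 , 372 blacklisted k-mers

panel <- design_markers(lifted, ref$genome, bl, cfg) |>
  filter(design_status == "ok") |>
  append_common_tags() |>
  pool_primers(pool_size = cfg$pool_size)
select(panel, marker_id, scaffold, genome_position, product_size, pool)
#>   marker_id scaffold genome_position product_size  pool
#> 1 u001_270  scaf01               790          146     1
#> 2 u007_201  scaf01              9215          122     1
#> 3 u010_216  scaf01             13780          121     1
#> 4 u014_212  scaf01             20209          142     1
#> # ... 44 markers in total
```

Every designed primer pair has a unique binding site, an amplicon of
120–160 bp containing its polymorphic site, and a repeat-free 3′ end.
Genotyping the simulated amplicon run:

```r
amp   <- simulate_amplicon_depths(panel, cross, ref, sc, seed = 20)
calls <- call_genotypes(amp$depths, cfg)
pcal  <- calls |>
  filter(grepl("^P[12]_amp", sample_id)) |>
  mutate(line_id = sub("_amp.*$", "", sample_id))
cls <- classify_markers(parental_consensus(pcal))
summarize_marker_classes(cls)
#>   class     n   pct
#> 1     1    26  59.1     # parents fixed and different: usable markers
#> 2     4     1   2.3     # one parent failed to amplify (allele dropout)
#> 3     5    17  38.6     # parents not fixed among replicate plants
```

Class 1 markers are converted to an A/H/B matrix, filtered, and checked
by two-point linkage:

```r
mat  <- build_genotype_matrix(filter(calls, sample_id %in% cross$sample_ids$f2), cls)
filt <- filter_matrix(mat, cfg)      # 24 of 26 markers kept
scan <- pairwise_linkage(filt$matrix)
glance(scan)
#>   n_markers n_pairs mean_rf max_lod n_low_information
#> 1        24     276   0.443    16.9                 0
group_markers(scan, lod_threshold = 4)
```

With only ~3 markers per 100-cM chromosome and 63 individuals, adjacent
markers ~50 cM apart often fall below LOD 4, so the 24 markers split into
11 groups — the same sparse-coverage behaviour that motivates refining a
first-pass panel (`refine_marker_set()`) before genotyping further
populations.

The bundled study bookkeeping tables give the summary functions something
real to chew on:

```r
classification_totals(onion_study_counts("site_classification"))
#>   anchored_polymorphisms anchored_unigenes anchored_markers ...
#> 1                   1311               237              209
```

A command-line front end over the same stage functions is installed at
`inst/cli/ampliconpanel.R`
(`Rscript inst/cli/ampliconpanel.R all --out run1 --seed 7`).

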