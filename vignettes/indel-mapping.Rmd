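---
title: "Mapping worm mutations with large indel markers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping worm mutations with large indel markers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelmapr)
library(dplyr)
```

## The problem

Forward genetics in *Caenorhabditis elegans* starts from a mutant phenotype
and works back to the causal mutation. Whole-genome sequencing shortens the
candidate list, but a mutagenised strain carries hundreds of mutations, so a
genomic interval from genetic mapping is still what turns that list into a
handful of candidates. The classic mapping partner is the Hawaiian wild
isolate CB4856, which differs from the N2 laboratory strain at many loci.

`indelmapr` models a mapping strategy built on a particular marker class:
insertion-deletion polymorphisms whose two alleles differ by 40 to 699 bp.
A single PCR across such an indel yields products whose sizes differ enough
to separate on a plain agarose gel, with no restriction digest, no
sequencing, and so little template that a fraction of a single worm lysate
suffices. Markers are designed so the N2 product is always the larger band;
in a pool of phenotype-selected mutant F2 animals, markers linked to the
mutation lose the smaller CB4856 band, and a consecutive block of such
markers localises the mutation.

The package implements the full desk side of this workflow: catalog
construction and filtering, wild-isolate coverage scoring, marker panel
validation and selection, simulation of the mapping cross and of PCR band
detection, interval calling and refinement, and candidate-burden
estimation. Everything operates on tibbles and composes with the pipe.

## Coordinates, catalog and coverage

Physical coordinates are 1-based; interval arithmetic is half-open
internally and rendered 1-based inclusive in reports, which makes the
per-Mb binning unambiguous: position $p$ falls in bin
$\lfloor (p-1)/10^6 \rfloor$ and a terminal partial window counts as a full
interval. Genetic positions are signed centimorgans with the chromosome
center near 0 and the left arm negative, the standard worm convention.

The size filter retains exactly the closed range $[40, 699]$ bp. The lower
bound is the smallest length difference reliably resolved beside a
400-1500 bp product on a 2% gel; above ~700 bp the two products stop
co-amplifying uniformly. Nearest-gene annotation minimises the physical
distance on the same chromosome; equidistant ties resolve to the lower
coordinate (a fixed, documented convention - the data source is silent on
ties).

An isolate is useful for whole-genome mapping only if every 1 Mb window
holds at least one marker-quality indel. `score_isolates()` therefore ranks
isolates by their number of empty windows; the pass threshold is an explicit
argument, never a baked-in constant, because "too many gaps" is a judgment
that depends on how much of the genome one needs to cover.
`sharing_matrix()` (pairwise Jaccard similarity of indel sets) plus
`isolate_clusters()` surface groups of closely related isolates - such
groups likely share phenotypes, so one representative per cluster is enough.

## The synthetic study conditions

The real catalog and marker tables derive from curated database exports that
the package does not ship. Three seeded generators reproduce their
*documented study conditions* so that every computation in the package can
run self-contained:

- `synthetic_natural_variants()`: 11,556 indels of 40-699 bp across 40
  isolates; CB4856 carries 1,664 of them with at least one per 1 Mb window;
  two further well-covered isolates and a closely related trio sharing a
  large common core; 34 sparse isolates with strongly arm-biased indels and
  many empty windows. Autosome arms (outer thirds) are enriched over
  centers, the well-known pattern for natural variation in this species.
- `synthetic_marker_table()`: 102 marker loci at roughly one per Mb; N2
  products within 500-1500 bp, CB4856 products within 400-1300 bp, N2
  always larger by the indel size; 95 of 102 primer pairs above 90% success
  with full (0.1 adult) template, 82 at or above 75% CB4856-band success
  with 1:9 CB4856:N2 template, about half of those at 100%; 96 loci fill a
  plate row-major in genome order, the rest are marked `NU`.
- `synthetic_mutagenesis_table()`: 656 strains at 50 mM EMS
  (376 +/- 100 total, 86 +/- 24 predicted-effect mutations per strain) and
  943 strains at EMS+ENU (545 +/- 149, 123 +/- 34).

These headline numbers are generator *conditions*, fixed once; positions,
carrier sets, primer sequences and per-strain counts are random under the
seed. What the generators do **not** emulate: linkage disequilibrium between
nearby indels, sequence context (primer sequences are random 20-mers
accepted near the 60 degC target), plate-position effects on PCR, and any
relationship between an isolate's phylogeny and which indels it shares.
Tests that pass on these fixtures therefore validate the *algorithms*, not
the biology of any particular isolate.

## Primer melting temperature

`estimate_tm()` implements the unified nearest-neighbor thermodynamic
parameter set: duplex $\Delta H$ and $\Delta S$ summed over dinucleotide
steps with terminal A·T / G·C initiation terms, an entropy salt correction
$\Delta S' = \Delta S + 0.368\,(N-1)\ln[\mathrm{mono}]$, and
$T_m = \Delta H / (\Delta S' + R \ln C_T/4) - 273.15$ with defaults of
50 mM monovalent cation and 0.25 uM primer. The panel's target is 60 degC
with a +/- 2 degC tolerance so that one annealing temperature serves the
whole plate. The implementation is duplex-symmetric (a primer and its
reverse complement score identically) and was checked against an
independent hand evaluation of the published parameter table.

## The cross and detection models

Meiosis in the F1 CB4856/N2 heterozygote uses the Haldane model: per
chromosome the crossover count is Poisson with mean equal to the map length
in Morgans, positions are uniform on the cM scale and mapped to bp by
inverse interpolation, and there is no interference and no obligate
crossover. This is the simplest model consistent with working in map
units; real worm meiosis shows strong interference, which makes real
crossovers *more* regular than simulated ones - simulated intervals are,
if anything, slightly conservative.

No genetic map ships with the variant data, so `ce_genetic_map()` supplies
a default: four anchors per chromosome spanning about 50 cM (~300 cM
genome-wide, the right scale for this species) with the outer thirds at
roughly twice the central recombination rate, reflecting the worm's
high-recombination arms. Interpolation beyond the terminal anchors clamps
to the anchor value - a stated convention, since extrapolating genetic
distance past the last anchored marker has no support in the data.

F2 individuals are two independent gametes (hermaphrodite selfing);
phenotype selection keeps individuals homozygous N2 at the mutation locus,
each with probability `penetrance` (default 1; the phenotypes this workflow
targets are fully scorable). Among selected animals, a marker $d$ cM away
carries the CB4856 allele per haplotype with the Haldane recombination
fraction $r(d) = (1 - e^{-2d/100})/2$, which the simulator reproduces and
the test suite checks at $d \in \{0, 5, 10, 20, 50\}$ cM.

Band detection uses the two measured anchor conditions per marker: success
$p_\mathrm{full}$ at allele fraction 0.5 and $p_\mathrm{dilute}$ at 0.1.
Between the anchors the curve is log-linear in the fraction; above 0.5 it
is constant; below 0.1 it decays as $p_\mathrm{dilute}^{0.1/f}$. The
sub-anchor branch is a deliberate modeling choice: success scales
geometrically with template copy number, vanishes as $f \to 0$ for any
imperfect marker, and degenerates to a step for a perfect marker
($p_\mathrm{dilute} = 1$), so the perfect-detection limit is exactly
"band present iff allele present". A linear decay to zero would instead
make perfect markers stochastically miss rare alleles, which contradicts
the perfect-detection limit the rest of the toolkit reasons with. The model
requires $p_\mathrm{full} \ge p_\mathrm{dilute}$ (more template never
hurts), which also guarantees monotonicity. Spurious bands are off by
default (`fp_rate = 0`); marker failures are independent across markers
and samples - no plate or row effects.

## Interval calling

`call_pooled()` scores a marker as *negative* when its N2 band is present
and its CB4856 band absent; requiring the N2 band mirrors the side-by-side
N2 control lane - absence of both bands is a failed reaction, which is
non-informative and does not break a run (per-marker PCR success is below
100% and a single dropout should not split an interval). The winning run of
consecutive negatives is the longest by marker count, ties broken by larger
physical span, then genome order; the interval extends to the nearest
CB4856-positive markers (or chromosome ends). A two-marker run is required
for a `linked` call; a single negative marker yields a `hint` result that
still reports its bracketing interval, because a lone marker localises
weakly but is the natural seed for follow-up, while `no_linkage` is
reserved for band patterns with no negative marker at all.

Refinement with individual worm genotypes excludes every marker at which
any phenotype-selected worm shows a CB4856 allele, brackets the best
all-NN stretch by the innermost excluded markers, and intersects with the
pooled interval so refinement can only narrow. If no marker inside the
pooled interval is all-NN, the genotypes contradict the pooled call and the
result is returned unchanged but flagged `inconsistent` rather than
silently re-localised.

The caller is verified against an exhaustive oracle - every contiguous run
enumerated by brute force with the same tie-breaks - across all 4,096
CB-presence patterns on 12 markers.

## Candidate burden

Laboratory-induced mutations land close to uniformly along the genome, so
the number of predicted-effect mutations inside a mapped interval is
Poisson with $\lambda = \bar{m}_\mathrm{effect} \cdot w / G$ for interval
width $w$ and genome size $G$ (default 100.3 Mb). With ~86 effect mutations
per EMS strain, $\lambda$ is below one per Mb: a 6-8 Mb mapped interval
leaves only a handful of candidates to triage, which is the whole point of
mapping before (or instead of re-) sequencing. The $\pm$ s.d. summaries use
the sample (n-1) standard deviation.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script use: $10^4$ F2 individuals for
segregation checks (multinomial goodness-of-fit at $\alpha = 0.001$); 4,100
F2 to yield $\ge$ 1,000 selected mutants for the closed-form recombination
check (3 standard errors); all $2^{12}$ band patterns for the caller
oracle; and 200 replicate simulated experiments (10-worm pools, the
96-marker plate, perfect detection) for end-to-end interval recovery.
These sizes were chosen so each check has conventional statistical power
while a full run stays in the minutes range on one core.

Under those end-to-end conditions the called or hinted interval contains
the true mutation locus in roughly 90% of replicates. The shortfall from
certainty is structural, not a bug: with 20 selected haplotypes the all-N2
region around the locus spans about 10 cM (each side is the minimum of 20
exponential crossover distances, mean 5 cM), and at ~3 cM marker spacing
that region occasionally covers zero markers, leaving nothing to call.
Imperfect detection - the realistic case - *raises* the call rate by
hiding single recombinant haplotypes, at the price of wider intervals;
perfect detection is the stricter regime and is what the recovery figure
above reports.

## Limitations

- No crossover interference and no obligate crossover; per-chromosome
  crossover counts are honestly Poisson.
- Hermaphrodite selfing only: males, X hemizygosity and complementation
  crosses are out of scope.
- The detection model has two anchors; behaviour at extreme dilution
  (0.001 adult templates) is extrapolated, not measured, and off-target
  amplification is only a flat optional false-positive rate.
- No statistical confidence interval on breakpoints: the interval is the
  observed bracketing, as in the bench protocol it models.
- Primer *design* (choosing sequences against a genome) is out of scope;
  the panel module validates and selects among supplied candidates.

## A worked pass through the workflow

```{r workflow, eval = FALSE}
catalog <- synthetic_natural_variants(seed = 1) |> filter_i40_699()
score_isolates(catalog, max_empty_bins = 10) |> head()

markers <- synthetic_marker_table(seed = 1)
plate <- markers |> filter(well != "NU")

ex <- simulate_mapping_experiment("II", 7.5e6, plate, n_pool = 10, seed = 1)
ex$result
glance(ex$result)
map_report(ex$result, catalog) |> head()

mu <- synthetic_mutagenesis_table(seed = 1) |> filter(method == "50 mM EMS")
s <- summarize_counts(mu$n_total, mu$n_effect, method = "50 mM EMS")
expected_candidates(glance(ex$result)$width_mb, s$mean_effect)
```
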