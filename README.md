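# indelmapr

Fast genetic mapping in *Caenorhabditis elegans* with large
insertion-deletion markers.

Forward genetic screens in the worm end with a mutant phenotype and a
strain carrying hundreds of mutagen-induced changes; genetic mapping is
what narrows those to a testable handful. `indelmapr` is a toolkit for a
PCR-only mapping strategy built on indel polymorphisms whose two alleles
differ by **40–699 bp** between the N2 laboratory strain and a wild isolate
(typically Hawaiian CB4856). One PCR per marker gives two products that
separate on a plain agarose gel — the N2 product designed to be the larger
band — so genotype is read directly from band sizes, from a fraction of a
single worm lysate, with no DNA purification, restriction digest or
sequencing.

The mapping logic: cross CB4856 males to the mutant, self the F1, select
homozygous mutant F2 by phenotype, and pool ~10 of them. At markers linked
to the (N2-background) mutation the pool is almost pure N2, so the smaller
CB4856 band disappears; a consecutive block of markers missing the CB4856
band localises the mutation. Among selected animals a marker *d* cM from
the locus carries the CB4856 allele per haplotype with the Haldane
recombination fraction

&nbsp;&nbsp;&nbsp;&nbsp;*r(d) = (1 − e^(−2d/100)) / 2*,

and the expected candidate-mutation count inside a mapped interval of
width *w* Mb is Poisson with *λ = m̄ · w / G* for *m̄* predicted-effect
mutations per strain and genome size *G* ≈ 100 Mb.

The package covers the full desk side of the workflow, tidyverse-style
(tibbles in, tibbles out, `tidy()`/`glance()` on results, `autoplot()`
figures):

- **catalog** — read/filter/annotate indel variant tables (TSV dialect or
  minimal VCF), per-isolate presence summaries, seeded synthetic catalogs;
- **coverage** — 1-Mb binning, empty-window gap finding, wild-isolate
  ranking, Jaccard sharing and clustering;
- **panel** — marker validation against product-size windows (N2 500–1500,
  CB4856 400–1300 bp), nearest-neighbor primer Tm, greedy genome-covering
  96-marker selection, plate-well layout;
- **crosssim** — Haldane (Poisson, no-interference) meiosis, F2
  populations, phenotype selection, pooled allele fractions;
- **detect** — two-anchor PCR band-detection model (success rates measured
  at equal-mix and 1:9 template), band simulation, genotype calls;
- **mapcall** — pooled interval calling from band runs, refinement with
  individual worm genotypes, gene reports;
- **burden** — mutagenesis count summaries and Poisson candidate burden.

## Worked example

```r
library(indelmapr)
library(dplyr)

# catalog at the study conditions: 11,556 indels across 40 wild isolates
catalog <- synthetic_natural_variants(seed = 1) |> filter_i40_699()
score_isolates(catalog, max_empty_bins = 10) |> head(4)
#>   isolate n_indels n_empty_bins passes
#> 1 CB4856      1664            0 TRUE
#> 2 JU1171      1186            0 TRUE
#> 3 MY14        1194            1 TRUE
#> 4 MY2         1193            1 TRUE
```

CB4856 leaves no 1-Mb window uncovered, which is why it is the default
mapping partner. Now simulate mapping a recessive mutation at II:7.5 Mb
with the 96-marker plate:

```r
plate <- synthetic_marker_table(seed = 1) |> filter(well != "NU")
ex <- simulate_mapping_experiment("II", 7.5e6, plate, n_pool = 10, seed = 1)
ex$result
#> <mapping_result>
#>   status: linked
#>   interval: II:4,743,565-9,937,182 (5.19 Mb)
#>   supporting markers (4): im022, im023, im024, im025
#>   flanking markers: im021, im026
```

Four consecutive markers lost their CB4856 band, bracketing a 5.19 Mb
interval that indeed contains the true locus. How many candidate mutations
should an EMS strain carry in such an interval?

```r
mu <- synthetic_mutagenesis_table(seed = 1) |> filter(method == "50 mM EMS")
s  <- summarize_counts(mu$n_total, mu$n_effect, method = "50 mM EMS")
s
#>   method    n_strains mean_total sd_total mean_effect sd_effect
#> 1 50 mM EMS       656       377.     104.        87.9      23.5

expected_candidates(glance(ex$result)$width_mb, s$mean_effect)
#>   lambda     p0     p1 p_le_1
#> 1   4.55 0.0106 0.0481 0.0586
```

About 88 predicted-effect mutations per strain — under one per Mb — leave
λ ≈ 4.5 candidates in the mapped interval, a list short enough to triage
with existing sequence data. `plot_indel_distribution()` and
`autoplot(ex$result, ex$observations)` draw the per-Mb marker coverage and
the band pattern around the called interval.

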