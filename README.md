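# aarscan

Comparative analysis of **tandem amino acid repeats** (AARs, homopeptides)
in protein-coding genes, for researchers studying low-complexity sequence
evolution in plants and other eukaryotes.

An AAR is an uninterrupted run of four or more identical amino acids.
Repeat content is measured as **RRPK** — repeated residues per kilo amino
acids:

```
RRPK = 1000 × (Σ repeat lengths) / (protein length)
```

so the 15-residue peptide `QQQQQSTWQQQQAAE`, with runs `QQQQQ` and `QQQQ`
totalling 9 repeated residues, has RRPK = 9/15 × 1000 = 600. A protein
with at least one AAR is a repeat-containing protein (RCP).

Around this statistic the package implements:

* **Repeat scanning** — per-protein and per-species RRPK, coding-sequence
  GC content and their Pearson correlation, protein-thirds positional
  profiles, repeat-vs-background residue composition, the GC-rich repeat
  class (Ala/Gly/Pro), and a Grubbs outlier test on species means.
* **Ortholog evolution** — mapping repeats into multiple-alignment
  columns, fails-to-align classification, conserved long repeats (length
  ≥ 8 with ≥ 8 supporting orthologs at ≥ 50% span identity), 33-residue
  flanking regions, and a self-contained Nei–Gojobori (1986) dN/dS
  estimator with Jukes–Cantor correction for flank-versus-whole-protein
  rate comparisons (Mann–Whitney U).
* **Structural disorder** — fully-disordered repeat fractions from
  per-residue binary annotations and a seeded random-segment permutation
  test with add-one empirical p-values (no exceedance in 1000 trials →
  p = 1/1001 < 0.001).
* **Transcript-level regulation** — expression normalisation and the
  tissue specificity index Σ(1 − x_i/x_max)/(N − 1), mRNA half-life
  comparisons (Welch), alternative/constitutive exon repeat content, and
  recombination-hotspot neighbourhood enrichment (Fisher's exact test).
* **A synthetic-data generator** — seeded, ground-truth-carrying bundles
  of orthologous proteomes whose repeat density is coupled to GC content,
  with conserved and lineage-specific repeats, disorder annotations,
  expression, half-lives, gene models and hotspot intervals, so the whole
  pipeline is testable offline.

See `vignettes/aarscan-methods.Rmd` for the models, parameter meanings and
numerical choices.

## Worked example

```r
library(aarscan)

aars <- detect_aars("QQQQQSTWQQQQAAE")
aars
#>   protein_id residue start end length
#> 1       <NA>       Q     0   5      5
#> 2       <NA>       Q     8  12      4
compute_rrpk(15, aars)
#> [1] 600
```

The two maximal glutamine runs cover 9 of 15 residues; start/end are
0-based half-open (written reports add 1-based columns).

A full synthetic study, end to end:

```r
b   <- generate_bundle(generator_config(seed = 1))   # 10 species x 80 ortholog groups
rep <- run_analysis(b, n_trials = 200)
rep
#> Repeat analysis report
#>   proteins: 800  repeats: 666
#>   species RRPK~GC: r = 0.9405483 , p = 5.0852e-05
#>   disorder (vsl2b_like): observed 0.3288288, p 0.004975124
#>   disorder (iupred_like): observed 0.01201201, p 0.01492537

head(rep$species_summary, 4)
#>   species n_proteins mean_rrpk   mean_gc aars_per_protein rcp_fraction
#> 1    sp01         80  82.50468 0.4860268           0.8500       0.6375
#> 2    sp02         80  93.13181 0.4932748           0.9500       0.6750
#> 3    sp03         80  87.85526 0.4931001           0.8125       0.6500
#> 4    sp04         80  95.64232 0.4964760           0.8375       0.6250
```

The generator seeded repeats whose expected length rises with each
species' GC target, and the scan recovers that coupling across the ten
species (r = 0.94, p = 5 × 10⁻⁵). The disorder permutation test reports,
per annotation track, the observed fully-disordered repeat fraction and
its empirical p against equal-length random segments. `rep$flank_whole`
holds the flank-versus-whole dN/dS comparison per species,
`rep$conserved_long` the conserved long repeats, and `rep$regulation` the
tissue-specificity, half-life, splice-class and hotspot reports.
`run_analysis(b, out = "reports/")` writes everything as headered TSV;
`write_bundle(b, "bundle/")` emits the bundle as FASTA/TSV/BED files.

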