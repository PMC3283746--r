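---
title: "Methods: tandem amino acid repeat analysis with aarscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tandem amino acid repeat analysis with aarscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aarscan)
```

## The problem

Tandem amino acid repeats (AARs, homopeptides) — uninterrupted runs of
four or more identical residues — are a conspicuous feature of eukaryotic
proteomes, particularly in plants. Their abundance varies severalfold
between species, they evolve rapidly, they sit preferentially in
intrinsically disordered regions, and the proteins carrying them
(repeat-containing proteins, RCPs) appear to be under distinctive
transcript-level regulation. `aarscan` implements the quantitative
machinery needed to study these phenomena on protein/CDS sequence sets,
ortholog alignments, disorder annotations, and expression data — together
with a seeded synthetic-data generator so that every stage can be
validated against known ground truth without any external genome download.

## Repeat detection and the RRPK statistic

An AAR is a *maximal* run of `min_len` (default 4) identical standard
amino acids. `'X'` and any other non-standard letter break runs and never
seed one: an ambiguous residue cannot be asserted identical to its
neighbours. Stop characters are stripped at load time; internal stops
invalidate a record.

Repeat content is summarised as **RRPK** (repeated residues per kilo amino
acids):

$$\mathrm{RRPK} = 1000 \cdot \frac{\sum_i \ell_i}{L},$$

where $\ell_i$ are the lengths of the detected repeats and $L$ the protein
length. Using total repeat residues rather than repeat counts makes the
statistic robust to the interruption of one long repeat into several short
ones:

```{r}
aars <- detect_aars("QQQQQSTWQQQQAAE")
aars
compute_rrpk(15, aars)
```

Coordinates are 0-based and half-open internally; written reports add
1-based inclusive columns, and every output header says so.

For positional analyses a protein is split into three near-equal parts.
For $L = 3q + r$ the remainder is assigned N-terminus first (sizes $q+1$
for the first $r$ segments) — the convention must be fixed because
N-terminal repeat accumulation is one of the quantities of interest. A
repeat spanning a boundary contributes its residues to each side, which
keeps the identity (segment length × segment RRPK summed over segments =
total repeat residues) exact.

GC content of a coding sequence is the fraction of unambiguous A/C/G/T
bases that are G or C; IUPAC ambiguity codes are excluded from numerator
and denominator. Alanine, glycine and proline — the amino acids with
GC-rich codons — define the GC-rich repeat class.

## Conservation within ortholog alignments

Given a protein multiple sequence alignment per 1-to-1 ortholog group (and
the member CDS for back-translation into a codon alignment), each repeat
is mapped to its minimal alignment-column span. A repeat **fails to
align** when every other member is mostly gaps over that span; "mostly" is
a configurable gap fraction strictly greater than 0.5 by default — the
natural reading of "filled with gaps" that still tolerates stray residues.

A **conserved long repeat** must (1) be at least 8 residues long (i.e.
longer than seven) and (2) find at least 8 other members whose span
identity — the fraction of span columns carrying the repeat's amino acid,
gaps counting as mismatches — is at least 50%. This is the simplest
operationalisation of "alignment identity" for a homopolymer block; we do
not additionally require the supporting members to span particular clades.

## Flanking regions and dN/dS

A flanking region extends up to 33 residues on each side of a repeat,
truncated at the protein ends and at adjacent repeats; the stretch between
two repeats closer than 66 residues is shared by both and deduplicated
before aggregation so no codon is counted twice.

Divergence is estimated with the Nei–Gojobori (1986) counting method on
pairwise codon alignments: fractional synonymous/nonsynonymous site counts
per codon (averaged over the two sequences), pathway-averaged difference
counts for codons differing at more than one position (orderings through
stop codons discarded), and the Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$ applied to both proportions.
Mutations to stop codons are excluded from the site space with per-position
renormalisation, so every codon contributes exactly 3 sites and
$N + S = 3 \times$ (codons compared) holds to machine precision. Codon
pairs containing a gap, an ambiguity code or a stop are excluded listwise
per pair. The estimator is deliberately a counting method rather than a
maximum-likelihood one: it is self-contained, exhaustively verifiable at
the single-codon scale, and adequate for the rank-order questions asked of
it (is the flank rate higher than the whole-protein rate; is the neutral
limit ≈ 1). Absolute values are not comparable to likelihood estimators
with transition/transversion and codon-frequency corrections, and the test
suite treats them accordingly.

Two numerical choices in the flank-versus-whole comparison deserve
explanation:

* **Counts are pooled before the ratio.** Per protein, synonymous and
  nonsynonymous differences and sites are summed over all ortholog pairs
  involving that protein (and over its flank regions) and a single
  corrected ratio is formed. Averaging many short-region ratios instead
  would inflate the expectation of the noisier flank estimates (a ratio of
  noisy estimates is upward-biased), producing spurious flank-vs-whole
  differences even under homogeneous constraint.
* **The focal repeat tracts are excluded from the whole-protein
  estimate.** A homopolymer tract cannot accumulate nonsynonymous
  differences while it remains a repeat, so its codons depress the
  whole-protein rate for purely definitional reasons. With tracts
  included, the comparison rejects a true null in the large majority of
  simulated data sets; with tracts excluded it holds its nominal level.
  The comparison therefore asks the scientifically meaningful question —
  do flanks evolve faster than the protein's non-repeat remainder plus
  flanks — rather than re-detecting the repeat definition itself.

The per-species comparison uses a Mann–Whitney U test on the per-protein
flank and whole values, and also reports the fraction of flank regions
with dN/dS > 1 (positive-selection candidates).

## Structural disorder and the permutation null

Per-residue binary disorder calls are consumed as input (two tracks may be
supplied, mirroring the common practice of running two predictors with
different sensitivity/specificity trade-offs; the package does not
reconcile them). A repeat is **fully disordered** iff every one of its
residues is called disordered.

Enrichment is tested with a random-segment permutation null: in each of
`n_trials` (default 1000) trials, each observed repeat is matched by one
equal-length segment drawn uniformly from the repeat-containing proteins
(protein uniform among those long enough, start uniform among valid
positions; a same-protein sampling mode is available), and the trial
statistic is the fraction of drawn segments that are fully disordered. The
empirical p-value uses the add-one estimator $p = (b+1)/(n+1)$, where $b$
counts trials whose fraction reaches or exceeds the observed one, so $p$
is never exactly 0 and no exceedance in 1000 trials gives
$p = 1/1001 < 0.001$. Drawn segments may overlap repeats; the null is
"segments of the same lengths placed anywhere in RCPs", not "segments
avoiding repeats". With a fixed seed the entire null distribution is
bit-reproducible.

## Transcript-level regulation

* **Expression normalisation**: present (above-background) values are
  log2-transformed, each tissue's mean is subtracted, and the grand mean
  over all present values is added back; column means then agree exactly.
  Base 2 is the microarray convention; no result depends on the base.
* **Tissue specificity index**:
  $\mathrm{TSI} = \sum_i (1 - x_i/x_{\max})/(N-1)$ over the $N$ usable
  tissues — 0 for uniform expression, 1 for single-tissue expression.
  Normalised log values can dip below zero, so values are floored at 0
  first and the gene is flagged; genes with fewer than 2 usable tissues or
  $x_{\max} \le 0$ are undefined. Multi-probe loci take the unweighted
  probe mean, for TSI and for mRNA half-lives alike.
* **Half-life comparison**: Welch's t-test between RCP and non-RCP loci.
* **Splice classes**: an exon (by exact genomic interval) is constitutive
  iff it appears in every model of its gene; a gene is alternatively
  spliced iff it has ≥ 2 models. Each residue is assigned to the exon
  containing the first base of its codon (junction codons go to the
  upstream exon — deterministic and consistent with first-base conventions
  in annotation tooling). Per-segment RRPK values are compared between
  classes with Welch's t-test, segments pooled across genes.
* **Recombination hotspots**: a gene is hotspot-neighbouring iff its
  interval overlaps a hotspot interval by ≥ 1 bp (both BED-style 0-based
  half-open); the RCP × neighbouring 2×2 table is tested with Fisher's
  exact test. Hotspot inference itself is out of scope; intervals are an
  input.

## Statistical core

Pearson correlation (t-based p), Welch's t and Fisher's exact 2×2 test are
thin wrappers with a uniform report type; the Mann–Whitney U test uses
midranks, tie-corrected variance and a continuity correction, switching to
exhaustive enumeration of rank assignments when both samples have at most
8 observations — the normal approximation is off by as much as 0.3 at
n = 2–4, so the small-sample switch is not optional. Grubbs's one-outlier
test converts $G = \max_i |x_i - \bar x|/s$ through the classical
t-distribution relation. All tests are two-sided by default; every
resampling procedure requires an explicit seed.

## The synthetic-data generator

`generate_bundle()` emulates the statistical structure the analysis
assumes, not any particular genome:

* a star phylogeny of `n_species` species over `n_groups` 1-to-1 ortholog
  groups (the analyses are pairwise or column-wise, and a star keeps the
  alignment exact by construction);
* an ancestor CDS per group at the mean GC target; species copies apply
  per-codon synonymous resampling (carrying a species-specific GC bias
  toward `gc_targets`) and amino-acid substitutions, with the
  nonsynonymous rate multiplied by `flank_relaxation` within 33 residues
  of a repeat tract;
* repeat tracts inserted at anchor points between backbone residues, so
  indels occur only inside tracts and alignment columns are placed
  unambiguously without an aligner. A tract is *conserved* with
  probability `conserved_repeat_prob` (same length ≥ 8 in every species)
  and otherwise lineage-specific (present per species with probability
  `tract_presence_prob`, length 4 + Poisson);
* the expected seeded repeat residues per protein follow
  `base_repeat_residues + slippage_gc_coupling × GC`, implemented through
  the mean length of non-conserved tracts (infeasible combinations — a
  mean tract shorter than the 4-residue minimum — are refused with the
  offending field named). Ground truth is reconciled after assembly: a
  seeded tract is extended over neighbouring residues that happen to match
  its residue, so truth equals what a maximal-run scanner can see;
* disorder calls are Bernoulli at `disorder_in_repeat_p` inside tracts
  ± `disorder_window` residues and `disorder_background_p` elsewhere, for
  two pseudo-tracks; expression is log-normal with a configurable fraction
  of single-tissue genes; half-lives are exponential with the RCP mean
  multiplied by `rcp_halflife_factor`; gene models drop a
  (repeat-enriched) exon in second models with probability
  `alt_splice_prob`; hotspot intervals are anchored on RCP genes with
  boosted odds.

Identical seed and configuration give a byte-identical bundle.

### What the defaults mean — and what they do not

The defaults are **desk-scale study conditions**: 10 species × 80 groups,
proteins of 100–200 residues, GC targets 0.40–0.62, and a repeat–GC
coupling of 50 expected repeat residues per unit GC. With ~80 proteins per
species instead of thousands, a coupling as weak as in real proteomes
would be statistically invisible; the generator therefore trades realistic
repeat density (its RRPK means, ~80–130, are an order of magnitude above
typical plant proteomes) for detectability of the qualitative structure.
The calibration experiments shipped in the test suite use these documented
sizes: the repeat–GC recovery runs 10 × 80 bundles, the flank-relaxation
recovery runs 6 species × 12 groups, and the disorder-permutation
calibration runs 2 species × 40 groups with short tracts
(`base_repeat_residues = 7.5`, coupling 0) so the fully-disordered
probability of a segment is far from 0 and 1. Passing these experiments
shows the estimators recover what the generator put in, under the
generator's assumptions — i.i.d. disorder, a star phylogeny, uniform
codon-level substitution; it does not certify behaviour on real data with
phylogenetic correlation, alignment error, or codon-usage structure.

## Known limitations

* The dN/dS estimator has no transition/transversion or codon-frequency
  correction; absolute values differ from likelihood methods.
* Conservation identity treats the repeat's amino acid as the reference;
  a conserved *position* occupied by a different homopolymer in other
  species does not count as support.
* The generator's star phylogeny makes all pairwise comparisons
  exchangeable; tree-structured correlation among pairs is not emulated.
* Disorder calls are binary; graded disorder propensities are out of
  scope, as is predicting disorder from sequence.
* Hotspot and ortholog inference are consumed as inputs, never computed.
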