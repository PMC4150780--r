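---
title: "Scoring variant effects on miRNA target sites: models and methods"
author: "mirvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring variant effects on miRNA target sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirvar)
```

## The problem

Genetic variants that fall within or near microRNA binding sites can change
how strongly a miRNA engages its target: by creating or destroying base
pairs of the miRNA:mRNA duplex, and — less obviously — by reshaping the
local secondary structure of the mRNA so that the site becomes more or less
accessible to the silencing complex. `mirvar` quantifies both channels. For
each miRNA:target interaction (a CLASH-style chimera: one miRNA plus a
42–119-nt target fragment) and each variant placed within the binding site
or in its 25-nt flanking blocks, it computes mutant-minus-wild-type
differences of five measures:

* $\Delta\Delta G_{hybrid}$ — change in the free energy of the
  intermolecular duplex. Positive values weaken the hybrid.
* $\Delta\Delta G_{total}$ — change in total hybridization energy under a
  two-step model, $\Delta G_{total} = \Delta G_{hybrid} + \Delta G_{open}$,
  where $\Delta G_{open}$ is the ensemble free-energy cost of opening the
  site. Positive values reduce the hybridization potential.
* $\Delta$site\_access, $\Delta$upstream\_access,
  $\Delta$downstream\_access — changes in the mean probability that each
  nucleotide of the site, or of the 25-nt block on either side, is
  single-stranded in the Boltzmann ensemble. Positive values increase
  accessibility.

Cohort-level analyses compare variant densities (variants per nucleotide)
between the whole transcriptome, the transcripts that appear in chimeras,
and the binding sites themselves, per region (mRNA, CDS, 3'UTR; the 5'UTR
is not an analysis region) and per frequency class (common: MAF $\ge$ 1%,
rare: MAF < 1%, unknown: no frequency data), with Fisher's exact test on
nucleotide-level 2x2 tables. Conservation of a site is the mean of
per-nucleotide scores over the site interval.

## Thermodynamic core

### Energy model

All folding uses one pinned nearest-neighbor parameter set
(`inst/extdata/energy_params_v1.tsv`, loaded by `defaultEnergyModel()`):
a Turner-style 6x6 stack table over the pairs AU, UA, CG, GC, GU, UG
(strand-reversal symmetric by construction), hairpin/bulge/internal-loop
size penalties with a $1.079\,\ln(n/n_{max})$ extrapolation, an affine
multiloop model ($a = 3.4$, $b = 0.4$, $c = 0$ kcal/mol), a 0.45 kcal/mol
terminal AU/GU penalty and a 4.09 kcal/mol intermolecular initiation term,
at 37&nbsp;°C with $RT = 0.6163$ kcal/mol. Pinning one versioned file makes
every number the package emits deterministic; the values are realistic but
the package's results should be read relative to this model, not as
reproductions of any particular external parameterization.

### Duplex model

`duplexMfe()` minimizes free energy over all monotone antiparallel
pairings of the miRNA with a target segment: stacks, bulges and internal
loops up to 15 nt per side, no intramolecular pairs, no multiloops, with
terminal penalties at both helix ends. The dynamic program is exact over
this grammar and is verified against exhaustive enumeration of every legal
hybrid for short sequences. Co-optimal hybrids are resolved
deterministically: the reported optimum takes the 5'-most target span
(smallest target start), then the smallest miRNA end index; within the
traceback, the most compact extension (smallest loop) is preferred. A best
energy above zero, or no allowed pair at all, yields a "no hybrid"
sentinel; such chimeras are flagged site-less and excluded downstream with
a logged count.

### Ensemble model

`partitionFunction()` computes the exact partition function over all
pseudoknot-free secondary structures with hairpin loops of at least 3 nt,
by inside/outside recursions in log space (no sampling noise, no
overflow). Per-nucleotide single-strandedness comes from the outside pass;
`constrainedLogPartition()` restricts the ensemble to structures leaving an
interval unpaired, giving the opening energy
$\Delta G_{open} = -RT(\ln Z_c - \ln Z) \ge 0$. Both quantities are
verified against exhaustive structure enumeration (lengths $\le 16$, which
covers hairpins, bulges, internal loops and multiloops) at $10^{-9}$
relative tolerance, and the outside pass is cross-checked against
per-position constrained refolds. `sampleStructures()` provides seeded
stochastic traceback; it exists as a cross-check of the exact path (its
empirical frequencies are chi-square-tested against enumerated Boltzmann
probabilities), not as the primary accessibility route.

## Feature computation policies

* **Folding window.** Accessibilities and opening energies are computed on
  a 200-nt window centered on the site (configurable; truncated at
  transcript ends). The window, not the whole transcript, is the folded
  unit: local windows are standard for accessibility and keep runtime flat
  in transcript length. Features are invariant to sequence outside the
  window by construction.
* **Mutant comparability.** The wild-type window is carried through the
  variant's coordinate map, so wild-type and mutant ensembles fold the
  same region. For within-site variants the mutant site is re-localized by
  a fresh duplex scan of the mutated fragment (indels shift registers);
  flank variants keep the mapped site, and their
  $\Delta\Delta G_{hybrid}$ is asserted to be identically zero since the
  site sequence is untouched. A deletion removing the whole site is
  flagged `site_destroyed` and scored against the best remaining hybrid; a
  mutant fragment with no hybrid at all is flagged `site_lost` (hybrid
  deltas become missing, accessibility deltas are still computed over the
  mapped interval).
* **Seed classes.** 6mer = Watson–Crick match to miRNA nts 2–7; 7mer-m8 =
  nts 2–8; 7mer-A1 = nts 2–7 plus a target A opposite nt 1; 8mer = nts 2–8
  plus the A; offset-6mer = nts 3–8; most specific class wins and GU never
  counts. The register (which target base sits opposite miRNA nt 1) is
  extrapolated from the 5'-most paired miRNA nucleotide of the located
  duplex, so the A1 position may legitimately lie outside the site
  interval; at a transcript's 3' end the A1-dependent classes are simply
  unavailable.
* **3' pairing.** The longest run of consecutive Watson–Crick pairs
  (adjacent on both strands; GU breaks a run) among miRNA nts 12 to the 3'
  end.
* **Region label.** A site takes the region containing it; a site crossing
  a region boundary is labelled `spanning`. Flank blocks truncated by a
  transcript end use the available nucleotides and carry a truncation
  flag; an empty flank yields a missing accessibility.
* **Coordinates.** Everything internal and in every output table is
  0-based half-open; VCF positions are converted at the boundary, VCF
  allele frequencies above 0.5 are folded to minor-allele frequencies, and
  indels are left-aligned to minimal representation before placement.
  Variants mapping to several transcripts are counted once per transcript
  by default (`dedupe = "per_variant"` exposes the alternative).

## Statistical choices

Fisher's exact test compares densities on 2x2 tables of (variant count,
non-variant nucleotides) by scope; the module reports raw p-values, as is
conventional for this analysis, with a Bonferroni column alongside for
transparency. The tendency of variants to weaken hybrids is tested with an
exact two-sided binomial test on the counts beyond $\pm$1 kcal/mol.
Histograms use 1 kcal/mol bins over $[-10, 10]$ with open outer bins for
the energy measures and 0.05 bins over $[-1, 1]$ with a central
$[-0.01, 0.01]$ bin for the accessibility measures; bin intervals are
half-open $(a, b]$ with a closed lowest bin. Summary percentages are
rounded half-up to one decimal.

## The synthetic cohort generator

`generateCohort()` produces a complete, mutually consistent file bundle —
FASTA transcriptome, BED12 annotation (1–3 exons per transcript, both
strands), chimera TSV, VCF, conservation TSV — with ground truth for every
downstream stage. Its defaults are the package's study conditions, chosen
once:

* 120 transcripts of 500–1200 nt (about $10^5$ nt; large enough that the
  engineered density contrasts are detectable at $\alpha = 0.05$ on a
  desk-scale run), 10/50/40% 5'UTR/CDS/3'UTR, uniform base composition
  with a GC knob.
* 12 miRNAs of 19–24 nt; 100 chimeras with 42–119-nt fragments over about
  a quarter of the transcripts, biased into 3'UTRs.
* Implanted sites: 18.7% carry a canonical seed class, the rest are
  seedless (3'-complementarity only), echoing the seed/seedless split of
  CLASH interactomes. An implant is the reverse complement of its miRNA
  with class-specific seed-region edits (designed A or non-A opposite
  nt 1, designed mismatches drawn from the bases that can form neither
  Watson–Crick nor GU pairs with their opposite nucleotide). Because a
  favorable extension of the duplex into random flanking sequence would
  make the realized optimum differ from the designed span, the generator
  verifies each implant with a duplex scan and resamples the placement and
  mismatch choices until the designed span is the fragment's unique
  optimum.
* Variant densities per nucleotide: rare CDS 0.020 vs rare 3'UTR 0.005
  (the 4x CDS enrichment of rare variants), common 3'UTR 0.010 vs common
  CDS 0.004; interacting transcripts thinned to 0.55x; inside sites,
  common variants survive with probability $0.10 + 0.30(1 - c)$ where $c$
  is the local conservation (purifying selection: density lower and
  decreasing with conservation) and rare variants with probability 0.35.
  Thinning both classes inside sites is a deliberate simplification of the
  real data's class-dependent pattern — at this cohort size the
  lower-site-density signal is otherwise undetectable.
* MAF mixture: rare alleles on $[5\times 10^{-4}, 0.01)$, common on
  $[0.01, 0.5]$, with about two thirds of variants rare and 3% lacking
  frequency data. When MAF–accessibility coupling is on (the default), the
  generator computes each near-site variant's $|\Delta$site\_access$|$
  with the package's own folding and shapes the MAF draw as
  $u^{1 + 8\min(1, |\Delta|/0.2)}$, pushing large structural effects
  toward the low end of their class — the engineered form of the
  observation that accessibility-altering variants have lower minor-allele
  frequencies.
* Conservation: Beta(1.2, 2.5) background; each site draws a target level
  (43% above 0.92, 21% below 0.08) written over the site with small noise.
* All randomness flows from the single mandatory seed; identical seeds
  give byte-identical files.

`nullCohort()` switches every engineered effect off (one flat density, no
thinning, no coupling) and additionally emits a table of sign-symmetric
synthetic effect values. That table — not a refolded cohort — is the input
for sign-bias calibration: recomputing thermodynamics for hundreds of
replicate cohorts is not informative about the test's calibration and is
far more expensive, so the null model is expressed directly in effect
space. Density-test calibration does run the real counting and Fisher
machinery on replicate null cohorts.

### What the generator does and does not emulate

Generated cohorts reproduce the statistical structure the analyses consume:
region- and class-dependent densities, a rare-skewed MAF spectrum,
fragment geometry, implanted sites of known class, conservation elevation
over sites, and a coupling between structural effect and allele frequency.
They do not emulate human sequence composition, codon structure, linkage,
ligation biases of the CLASH protocol, or AGO footprints — so green tests
certify the pipeline's correctness and statistical behaviour under known
truth, not biological conclusions about real transcriptomes.

## Numerical notes and limitations

* Ensemble arithmetic is in log space; oracle comparisons are asserted at
  $10^{-9}$ relative tolerance on lengths where exhaustive enumeration is
  feasible.
* The duplex grammar has no multiloops, coaxial stacks or dangling ends,
  and the single-sequence grammar no pseudoknots — standard simplifications
  for this problem class.
* Degenerate inputs: empty intervals return the unconstrained partition
  function; a homopolymer has $\ln Z = 0$ and unit accessibility
  everywhere; ties in the duplex are broken as described above.
* Swapping the roles of the two alleles negates all five deltas when the
  comparison is anchored consistently (same folding window; for flank
  variants, whose policy never re-localizes the site, also the same site
  interval and duplex). Without that anchoring a flank substitution can
  move where a fresh duplex scan of the swapped "wild type" would put the
  site, which is a bookkeeping artifact rather than an asymmetry of the
  measures.
* Within-site indels make the mutant "site" interval a modelling choice;
  we re-scan the mutated fragment and document the `site_destroyed` /
  `site_lost` flags rather than pretending the wild-type interval
  survives.
* Problem sizes used by the shipped tests (cohort of ~100 chimeras and
  ~1,800 variants; enumeration oracles at lengths $\le 16$; 120 null
  replicates) were chosen so the full suite runs comfortably on one CPU;
  all are configuration, not limits of the methods.

## Worked example

```{r, eval = FALSE}
cfg <- cohortConfig(seed = 1)
coh <- generateCohort(cfg, dir = tempdir())
rc <- runConfig(coh$paths$fasta, coh$paths$bed, coh$paths$chimeras,
                coh$paths$vcf, coh$paths$conservation)
bundle <- runPipeline(rc)
head(bundle$summary)
```
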