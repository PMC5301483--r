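---
title: "Gene-dosage qPCR for sex-chromosome homology and molecular sexing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-dosage qPCR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zdose)
```

## The measurement model

Quantitative PCR on genomic DNA reports, per well, a quantification cycle
Cq — the cycle at which fluorescence crosses threshold. Under exponential
amplification with per-cycle efficiency $E \in (1, 2.2]$, the template
quantity behind a well is proportional to $E^{-\mathrm{Cq}}$:
`relative_quantity()` implements exactly this, so one cycle earlier means
$E$ times more template, and quantities are relative (Cq 0 maps to 1),
which is all a ratio statistic needs.

An individual's relative dose of a target gene $t$ is its target
quantity normalized by the geometric mean of its reference-gene
quantities,

$$ d_i \;=\; \frac{E_t^{-\mathrm{Cq}_{t,i}}}
{\operatorname{geomean}_{g \in \mathrm{refs}} E_g^{-\mathrm{Cq}_{g,i}}}, $$

and the female:male dose ratio for a gene in a species is

$$ r \;=\; \frac{\tfrac{1}{n_f}\sum_{i \in \mathrm{F}} d_i}
               {\tfrac{1}{n_m}\sum_{j \in \mathrm{M}} d_j}. $$

Under female heterogamety, a gene present on Z and absent from the
degenerated W gives $r = 1/2$ (females hemizygous), while autosomal and
pseudoautosomal genes give $r = 1$. With $E = 2$ everywhere the statistic
reduces to the familiar $2^{-\Delta\Delta \mathrm{Cq}}$ form. The
normalization makes $r$ exactly invariant to per-sample template-amount
offsets: adding a constant to every Cq of one sample multiplies the
numerator and denominator of $d_i$ by the same factor. The test suite
asserts this invariance to machine precision.

Means over individuals are taken per sex (not pooled wells) because the
question is a contrast between sexes; individuals are the experimental
units and wells only measure them.

## Replicate quality control

Wells come in technical triplicates with a flag: `ok`,
`no_amplification` (primers failed to bind), or `secondary_product`
(melt curve showed unspecific amplification). The QC rules in
`aggregate_replicates()` are:

* any `secondary_product` well excludes the whole sample-by-gene cell —
  an unspecific product contaminates the quantification, so the assay is
  untrustworthy in that animal, not just that well;
* among `ok` wells, a well deviating more than `max_spread` (default 0.5
  cycles) from the cell median is dropped as a pipetting outlier;
* fewer than `min_replicates` (default 2) usable wells excludes the cell;
* missing wells are never imputed.

A gene excluded in every animal of one sex yields a `not_tested` marker,
deliberately distinct from any numeric ratio: "we could not measure
this" must never be confused with "dose zero". When one of the two
reference genes drops out in a sample, normalization falls back to the
remaining reference with a logged warning — a single good single-copy
reference is sufficient, and panels do fail gene-by-gene in species
distant from the primer-design genome.

## Bootstrap uncertainty

The experiment has two nested levels of replication: wells within
animals, animals within sexes. The default interval is a percentile
bootstrap with 1000 resamples in a two-stage scheme: each iteration
resamples the usable wells within every cell (with replacement, same
size), recomputes each animal's dose, then resamples animals within each
sex. Seeding is strict: the generator is seeded once per gene-by-species
fit and streams are consumed in a fixed documented order (replicate
draws for females in sample-id order then males, target gene before
references in alphabetical order; then female, then male animal draws),
so a seed fully determines the interval. The test suite holds the
implementation to an independently written naive reimplementation of the
whole procedure, loop by loop, at identical seeds.

Why two-stage rather than resampling one level? With $n = 3$ animals per
sex and $k = 3$ wells, any single-level bootstrap understates the
sampling variance by its $(m-1)/m$ factor and the intervals undercover
severely (measured around 80% at nominal 95% in this package's
calibration study). The two-stage scheme partially double-counts
technical noise — in a design where between-animal spread is itself
mostly technical, each level sees a share of the same variance — but
that inflation and the two shrinkage factors nearly cancel, and the
measured coverage over 500 seeded simulations (technical sd 0.2 cycles,
3 animals/sex, triplicates, 1000 resamples) is 96–98%: close to nominal
and slightly conservative, which is the right side to err on for a
classifier that demands interval containment. That coverage measurement
is part of the acceptance test suite, not a claim made once during
development. Single-level schemes remain available via `boot_scheme=`
for designs with many animals or many replicates.

## Classification bands

Gene calls are made on the interval, not the point estimate: a gene is
`z_specific` only when its whole CI fits inside the Z band (default
$[0.35, 0.65]$) and `autosomal` only inside $[0.85, 1.15]$; anything
else is `indeterminate`. The bands are this package's construction — the
underlying expectations are exact (0.5, 1.0) but any practical tolerance
is a choice, and CI containment makes `indeterminate` an honest
category: a noisy estimate near 0.5 with a wide interval does not get
promoted to a linkage claim. Both bands widen monotonically: enlarging a
band can only move calls out of `indeterminate`, never flip
`z_specific` to `autosomal` (a property test).

A species is called ZZ/ZW when at least `min_z_genes` (default 3) genes
are Z-specific *and* at least one autosomal control behaved autosomally;
the control requirement guards against normalization artefacts producing
a uniform halving. Intervals sitting around $r = 2$ (the X-specific
pattern under male heterogamety) are flagged in a note but never turned
into a system call: a female-heterogametic panel has no business calling
XX/XY.

## Molecular sexing

Two assays are provided. The recommended one scores a sample's Z-gene
doses against known male references: the per-gene relative dose is near
0.5 for females and 1.0 for males, and the median over the validated
Z-specific genes is classified with the same bands as linkage calls.
Protein-coding dosage is evolutionarily stable across the family, so the
same panel sexes any member species. Out-of-band medians return
`unreliable` — at high plate noise the assay abstains rather than
missexes (the suite checks zero missexing at technical sd 0.3 cycles,
and 100% definitive calls in the clean-plate regime).

The second assay uses 18S rDNA copy number: in many trionychids the W
chromosome carries a large rRNA amplification, so females show several
times the male level (normalized against *rag1*; there is deliberately
no fallback reference for this assay, since the usual alternative
control proved failure-prone). The female threshold defaults to 200% of
the male reference level, below the lowest simulated/observed female
regime (280%) and above male-like failures; the male band is
$[50, 150)\%$, bracketed symmetrically as no male dispersion figure is
available. Because rRNA clusters are evolutionarily labile,
`assess_rrna_reliability()` derives a per-species reliability table from
known-sex individuals, and any call in an unreliable species is forced
to `unreliable` regardless of score — reproducing the known failure of
this assay in both *Lissemys punctata* subspecies, whose fixture
multipliers (0.94, 0.62) put females at or below the male level.

## Ancestral states and the origin bracket

Tip states (`esd` / `zw` / `unknown`) are mapped on a user-supplied
ultrametric chronogram. Reconstruction is standard Fitch small parsimony
(postorder intersection/union; unknown tips contribute the full state
set and never force changes); the score equals the minimum number of
changes, which the suite verifies against exhaustive enumeration over
all internal assignments for every rooted topology up to 5 tips and
seeded random trees to 8 tips, plus an independent library
implementation. A Dollo option (`method = "dollo"`) constrains the
derived state to a single gain with losses only — defensible for
differentiated sex chromosomes, which are hard to un-evolve — and
matters only when ingroup tips revert; on the packaged data both methods
agree.

The origin bracket takes the maximal clade whose crown set is exactly
the derived state: its crown age is the lower bound (the trait was
certainly present in that ancestor) and its stem age the upper bound
(the trait cannot predate the split from the sister lacking it). A
derived state confined to one tip degenerates to a (0, stem) bracket
with a warning; a derived state reconstructed at the root has no bracket
and errors. The packaged chronogram carries exactly two meaningful
calibrations — the family split at 200 Mya and the ingroup crown at 120
Mya (105 available via `trionychid_fixture_tree(crown_age = 105)`, the
lower edge of published crown estimates); all other node ages are
invented fixture values that scale with the crown age. The tree is a
test harness and demonstration input, not an inference.

## The synthetic data generator

`simulate_cq_table()` inverts the measurement model: a well's expected
Cq is $\mathrm{baseline} - \log_E(\mathrm{copies} \times
\mathrm{template})$, with

* per-well technical noise (`cq_sd`, cycles),
* per-sample lognormal template variation (`template_sd`, cancels
  exactly through normalization),
* per-species-by-gene assay failures drawn once per species (primer
  dropout and secondary products model primer-template divergence, which
  is a property of the species, not the well),
* a per-species female:male 18S multiplier with lognormal individual
  jitter (rRNA copy number varies between individuals).

Baseline constants (Cq 22 for single-copy genes, −8 cycles for the
high-copy rDNA assay) are arbitrary and cancel in every ratio. A single
integer seed governs all draws through a fixed stream order (species,
then per-species assay fates, then samples — females first — template,
genes in panel order, wells), so a seed yields a byte-identical table.

The packaged fixture emulates a 10-taxon softshell-turtle study: 7
Trionychinae and 3 Cyclanorbinae (both *Lissemys punctata* subspecies),
a panel of 2 autosomal controls, 6 candidate Z genes, 2 references and
18S, triplicates, 3 animals per sex, with a deterministic dropout
pattern that removes up to 3 Z assays in lineages distant from the
primer-design genome while always leaving both controls and at least 3
usable Z genes. Non-*Lissemys* 18S multipliers draw uniformly from
[2.8, 18.4] (the observed female range), with *Apalone spinifera* pinned
at 3.43. Two species are flagged as previously documented, so a full
fixture run reports 8 newly documented ZZ/ZW systems.

Noise defaults deserve a note. The fixture's default technical sd is
0.05 cycles — a clean plate from a well-optimized assay — because the
fixture's contract is that every taxon resolves end-to-end under default
settings, and with interval-containment classification the autosomal
band ($\pm 0.15$) requires interval half-widths below it; the
delta-method half-width of the two-stage bootstrap is roughly
$0.9 \times$ `cq_sd` near $r = 1$, so 0.05 leaves margin at any seed
while 0.2 would make autosomal confirmation structurally impossible.
Property and calibration tests deliberately use harsher noise (0.2–0.3
cycles) where dispersion itself is under test. What the simulator does
*not* model: biological copy-number variation of protein-coding genes
between individuals, partial W degeneration (intermediate female
copies), cross-amplification between paralogs, or plate effects beyond a
scalar template offset. Passing tests therefore certify the estimator
and pipeline logic under the stated noise model, not the wet-lab
behaviour of any particular primer pair.

## Numerical and degenerate-input choices

* Quantities are computed in log space where geometric means are
  involved; efficiencies at the boundary ($E \le 1$) error immediately.
* The percentile interval uses R's default quantile definition (type 7).
* Cq values are validated as present iff the well is `ok`; empty tables,
  mixed-cell aggregation, malformed intervals (low > high), duplicated
  replicate indices and unknown genes in the Cq table all error with the
  offending record named, before any stage runs.
* Pipeline warnings carry machine-parseable codes
  (`REPLICATE_DROPPED`, `REFERENCE_FALLBACK`, `RRNA_SPECIES_UNRELIABLE`,
  `SPECIES_NOT_IN_RELIABILITY_TABLE`, `SINGLE_LINEAGE`, `PLOT_FAILED`)
  and each distinct message appears exactly once in the run log.
* Re-running `run_full_analysis()` with the same configuration and seed
  writes byte-identical outputs; the figure is best-effort and its
  failure downgrades to a warning.

## Problem sizes in the shipped tests

The suite's simulation studies use 3 animals/sex with triplicates (the
fixture design), 500 seeded repetitions for interval coverage, 100 seeds
for parameter-recovery medians and for the rRNA reliability contrast,
and 200 simulated juveniles for sexing accuracy; parsimony is exhausted
over all rooted topologies to 5 tips and sampled to 8. These sizes give
stable pass/fail behaviour at conventional tolerances while keeping the
default check fast on one CPU.

## Known limitations

* Bands, thresholds and the rRNA male band are constructions calibrated
  to the simulated regimes, not estimated from data; real studies should
  inspect `indeterminate` calls rather than tighten bands.
* The two-stage bootstrap is slightly conservative by design; with many
  animals and genuine biological dose variance, `boot_scheme =
  "individuals"` is the textbook choice.
* At the harsh end of the modelled noise range (0.3 cycles) the sexing
  assay abstains on a noticeable fraction of animals instead of calling
  them; that is intended behaviour, not accuracy loss.
* Fitch reconstruction treats states as unordered with equal costs;
  likelihood or stochastic-mapping reconstruction is out of scope.
* Absolute copy numbers, standard curves, melt-curve analysis and primer
  design are all upstream of this package's inputs.
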