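---
title: "Methods: indel mutation-rate evolution and the drift barrier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indel mutation-rate evolution and the drift barrier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(driftbarrier)
library(dplyr)
```

## The question

The drift-barrier hypothesis (DBH) holds that natural selection refines
replication fidelity only until the fitness advantage of a further
improvement drops below the power of random genetic drift, which is of
order $1/N_e$ ($1/(2N_e)$ in diploids). If so, the genome-wide deleterious
mutation rate should decline with increasing effective population size
$N_e$ across the tree of life. Insertion–deletion (indel) mutations are a
sharp test case: they arise and are repaired by largely different
molecular machinery than base substitutions, and in coding DNA almost
every indel is a frameshift, so the *number of indel events* — not the
number of base pairs involved — sets the deleterious burden. This package
implements the full chain of analysis:

1. estimate per-site, per-generation rates $u_{bs}$ and $u_{id}$ from
   mutation-accumulation (MA) line sequencing,
2. estimate $N_e$ from silent-site diversity and $u_{bs}$,
3. regress the log genome-wide indel burden $u_{id} G_e$ on $\log_{10} N_e$,
   with and without phylogenetic correction, and
4. translate the drift barrier into the minimum rate reduction an
   antimutator allele needs in order to be visible to selection.

Because raw MA sequencing data are not distributed with the package, a
synthetic-data generator reproduces the statistical structure those
estimators assume, with full ground truth, so every stage can be tested
for parameter recovery.

## Rate estimation from MA lines

An MA experiment propagates ~dozens of lines through repeated
single-colony bottlenecks, so selection is nearly powerless and mutations
accumulate at the spontaneous rate. For a line with $m$ called mutations
over $n$ callable sites and $T$ generations,

$$u = \frac{m}{nT}, \qquad \mathrm{SE}(u) = \sqrt{\frac{u}{nT}},$$

the latter being the Poisson sampling error. Rates are pooled across $N$
lines as the unweighted mean, with
$\mathrm{SE}_{pooled} = s/\sqrt{N}$ where $s$ is the SD of the per-line
rates. We deliberately use the unweighted mean (not an $n$-weighted one)
because that is the estimator the pooled-SE formula describes; with
near-equal callable fractions per line the difference is negligible.
Generations per line are the number of transfers times the mean of
$\log_2(\text{viable cells per colony})$ — a colony founded by a single
cell reaches $N$ cells after $\log_2 N$ doublings. `line_rate()`,
`pooled_rate()`, `generations_from_colonies()` and `split_rates()`
implement these; `split_rates()` counts indel *events* after merging, so a
50-bp deletion contributes exactly 1 to $m_{id}$.

Lines with zero callable sites are dropped with a warning rather than
propagating NaN rates. Per-line generation counts are supported, but a
single shared $T$ is the default, matching how MA studies report a
per-species average.

## Consensus calling

Mutations are called from per-site count configurations — eight integers
per site per line (A, a, C, c, G, g, T, t; upper case forward strand).
`consensus_base()` requires pooled depth ≥ `min_coverage` (default 10), a
winning-base fraction ≥ `min_consensus_fraction` (default 0.8, threshold
inclusive), and ≥ `min_forward`/`min_reverse` (default 2/2) reads on each
strand. These thresholds are explicit stand-ins consistent with
consensus-method MA studies; the number of sites passing them per line is
the rate denominator $n$ (`callable_sites()`).

`call_line_substitutions()` is reference-free across lines: line $i$ gets
a call where its consensus differs from the modal consensus of the other
lines. A variant carried by more than `max_lines_sharing` lines (default
1) is almost certainly a founder variant or a systematic artifact, not an
independent mutation; such variants are excluded from $m$ and reported in
a `shared_variants` diagnostic. When a reference is supplied, variants
unanimous across lines — invisible to a purely cross-line rule — are
flagged the same way.

Indels are taken only from the concordance of two aligner-derived
gap-call tracks (`intersect_indel_callsets()`), mirroring dual-aligner
(e.g. BWA ∩ NOVOALIGN) practice: same event kind within `position_slop`
(default 3 bp), equal lengths required for short events. Runs of adjacent
same-sign per-base gap calls merge into single events
(`merge_indel_events()`, idempotent); events longer than 9 bp are
classified "large". We fix the short/large boundary at > 9 bp and apply it
consistently (the verification literature sometimes writes the same split
as "< 10 bp" / "> 10 bp"; we treat these as one boundary, and events of
exactly 10 bp are "large").

## Diversity and effective population size

Watterson's estimator and nucleotide diversity are
$$\hat\theta_s = \frac{S}{a_n L}, \quad a_n = \sum_{i=1}^{n-1} \frac{1}{i},
\qquad \pi_s = \frac{n}{n-1}\,\overline{2p(1-p)},$$
per silent site, with $S$ segregating sites among $n$ alleles over $L$
sites. Under neutral equilibrium $E[\theta_s] = E[\pi_s] = 2N_e u_{bs}$
(haploids) or $4N_e u_{bs}$ (diploids), so `effective_population_size()`
divides the diversity estimate by $2u_{bs}$ or $4u_{bs}$. $\theta_s$ is
preferred over $\pi_s$ where both exist, because genome-wide segregating
site counts have lower evolutionary sampling variance than locus-limited
heterozygosity. Sites with more than two alleles count once as
segregating (infinite-sites convention). `theta_stability()` provides the
allele-subsampling diagnostic.

The packaged species table assigns haploid scaling to the seven bacteria
and to *C. reinhardtii* and *S. cerevisiae*, diploid scaling to the six
multicellular eukaryotes and *P. tetraurelia*. `recompute_ne()` checks
that these assignments reproduce the tabulated $N_e$: a row is
"consistent" when the tabulated $N_e$ lies in the interval obtained by
perturbing the rounded diversity input by ±2 units in its last printed
digit (the inputs carry only 1–3 significant digits, so exact agreement
is not a meaningful target). Fourteen of the fifteen rows are consistent;
the *M. musculus* row is not reproducible from its own diversity and
$u_{bs}$ under either ploidy convention and is flagged in the fixture
rather than silently adjusted.

## Cross-species regressions and phylogenetic correction

All comparative fits are ordinary least squares on $\log_{10}$ values
(`loglog_regression()`), with parameter SEs from the residual variance
and a two-sided $t$ test on the slope (df = $n-2$). The fitted responses
are the burden $u_{id} G_e$ (proteome-size effective genome), the expanded
burden $u_{id}(G_c + G_{nc})$, and $u_{id}$ against $u_{bs}$; a subset fit
restricted to the ten unicellular species (bacteria plus unicellular
eukaryotes) guards against the relationship being a multicellularity
artifact. We require at least three points per fit so that residual
degrees of freedom exist.

Phylogenetic non-independence is handled with Felsenstein's independent
contrasts (`pic_contrasts()`): at each internal node the standardized
contrast is $(x_i - x_j)/\sqrt{b_i + b_j}$, the node value is the
$1/b$-weighted average, and the parent branch is extended by
$b_i b_j/(b_i+b_j)$. Contrasts of $\log_{10}(u_{id} G_e)$ are regressed on
contrasts of $\log_{10} N_e$ through the origin
(`origin_regression()`, df = $n-1$), with each contrast pair oriented so
the predictor contrast is non-negative; the fit is provably invariant to
that orientation, and a zero predictor contrast simply contributes
nothing to the slope while remaining in the df. The through-origin PIC
slope is algebraically identical to the phylogenetic GLS slope under
Brownian covariance, and the test suite verifies this identity on random
trees, alongside agreement with `ape::pic()`.

The packaged 15-taxon tree follows standard taxonomy — proteobacteria
(*Agt*, (*Ec*, *Vc*), *Pa*) sister to firmicutes plus mollicutes
((*Bs*, *Se*), *Mf*); opisthokonts
(*Sc*, (*Dm*, (*Ce*, (*Hs*, *Mm*)))) with the green lineage (*At*, *Cr*)
and *Pt* on the eukaryote side — with every branch length set to 1.0, the
convention under which the published contrasts were computed. The exact
published topology is not recoverable from text, which is why the PIC
acceptance band is wider than the ordinary-regression bands; the tree
ships as an editable newick file, not hard-coded.

```{r}
report <- reproduce_analysis()
report
```

The `checks` component compares each fitted quantity against packaged
reference values with explicit tolerances:

```{r}
report$checks
```

## Antimutator thresholds

Setting the selective advantage of an antimutator,
$s\,t\,\Delta u_{id}\,G_e$, equal to the power of drift and solving gives

$$\Delta u_{id} = \frac{1}{N_e\,s\,t\,G_e} \;\;(\text{haploid}), \qquad
\frac{1}{2N_e\,s\,t\,G_e} \;\;(\text{diploid}),$$

with defaults $s = 0.01$ (mean deleterious effect per mutation) and
$t = 2$ generations of linkage between a modifier and the mutations it
causes. `antimutator_threshold()` reports $\Delta u_{id}$ and its ratio to
the standing $u_{id}$; for most species the required reduction is ~0.1–1%
of the current rate — small enough that mutation-rate refinement stalls,
exactly as the DBH predicts.

## What the generator emulates — and what it does not

`simulate_ma_experiment()` draws per-line substitution and indel-event
counts as Poisson with means $u_{bs} n T$ and $u_{id} n T$; positions are
uniform; signed indel lengths come from a configurable distribution
defaulting to 85% short (1–9 bp, geometric with ratio 0.5) and 15% large
(10–200 bp, uniform), the short/large mixture reported for bacterial MA
data (the per-species empirical length spectrum is not published, so the
default is a stylized stand-in). A single Poisson draw per line replaces
per-transfer accrual: bottlenecking makes selection negligible, and the
estimators only ever see totals. Insertions carry positive sign,
deletions negative; positions are 0-based half-open internally and
1-based in emitted VCF/TSV. `simulate_site_counts()` models ~100×
sequencing as Poisson depth split binomially across strands with
independent per-read-base errors (uniform across the three wrong bases);
deleted sites get zero coverage. Two gap-call tracks per line emulate
independent aligners: both contain the truth (the second with ±1 bp
per-event jitter), each salted with rare track-specific false calls
(5×10⁻⁷ per site) that only concordance filtering removes; optional
founder variants shared by all lines exercise the shared-variant screen.
`simulate_population_sample()` is a standard Kingman coalescent with
infinite-sites mutation (rate $\theta L/2$ per unit coalescent time), and
`simulate_transfer_log()` scatters colony sizes lognormally (geometric
mean at the target size, `sdlog` 0.2 by default — about ±30% plating
noise).

Deliberately *not* modeled: read-level data (quality scores, mapping
ambiguity, paralogy), alignment itself, structural variants beyond simple
indels, selection during the MA, recombination and demography in the
coalescent, and backup-plate growth (generation counts are taken as
given). Passing recovery tests therefore shows the estimators are correct
*under their own assumptions*; it does not certify performance on real
alignments with repeat-induced artifacts.

## Numerical and design choices

- Consensus ties are impossible for the winning base (fraction must
  exceed 0.5); the threshold comparison is inclusive (≥).
- Cross-line modal ties leave a site uncalled for that line rather than
  guessing; calls are invariant to line ordering.
- Indel placement rejects overlaps and same-sign adjacency so planted
  events never merge; an event must fit inside the reference.
- OLS is fitted via `stats::lm`; the tests hold it to the closed-form
  normal equations at 10⁻¹⁰ relative tolerance.
- Contradictory gap calls (insertion and deletion at one position) are
  dropped and reported as conflicts, never silently resolved.
- Seeds: every stochastic function takes an explicit `seed` and restores
  the caller's RNG state; the pipeline derives per-stage seeds by fixed
  offsets from one master seed.
- Problem sizes in the test suite were chosen to make Monte-Carlo checks
  decisive at comfortable runtimes: the parameter-recovery run uses 50
  lines × 10⁶ sites at 100× coverage (error 10⁻³ and 0), estimator
  oracles use 100 random ≤ 8-taxon trees and 1000 coalescent replicates.

## Known limitations

- The consensus caller assumes clonal lines and biallelic sites; it is
  not a general diploid genotyper.
- $N_e$ from $\theta_s/u_{bs}$ inherits every caveat of equilibrium
  neutral theory (linked selection, demography, population structure).
- The comparative analysis takes $G_e$ and $G_c + G_{nc}$ as inputs;
  estimating constrained noncoding fractions from annotation is out of
  scope.
- With 15 species, individual regression coefficients are sensitive to
  single rows; the packaged reference checks encode the tolerance bands
  appropriate to inputs printed at 2–3 significant figures.
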