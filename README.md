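# driftbarrier

Tools for studying the evolution of the insertion–deletion (indel)
mutation rate under the drift-barrier hypothesis. The package is aimed at
population geneticists working with mutation-accumulation (MA)
experiments and cross-species comparative data: it estimates mutation
rates from MA-line sequencing, converts silent-site diversity into
effective population sizes, and fits the comparative regressions that
test whether genome-wide mutation rates are pinned at the limit set by
random genetic drift.

## The model

For an MA line with `m` called mutations over `n` callable sites and `T`
generations, the per-site per-generation rate and its Poisson standard
error are

    u = m / (n T),        SE(u) = sqrt(u / (n T)),

pooled across `N` lines as the unweighted mean with
`SE_pooled = s / sqrt(N)` (`s` = SD of per-line rates). The indel rate
`u_id` counts merged indel *events* (a 50-bp deletion is one event),
since each event disrupts a reading frame regardless of size.

Effective population size comes from silent-site diversity: under
neutrality `theta_s` (Watterson, `S / (a_n L)`) or `pi_s` (mean pairwise
heterozygosity) has expectation `2 Ne u_bs` in haploids and `4 Ne u_bs`
in diploids, so `Ne` follows by dividing out `u_bs`.

The drift-barrier test regresses `log10(u_id * Ge)` (the genome-wide
deleterious indel burden, `Ge` = effective genome size) on `log10(Ne)`
by OLS, repeats it with the expanded genome `Gc + Gnc` and on the
unicellular subset, relates `log10(u_id)` to `log10(u_bs)`, and applies
Felsenstein's independent contrasts with a through-origin fit to remove
phylogenetic non-independence. Finally, setting an antimutator's
advantage `s t Δu_id Ge` equal to the power of drift (`1/Ne`, or
`1/(2 Ne)` in diploids) gives the smallest rate reduction selection can
see.

A synthetic-data module simulates the whole data-generating process —
reference genomes, Poisson mutation accrual along bottlenecked lines,
per-site strand-specific read counts at ~100×, dual-aligner indel call
tracks, coalescent population samples and colony-count transfer logs —
with ground truth retained, so the estimator chain is testable end to
end.

## Worked example

The packaged 15-species table (7 bacteria, 8 eukaryotes, with genome
sizes, rates, silent-site diversity and Ne) and its phylogeny drive the
whole comparative analysis:

```r
library(driftbarrier)
report <- reproduce_analysis()
report
#> <drift_barrier_report>
#>
#> Fits:
#>   fig1a       <rate_regression> log10(y) = 2.233 (0.485) -0.730 (0.068) log10(x)
#>   r2 = 0.899, P = 7.74e-08, d.f. = 13, n = 15
#>   fig1b       <rate_regression> log10(y) = 3.482 (0.655) -0.874 (0.092) log10(x)
#>   r2 = 0.875, P = 3.15e-07, d.f. = 13, n = 15
#>   fig3        <rate_regression> log10(y) = -1.456 (0.686) +0.925 (0.075) log10(x)
#>   r2 = 0.922, P = 1.47e-08, d.f. = 13, n = 15
#>   unicellular <rate_regression> log10(y) = 0.538 (0.964) -0.523 (0.124) log10(x)
#>   r2 = 0.691, P = 0.00287, d.f. = 8, n = 10
#>   pic         <rate_regression> through origin: y = -0.582 (0.077) x
#>   r2 = 0.815, P = 4.03e-06, d.f. = 13, n = 14
#>
#> Reference checks passed: 12 / 12
#> Ne recomputation consistent: 14 / 15 (1 flagged)
#> Antimutator threshold fraction in [0.1%, 1%]: 11 / 15 species
#> u_id / u_bs across species: 0.057 - 0.461
```

Reading the output: the burden of indel events per effective genome per
generation falls by a factor ~5 for every 10-fold increase in `Ne`
(slope −0.73), the relationship survives phylogenetic correction (PIC
slope −0.58, r² 0.82) and restriction to unicells (r² 0.69), and indel
and substitution rates co-vary nearly proportionally (slope 0.93) —
the signature expected if drift, not physiology, sets the floor on
replication fidelity. `plot_burden_ne(read_species_table())` and
`autoplot()` on any fit draw the corresponding figures, and
`tidy()`/`glance()` return the fits as tibbles.

The simulation-to-estimation loop runs the other half of the package:

```r
res <- run_pipeline(pipeline_config(seed = 4, n_sites = 5e4, n_lines = 6,
                                    u_bs = 1e-7, u_id = 2e-8, t_gen = 1000))
res$pooled
#> # A tibble: 2 × 5
#>   type        mean_u            s n_lines     se_pooled
#>   <chr>        <dbl>        <dbl>   <int>         <dbl>
#> 1 bs    0.0000000900 0.0000000352       6 0.0000000144
#> 2 id    0.0000000200 0.0000000179       6 0.00000000730
```

Both pooled rates recover the simulated truth (1e-7 and 2e-8) within
sampling error, from consensus calling of simulated read counts and
dual-aligner indel concordance — not from the ground truth, which is
kept only for verification.

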