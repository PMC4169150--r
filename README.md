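# dynqtl

Dynamic multi-family QTL mapping across developmental stages, for doubled
haploid (DH) populations of the kind used in small-grain cereal breeding
(multi-parent designs of partially connected biparental families, scored
repeatedly as the crop develops).

Many agronomic traits are *dynamic*: the loci steering a plant's development
when awns emerge need not be the loci steering late flowering or grain
filling. `dynqtl` implements the full analysis chain for such data —

1. **Population and phenotype simulation**: partially connected DH families
   from homozygous parents (one meiosis per line, Haldane map function,
   dominant-scored 0/1 markers on a multi-linkage-group cM map), and
   plot-level phenotypes with stage-specific QTL, epistasis, polygenic
   background, genotype-by-environment (GxE) interaction and plot error.
2. **Phenotype reduction**: per-line BLUEs across environments
   (`y ~ line + environment` by least squares), REML variance components and
   entry-mean heritability, inter-stage correlations.
3. **Multi-family association scan**: for each marker *q*, the model

   `Y = 1 mu + X_f M_f + X_q b_q + sum_{c != q} X_c b_c + e`

   with a family effect `M_f`, stepwise-selected cofactors `X_c` (Schwarz
   Bayesian Criterion, `SBC = n ln(RSS/n) + k ln(n)`), a 1-df F test of the
   allele-substitution effect `b_q`, and Bonferroni–Holm control of the
   family-wise error.
4. **Epistasis scan**: a full two-dimensional scan of marker pairs testing
   the interaction term `X_qq' b_qq'` at the region-pair Bonferroni threshold
   `alpha / choose(2L, 2)` for `L` linkage groups (with `L = 22`,
   `0.05/946 ≈ 5.3e-5`).
5. **Explained genotypic variance**: `p_G = 100 * R2_adj / h2`, with
   per-QTL sequential partial R² from a simultaneous fit (most significant
   markers first).
6. **Fivefold cross-validation**: the whole detection pipeline re-run on
   estimation sets, validated on held-out test sets, yielding
   asymptotically unbiased `p_G` and the *relative bias*
   `100 (p_G-ES − p_G-TS) / p_G-ES` of in-sample estimates.
7. **Dynamic layer**: QTL matched across stages within a cM window
   (single-linkage regions), Venn partition of stage membership, scans of
   the progression trait `Δ = BLUE(t+1) − BLUE(t)`, and a report of QTL
   whose effect sign flips between stages.

Everything is tibble-in / tibble-out and pipes cleanly; fitted results have
`tidy()` / `glance()` methods and `autoplot()` / `plot_*()` figures.

## Worked example

Simulate the default study preset — 647 DH lines in four partially connected
families (131/120/200/196) from six parents, ~1000 markers on 22 linkage
groups, three developmental-stage traits (DS1–DS3, BBCH-like scores near
49/69/81) in 4 environments — and run the DS1 scan:

```r
library(dynqtl)

sim <- simulate_study(default_study_preset(), seed = 42)

variance_components_table(sim$phenotypes, lrt = FALSE)
#>   stage sigma2_G sigma2_GxE sigma2_eps    h2
#> 1 DS1       3.27      0.745      0.779 0.900
#> 2 DS2       3.64      1.27       1.16  0.863
#> 3 DS3       3.31      2.91       2.49  0.720

blues <- compute_blues_wide(sim$phenotypes)
stage_correlations(blues)
#>   stage_a stage_b     n     r         p
#> 1 DS1     DS2       647 0.849 1.32e-180
#> 2 DS1     DS3       647 0.675 2.52e- 87
#> 3 DS2     DS3       647 0.728 7.33e-108

b1 <- blues[, c("line", "family", "DS1")] |> setNames(c("line", "family", "blue"))
scan1 <- association_scan(b1, sim$genotypes, sim$map)
glance(scan1)
#>   stage m_tested n_significant n_cofactors alpha
#> 1 DS1       1000            13          20  0.05

head(tidy(scan1)[order(tidy(scan1)$p), c("marker", "group", "pos_cM", "beta", "p")], 5)
#>   marker group pos_cM   beta        p
#> 1 6R_016 6R      55.7  1.20  5.05e-14
#> 2 2B_023 2B      58.6  0.991 8.59e-12
#> 3 4R_027 4R      59.0  0.997 1.13e-11
#> 4 1A_025 1A      59.9  0.915 4.21e-10
#> 5 2B_024 2B      61.4 -1.11  2.36e- 9
```

The 13 Holm-significant markers at DS1 sit on the simulated QTL groups (1A,
2B, 4R, 5R, 6R, 6A plus the epistatic pair's groups); the top markers are
the causal ones or their immediate neighbours, and the allele-substitution
effects (`beta`, in BBCH units per allele dose) recover the simulated sizes.
Accounting for the genotypic variance they explain:

```r
h2 <- variance_components_table(sim$phenotypes, lrt = FALSE)$h2[1]
sig <- scan1$marker[scan1$significant & is.na(scan1$duplicate_of)]
shares <- sequential_partial_r2(b1, sim$genotypes,
                                scan1[match(sig, scan1$marker), c("marker", "p")],
                                h2 = h2, map = sim$map)
attr(shares, "account")
#> p_G (DS1): 43.5%  (R2adj = 0.391, h2 = 0.900)
```

i.e. the detected markers explain 43.5% of the genotypic (not phenotypic)
variance at DS1. `run_cv()` then quantifies how optimistic such in-sample
numbers are, `scan_pairs()` hunts interaction QTL, and `match_regions()` /
`venn_counts()` / `progression_scan()` / `sign_change_report()` describe how
the architecture shifts between stages. `run_pipeline()` chains all of it
from TSV inputs to a directory of audited result tables, and
`inst/cli/dynqtl.R` exposes the same steps as shell subcommands.

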