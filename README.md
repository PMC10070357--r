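# mfdburst

Burst analysis for diffusion-based single-molecule FRET (smFRET) with
multiparameter fluorescence detection (MFD) and pulsed interleaved
excitation (PIE).

In these experiments single labeled molecules (for example a GPCR in a
lipid nanodisc, carrying a donor and an acceptor dye) diffuse through a
confocal spot in ~1–10 ms, emitting a burst of photons. Each photon is
tagged with its arrival time, its TCSPC delay with respect to the laser
pulses, its spectral band and its polarization. From these four
dimensions the package reconstructs, per molecule, the corrected FRET
efficiency

&nbsp;&nbsp;&nbsp;&nbsp;*E* = (F_BR − ct·F_BB − de·F_RR) / (γ·F_BB + F_BR − ct·F_BB − de·F_RR)

and stoichiometry *S* (crosstalk *ct*, direct excitation *de*, detection
factors γ and β), fluorescence lifetimes by maximum likelihood,
steady-state anisotropies, and then asks the central question: are the
molecules static, or do they exchange between conformational states on
the microsecond–millisecond timescale? Four complementary indicators
answer it:

* the **static FRET line** in the E-vs-donor-lifetime plane with a
  simulation-based significance test for lifetime shifts,
* **FRET-2CDE**, a kernel-density score that marks within-burst FRET
  fluctuations (≈10 for static molecules) with a photon re-coloring
  null,
* **burst variance analysis (BVA)** against the binomial shot-noise
  expectation √(PR(1−PR)/n),
* **species-filtered FCS (fFCS)**: statistical unmixing of the photon
  stream into low-FRET/high-FRET pseudo-species and cross-correlation,
  whose anticorrelation term carries the exchange relaxation time
  τ_ex = 1/(k12+k21),

and **dynamic photon distribution analysis (PDA)** finally quantifies
state populations by fitting FRET-efficiency histograms at several bin
durations with an exact shot-noise/background forward model that includes
two-state exchange within bins (occupancy-time distribution in closed
form, modified Bessel functions).

A forward Monte-Carlo generator (`simulate_mfd()`, `simulate_bursts()`,
`generate_reference_dataset()`) produces photon streams with known ground
truth — Brownian transits of the 3D Gaussian spot, Markovian state
kinetics, lifetimes, polarization, crosstalk, background — so every stage
of the pipeline is testable without instrument data.

## A worked example

```r
library(mfdburst)

## simulate a full-agonist-like condition: static low-FRET state (E = 0.2,
## 15 %) plus a medium/high-FRET pair (E = 0.5 / 0.8) exchanging with
## tau_ex = 390 us, high-FRET population 0.76
ref <- generate_reference_dataset("full_agonist", n_target_bursts = 500, seed = 1)
ps  <- ref$stream

bursts <- find_bursts(ps)                       # 500-us sliding window search
bt <- analyze_bursts(ps, bursts, sim_config()$corrections)
table(bt$species)
#>       double unclassified
#>          458          122
dbl <- bt[bt$species == "double", ]
round(c(E = mean(dbl$E), S = mean(dbl$S), tau_D = mean(dbl$tau_D_ns, na.rm = TRUE)), 3)
#>     E     S tau_D
#> 0.673 0.509 1.595
```

The mean corrected E of 0.67 reflects the population-weighted average of
the three states (0.15·0.2 + 0.09·0.5 + 0.76·0.8 ≈ 0.68 with burst-level
scatter); S centres at 0.5 because the true β was applied; the mean donor
lifetime is strongly quenched relative to the 3.8 ns donor-only lifetime,
as expected at high FRET. Static molecules would score FRET-2CDE ≈ 10;
here the exchanging pair adds real within-burst FRET dynamics:

```r
round(mean(bt$fret_2cde, na.rm = TRUE), 2)
#> [1] 11.78
```

From here, `fret_2cde_null_test()`, `bva()` and `lifetime_shift_test()`
flag the dynamics as significant, `build_species_patterns()` /
`compute_filters()` / `filtered_correlation()` / `fit_ffcs_model()`
extract the exchange time, and `bin_bursts()` / `fit_pda()` recover the
state populations. `run_pipeline()` chains all stages for a multi-
condition comparison. The methods vignette
(`vignettes/mfd-burst-analysis.Rmd`) documents every model and default.

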