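---
title: "Models and methods behind mfdburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mfdburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mfdburst` implements the complete burst-wise analysis chain for
diffusion-based single-molecule FRET experiments recorded with
multiparameter fluorescence detection (MFD) and pulsed interleaved
excitation (PIE), together with a forward Monte-Carlo photon-stream
generator that makes every stage verifiable against known ground truth.
This vignette explains the models, the tunable parameters, and the design
choices where several defensible options existed.

## The measurement model

A confocal microscope records photons from single labeled molecules
diffusing through a diffraction-limited spot approximated by a 3D Gaussian
with half-widths 0.5, 0.5 and 2 micrometres. Two interleaved pulsed lasers
(sync rate 26.67 MHz, pulses 18 ns apart) alternately excite the donor and
the acceptor dye; four detectors split the emission by spectral band (blue
B / red R) and polarization (parallel/perpendicular). Every photon carries
a macrotime (sync count), a microtime (TCSPC delay within the 37.5 ns sync
period) and a detector label. The microtime decides which laser excited
the molecule, yielding six live PIE gates: BB (donor emission after donor
excitation), BR (acceptor emission after donor excitation -- FRET,
crosstalk and direct excitation) and RR (acceptor emission after acceptor
excitation), each split by polarization. The default gate boundaries put
the donor-excitation window at [0, 18) ns and the acceptor-excitation
window at [18, 37.5) ns; the instrument literature states only the 18 ns
inter-pulse delay, so both windows are configurable. Blue-detector photons
in the acceptor window fall in a physically dark channel and are
discarded. Internally both times are exact integers (sync counts, TCSPC
bins; 4096 bins per period by default), so file round trips are
bit-faithful; the plain-TSV interchange layout is documented in
`?read_photons`.

## Burst search and per-burst photometry

The all-photon burst search uses a 500 microsecond sliding window centred
on each photon: a photon is eligible when at least 5 photons (all gates)
fall in the closed window; maximal runs of consecutive eligible photons
are candidate bursts (runs also terminate across inter-photon gaps longer
than the window, which cannot be bridged by any window); bursts keep at
least 50 photons and a duration of at most 20 ms.

With background-corrected gate counts $F_X = S_X - B_X$, the corrected
FRET efficiency and stoichiometry are

$$E = \frac{F_{BR} - ct\,F_{BB} - de\,F_{RR}}
           {\gamma F_{BB} + F_{BR} - ct\,F_{BB} - de\,F_{RR}}, \qquad
  S = \frac{\gamma F_{BB} + F_{BR} - ct\,F_{BB} - de\,F_{RR}}
           {\gamma F_{BB} + F_{BR} - ct\,F_{BB} - de\,F_{RR} + F_{RR}/\beta}.$$

The package uses the convention in which the red-excitation term enters
the stoichiometry as $F_{RR}/\beta$. This is the convention under which
(i) double-labeled molecules centre at $S \approx 0.5$ when the true
$\beta$ is applied, and (ii) the calibration identities
$\Omega = 1 + \gamma\beta$, $\Sigma = \beta(1-\gamma)$ hold for the
straight-line relation $1/S = \Omega + \Sigma E$ fitted on
crosstalk/direct-excitation-corrected quantities
(`fit_correction_factors()`), from which
$\gamma = (\Omega-1)/(\Omega+\Sigma-1)$ and $\beta = \Omega+\Sigma-1$.
Typical factors for the modelled instrument are $ct = 0.0059$,
$de = 0.024$, $\gamma = 0.69$, $\beta = 1.9$, $G_B = 0.99$, $G_R = 1.13$.
The regression axis (1/S on E, or E on 1/S and inverted) is selectable;
1/S on E is the default.

Burst-wise fluorescence lifetimes maximise a single-exponential likelihood
truncated to the gate window plus a flat background fraction; the
instrument response is treated as a delta at the gate origin, adequate for
lifetimes well above the TCSPC bin width. Steady-state anisotropies use
$r = (G F_\parallel - F_\perp)/(G F_\parallel + 2 F_\perp)$. Species
selection applies the conventional MFD-PIE windows (see
`?select_species`) on ALEX-2CDE, E, S, lifetimes and anisotropies; all
window tests are strict inequalities.

## Dynamics indicators

*Static FRET line.* For a single conformation whose apparent
donor-acceptor distance fluctuates rapidly with Gaussian width
$\sigma$ = 6 Å (dye linkers) around a centre value, the locus of
(intensity-averaged E, intensity-weighted donor lifetime) bends away from
the ideal line $E = 1 - \tau/\tau_{D0}$; `static_fret_line()` computes it
by quadrature (Förster distance $R_0$ = 49 Å, donor-only lifetime 3.8 ns
by default). The lifetime-shift test groups double-labeled bursts into 50
equal E intervals (at least 200 bursts per analysed group), inverts the
linker-averaged E(R) per burst by bisection (tolerance 1e-4 in E),
simulates per-photon distances, efficiencies and exponential delays, and
compares the experimental intensity-weighted lifetime
$\tau_{INT} = \sum t_{ij}(1-E_{ij}) / \sum (1-E_{ij})$ with the simulated
Bonferroni-corrected confidence band (default 100 replicates,
$\alpha$ = 0.001). Experimentally the per-photon FRET efficiency is not
observable, so the experimental weights use the burst E; the simulation
uses per-photon values, matching the estimator's form.

*FRET-2CDE.* Kernel density estimators with a 100 microsecond
exponential kernel over the donor-excitation photons give per-photon
FRET estimates whose burst average scores static molecules near 10
regardless of E; the neighbour-exclusion factor $(1 + 2/N)$ removes the
self-count bias. The null test re-colors each burst's photons with its own
acceptor-photon fraction (destroying within-burst FRET fluctuations while
preserving times and mean color), builds group-weighted scores
$110 - 100(\sum N_D \langle E_D\rangle/\sum N_D + \sum N_A \langle
(1-E)_A\rangle/\sum N_A)$, and flags groups exceeding the
Bonferroni-corrected bound. ALEX-2CDE applies the same kernel machinery
across the donor-excitation and acceptor-excitation streams, scoring
stoichiometry fluctuations (bleaching, blinking); the cited-literature
definition is used since the primary source names but does not print it.

*BVA.* Bursts are cut into consecutive 5-photon windows; the pooled
standard deviation of window proximity ratios per PR group (20 groups,
more than 100 bursts each) is compared with the binomial expectation
$s = \sqrt{PR(1-PR)/5}$ and a simulated static confidence band with
matched window counts. Group PRs convert to corrected E through the
closed-form proximity-ratio relation (`pr_to_efficiency()`).

## Species-filtered FCS

The four donor-excitation gates, each rebinned to 32 microtime bins, are
stacked into one 128-channel axis. Reference patterns for the low-FRET
(E < 0.3 bursts) and high-FRET (E > 0.7 bursts) pseudo-species -- and, by
default, a background pattern estimated from out-of-burst photons, so that
background load does not bias the species channels -- give statistical
filters via the variance-weighted pseudo-inverse
$F = (P^TWP)^{-1}P^TW$, $W = \mathrm{diag}(1/S_j)$. The coarse microtime
rebinning deliberately trades lifetime resolution for filter noise; 32
bins per gate is the default. Filter-weighted photon streams are
correlated on a multi-tau grid (14 cascades of 8 lags, finest bin 2
microseconds) within a 10 ms window around the selected bursts; both
cross directions are averaged. Error bars are the scatter of ten
equal-photon-count segments; the fitting weights use a
leave-one-segment-out jackknife of the pooled sums, which stays well
conditioned when single segments hold few photons of a sparse species.

Cross-correlations are fitted with
$G(\tau) = G_{diff}(\tau)\,(1 - \sum_i A_i e^{-\tau/\tau_i}) + y_0$,
$G_{diff}(\tau) = \frac{1}{\sqrt8 N}\left[(1+\tau/\tau_{diff})
\sqrt{1+\tau/(p^2\tau_{diff})}\right]^{-1}$ with aspect ratio $p = 4$
from the spot geometry, the diffusion time shared globally across
conditions. Amplitudes are bounded in (0, 2) -- a strongly
anti-correlated species pair pushes the short-lag curve below zero --
and the anticorrelation and diffusion times are box-constrained to the
window the lag grid resolves, with a small multi-start grid guarding
against the local optimum in which an anticorrelation term collapses into
a pure amplitude rescaling. Confidence intervals come from the numerical
Jacobian at the optimum. In burst-restricted sub-ensemble correlation the
effective diffusion term is shaped by burst selection as much as by free
diffusion; for that reason exchange times are extracted from a global fit
in which a condition without sub-millisecond exchange (or the static
species' autocorrelation) pins the diffusion term, mirroring standard
practice.

## Dynamic photon distribution analysis

Bursts are re-cut into bins of 0.5, 1 and 2 ms; bins keep 20 to 300
donor-excitation photons and an uncorrected stoichiometry between 0.2 and
0.6. The forward model conditions on each bin's observed photon number:
static states are Gaussian distributions of apparent distance (global
means and widths), mapped through the crosstalk/direct-excitation/gamma
rates to an acceptor-photon probability; counts are binomial, convolved
with the Poisson background of both donor-excitation gate groups, and
pushed through the same counts-to-E mapping as the data (the
direct-excitation term uses the dataset-average red-excitation counts, so
the mapping is a deterministic function of the count pair). A dynamic
two-state pair integrates additionally over the occupancy-time
distribution of the exchange within the bin -- two no-transition atoms
plus a continuous part with the modified-Bessel closed form, derived by
Poisson counting on the per-state occupation clocks -- with fixed
exchange time and a fitted forward/backward ratio. The expected histogram
is assembled from tables of $P(E\ \mathrm{bin} \mid N, \varepsilon)$
precomputed on an acceptor-probability grid (101 points, linear
interpolation), making a model evaluation cheap enough for the
chi-square-guided simplex search (iterated Nelder-Mead with jittered
multi-starts and a strict distance-ordering constraint that pins state
identities). The Poissonian reduced chi-square is evaluated over occupied
histogram bins.

Because photons sample the conformational trajectory in proportion to the
time-varying detection rate of a diffusing molecule, exchange averaging
inside a bin is governed by an effective window somewhat shorter than the
nominal bin duration. `pda_effective_duration()` measures the pairwise
exponential-kernel statistic of each bin's photon arrival times at the
exchange timescale and converts it into the uniform-window equivalent;
the dynamic pair is evaluated on that effective duration. The correction
is estimated from the data alone.

## The synthetic-data generator

The generator is a forward Monte-Carlo of the whole measurement: Brownian
paths (default D = 40 um^2/s, giving a ~1.6 ms lateral diffusion time, in
the middle of the 1-10 ms residence range typical for nanodisc-embedded
receptors) in reflecting boxes whose volume keeps the mean number of
simultaneously excited molecules below 0.1 (single-molecule regime);
Markov-chain conformational state paths; photon emission by Poisson
thinning on a 1 microsecond grid with per-photon apparent-distance draws
(fast-linker limit), crosstalk, direct excitation, gamma/beta detection
factors, truncated-exponential microtimes (donor lifetime quenched as
$\tau_{D0}(1-E)$, FRET photons additionally delayed by the acceptor
decay), per-photon polarization from the steady-state anisotropy, and
per-gate Poisson background. Rare far-field excursions are propagated on
a 64-fold coarser grid and refined by Brownian bridges only near the
focus, where the excitation weight exceeds about 1e-4; the neglected
far-field emission is below ten photons per second and never
burst-relevant. Free parameters never printed for the modelled
instrument -- brightness (1e5 detected donor-scale photons/s at the spot
centre), background (1 kHz per gate), donor-only lifetime 3.8 ns,
acceptor lifetime 1.7 ns, steady-state anisotropies 0.2/0.25 -- are
declared defaults, chosen once as realistic values for this class of
experiment.

The three-state receptor scenarios place a static low-FRET state at
E = 0.20 and an exchanging medium-FRET/high-FRET pair at E = 0.50/0.80
(consistent with the pattern-building thresholds E < 0.3 and E > 0.7);
the static fraction is 0.15 (middle of the 10-20% range), the high-FRET
population is 0.20 (apo, antagonist; exchange relaxation 200 ms, i.e.
effectively frozen on the burst timescale), 0.56 (partial agonist) or
0.76 (full agonist), the agonist exchange relaxation time is 390
microseconds. Kinetic schemes are allocated to molecules by stratified
largest-remainder sampling so that a handful of molecules already
realises the nominal composition. What the generator does not emulate:
detector dead time and afterpulsing, a measured instrument response
function (microtimes start at the gate origin), rotational-diffusion
photon-by-photon depolarization (the anisotropy module's fixtures use a
dedicated time-dependent generator, `simulate_polarized_decay()`),
acceptor photobleaching, and spectral fluctuations beyond the optional
two-state microsecond blinking model. Passing tests therefore validate
the estimators under the stated statistical model, not under every
instrumental artefact of real recordings.

Because the generator draws apparent distances per photon, FRET
histograms are shot-noise limited at the linker-averaged acceptor
probability; the quasi-static Gaussian widths fitted by PDA on such data
legitimately shrink towards zero while state means and populations retain
their meaning.

## Time-resolved anisotropy

Polarized microtime histograms of single-labeled bursts give
$r(t) = (G F_\parallel(t) - F_\perp(t))/(G F_\parallel(t) + 2F_\perp(t))$
with the time origin at the decay peak. The biexponential model
$r(t) = ((r_0 - r_p)e^{-t/\rho_F} + r_p)\,e^{-t/\rho_p}$ is fitted by
weighted least squares (weights $G F_\parallel + 2F_\perp$, which make
the count-weighted time average of $r(t)$ identical to the steady-state
anisotropy of the same photons); the slow whole-particle time $\rho_p$ is
bounded below at 10 ns and reported as "beyond the bound" when it runs
into the upper limit. The printed form of this model in parts of the
literature carries $+ r_0$ inside the bracket, which would give
$r(0) = 2r_0 - r_p$; the standard form above is implemented. The residual
anisotropy converts to a wobbling-in-a-cone semi-angle by the positive
root of $\cos\theta(1+\cos\theta)/2 = \sqrt{r_p/r_0^*}$ with the rigid
reference $r_0^* = 0.4$.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the package's own working points: null-calibration datasets of about 260
bursts with at least 100 donor-excitation photons each; oracle
equivalence of the burst search and the correlator on streams of a few
hundred photons over 20 random seeds; correction-factor recovery from 600
bursts spanning six FRET efficiencies; PDA property checks on 10^4
model-drawn bins; and a full-pipeline parameter recovery from roughly
3000-burst reference datasets for the full-agonist and apo scenarios,
fitted globally. The reference datasets for the recovery checks use a 2
microsecond propagation step (the emission model is insensitive to the
step at these rates, since states and microtimes are drawn at exact
photon times) and analyse all found bursts -- every simulated molecule is
double-labeled by construction, so the single-molecule species filter
would only thin valid bursts. Occupancy-time quadrature uses 33
Gauss-Legendre nodes (validated against a Monte-Carlo CTMC oracle to
sup-norm 0.015 at 2 x 10^4 paths); Gaussian distance integration uses 17
nodes over +/-5 sigma; the PDA acceptor-probability tables use 101 grid
points with Poisson background tails truncated at 1e-6 mass. Exchange
times are reported in the units of the fitted lag axis (seconds), cone
angles in degrees, distances in Angstrom, lifetimes in nanoseconds.

## Known limitations

The fFCS exchange-time estimate from a single ~3000-burst dataset carries
a wide confidence interval; the global multi-condition fit is the
intended mode of use. The PDA forward model ignores residual intra-bin
intensity-weighting effects beyond the effective-duration correction and
assumes equal state brightness. Burst-search and species-selection
windows are the published conventions and are not auto-tuned. Vendor
raw TTTR formats are out of scope; use existing converters to the
documented TSV layout.
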