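---
title: "Wavelet-packet super-resolution and automated mixture analysis for 1H NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-packet super-resolution and automated mixture analysis for 1H NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wptmix)
```

## The scientific problem

A 1D proton NMR spectrum of a small molecule is, to good approximation, a
sum of Lorentzian lines. Scalar (J) coupling splits the resonance of each
chemically distinct proton site into a multiplet — a doublet, triplet,
quartet, ... — of lines spaced by the coupling constant (a few Hz, i.e. a
few thousandths of a ppm at 500 MHz) with binomial intensity ratios. In a
mixture of molecules these multiplets interleave and overlap, which is the
central obstacle to answering the question this package automates: *which
library molecules are present in a measured mixture spectrum?*

The approach taken here removes the coupling fine structure numerically.
Repeatedly low-pass filtering a spectrum with the analysis branch of a
wavelet filter bank replaces each multiplet by a single smooth peak at the
multiplet centre — the spectrum one would obtain if every site were an
uncoupled singlet. Working with these collapsed "WPT spectra" (and their
sparse peak lists, the "shift spectra") turns mixture analysis into a
far better conditioned matching and unmixing problem.

## The wavelet engine

### Filter bank

The package implements the Daubechies-9 (db9) orthogonal filter bank: an
18-tap extremal-phase low-pass filter $h$ (embedded as published
constants), its quadrature mirror high-pass $g_k = (-1)^k h_{L+1-k}$, and
the time-reversed pair for synthesis. One analysis step extends the signal
symmetrically by $L-1 = 17$ samples on each side (half-point reflection),
convolves, and keeps every second sample. `wpt_analyze_step()` /
`wpt_synthesize_step()` invert each other to machine precision
(`test-wpt.R` checks $10^{-8}$; the observed error is $\sim 10^{-15}$),
and `wpt_decompose()` is verified against an independently written
direct-convolution oracle at $10^{-10}$.

Only the approximation (low-pass) cascade feeds the downstream analysis:
the detail channels carry the coupling structure we want removed, and are
kept purely as diagnostics. Coefficient amplitudes are rescaled by
$2^{-\mathrm{level}/2}$ so a flat signal keeps its value, and each
decimated coefficient is assigned the chemical shift of the centre of its
support through the filter's group delay so peak positions survive
decimation.

### Why the smoothing is computed without decimation

At a typical digital resolution of 4096–8192 points over 10 ppm, a 1.5 Hz
line spans only about two samples. The decimated approximation
coefficients of such a narrow line sample the *oscillatory scaling
function* of the db9 filter rather than its smooth envelope, so an
interpolated decimated spectrum looks jagged and peak counting on it is
unstable. `wpt_spectrum()` therefore evaluates the identical repeated
low-pass filter as a shift-invariant ("à trous") cascade: at stage $j$ the
filter is upsampled by $2^{j-1}$ and applied without downsampling. The
result is exactly the smooth envelope that the decimated coefficients
subsample, on the original grid.

Because db9 is extremal-phase (maximally asymmetric), compensating each
stage by the filter's nominal group delay would still leave a
level-dependent drift of narrow-line apexes. Each stage is instead aligned
on the apex of the cumulative equivalent kernel (located once, with
parabolic refinement, and cached), which pins singlet positions to within
$\sim 0.007$ ppm up to level 7. A side effect of the asymmetric kernel is
a chain of small satellite bumps (15–20 % of the parent height) a few
kernel widths to the left of every strong peak; peak counting suppresses
any local maximum below $0.3\times$ a taller peak within $6 \cdot 2^L$
grid steps, a window that scales with the kernel width.

### Choosing the decomposition level

The depth of the cascade is the one free parameter, and it is selected per
spectrum by counting prominent local maxima above 5 % of the maximum at
every level (`wpt_select_level()`):

* While couplings are being smoothed out the count falls level by level.
* Once every multiplet has collapsed the count is *stable* for several
  consecutive levels — the kernel is wider than any coupling pattern but
  still narrower than the distance between chemically distinct sites.
* Much deeper, unrelated sites merge and the count falls again.

The selected level is the start of the earliest constant-count run (of
length at least two) whose count lies below the raw-spectrum count, then
advanced within that run to the first level whose above-threshold regions
are literally unimodal, since a just-merged doublet can keep a shallow
double apex for one extra level. A spectrum of pure singlets never drops
below its raw count and selects level 1. Densely crowded spectra — such
as mixtures of many molecules — may show no stable run at all because
multiplet collapse blends directly into site merging; the count curve
then decreases at every level, quickly while couplings vanish and slowly
afterwards, and the selection falls back to the elbow (the maximum second
difference) of the curve. On the synthetic benchmark this places pure
molecules at levels 2–5 and mixtures at levels 3–5, and the elimination
stage below tolerates a mixture level that is off by one in either
direction because matching works on peak positions with a 0.02 ppm
tolerance — wider than any coupling offset it might leave behind.

## The synthetic generator and its limits

`generate_library()` draws molecules with 2–8 multiplets (multiplicities
1–4, couplings 4–12 Hz, relative amplitudes 0.3–1) at centres kept 0.25
ppm apart within a molecule, and simulates each spectrum as a sum of
Lorentzians (1.5 Hz full width) on its own 4096–8192-point grid over
0–10 ppm. `generate_augmented_dataset()` mixes max-normalized components
with proportions drawn from [0.15, 0.4] and renormalized to sum to one,
then adds Gaussian noise relative to the mixture maximum. Everything is
reproducible from one master seed; per-mixture seeds are derived with an
integer hash so datasets are stable under partial regeneration.

Known idealisations: lines are pure Lorentzians with a single global
linewidth; multiplets are strictly first order (binomial intensities, no
roofing or strong coupling); baselines are flat; chemical shifts do not
respond to concentration, pH or temperature; and 4096–8192 points over
10 ppm (0.6–1.2 Hz per point) is coarser than a real high-field spectrum,
which the shift-invariant smoothing tolerates but which leaves only a few
samples per line. Real spectra will also violate the implicit assumption
that a molecule's peak pattern in a mixture equals its pure-spectrum
pattern.

## The four-step composition analysis

`analyze_mixture()` runs, per mixture:

1. **Conversion.** Max-normalize, select the level, compute the WPT
   spectrum $Y_2$ and its peak list (the shift spectrum).
2. **Matching (L I).** For every library molecule, the fraction $p/n$ of
   its $n$ shift peaks lying within 0.02 ppm of some mixture shift peak is
   its presence probability; molecules with $p > 0$ form candidate list
   L I.
3. **Elimination (L II).** On the grid of mixture shift-peak positions,
   build the design matrix $X$ whose column $j$ holds candidate $j$'s
   nearest-peak heights (zero outside the candidate's own spectral
   domain), and minimise $J(\Theta) = \sum (Y - X\Theta)^2 / m$ by
   gradient descent (fixed learning rate 0.1, null start, weights
   projected onto $\Theta \ge 0$). Candidates with non-zero weight
   survive. This step is conservative by construction — a true component
   always has peaks to explain, so at zero noise it is never eliminated
   (verified over 50 random mixtures) — while it removes the bulk of the
   spurious matches.
4. **Identification.** The top 15 of L II are refit against the *full*
   WPT curve (columns are the candidates' WPT spectra interpolated onto
   the mixture grid) with the learning rate redrawn uniformly from
   [0.01, 0.1] at every iteration — a cheap stochastic perturbation that
   de-correlates near-collinear candidates; it is seeded, so predictions
   are bit-reproducible. Weights above 0.1 form the final composition.

Internally the optimiser rescales every column to unit maximum so a single
learning rate works across heterogeneous intensity scales, and returns
weights on the original scale; with the $2/m$ gradient normalisation a
rate of 0.1 is comfortably below the stability bound for both design
matrices. Unconstrained runs agree with the normal-equations solution to
$10^{-4}$ (tested), and a tenfold cost increase aborts with a divergence
error rather than returning noise.

## Performance on the packaged benchmark

`standard_benchmark(seed)` reproduces the full study protocol: a
74-molecule library, a 20-molecule mixing subset (so 54 molecules are
known true negatives), 100 mixtures of 3–7 molecules, 0.5 % noise. With
`seed = 1` the medians are: final-stage true positive rate 1.0 with false
positive rate 0.00 (mean 0.01), elimination-stage true positive rate 1.0
with false positive rate 0.36, and the final false positive rate is
below the elimination-stage one in every mixture — the identification
step is what buys precision. Even the hardest 7-molecule stratum keeps a
median true positive rate of 1.0. A raw-spectrum matcher
(`baseline_direct_match()`) is included for before/after comparisons.

These numbers come from a synthetic library whose shifts are drawn almost
uniformly; real molecule libraries concentrate their resonances in
crowded regions and share common fragments, so false positive rates on
real data should be expected somewhat higher (a few false assignments per
mixture) at the same true positive rate.

## Reproducing the numbers

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

writes the five headline medians (final/elimination-stage TPR and FPR,
plus the 7-molecule-stratum TPR) computed from a fresh run of
`standard_benchmark()`. The same protocol is exposed on the command line
(`wptmix benchmark`), alongside `wptmix simulate`, `wptmix build-library`
and `wptmix analyze` for file-based workflows.
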