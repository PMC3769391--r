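---
title: "Methods: single-trial phase coupling and hyper-brain graph analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-trial phase coupling and hyper-brain graph analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperbrain)
```

## The problem

When two people interact — playing music together, coordinating movements —
their EEG signals can exhibit phase relationships both within each brain and
*between* the two brains.  `hyperbrain` implements a complete analysis chain
for such dual-EEG (hyperscanning) data: single-trial phase-synchronization
measures computed from instantaneous Morlet-wavelet phases, surrogate-based
significance thresholding, and graph-theoretic characterization of the joint
"hyper-brain" network whose nodes are the electrodes of *both* participants
(42 nodes for two 21-channel montages).

Because no public dual-EEG dataset accompanies the design this package
follows, a coupled-oscillator generator (`generate_oscillator_pair()`,
`generate_hyper_brain_dataset()`) provides controlled synthetic data for
validation and testing.

## Phase extraction

Each channel of each epoch is convolved with an analytic complex Morlet
kernel

$$\psi_f(t) = e^{i 2\pi f t}\, e^{-t^2 / (2\sigma^2)},$$

and the instantaneous phase at frequency $f$ is the argument of the complex
coefficient.  Coefficients are evaluated every `step` samples (default 5;
at 250 Hz this is a 20-ms coefficient interval).  Defaults analyse the 17
frequencies of interest 2–28 Hz.

Tunable parameters:

* `cycles` (default 7): the envelope width is $\sigma = c/(2\pi f)$, a
  standard convention giving frequency-proportional bandwidth.  The source
  design does not state $\sigma$; 7 cycles is a common EEG choice balancing
  time against frequency resolution, and it is configurable.
* **Edge handling**: coefficients within $c/(2f)$ seconds of an epoch
  boundary are flagged invalid and excluded from every coupling statistic,
  because the convolution there mixes in zero-padding.  The normalizing
  count $k$ below always refers to *valid* coefficient times.
* **Wrapping**: all phases and differences live in $(-\pi, \pi]$
  (`wrap_pi()`), everywhere.

## The five coupling measures

For an ordered channel pair $(m, n)$, $\Delta\varphi_{mn}(t, f) =
\mathrm{wrap}(\varphi_m - \varphi_n)$; positive values mean $m$ leads.

* **PSI** — mean resultant length $\bigl|\tfrac1k \sum_t e^{i\Delta\varphi}\bigr|$:
  phase *stability* across time, blind to the preferred angle.
* **Coding** — each time point is coded $+1$ if $\Delta\varphi \in [0, \pi/4)$,
  $-1$ if $\Delta\varphi \in (-\pi/4, 0)$, else $0$ (non-synchronization).
* **Cleaning** — maximal same-sign nonzero runs shorter than one period
  $T = 1/f$ are recoded to 0, removing "accidental" synchronization.  A run
  of $r$ points counts as $r \cdot \mathrm{interval}$ seconds of locking;
  at $f = 10$ Hz and a 20-ms interval, runs of 4 points are discarded and
  runs of 5 or more survive.
* **PCI / NCI / ACI** — fractions of $+1$, $-1$, and either code among the
  $k$ valid points; ACI = PCI + NCI is symmetric, and exactly
  $\mathrm{PCI}_{mn} = \mathrm{NCI}_{nm}$.
* **ICI** — the directed index $\mathrm{ICI} = \mathrm{PCI}/(1 + \mathrm{NCI})$.

### Design choices worth knowing

* **ICI transcription.** The algebraic form of ICI was fixed here from its
  documented behaviour: ICI $= 1$ when all points are positive-locked;
  when all locked points are negative an intermediate term approaches $0.5$
  and multiplication drives ICI to 0; range $[0, 1]$; asymmetric under pair
  reversal.  $\mathrm{PCI}/(1+\mathrm{NCI}) = \mathrm{PCI} \cdot
  \tfrac{1}{1+\mathrm{NCI}}$ is the simple rational form meeting every one
  of these constraints — the factor $1/(1+\mathrm{NCI}) \in [0.5, 1]$ is
  exactly the term that approaches $0.5$.  The boundary identities are
  enforced by tests regardless of transcription.
* **Coding boundaries.** $\Delta\varphi = 0$ exactly is assigned to the
  positive bin; $\pm\pi/4$ exactly code 0.  Both are measure-zero events on
  continuous data; the choice is documented for bit-exactness.  (It is also
  why the mirror identity PCI$_{mn}$ = NCI$_{nm}$ could in principle break
  at $\Delta\varphi \in \{0, \pi\}$ — never observed on real-valued input.)
* **$k$ is the count of valid coefficient times**, not of surviving locked
  points, so cleaning can only decrease PCI/NCI/ACI.
* **Cleaning applies to the coded indices only**; PSI is computed from the
  raw phase differences.

## Surrogate thresholding

Surrogates are built by independently permuting every channel's samples
within every epoch (`shuffle_surrogate()`): all temporal structure is
destroyed, amplitude histograms are preserved exactly.  The identical
spectral + coupling chain runs on the surrogate, and values are pooled per
measure × FOI across all pairs and epochs — a single global threshold per
measure and FOI.  Only values *strictly greater* than the threshold become
edges.

`estimate_threshold()` offers two readings of "bootstrap mean plus
confidence interval at $p < 0.0001$" (1,000 resamples by default):

* `method = "quantile"` (default): mean over bootstrap resamples of each
  resample's $(1-\alpha)$ value-quantile.  This controls the *per-pair*
  false-positive rate at about $\alpha$ and produces the sparse,
  highly-reliable networks the procedure is intended to yield.
* `method = "ci"`: mean of bootstrap means plus the one-sided $(1-\alpha)$
  half-width of the bootstrap-*mean* distribution.  This literal reading is
  retained behind the switch, but note that for large pooled samples the CI
  of the mean sits negligibly above the surrogate mean, so roughly half of
  all independent-noise pairs would exceed it — it cannot produce sparse
  networks, and it fails any per-pair type-I-control requirement.  That is
  why it is not the default.

The type-I property is tested at a relaxed $\alpha = 0.01$ (Monte-Carlo at
$10^{-4}$ would need millions of noise pairs).

## Graph metrics

Thresholded matrices become `hyper_brain_graph` objects — weighted plus
binarized adjacency, directed for PCI/NCI/ICI, undirected for PSI/ACI, node
metadata (electrode, brain, region).

* **Strengths** (`strengths()`): in/out row and column sums; the intra-brain
  component uses the within-brain blocks and the inter-brain component is
  total minus intra, per node.
* **Clustering** (`clustering_coefficient()`): binary
  $C_i = 2t_i/(k_i(k_i-1))$; weighted uses the geometric-mean triangle
  intensity of max-normalized weights; directed graphs use the directed
  triangle formula with denominator $k^{tot}(k^{tot}-1) - 2k^{bi}$.
  Nodes with fewer than two neighbours get $C_i = 0$.
* **Path length** (`characteristic_path_length()`): shortest paths on the
  binary adjacency, or on lengths $1/w$ for weighted graphs (strong
  coupling = short distance — the standard connectivity-to-length map).
  Unreachable pairs are *excluded* from the mean and counted in an
  attribute; a harmonic-mean variant is available (`method = "harmonic"`)
  for workflows that prefer smooth penalization of disconnection.
* **Null models** (`null_models()`): degree-preserving double-edge swaps
  for random nulls; lattice nulls start from a randomized copy and accept
  only swaps that reduce the total $|i-j|$ edge distance, with proposals
  targeted at the longest current edges.  Twenty realizations per kind by
  default, fully seeded; node count and the exact degree sequence are
  preserved in every realization (weights travel with edges).
* **Small-worldness** (`small_worldness()`):
  $\sigma = (CC/CC_{rand})/(CPL/CPL_{rand})$ and
  $\omega = CPL_{rand}/CPL - CC/CC_{latt}$, with $\omega$ clamped to
  $[-1, 1]$ (warning) if estimation noise pushes it outside.  Binary CC/CPL
  are the default basis (the weighted variants are available through the
  `mode`/`weighted` arguments); $\sigma$ and $\omega$ are computed per FOI
  and band values are means of FOI values.

## Community structure and node roles

`optimize_partition()` maximizes the weighted Newman modularity
(undirected) or the Leicht–Newman in/out-degree form (directed) by seeded
multi-restart greedy optimization: local node moves from singleton starts
interleaved with greedy module merges, best of `restarts` runs, ties broken
toward the first-found partition and module ids canonicalized — identical
(graph, seed, restarts) gives identical output.  On small graphs the result
is verified against exhaustive partition enumeration in the test suite.

$Z_i$ (within-module degree z-score) uses the *population* standard
deviation; a module whose nodes all have equal within-module degree gets
$Z = 0$ for every node, including singleton modules.  $P_i = 1 - \sum_m
(k_i(m)/k_i)^2$; isolated nodes get $P = 0$.  Degrees are binary on the
thresholded graph by default (`weighted = TRUE` switches to strengths).

Role boundaries: hubs are $Z \ge 1.4$ (the source material prints both
$\ge$ and $>$; $\ge$ was chosen).  Participation bins are half-open with
$P \le 0.05$, $0.05 < P \le 0.5$, $0.5 < P \le 0.8$, $P > 0.8$ (the $\le$
convention), giving roles R1–R4 (non-hubs) and R5–R8 (hubs).
`hyper_brain_modules()` reports modules spanning both brains;
`role_census()` pools role tables into percentages.

## The synthetic-data generator: a stated world

`generate_oscillator_pair()` emulates the validation design: unit-amplitude
sinusoids at 5/10/20 Hz, 3,000-ms epochs, channel B shifted by a per-epoch
phase drawn uniformly from $(-\pi, \pi]$ (drawn once per epoch, not per
sample) and/or delayed by a fixed lag, additive white Gaussian noise on
each channel independently.  The noise model and amplitudes are not stated
in the source design; white Gaussian noise with sd 0.5 against amplitude-1
oscillations was fixed once as a realistic moderate-noise regime, and the
validation-distribution comparisons are therefore qualitative, not
numerical.  `generate_hyper_brain_dataset()` extends this to two
21-channel "brains" of independent noise carrying selected coupled pairs
with configurable lag and strength.

What these generators do *not* emulate: 1/f background spectra, volume
conduction and common reference effects, non-stationary amplitude
envelopes, genuine neural-mass dynamics.  A green test on synthetic data
therefore establishes the *computational* correctness and calibration of
the measures (lead–lag recovery, type-I control, boundary identities), not
their neurophysiological validity on real EEG.

## Numerical conventions

* All generators, surrogates, bootstraps, null models and the modularity
  optimizer are pure functions of (input, seed); the pipeline records all
  seeds in `provenance.json`.
* Band-pass filtering and resampling are Fourier-domain operations: exactly
  zero-phase (no phase distortion entering the coupling measures),
  raised-cosine transition bands, band-limited interpolation.
* The artifact criteria are unit-agnostic amplitude thresholds (defaults 50
  and 200 in recording units) — a gradient criterion per consecutive-sample
  step and a max-minus-min difference criterion per epoch; the interactive
  visual-inspection step of lab practice is replaced by the deterministic
  criteria plus a rejection log.
* Degenerate inputs are first-class: empty graphs yield `NA` CPL with a
  warning, zero-clustering null ensembles abort `small_worldness()` with a
  diagnostic, all-rejected epoch sets warn, and zero-variance EOG
  regressors are an error.

## Known limitations

* Cross-frequency ($n{:}m$) phase relations, PLV-across-trials,
  Granger/transfer-entropy coupling, FDR-style multiple-testing control and
  consensus clustering are out of scope.
* The internal 0.002-Hz transform grid of the original toolchain is not
  reproduced; analysis is evaluated at the 17 FOIs that all downstream
  statistics use.
* Whether the original headline small-world values used weighted or binary
  CC/CPL is not fully explicit; both variants are provided, binary being
  the default.
* Empirical results that depend on the original (undeposited) recordings
  are not reproduction targets; every number this vignette or the README
  mentions is computed by the package's own tests or acceptance script.
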