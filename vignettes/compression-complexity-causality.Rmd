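---
title: "Compression-Complexity Causality: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compression-Complexity Causality: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cccausality)
```

## The problem

Granger causality and transfer entropy infer causation from associations
between well-separated samples: the past of a putative cause is asked to
improve prediction of (or reduce uncertainty about) the present of the
effect, sample by sample. When cause and effect are inseparable in the
measurements — long-memory processes, measurements at the wrong temporal
scale, aliasing, missing samples — these associational estimators degrade
or reverse direction. `cccausality` implements an *interventional*
alternative: causality is read off changes in the dynamical
compression-complexity of short windows, using hypothetical data blocks
created by surgery rather than joint probabilities of observed samples.

## Effort-To-Compress

The complexity primitive is Effort-To-Compress (ETC): the number of
iterations Non-sequential Recursive Pair Substitution (NSRPS) needs to
reduce a symbol sequence to a constant sequence. One iteration counts
every adjacent symbol pair (non-overlapping, scanning left to right, so
`111` contains `11` once), and replaces all non-overlapping occurrences of
the most frequent pair by a fresh symbol; frequency ties go to the pair
whose first occurrence is leftmost. A constant sequence has ETC 0, a
length-$m$ all-distinct sequence has ETC $m-1$, and dividing by $m-1$
(always the *original* length) normalizes ETC to $[0,1]$:

```{r}
etc_complexity("12121112", normalized = FALSE)  # trace: 12121112 -> 33113 -> 4113 -> 513 -> 63 -> 7
etc_complexity("12121112")
```

The joint measure `etc_joint(x, y)` scans two aligned sequences
simultaneously and replaces the most frequent jointly occurring adjacent
pair in both. We halt when no two aligned symbol *tuples* differ (or at
length 1). This choice matters: it makes the joint step count identical to
single-sequence ETC of any bijective tuple fusion of the pair
(`dictionary_sequence()`), which in turn makes the conditional estimator
with an empty conditioning set collapse exactly onto the pairwise one.
ETC is invariant under relabeling of the alphabet and subadditive:
$ETC(X,Y) \le ETC(X) + ETC(Y)$.

The NSRPS inner loop is implemented in C++ (the estimator evaluates it
hundreds of thousands of times in a simulation study); an independent
brute-force R implementation lives in the test suite and the two are
checked against each other over exhaustive enumerations of short
sequences.

## From complexity to causality

For a target series $X$, take a moving current window $\Delta X$ of length
$w$ and its immediate past $X_{past}$ of length $L$. The *dynamical
complexity* of the evolution is

$$CC(\Delta X \mid X_{past}) = ETC(X_{past} + \Delta X) - ETC(X_{past}),$$

where $+$ is appending. This is deliberately *not* the complexity rate
$C(X_{past}, \Delta X) - C(X_{past})$ built on joint complexity
(`complexity_rate()` is provided as a contrast utility; the two disagree
in general), because joint occurrence statistics are exactly what fail
when cause and effect are inseparable.

To ask whether a source $Y$ influences $X$, we *intervene*: the block
$Y_{past} + \Delta X$ is created surgically — it never occurs in the data
— and the dynamical complexity of $\Delta X$ is recomputed as if it had
evolved jointly from both pasts:

$$CC(\Delta X \mid X_{past}, Y_{past}) =
  ETC(X_{past}+\Delta X,\; Y_{past}+\Delta X) - ETC(X_{past}, Y_{past}),$$

with joint ETC on the aligned pairs. Compression-Complexity Causality is
the window-averaged difference

$$CCC_{Y \to X} = \overline{CC}(\Delta X \mid X_{past}) -
  \overline{CC}(\Delta X \mid X_{past}, Y_{past}),$$

with $\Delta X$ slid in steps of $\delta$. A value statistically
indistinguishable from zero means no detected influence (or identical
processes — self-causality is exactly zero, window by window). Both signs
are genuine causation: positive CCC means the source's past shapes the
target's dynamics *similarly* to the target's own past, negative CCC means
*dissimilarly* (typical of coupled chaotic maps before synchronization).
The divergence helpers (`distribution_divergence()`: symmetric
Kullback–Leibler and Jensen–Shannon, in nats) support this reading: when
the marginal distributions of the coupled processes diverge increasingly
with coupling, CCC tends to grow negative.

### Symbolization

The four blocks $X_{past}$, $Y_{past}$, $X_{past}+\Delta X$ and
$Y_{past}+\Delta X$ are each binned separately — the appended blocks as
one raw unit — into $B$ equal-width bins over the block's own min–max
range. Because every block is encoded over its own range, the estimate is
exactly invariant to a *common* positive affine rescaling of the data
(e.g. a unit change applied to the recording), and the target's own
dynamical complexity $CC(\Delta X \mid X_{past})$ is invariant to
rescaling of the target alone. It is *not* invariant to rescaling the two
series independently: the surgical block deliberately mixes the raw
amplitudes of $Y_{past}$ and $\Delta X$, and that amplitude relation
carries part of the signal — encodings that sever it (binning each piece
separately, or min–max normalizing each series first) empirically erase
most of the sensitivity of the estimator on the validation systems. The
practical rule is to keep both series in comparable, consistent units and
not to rescale one of them in isolation. Values on an
internal right bin edge go to the lower bin; the maximum goes to bin $B$;
a constant block (zero range) maps to the all-1 sequence, which has zero
complexity, rather than erroring: flat windows are legitimate data.

### Conditional CCC

With conditioning variables $Z, W, \ldots$, aligned binned blocks are
fused position-wise into dictionary sequences: $D'$ encodes
$(X, Z, W)$ tuples and $D$ encodes $(X, Y, Z, W)$ tuples, via a fixed
mixed-radix code (any bijection gives the same ETC, and permuting the
conditioning set provably leaves the estimate unchanged). The extended
dictionaries encode $X_{past}+\Delta X$, $Y_{past}+\Delta X$,
$Z_{past}+\Delta X, \ldots$ — every member's past is extended by the
*target's* current block $\Delta X$, i.e. the surgical interventional
block is built for the source and conditioning variables alike, treating
$\Delta X$ as a candidate evolution of each variable's past. Then

$$CCC_{Y \to X \mid Z, W} = \overline{CC}(\Delta X \mid D') -
  \overline{CC}(\Delta X \mid D).$$

## Parameters

* `L` — past-window length (samples). This is the temporal scale at which
  the source is hypothesized to influence the target; it must be long
  enough for ETC of the binned past to stabilize. The validation
  protocols use 150 (stochastic systems) and 100 (tent maps). When in
  doubt, scan a small grid (e.g. 50–150) and use the smallest `L` where
  the estimate stabilizes.
* `w` — current-window length (default 15). Short windows track
  time-varying causality; below ~10 samples the appended block adds too
  little material to move the complexity.
* `delta` — window step (default `w`, i.e. non-overlapping current
  windows). Smaller steps give more, but correlated, windows.
* `B` — bins per variable (default 2). Two bins suffice for noisy
  stochastic signals and keep dictionary alphabets small; deterministic
  chaotic data resolve better with `B = 8`.
* `significance` — `"ttest"` (default): one-sample t-test of the window
  values against zero, appropriate when `delta` is not much smaller than
  `L + w` so windows are approximately independent. `"surrogate"` builds
  a null from circular shifts of the source by offsets of at least `L`,
  preserving its autocorrelation while destroying alignment with the
  target — but because CCC's surgical block mixes raw amplitudes, part of
  a genuine causal signal (the distribution-level influence of the source)
  survives shifting, and the surrogate null can sit near the observed
  value even under strong coupling. The surrogate test therefore answers
  the narrower question "is there alignment-specific influence beyond
  what the source's marginal statistics explain", and should be read as
  conservative.

## The simulators: what they emulate

The package generates the coupled systems used to validate the estimator,
all seeded and exactly reproducible:

* `simulate_ar1()` / `simulate_ar100()` / `simulate_ar_lag5()` — linear
  Gaussian AR pairs with unidirectional coupling at lag 1, 100, or with
  lag-5 self terms (defaults $a = 0.9$, $b = 0.8$, noise intensity
  $\nu = 0.03$, standard-normal innovations). Lag-100 coupling emulates
  long-range memory; the lag-5 system is the testbed for filtering and
  decimation robustness. Series start at zero with pre-sample lags
  treated as zero — with stable coefficients the initialization washes
  out, and the noise-free uncoupled recursion stays identically zero.
* `simulate_tent()` — coupled slope-2 tent maps, the deterministic
  chaotic testbed (length 3000 with the first 2000 discarded, by
  default). Exact binary floating point is a degenerate substrate for
  this map — every dyadic-rational orbit collapses to 0 within about 50
  iterations — so each tent update carries a jitter uniform on
  $[0, 10^{-12}]$, reflected into $[0,1]$. The jitter is orders of
  magnitude below any bin width used downstream, keeps orbits on the
  chaotic attractor, and is not applied to the coupling mix, so full
  coupling still synchronizes the pair exactly. Initial conditions avoid
  the fixed points 0 and 2/3. The quadratic (`"nonlinear"`) coupling
  variant mixes $Y^2$ instead of $Y$; it is a labelled reconstruction
  and its results are interpreted qualitatively only.
* `simulate_mvar3()` — a common-driver triple: $Z$ (AR(1), 0.8) drives
  $X$ and $Y$ at lag 100 with weights 0.4 and 0.8, with only 250 samples
  retained: a short-length stress test for conditional estimation.
* Perturbations: `nonuniform_sample()` removes a percentage of samples
  at random positions from the dependent series and truncates the
  independent one to match (non-synchronous measurements with no time
  stamps); `moving_average()` and `decimate()` model low-pass filtering
  and sub-sampling, with exact length bookkeeping (2000 samples filter
  to 1998 with window 3 step 1; decimation by 2 then filtering leaves
  998). The decimate-then-filter order is the one whose arithmetic
  matches the reported 998.

What the simulators do *not* emulate: observational noise distinct from
process noise, non-stationary regime switches, amplitude quantization,
and real measurement artifacts. Passing the simulation battery shows the
estimator behaves correctly in these controlled regimes; it does not by
itself certify performance on any particular real recording.

## Validation protocols (`run_experiment()`)

The canned experiments reproduce the structure of the original evaluation:
`table1` (filtering/decimation robustness of the lag-5 AR pair, 10
trials), `fig3`/`fig5` (coupling sweeps for AR(1) and AR(100), 50 trials),
`fig6` (tent-map sweep, 50 trials), `fig8` (non-uniform sampling sweep, 10
trials), and `fig10` (conditional network recovery on the common-driver
triple, 10 trials). The acceptance script and the test suite run these at
the stated trial counts, except the coupling sweeps, which the tests run
at 25 trials — the qualitative patterns they assert (monotonicity,
direction, sign) are stable well below 50 trials.

For `fig10` the per-edge verdict aggregates trials with a one-sample
t-test against zero, Holm-corrected across the six scanned edges.
Circular-shift surrogates are the package default for a single fit, but
they are structurally weak in this protocol: with `L = 150` past windows
inside a 250-sample series, a rotation barely changes the window contents,
so the surrogate null hugs the observed value. The across-trial test with
family-wise control is the standard alternative for a network scan. At
these short lengths a weak common-driver leak into the `X`–`Y` pair
remains possible on occasional seeds; the same hazard is what makes the
protocol a meaningful stress test.

## Numerical choices and degenerate inputs

* Bin edges: equal-width over the block's own range; right-edge values
  down, maximum up; zero-range blocks map to symbol 1.
* NSRPS ties: leftmost first occurrence wins; fresh symbols are
  `max(alphabet) + 1` (immaterial by relabeling invariance).
* Normalization always divides by the block's original length minus one.
* Missing values are rejected, never imputed — the estimator's robustness
  to missing data applies to *removed* samples (`nonuniform_sample()`),
  not NA placeholders.
* Divergences: histograms on a shared equal-width partition over the
  pooled range (default 8 bins); zero-probability bins make the directed
  KL infinite rather than being smoothed silently (`smooth` adds explicit
  pseudo-counts); JSD is always finite and bounded by $\ln 2$.
* Surrogate p-values are the plain fraction of null means at least as
  extreme as the observed one; identical series therefore get p = 1.

## Limitations

* CCC is an effect-level estimator: it does not recover generative
  coupling coefficients, only the presence, direction, strength and
  *kind* (similar/dissimilar) of dynamical influence.
* Window parameters matter; the defaults here are sensible for data
  resembling the validation systems, but `L` should be chosen per
  application (stability scan) rather than trusted blindly.
* The conditional estimator's dictionary alphabet grows as $B^{k}$ with
  the number of variables; with short windows this practically limits
  conditioning sets to a few variables at `B = 2`.
* Significance via circular-shift surrogates requires series several
  times longer than `L`.
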