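---
title: "A half-adder circuit model of ego-to-allo vector transformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A half-adder circuit model of ego-to-allo vector transformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebnav)
```

## The problem

An insect that tracks where it is going must reconcile two reference
frames: the *egocentric* frame, where directions are measured against
its own head axis, and the *allocentric* frame, anchored to the outside
world. The relation between the two travelling directions is a
rotation by the heading angle,

$$T_{\mathrm{allo}} = T_{\mathrm{ego}} + H \pmod{2\pi},$$

and path integration additionally requires *adding* direction vectors.
In the Drosophila central complex these computations are carried by
sinusoid-shaped activity bumps across the ellipsoid body (EB) and
protocerebral bridge (PB). `ebnav` implements a discrete, parameter-free
circuit model of that machinery: vectors become sampled sinusoids,
sinusoids become sparse binary population codes, addition becomes
bitwise half-adder logic, and the result is read back by locating the
activity peak.

## The model, layer by layer

### Phasor layer

A vector $(r, \theta)$ is represented by the sinusoid

$$f(\phi) = r\,\sin(\phi - \theta + \tfrac{\pi}{2}) = r\,\cos(\phi - \theta),$$

sampled at $N$ equally spaced angles $\phi_i = 2\pi i/N$,
$i = 0,\dots,N-1$ (default $N = 360$, i.e. 1° spacing). The amplitude
carries the magnitude and the phase the direction, and — the phasor
property — the pointwise sum of two such sinusoids is exactly the
sinusoid of the vector sum. `sample_sinusoid()`, `sinusoid_sum()` and
`fit_sinusoid()` implement this layer; the closed-form oracle lives in
`vector_sum()`.

### Range-number (thermometer) encoder

Each sample is binarized by the range-number encoder: a value
$x \in [0, R]$ maps to an $M$-bit code whose first
$\operatorname{round}(kx)$ bits are 1, with $M = kR$. The defaults are
$R = 10$ (the magnitude ceiling of the reference experiments) and
$k = 20$, giving $M = 200$ bits and a quantization step of
$1/k = 0.05$ per sample. The value is recovered as popcount$/k$, with
round-trip error at most $1/(2k)$.

Sinusoid samples are negative half the time, while the encoder domain
is non-negative. Each signal is therefore affine-rescaled before
encoding,

$$v(\phi) = \tfrac{1}{2}\bigl(f(\phi) + r\bigr) \in [0, r],$$

a choice with three useful consequences: the code length stays $kR$
regardless of phase; the shift is a constant per signal, so it drops
out of both decoding statistics (peak position and max − min); and
under half-adder summation the combined profile's max − min equals the
sum magnitude *exactly* (see below). Samples pushed outside the
encoder range — possible only under injected noise — are clipped and
counted, and the clip count travels with every result.

Rounding is half-away-from-zero, fixed explicitly because the default
round-half-to-even would flip popcounts on exact half-step inputs.

### Half-adder layer (EB)

Two coded signals are combined lane-by-lane: for input bits
$X_1[i], X_2[i]$ the layer emits an OR bit (was anything present) and
an AND bit (were both present), interleaved into a $2M$-bit output.
For any pair of codes,
$\mathrm{OR} + \mathrm{AND} = X_1[i] + X_2[i]$ per position, so the
output popcount is exactly the sum of the input popcounts — the layer
performs addition in code space. The carry line must be AND, not the
XOR of a textbook half-adder's sum line: XOR would break popcount
additivity and with it the decoder. With $N = 360$ lanes per signal the
network shape is 720 input / 360 hidden / 360 output lanes
(`network_shape()`).

For sums of more than two vectors (`fold_signals()`), intermediate
outputs are re-thermometerized — the per-lane popcount re-laid as a
prefix of ones — so each intermediate is again a valid half-adder
input. The encoder ceiling is scaled to the worst-case running sum
($R = 10\,n_{\mathrm{inputs}}$ in the harness), so folds cannot
overflow; any overflow that does occur under other settings is clipped
and counted, never silent.

### Decoding layer (PB)

The output layer reads the per-lane popcounts back into a real-valued
profile $w(\phi_i)$, which is the shifted sum sinusoid
$\tfrac{1}{2}(f_1 + f_2) + \text{const}$ to within $1/k$ per sample.
Two statistics recover the vector:

* **Magnitude**: $r = \max(w) - \min(w)$. The underlying sum sinusoid
  $\tfrac12(f_1+f_2)$ has amplitude $r_{\mathrm{sum}}/2$, so its
  max − min is $r_{\mathrm{sum}}$ and the constant shift cancels.
  The first-harmonic amplitude is also computed but reported only as a
  diagnostic.
* **Direction**: the peak position, in one of two modes.
  `"argmax"` takes the lane with the most ones; quantization produces
  a flat plateau around the true peak, and ties are broken by the
  circular mean of the tied lanes, which recovers the plateau centre.
  `"refined"` (the default) takes the phase of the first circular
  harmonic of the mean-removed profile,
  $\arg \sum_i w_i e^{\mathrm{i}\phi_i}$, which is exact for a pure
  sampled cosine and pools all lanes, giving sub-sample accuracy and
  better noise robustness.

A constant (degenerate) profile — two vectors cancelling exactly —
decodes to the zero vector with $\theta = 0$ by convention.

### Reference frames

`ego_to_allo()` is the direct rotation. `four_axis_transform()` is the
biological route: the egocentric vector is projected onto four
reference axes at ±45° and ±135° from the head axis, each axis is
rotated by $H$, and the component-weighted unit vectors are recombined.
Because the four axes form two orthogonal pairs, the raw recombination
doubles the magnitude,

$$\sum_j \cos(T - a_j)\,\mathbf{u}(a_j + H) = 2r\,\mathbf{u}(T + H),$$

(the second-harmonic terms $\sum_j e^{2\mathrm{i}a_j}$ vanish over this
axis set), so the package renormalizes by $1/2$; after that the two
routes agree to machine precision, which the test suite verifies on the
full 360 × 360 grid of $(T, H)$. Internally every angle is a standard
counter-clockwise radian; the clockwise-positive degree convention of
head-centred diagrams exists only at the CLI boundary
(`--clockwise-degrees`).

## Error structure and accuracy bounds

Each encoded sample carries rounding error at most $1/(2k)$, so a
combined two-signal lane is off by at most $1/k$. The decoded magnitude
(max − min) is therefore within $2/k$ of the closed form — 0.1 at the
defaults — and in practice much closer, because the extremes of a
quantized cosine are biased far less than the worst case.

The decoded direction is quantization-limited only while the sum is
resolvable. The harmonic estimator's phase error scales like the
quantization noise over the signal strength, roughly
$\propto 1/(k\,r_{\mathrm{sum}})$: for $r_{\mathrm{sum}} \gtrsim 1$ it
stays below half a sample step ($\Delta\theta/2 = 0.5°$ at
$N = 360$), while for near-cancelling pairs the direction of an almost
zero-length sum is intrinsically ill-determined — the decoded angle can
swing by up to the angle subtended by the quantization displacement,
$\arcsin\!\bigl(\min(1, (2/k)/r_{\mathrm{sum}})\bigr)$. The test suite
asserts exactly these two regimes. This small-sum sensitivity is the
model's analogue of the 0°/360° boundary artifact: rare trials with
near-zero sums dominate the tails of the angle-error distribution and
explain why the angle RMSE sits well above the mean angle error.

## The experiment harness

`run_experiment()` reproduces the reference evaluation: `n_pairs`
trials (default 200), magnitudes uniform on $[0, 10]$, angles uniform
on $[0, 2\pi)$, every draw governed by one integer seed. Per trial the
decoded sum is compared against the closed form, and the report
aggregates mean absolute errors and RMSEs for magnitude and angle
(wrapped, in degrees by default — the units in which the reference
operating point of mean $|\Delta r| \approx 0.034$ and magnitude RMSE
$\approx 0.040$ is quoted; `scripts/acceptance.R` recomputes these
statistics over ten seeds). Aggregates are recomputed from the
per-trial records and verified on every run, and a report is
bit-reproducible from its configuration.

```{r, eval = FALSE}
rep <- run_experiment(experiment_config(n_pairs = 200, seed = 1))
rep$summary
```

### Noise model

The robustness sweep adds independent zero-mean Gaussian noise of
standard deviation `noise_sigma` to every sinusoid sample *before*
encoding — corruption of the analog input, against which the sparse
binary code is the claimed defence. The noise level is a free
parameter swept over a grid (the tests use
$\sigma \in \{0, 0.05, 0.1, 0.2, 0.4\}$, bracketing the quantization
step $1/k = 0.05$); the asserted property is the trend — errors grow
monotonically in expectation with $\sigma$ — not any particular value.

### Multi-input scaling

The scaling runs sum 20 or 30 vectors per trial via `fold_signals()`
with the encoder ceiling scaled to the worst case. Quantization
accumulates with one rounding per input, so the asserted bound is the
accumulated budget $n_{\mathrm{inputs}}/k$ on the mean magnitude error
(with angle errors remaining sub-degree), rather than a constant
multiple of the two-input error.

### Complexity accounting

`complexity_report()` counts forward operations for a dense reading of
the three-layer shape, $n_{\mathrm{in}} n_{\mathrm{hid}} +
n_{\mathrm{hid}} n_{\mathrm{out}}$ — 388,800 at the reference shape —
together with the weight count and per-sample activations, and the
linear scaling formulas for $d$ coded inputs of $M$ bits. The counts
describe the modelled network; the actual implementation is
parameter-free bitwise logic with no trained weights.

## What the synthetic generator does and does not show

All experiments are synthetic by construction: the generator draws the
same uniform magnitude/angle batches the error statistics are defined
over, so passing tests demonstrate correctness of the circuit
*mechanism* — encoding, bitwise addition, decoding, frame equivalence —
and its quantization behaviour. They do not exercise correlated sensor
noise, non-uniform direction statistics, temporal dynamics, or any
biological variability; no claim about real neural recordings follows
from them. Spiking dynamics, synaptic plasticity and 3D extensions are
out of scope.

## Numerical choices and problem sizes

* Rounding: half-away-from-zero everywhere a value meets the bit grid.
* Argmax ties: circular mean of the tied lanes (exact for plateaus
  symmetric about the true peak).
* Degenerate profiles: zero vector, $\theta = 0$.
* Even $N$ required by default (on-grid min equals −max exactly);
  odd $N$ opt-in with a documented amplitude bias.
* Angle metric: wrapped circular distance, reported in degrees by
  default; an unwrapped option exists solely to expose the 0°/360°
  boundary artifact.
* Test problem sizes: 1,000 random pairs for the oracle-equivalence
  property, 10 × 200 pairs for the operating-point statistics,
  3 seeds × 80 pairs per noise level, 5 trials per fold length, and
  exhaustive enumeration for the half-adder (all bit patterns at
  $M \le 8$, randomized at $M = 200$). These sizes give stable
  statistics for the asserted tolerances while keeping the default
  suite fast.

## Limitations

* The magnitude ceiling is global per batch: one vector of magnitude
  above $R$ aborts encoding rather than degrading gracefully.
* Near-cancelling sums have ill-determined directions (see above);
  downstream consumers should gate on the decoded magnitude.
* The four-axis path is exact only in the continuous domain; pushed
  through the coded pipeline it inherits the same quantization bounds
  as any other coded addition.
* The complexity figures are an accounting of the modelled dense
  shape, not measured costs of this implementation.
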