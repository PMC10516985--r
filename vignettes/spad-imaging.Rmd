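---
title: "Physics-informed SPAD imaging: noise model, calibration and enhancement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed SPAD imaging: noise model, calibration and enhancement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spadkit)
```

## The measurement model

A single-photon avalanche diode (SPAD) array pixel reports, per integration
window, a single bit: did at least one avalanche fire. A stack of such 1-bit
frames $I(x, y, n)$ is the raw measurement; summing $2^b$ consecutive
subframes gives a $b$-bit image (16 subframes for 4 bits, 1024 for 10 bits).
`spadkit` simulates, calibrates and enhances this measurement chain.

The forward model composes the physically distinct event sources of a SPAD
pixel, combined by OR (the detector saturates at one count per window):

* **Shot noise + fixed-pattern response.** Photon arrivals are Poisson with
  per-window expectation $\chi(x,y)$ (the latent image). Each incident
  photon is detected with the pixel's photon detection efficiency (PDE)
  $\eta(x,y)$. Binomial thinning of a Poisson stream is again Poisson, so
  the per-window detection probability is
  $p_{det} = 1 - e^{-\eta \chi}$.
  The thinned-Poisson coupling is a modeling choice: PDE acts per incoming
  photon, and this is the unique form consistent with that assumption.
* **Dark counts.** Thermal carriers trigger avalanches in darkness,
  Poisson with per-frame expectation $\lambda_{dcr}(x,y)$; as a 1-bit event,
  Bernoulli$(1 - e^{-\lambda})$.
* **Afterpulsing.** Carriers trapped during an avalanche can re-trigger the
  same pixel. The model is memory-one: if the pixel fired in frame $n-1$,
  it re-fires in frame $n$ with fixed probability $p_{ap}(x,y)$. Frame 0 has
  no afterpulse. (Physical afterpulse probability decays with time; the
  fixed one-frame map is deliberately the simplest statistical summary.)
* **Crosstalk.** Photons emitted during a neighbouring pixel's avalanche can
  trigger a pixel in the same frame. Each firing 4-connected neighbour
  (8-connected optionally) independently triggers the receiving pixel with
  its $p_{ct}(x,y)$. Crosstalk is seeded only by primary (shot/dark) and
  afterpulse events in a single pass: crosstalk-of-crosstalk chains would
  require a fixed-point iteration the underlying statistical model does not
  define, and at realistic rates ($p_{ct} \sim 10^{-2}$, firing rates
  $\sim 10^{-2}$) the neglected second-order events are $O(10^{-6})$ per
  pixel-frame.
* **Deadtime.** Quenching makes the pixel blind after an avalanche. It is
  never simulated as an event source; instead `validate_timing()` enforces
  the regime in which it is negligible — the frame period must cover
  integration plus deadtime (e.g. 20 ns integration, 60 ns dead, 80 ns
  readout in a 160 ns period). Violating configurations produce a warning,
  not silently wrong simulation.

Event order is fixed (primary, then afterpulse, then crosstalk) and every
frame consumes a fixed number of uniform draws from R's Mersenne-Twister
stream regardless of parameter values, so stacks are bit-identical across
runs and platforms for a fixed seed, and aligned seeds give pointwise
stochastic domination when parameters are raised (a property the test suite
exploits).

## Dark-frame calibration

In darkness, shot and fixed-pattern terms vanish and the remaining
parameters are identifiable from a long acquisition (60,000 frames by
default). `classify_events()` labels every fire:

* afterpulse, if the same pixel fired in the previous frame (consecutive
  detections at the low rates of a dark acquisition are most likely
  afterpulsing);
* otherwise crosstalk, if any connected neighbour fires in the same frame;
* otherwise residual dark count.

Afterpulsing takes priority when both rules match, making the classes
disjoint. The estimators are per-pixel ratios: classified afterpulse
(respectively crosstalk) counts over residual counts, and residual counts
per frame for $\lambda_{dcr}$. Pixels that never fire cleanly yield 0/0,
defined as 0 — no evidence of the source; ratios above 1 are clipped with a
warning.

Two properties of these raw ratio estimators are worth stating plainly,
because they determine what "recovery" can mean:

* **Chance coincidences are indistinguishable from events.** Two
  independent dark counts in consecutive frames are classified as an
  afterpulse; independent same-frame fires at neighbours are classified as
  crosstalk. At per-frame rate $r$ the crosstalk numerator therefore has a
  floor of roughly $r(1-(1-r)^4)$ per pixel-frame even on a sensor with no
  crosstalk at all, and a crosstalk event marks *both* pixels of the pair.
  When the true $p_{ct}$ is of the same order as the firing rate, the ratio
  estimate exceeds the generative per-neighbour probability severalfold.
* **The denominator excludes classified events,** so the afterpulse ratio
  estimates approximately $p_{ap}/(1 - f_{ap} - f_{ct})$ (the classified
  fractions), an upward bias of order 10–30% at calibration-bench rates.

The estimates are consequently *effective* per-sensor noise scores in
estimator units — self-consistent summaries of the event statistics —
rather than unbiased estimates of the generative parameters. The
`debias = TRUE` option subtracts the analytic coincidence expectation from
the numerators (computed from the observed marginal rates under
independence), which removes the floor but not the denominator and
double-marking effects; it is off by default because the raw ratio is the
procedure's definition. The dark-count estimate is much better behaved: the
residual rate recovers $1 - e^{-\lambda}$ up to the small classified-away
fraction (a few percent), and adding the classified counts back restores
the raw firing rate exactly (a conservation law the tests assert).

## Dataset synthesis

`build_dataset()` crosses clean scenes with condition grids of
super-resolution scale (2, 4, 8, 16), bit depth (4–10) and illumination
level, producing paired (low-bit low-resolution measurement, high-resolution
ground truth) sets: crop to a 512×512 (configurable) square, area-average
downsample — the photon-collection analogue of binning detector area, chosen
over interpolating kernels for that physical reason — map intensity to flux,
simulate $2^b$ frames through a calibrated sensor, accumulate.

Intensity-to-flux mapping is linear, $\chi = \varphi \cdot I$, with named
levels low/mid/high defaulting to $\varphi = 0.5/1/2$ — a 2× illumination
ladder emulating stepped laser power. No absolute radiometric scale is
implied; $\varphi$ is expected photons per window at white. Note the
measurement mean is $1 - e^{-\varphi I}$: high flux *saturates* the 1-bit
detector, which is a feature of the real device the synthesizer reproduces.

The procedural phantom generator supplies sources when no natural-image
corpus is wanted: seeded compositions of oriented gradients, disks (one
forced white and one forced black, guaranteeing dynamic range), rectangles
and resolution-bar triplets of known width. Phantoms emulate the *piecewise
structure* (edges, bars, smooth shading) that matters for super-resolution,
but not natural-image texture statistics, occlusion or semantic content —
toy-scale training results on phantoms demonstrate that the pipeline
optimizes and generalizes across its training set, not natural-image
performance.

## The enhancement network

The gated-fusion transformer maps a normalized low-bit image
($h \times w$, counts divided by $2^b$) to an $sh \times sw$ enhancement:

1. **Shallow extraction** $F_0 = H_{FE}(I_{LQ})$: 3×3 convolution, batch
   normalization, GELU; $c$ channels.
2. **Dense window-attention blocks**
   $F_i = H_{DCSTB}(F_0, \ldots, F_{i-1})$: all earlier features are
   channel-concatenated and projected back to $c$ by a 1×1 convolution
   (the dense-merge operator), then pass through window multi-head
   self-attention layers. Alternate layers shift the window grid by half a
   window, with the canonical region-id attention mask so tokens never
   attend across the cyclic-shift seam. Pre-norm residual layout; the MLP
   expands by `mlp_ratio`. Relative-position bias is omitted — at the
   window sizes used here (4–8) its capacity contribution is marginal and
   the content-based attention is the mechanism of interest.
3. **Gated fusion** $F_{DF} = \sum_i w_i F_i$ with learnable scalar gates,
   initialized to $1/n$ so every block contributes equally before training.
   The identities (zero gates give zero; one-hot gates return that block
   exactly; linearity) hold to machine precision and are tested.
4. **Reconstruction** $I_R = H_{REC}(F_0 + F_{DF})$: convolution, GELU,
   expansion to $c_{in} s^2$ channels, pixel shuffle to scale $s$, and a
   final 3×3 convolution whose weights start small and whose bias starts at
   0.5 — the output head begins near mid-gray, inside the image range,
   which makes short training schedules robust to initialization (an
   arbitrary initial offset can strand a 200-step run in a bad basin).

Because no deep-learning framework is assumed, the package carries its own
tape-based reverse-mode differentiation engine (`R/autograd.R`); every
operator's gradient is validated against central finite differences in the
test suite, and end-to-end first-step gradients are seeded-deterministic.

**Loss.** $\alpha\,\mathrm{mean}|I_R - I_G| + \beta\,\|\varphi(I_R) -
\varphi(I_G)\|_2 + \gamma(1 - \mathrm{SSIM}(I_R, I_G))$ with defaults
$\alpha = 0.1$, $\beta = 10$, $\gamma = 100$. The perceptual distance is the
root-mean-square difference of features from a pluggable extractor; the
default is a small *fixed-seed random* convolutional stack (conv–GELU–pool–
conv–GELU). Random frozen features are a self-contained choice that needs no
downloaded weights; an adapter around a pretrained stack (e.g. VGG19 pool-3)
can be substituted where available. The SSIM term is computed with the same
11×11 Gaussian window as the metric, differentiably.

**Training.** Adam with $\beta_1 = 0.5$, $\beta_2 = 0.999$, weight decay
$5\times10^{-5}$, batch size 24 (capped at the dataset size), initial
learning rate $3\times10^{-4}$ decayed by 10% every 100 epochs — the
recipe for full-scale training. The toy demonstrations in the tests and the
acceptance script (8 phantom pairs, 16×16 inputs, scale 2, 200 steps, tiny
widths: $c = 8$, 2 blocks × 2 layers, window 4, 2 heads) use a learning
rate of $10^{-3}$: the production rate is tuned for a 1000-epoch schedule
and underuses a 200-step one. Training aborts with diagnostics on a
non-finite loss.

## Evaluation

PSNR is $10 \log_{10}(R^2/\mathrm{MSE})$ with the data range $R$ explicit
(1 for normalized images, $2^b$ for counts; normalized is the default
convention). Identical images are reported at the 100 dB cap rather than
infinity so aggregates stay numeric. SSIM uses the standard 11×11 Gaussian
window, $\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, Gaussian-weighted
population moments, averaged where the full window fits; both metrics agree
with an independent reference implementation to $10^{-8}$ on frozen seeded
images. `rad_per_us_to_rpm()` converts angular rates measured from
microsecond-interval frame sequences to RPM, rounded to the nearest
thousand, the reporting resolution for high-speed rotation demonstrations.

## Numerical and scale choices

* Coordinates are (row $y$, column $x$), origin top-left; frames are
  indexed from 1 in R code.
* The simulator core is C++ (via Rcpp) using R's RNG, one pass per frame;
  60,000 frames on a 64×32 sensor simulate in well under a minute and
  calibrate in seconds.
* Test and demonstration problem sizes — 60,000-frame calibrations at
  64×32 and 32×32, 20,000-frame property checks at 16×16–32×16, 200-step
  toy training — were chosen so the full suite exercises the study-scale
  calibration conditions while the network demonstrations stay CPU-friendly.
* SSIM's $\sqrt{\cdot}$ in the perceptual term guards its backward pass at
  the origin ($1/(2\sqrt{\max(x, 10^{-12})})$); attention masks use a
  $-10^4$ additive bias rather than $-\infty$ so softmax gradients stay
  finite.
* 0/0 ratios estimate 0; estimator clipping to $[0,1]$ warns.

## Limitations

* The calibration ratio estimators inherit the biases described above;
  treat their output as effective noise scores unless rates are orders of
  magnitude below the coincidence floor.
* No time-stamped (TCSPC) arrival simulation, no wavelength-dependent PDE,
  no coherent speckle; deadtime only as a validation contract.
* The shipped network defaults are deliberately small; reproducing
  benchmark-scale restoration quality requires corpus-scale data and
  compute outside this package's scope.
* The frame period is free configuration; the package does not resolve
  vendor-specific timing conventions beyond the validation rule.
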