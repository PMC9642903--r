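---
title: "An opponent-channel model of color perception with Poisson filling-in"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An opponent-channel model of color perception with Poisson filling-in}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(chromafill)
```

## The model

Cortical color processing separates a stimulus into opponent channels — a
red–green difference (RG), a blue–yellow difference (BY), and an achromatic
luminance channel (I) — and represents each through two cell families.
*Single-opponent* (SO) cells report the local color content of their
receptive field and act as spatial low-pass filters; *double-opponent* (DO)
cells respond to chromatic edges and act as high-pass filters. Perceived
surfaces, however, are filled-in: uniform regions are seen as uniformly
colored even though the cortex mostly encodes their edges.

`chromafill` implements this picture as a four-stage pipeline:

1. **Opponent transform.** An RGB stimulus is mapped per pixel by the fixed
   matrix with rows $(\tfrac12, -\tfrac12, 0)$,
   $(\tfrac16, \tfrac16, -\tfrac26)$ and $(a, b, c)$ with
   $a = 0.2989$, $b = 0.587$, $c = 0.114$ (the Rec. 601 luminance weights;
   `opponent_matrix()`). The transform is linear and exactly invertible.
2. **Receptive fields.** Each opponent plane is convolved with a normalized
   Gaussian (window $W = 21$, $\sigma = 5$ pixels by default) to produce
   the SO planes, and with the discrete Laplacian stencil
   $(0,-1,0;\,-1,4,-1;\,0,-1,0)$ to produce the DO planes. Note the stencil
   is the *negative* of the analyst's five-point Laplacian: a bright center
   responds positively, and the filling-in stage consumes it with the
   matching sign.
3. **Filling-in.** Each DO plane is treated as the right-hand side of a
   steady-state Poisson problem, $\Delta O = -\mathrm{DO}$, whose solution
   is the filled surface. Because the DO plane is itself the (negated)
   Laplacian of the stimulus plane, the exact solution of the Dirichlet
   problem recovers the stimulus plane up to boundary terms — the model's
   central self-consistency, asserted in the tests.
4. **Recombination.** The perceived channels are the convex mixtures
   $P_{RG} = \beta_c\,SO_{RG} + \alpha_c\,O_{RG}$ (and likewise BY), and
   $P_I = \beta_i\,I_{LPF} + \alpha_i\,O_I$, with $\beta = 1 - \alpha$
   always. The inverse opponent transform then yields the perceived RGB
   image. $\alpha$ near 1 emphasizes edge-derived (high-pass) structure;
   $\alpha$ near 0 emphasizes the blurred SO content.

The two weights $\alpha_c, \alpha_i$ are the model's interpretive knobs:
different observers (or the same observer on different images) correspond
to different weightings of the two pathways.

## Solver backends

The Poisson stage has three interchangeable backends:

- `fillin_direct()` — a sparse direct solve of the five-point system
  (`Matrix`), exact to machine precision. It is the oracle against which
  the others are validated, capped at 128 × 128 grids.
- `fillin_iterative()` — the reference recurrence
  $I_k = I_{k-1} + \tau\,(\mathrm{src} + \Delta I_{k-1})$ with
  $\tau = 0.25$, the largest step for which the explicit five-point update
  is stable. *Converge* mode iterates until the estimated solution error
  drops below `tol`; *snapshot* mode stops after a fixed step count and
  models the partial filling of large surfaces observed in cortex.
- `fillin_snn()` — a recurrent spiking neural network that hosts the same
  recurrence in neuron populations (below).

**Convergence criterion.** The per-step update understates the remaining
error by the factor $1/(\tau\,\lambda_{\min})$ on the slowest diffusion
mode ($\lambda_{\min}$ the smallest Laplacian eigenvalue — about 220× on a
32 × 32 grid), so the iteration stops when
$\max|I_k - I_{k-1}|/(\tau\,\lambda_{\min}) < \mathrm{tol}$, using the
closed-form eigenvalue of the grid. `tol` therefore bounds the max-abs
error of the returned surface, which is what the cross-backend tests
verify.

**Boundary rule.** The recurrence needs a rule for missing neighbors at
the frame. The default is a Dirichlet zero-clamped border: it pins the
Poisson solution uniquely (making oracle tests exact) and matches the
picture of activity spreading inward from edges. A replicate/Neumann rule
is available; the operator is then singular, so sources are projected to
zero mean, the direct solve is grounded at one pixel, and surfaces are
returned mean-centred. A consequence of the Dirichlet default worth noting:
a zero edge code fills to the zero surface, so the DC level of a uniform
region survives only through the $\beta$-weighted SO path.

**Snapshot calibration.** The snapshot default of 200 steps is a
calibration, not an empirical constant: with $\tau = 0.25$ the diffusion
length after 200 steps is about $\sqrt{2 \tau k} = 10$ px, so squares of
5–10 px fill completely (`fill_ratio()` > 0.98) while an 80 px square
stays hollow (ratio < 0.01), reproducing the size ordering seen in
cortical activity maps.

## The spiking network

The spiking backend follows Neural Engineering Framework (NEF)
conventions. Each pixel's surface value is represented by one ensemble of
spiking rectified-linear neurons (20 by default): encoders $e_i \in
\{-1, +1\}$, intercepts uniform on $(-1, 0.95) \cdot \mathrm{radius}$,
maximum rates uniform on (100, 200) events/s, with gain and bias solved
from those samples. The represented radius defaults to 0.6 — 1.2 times the
largest chromatic-plane magnitude a $[0,1]$ stimulus can produce. All
sampling is driven by a single integer seed, and spike generation is a
deterministic integrate-to-threshold realization of the instantaneous
rate, so every run is exactly reproducible.

Identity decoders are obtained by Nengo-style regularized least squares
over 200+ evaluation points. The regularization default (0.005 of the
peak activity) is deliberately small: the recurrent Poisson loop amplifies
static decode distortion by $1/(\tau\,\lambda_{\min})$ on slow modes, so
decoder accuracy is a method requirement. Identity happens to lie almost
exactly in the span of ±ReLU tuning curves, which is why small
regularization is safe here.

The dynamics $\dot I = \mathrm{src} + \Delta I$ are realized through the
NEF dynamics principle: the recurrent connection decodes
$\tau_{step}(\mathrm{src} + \Delta \hat I) + \hat I$ with
$\tau_{step} = 0.25$ through a first-order synapse
($\tau_{syn} = 5$ ms, $dt = 1$ ms). Using the relaxation step weight
rather than the synaptic time constant in the feedback deliberately
time-rescales the dynamics so that each synaptic time constant performs
one $\tau = 0.25$ relaxation step; a 1 s run is then equivalent to roughly
200 reference iterations, matching the snapshot regime. Each interior
ensemble has exactly five recurrent connections (itself and its four
neighbors). The synaptic filter acts once, on the spike trains; decoded
feedback and external drive are injected as current, preserving the
single-pole loop the NEF mapping assumes.

Because every pixel is a spiking approximation, the network never reaches
an exact steady state. The returned surface is the decoded state averaged
over the final 20% of the run and carries an honestly computed residual.
On a 16 × 16 problem with 20 neurons/pixel the median RMSE against the
converged reference is below 3% of the surface's dynamic range, and does
not worsen with 80 neurons/pixel.

## Stimuli and what the tests do (and do not) show

All quantitative claims are made on stimuli the package generates:

- `make_square()` — uniform squares of 5–80 px, the filling-in size
  battery (standing in for 0.5°–8° of visual field).
- `make_assimilation_grid()` — thin 45° colored lines (width 3 px, step 15
  or 50 px) over an achromatic base, with line chroma amplified 4× in
  opponent space. The chroma amplification is defined here operationally:
  $(RG, BY) \leftarrow \mathrm{ratio} \cdot (RG, BY)$ with I unchanged,
  clipped at the gamut only on export, since "saturation ratio" has no
  standard formula. The achromatic base is the opponent reconstruction
  with zeroed chromatic channels, which makes the ratio-0 identity exact.
- `apply_illumination()` and `make_mondrian()` — a seeded colored-patch
  scene under a multiplicative global tint, a synthetic stand-in for
  photographs under colored illuminants.
- `extract_profile()` / `compare_profiles()` — cross-sectional activation
  profiles (averaged over ±2 lines, smoothed with a 1-D Gaussian,
  $\sigma = 2$) and edge-anchored linear regression between profiles. For
  generated stimuli the edge indices are known analytically, which
  replaces manual alignment to recorded data.

These stimuli have exact geometry, no sensor noise, no gamma ambiguity and
no natural image statistics. Passing tests therefore demonstrate the
model's internal identities and the direction of its perceptual effects
(assimilation grows with grid density and SO dominance; a global tint is
discounted under DO dominance; a red square grows a cyan fringe under pure
edge perception) — they do not certify quantitative agreement with
recordings or photographs, which would require the original data.

## Evaluation tools

`retinex()` implements the single-scale, non-logarithmic Retinex baseline:
per channel, the image minus its Gaussian surround
$\exp(-(x^2+y^2)/s^2)$ taken over the full image support. The surround is
normalized per pixel by the kernel mass falling inside the image — the one
reading under which a constant image maps to exactly zero *and* the
large-$s$ limit subtracts the plain image mean. Raw output is signed; the
display variant adds mid-gray 0.5 and clips. On a tinted scene its chroma
grows monotonically with $s$; on the assimilation grid its best
between-grid chroma stays an order of magnitude below the model's
single-opponent reconstruction — reported comparatively by the acceptance
script rather than asserted against a threshold.

`perceptual_distance()` is a feature-space contract: a pluggable extractor
returns feature layers and the distance is the pixel-averaged weighted
squared L2 of their differences. The shipped default extractor is the
identity (pixel space, unit weight), i.e. mean squared error; learned
extractors can be plugged in through the same interface but are not
bundled, keeping the package deterministic and self-contained.

Chromaticity evaluation uses CIE 1976 u'v' via the standard sRGB (D65)
chain. The working RGB space of the model itself is left untouched — the
pipeline treats stored values as its linear working space, and the display
model enters only in `rgb_to_upvp()`, so the choice is isolated in one
function.

## Numerical choices and degenerate inputs

- Convolution uses replicate-edge padding everywhere in the
  receptive-field stage, so constant planes are exact fixed points of the
  normalized Gaussian and the Laplacian has zero response on constants up
  to the frame. Zero padding would inject spurious high-contrast borders
  that dominate filling-in on small test canvases.
- Both model kernels are point-symmetric, so convolution equals
  correlation; the code computes the correlation form.
- Out-of-gamut values arising inside the pipeline (the filled surfaces can
  overshoot) are preserved; clipping happens once, at export.
- Zero-luminance pixels have undefined chromaticity and are flagged, not
  silently NaN-propagated; zero-variance profiles make $R^2$ undefined and
  are flagged instead of fitted.
- $\tau > 0.25$ breaks the explicit-iteration stability bound and warns;
  a linear recurrence whose discretized update is expansive warns in
  `simulate_recurrent()`.
- Problem sizes in the test-suite and acceptance battery (32 × 32 solver
  grids, 16 × 16 spiking grids, 90–100 px stimulus canvases, 5 seeds per
  Monte-Carlo median) were chosen as the smallest sizes at which the
  asymptotic behavior under test is already clean.

## A worked example

```{r example}
sq <- make_square(20, canvas = c(64, 64), fill_rgb = c(1, 0, 0),
                  background_rgb = c(0.5, 0.5, 0.5))
cfg <- perception_config(weights = perception_weights(alpha_c = 1, alpha_i = 0.5),
                         mode = "snapshot")
res <- perceive(sq, cfg, intermediates = TRUE)
res$perception

# edge enhancement and the complementary fringe
mask <- attr(sq, "mask")
mid <- 32
left <- min(which(mask[mid, ]))
c(inside = res$perception$p_rg[mid, left + 2],
  outside = res$perception$p_rg[mid, left - 2])
```

At $\alpha_c = 1$ the square's interior is only partially filled and the
RG channel just outside the edge turns negative — the complementary
(cyan) fringe of pure double-opponent perception. Lowering $\alpha_c$
restores the filled reddish interior through the SO path.

## Known limitations

- The weights $\alpha_c, \alpha_i$ are global; perceptual evidence
  suggests they may act locally. Only the isotropic Laplacian DO model is
  implemented — no orientation-selective variants.
- The direct solver is capped at 128 × 128; the iterative and spiking
  backends scale further but the iterative converge mode slows as
  $1/\lambda_{\min}$ with grid size.
- The spiking backend's accuracy is bounded by decode distortion amplified
  through the recurrent loop; very deep (large) grids would need more
  neurons per pixel or longer runs.
- The perceptual-distance default is pixel MSE; it is a contract for
  plugging in learned feature extractors, not a claim that MSE matches
  human similarity judgments.
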