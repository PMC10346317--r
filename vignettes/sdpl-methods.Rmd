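---
title: "Similarity-driven penalized-likelihood PET reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-driven penalized-likelihood PET reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdplpet)
```

## The reconstruction problem

A 2-D PET emission scan measures Poisson counts $g_i$ along rays indexed
by view angle and detector bin; the system matrix $H_{ij}$ gives the
contribution of pixel $j$ to ray $i$. Penalized-likelihood (PL)
reconstruction estimates the activity image $f$ by minimizing

$$ E(f) \;=\; \sum_i \left[(Hf)_i - g_i \log (Hf)_i\right] \;+\;
   \lambda\, R(f), $$

the Poisson negative log-likelihood plus a roughness penalty
$R(f) = \sum_j \sum_{j' \in N_j} \varphi(f_j - f_{j'})$ over the
4-neighborhood $N_j$, weighted by the smoothing parameter $\lambda$.
Edge-preserving convex non-quadratic potentials carry a *control
parameter* that sets where the potential turns from quadratic into
linear growth:

* **LN** (Lange): $\varphi(\xi) = \delta^2\left(|\xi|/\delta -
  \log(1 + |\xi|/\delta)\right)$, with $\varphi' \to \delta$;
* **HB** (Huber): $\varphi(\xi) = \xi^2$ for $|\xi| \le \sigma$,
  $2\sigma|\xi| - \sigma^2$ beyond, with $\varphi' \to 2\sigma$;
* **QD**: $\varphi(\xi) = \xi^2$ as the non-edge-preserving reference.

A smaller control value preserves edges more aggressively but smooths
noise less. Picking a single value for a whole image is the weakness the
similarity-driven method addresses: edges and flat regions want
different values.

We write the LN potential with $|\xi|$ although a common typeset form
omits the absolute value; the potential must be even to act on signed
neighbor differences.

## Similarity-driven fine-tuning (SDPL)

Around each pixel the package measures how self-similar the current
estimate is, in the spirit of non-local-means denoising. For every
directed neighbor pair $(j, j')$:

$$ W_{jj'} = \exp\!\left(-\Delta\rho_{jj'} / h^2\right), \qquad
   \Delta\rho_{jj'} = \sum_{p=1}^{P}\left(f_j(p) - f_{j'}(p)\right)^2, $$

with $P = 9$ for the default $3\times3$ patches (replicate padding at
borders). The per-pair control value is then

$$ \delta_{jj'} = \delta_0\,(1 + W_{jj'} + \alpha_j\, w), $$

where $w$ is the global mean of the pair weights and
$\alpha_j \in [-1, 1]$ modulates by local roughness through a modified
Butterworth polynomial of order $r = 0.1\lambda$ with turning point $t$
set to the mean roughness. Three roughness measures are provided:
gradient magnitude (GR), local standard deviation over the $3\times3$
window with divisor $L-1$ (SD), and mean patch similarity over the
available neighbors (PS). GR and SD grow with roughness while PS grows
with flatness, so the Butterworth argument is $z/t$ for GR/SD and $t/z$
for PS; either way flat pixels map toward $\alpha = +1$ (control rises
toward $3\delta_0$, approaching quadratic smoothing) and rough/edge
pixels toward $\alpha = -1$ (control falls as low as
$\delta_0(1 - w)$, sharpening edge preservation). We chose this
orientation because it is the only one that realizes the intended
extreme cases -- smaller-than-$\delta_0$ control at irregular edges,
larger in flat regions; prose descriptions of the rule are easy to read
the other way around, but the opposite orientation visibly inverts the
mechanism. The tuned field is refreshed once per outer iteration from
the previous outer estimate; tuning therefore sits outside the subset
loop, and the very first outer iteration -- whose "previous estimate"
is the structureless uniform initialization -- uses the fixed
$\delta_0$.

The ratio entering the Butterworth polynomial is clamped to
$[10^{-12}, 10^{12}]$ before being raised to the (generally
non-integer) power $2r$; this realizes the continuous $\pm 1$ limits,
including identically flat neighborhoods, without overflow.

### Choice of bandwidth

No canonical value of $h$ exists for reconstruction iterates whose
intensity scale changes with the count level, so the default is
scale-free: $h^2$ equals the mean of $\Delta\rho$ over all pairs of the
current estimate (floored at a machine-epsilon-scaled value so constant
images remain defined). This keeps the weights spread over $(0, 1)$
regardless of the activity scale; a fixed $h$ can be supplied when
reproducing a specific configuration. The global mean $w$ excludes the
self-weights $W_{jj} = 1$; including them (a constructor flag) only
compresses $w$ toward 1 and does not change the mechanism.

## The COSEM iteration

The optimizer is the complete-data ordered-subsets EM (COSEM) family,
which -- unlike plain OSEM -- has an explicit objective and converges.
The unobserved complete data $C_{ij}$ (counts emitted in pixel $j$ and
detected on ray $i$, $\sum_j C_{ij} = g_i$) is summarized per subset by
the accumulators $A_j^{(q)} = \sum_{i \in S_q} C_{ij}$, the only
statistic the updates need; $C$ is never materialized. Each subset
iteration alternates:

* **C-update** (subset $q$):
  $A_j^{(q)} \gets f_j \sum_{i \in S_q} H_{ij}\, g_i / (Hf)_i$, other
  subsets' accumulators held stale;
* **f-update**: each pixel minimizes its separable paraboloidal
  surrogate (SPS), a quadratic whose positive root is closed-form:
  $a f^2 + b f + c = 0$ with
  $a = 8\lambda \sum_{j'} \psi(\xi_{jj'})$,
  $b = \sum_i H_{ij} - 4\lambda \sum_{j'} \psi(\xi_{jj'})(f_j + f_{j'})$,
  $c = -\sum_q A_j^{(q)}$, where $\psi(\xi) = \varphi'(\xi)/\xi$ is the
  optimal surrogate curvature (extended continuously at 0) and all
  neighbor values are frozen at the pre-update estimate (Jacobi sweep).

With $\lambda = 0$ the update collapses to the COSEM-ML M-step
$f_j = \sum_q A_j^{(q)} / \sum_i H_{ij}$, and with a single subset the
iteration reproduces classic EM-ML to machine precision -- both are
asserted in the test suite. The constant coefficient $c$ sums the
complete data over *detector pairs* (all subsets); only that reading
makes the $\lambda = 0$ reduction exact.

### The energy that decreases

The coefficients above carry an overall pair factor of 4: relative to a
single count of each unordered neighbor pair, the surrogate curvature
$8\lambda\psi$ is four times the tangent-matched value. The energy this
iteration provably decreases is therefore the one whose penalty weighs
each unordered pair by $4\lambda$ (equivalently $2\lambda$ per directed
pair), and that is exactly what `penalizedObjective()` reports:

$$ E(f) = \sum_i \left[(Hf)_i - g_i \log (Hf)_i\right] +
   2\lambda \sum_j \sum_{j' \in N_j} \varphi(f_j - f_{j'};
   \delta_{jj'}). $$

Reporting a penalty with half this weight alongside the same update
would amount to tracking an objective the algorithm does not minimize
(its monotone decrease is not guaranteed and its fixed point is
different); the package treats the update equations as the definition
of the method and reports the matching energy. Monotone decrease of
this energy for fixed-parameter PL is asserted per iteration in the
tests. For SDPL the control field changes between outer iterations, so
only the within-iteration surrogate descent (also tested) is
guaranteed; no convergence theory is claimed for the adaptive
iteration.

### Numerical safeguards

* positivity floor $\varepsilon = 10^{-12} \max f^{(0)}$ on all
  iterates (log/division safety);
* stable quadratic root ($-2c / (b + \sqrt{b^2 - 4ac})$ when $b > 0$)
  against cancellation;
* rays with $g_i > 0$ but $(Hf)_i = 0$ flag a model/support
  inconsistency (warning; infinite energy);
* initialization: uniform image scaled so predicted and measured totals
  match (a uniform start is the standard convention and keeps the
  ML-equivalence checks exact);
* subsets visit views by interleaving and are processed in fixed
  ascending order for reproducibility.

## System model

The projector is a parallel-beam geometry: `nAngles` views over
$[0^\circ, 180^\circ)$, `nBins` detector bins at unit (pixel) spacing.
$H_{ij}$ is the exact intersection length of the central ray of bin $i$
with pixel $j$, evaluated by the closed-form trapezoid chord profile of
a unit square; forward and backprojection share the one sparse matrix
and are exact adjoints (tested against an independently constructed
dense matrix at $10^{-8}$). The detector must cover the grid, and full
angular coverage holds on the inscribed circle, so phantoms live inside
that field of view. Attenuation, scatter, randoms, detector blur and
depth effects are deliberately absent -- the method under study does
not model them either.

## The phantom generator and what it stands for

`makeBrainPhantom()` builds a procedural brain-like slice: elliptical
head, a sinusoidally convoluted gray-matter band, inner white matter,
two elliptical ventricles, with activity gray:white:CSF = 4:1:0 --
piecewise-constant with exactly three values. It preserves the
statistical structure that the similarity machinery exploits (three
tissue classes, thin high-contrast folds, flat interiors) without
claiming anatomical fidelity to any particular digital brain phantom
slice; absolute metric values on a real anatomical bitmap will differ,
which is why the package's quantitative claims are directional
(adaptive vs fixed under matched conditions) rather than value-exact.
`simulateScan()` scales the phantom so the noiseless projections sum to
a target count total (500,000 at the full 128-pixel protocol; 125,000
at the 64-pixel desk scale, preserving counts per pixel area) and draws
independent Poisson bins. Real sinograms additionally contain
attenuation, scatter and randoms; passing the ensemble tests therefore
demonstrates the mechanism under the stated Poisson model, not clinical
performance.

ROI layouts (five rectangles for regional error, three
contrast-recovery discs plus a background disc) scale with the grid and
mimic the usual placement over cortical band and white matter; exact
coordinates are configurable since no canonical set exists. True
contrasts $CR^0_R$ are recorded from the phantom at construction, so
the truth scores contrast recovery exactly 1.

## Evaluation protocol

All paired metrics normalize both images by the reference maximum
(dynamic range 1): then PSNR $= -20\log_{10}$ RMSE exactly, an identity
the tests assert, and SSIM (Gaussian $11\times11$ window, sd 1.5,
$K_1 = 0.01$, $K_2 = 0.03$) and pixel-domain VIF (four Gaussian scales,
noise variance 2.0) use their standard parameterizations. The ensemble
mean percentage error over $K$ noise trials is

$$ \mathrm{MPE} = \frac{1}{K}\sum_{k=1}^{K}
   \sqrt{\sum_j (\hat f_j^k - f_j)^2 \Big/ \sum_j f_j^2} \times 100\%,$$

computed on raw images (its normalization is built in); the square root
over the energy ratio is the reading consistent with the reported
magnitudes of percentage errors and their fixed ratio to RMSE. MAE and
RMSE are computed over the full grid (no head mask), the simplest
reproducible convention.

The ensemble driver pairs noise across arms: every method arm in a
trial reconstructs the identical sinogram, so arm contrasts are paired
and Monte-Carlo variance largely cancels. The whole report is a pure
function of the plan (tested byte-identical across runs).

## Default study conditions

The full protocol (128-pixel grid, 128 views, 500,000 counts, 4
subsets, 80 outer iterations, 50 trials) is available but deliberately
not the default. The package's default plan runs the same pipeline at
desk scale: 64-pixel grid and views, 125,000 counts, 4 subsets x 20
outer iterations, 10 shared-noise trials, PL vs SDPL-SD for LN
($\lambda = 40$, $\delta_0 = 0.1$) and HB ($\lambda = 20$,
$\sigma_0 = 0.06$) -- the high-smoothing parameter group of each
penalty, where adaptive tuning has the most work to do. The four
printed parameter groups per penalty are available via `tableArms()`.
At these sizes the adaptive method beats the fixed-parameter method on
all six metrics for both penalties, the same ordering the full-scale
protocol reports row by row.

## Known limitations

* 2-D only; no attenuation/scatter/randoms modeling (out of scope by
  design).
* No convergence proof for SDPL with iteration-varying control values;
  the monotone guarantees cover fixed-parameter runs and
  within-iteration surrogates.
* The procedural phantom is not the Hoffman bitmap; absolute metric
  values are not comparable across phantoms.
* The data-driven bandwidth default is a heuristic; studies targeting a
  specific operating point should fix `h`.
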