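# sdplpet

Similarity-driven penalized-likelihood (SDPL) PET image reconstruction
at desk scale, for researchers studying adaptive regularization in
emission tomography.

Penalized-likelihood reconstruction minimizes
$\sum_i [(Hf)_i - g_i \log(Hf)_i] + \lambda R(f)$, where $H$ is the
system matrix of the scanner, $g$ the Poisson sinogram, and
$R(f) = \sum_j \sum_{j' \in N_j} \varphi(f_j - f_{j'})$ an
edge-preserving roughness penalty. The Lange and Huber potentials carry
a *control parameter* ($\delta$, $\sigma$) that sets the edge
sensitivity — and one global value cannot suit both edges and flat
regions. The method at the core of this package fine-tunes the control
parameter per directed pixel pair from non-local-means patch
similarities of the running estimate:

$$\delta_{jj'} = \delta_0\,(1 + W_{jj'} + \alpha_j\, w), \qquad
  W_{jj'} = e^{-\Delta\rho_{jj'}/h^2},$$

where $w$ is the mean pair similarity and $\alpha_j \in [-1,1]$ is a
Butterworth-modulated pixel-roughness score (gradient, local SD, or
mean patch similarity). At edges $\delta_{jj'}$ drops below $\delta_0$
(stronger edge preservation); in flat regions it rises toward
$3\delta_0$ (stronger smoothing). The optimizer is the convergent
complete-data ordered-subsets EM (COSEM) with closed-form separable
paraboloidal surrogate pixel updates.

The package also provides the surrounding laboratory: a procedural
three-tissue brain-like phantom (gray:white:CSF = 4:1:0), an exact
adjoint parallel-beam projector, Poisson scan simulation, EM-ML /
COSEM-ML / PL / SDPL reconstruction, six image-quality metrics (PSNR,
SSIM, VIF, MAE, RMSE, ensemble MPE), ROI contrast recovery, and a
paired-noise ensemble study driver.

## Worked example

Fixed-parameter PL versus similarity-driven SDPL on one simulated scan
(64 × 64 phantom, 125,000 counts, 4 subsets × 20 iterations, Lange
penalty, λ = 40, δ₀ = 0.1):

```r
library(sdplpet)
ph    <- makeBrainPhantom(64)
model <- buildSystemModel(64, 64, 64)
scan  <- simulateScan(model, ph, 125000, seed = 1)

pl   <- runCosem(scan$sinogram, model, penaltySpec("LN", 0.1), lambda = 40,
                 subsets = 4, iterations = 20)
sdpl <- runCosem(scan$sinogram, model, penaltySpec("LN", 0.1), lambda = 40,
                 subsets = 4, iterations = 20, sdpl = TRUE, measure = "SD")

rbind(`PL-LN`      = iqaMetrics(scan$truth, estimate(pl)),
      `SDPL-LN-SD` = iqaMetrics(scan$truth, estimate(sdpl)))
#>              PSNR  SSIM  VIF   MAE  RMSE    MPE
#> PL-LN      13.193 0.424 0.18 0.169 0.219 41.032
#> SDPL-LN-SD 13.817 0.470 0.22 0.157 0.204 38.185

sdpl@control
#> ControlField: delta0 = 0.1 , fine-tuned range [ 0.01812 , 0.2819 ]
```

Higher PSNR/SSIM/VIF and lower MAE/RMSE/MPE for the adaptive method;
the tuned control spans well below and above its initial value, which
is the mechanism doing the work. The full ensemble protocol (shared
noise across arms, K trials) runs through `experimentPlan()` /
`runEnsemble()`; `tableArms("LN")` reproduces the four printed
hyperparameter groups per penalty.

A thin command-line wrapper with `phantom`, `project`, `recon`,
`evaluate` and `ensemble` subcommands is installed under
`inst/cli/sdplpet.R`.

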