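---
title: "Estimating PET random coincidences from singles and prompts"
author: "randcoinc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating PET random coincidences from singles and prompts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(randcoinc)
```

## The detection model

Every quantity in this package derives from one statistical picture of a
PET acquisition. Positron annihilations occur as a Poisson process; each
annihilation emits two back-to-back 511 keV photons. Depending on geometry
and detection efficiency, zero, one, or both photons of a pair are
detected. Classifying a Poisson process preserves Poissonness, so the
singles seen by detector $i$ decompose into two independent sources:

* *uncorrelated singles* — one photon of a pair, the partner lost — at
  rate $\lambda_i$ (counts/s), and
* *correlated singles pairs* — both photons detected — at rate
  $\rho_{ij}$ (pairs/s) for the detector pair $(i, j)$.

Totals are written $\lambda = \sum_i \lambda_i$,
$\rho = \sum_i \rho_i = 2\sum_{i<j}\rho_{ij}$ (singles/s contributed by
pairs), $S = \lambda + \rho$ (total singles rate), and the
*window-occupying* rate $\Lambda = \lambda + \rho/2$. The `RateModel`
class stores $(\lambda_i, \rho_{ij})$ and enforces
$\Lambda = \lambda + \rho/2$ by construction.

A *prompt* is a pair of singles grouped by the coincidence sorter; it is
a *true* if both singles share an annihilation and a *random* otherwise
(by this definition a scattered same-annihilation pair still counts as a
true — randoms estimation does not need to know about scattering). The
single-window (SW) sorter walks the time-ordered stream with one window
open at a time: an event with no open window opens a window of length
$\tau$; exactly one further event inside makes a prompt, two or more make
a *multiple coincidence* and all involved singles are discarded, none
drops the opener. For Poisson streams this yields the randoms rate

$$R_{ij} = 2\tau\,\lambda_i\lambda_j\,e^{-2\Lambda\tau},$$

where $e^{-2\Lambda\tau}$ is the pile-up attenuation: the chance that an
otherwise-valid coincidence window stays free of a third event.

## The three estimators and the ideal reference

**SR** uses only singles: $R^{SR}_{ij} = 2\tau S_i S_j$. It inherits two
upward biases: $S_i \ge \lambda_i$ (correlated singles are counted as if
they could make randoms) and the missing pile-up factor, which costs a
further $e^{2\Lambda\tau}$ at high rates.

**DW** delays a copy of the stream far beyond the time resolution
(500 ns here) and extracts coincidences between the original and the
delayed copy with the same sorter; any such coincidence is necessarily
accidental. It is unbiased for uncorrelated-only streams but counts
coincidences, so its replicate variance corresponds to a Poisson counting
process (Fano factor $\approx 1$), and per LoR it can only produce
integer counts.

**SP** solves for the uncorrelated rate from the two measured totals.
With $P_i = \sum_j P_{ij}$ the per-detector prompts rate and
$P = \sum_i P_i$ (twice the scanner prompts rate), $\lambda$ is the
physical root of

$$2\tau\lambda^2 - \lambda + S - P e^{(\lambda+S)\tau} = 0,$$

and the estimate takes the same product form as SR with an *effective*
window and *effective* singles rates:

$$R^{SP}_{ij} = 2\bar\tau\,\bar S_i \bar S_j,\qquad
\bar\tau = \frac{\tau e^{-\tau(\lambda+S)}}{(1-2\tau\lambda)^2},\qquad
\bar S_k = S_k - P_k e^{\tau(\lambda+S)}.$$

On exact model inputs $\bar S_k = \lambda_k (1 - 2\tau\lambda)$, the
$(1-2\tau\lambda)^{-2}$ in $\bar\tau$ cancels the same factor squared,
and $R^{SP}_{ij}$ reproduces $2\tau\lambda_i\lambda_j e^{-2\Lambda\tau}$
exactly; the test suite asserts this round trip at machine precision.

The **ideal** estimate is only available on simulated data: prompts are
classified with the ground-truth annihilation tags every simulated single
carries, and $R^0_{ij}$ is the labeled-random count per LoR over the
acquisition time. It is the reference all methods are compared against.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `nDetectors` | 148 | — | one transaxial ring of a small-animal scanner |
| `ringDiameter` | 94.2 | mm | matching small-animal ring geometry |
| `timeResolutionFwhmNs` | 5 | ns | coincidence time resolution |
| `tcwNs` | 10 | ns | conventional $\tau = 2\times$ FWHM |
| `dwDelayNs` | 500 | ns | far beyond the time resolution |
| `deadTimeNs` | 300 | ns | paralysable, per detector, opt-in |
| `efficiency` | 0.5 | — | per-photon detection probability (below) |

The per-photon detection efficiency $\varepsilon$ is the package's one
free physics knob. The full scanner response (energy windows, crystal
efficiency, axial acceptance) is deliberately not modelled; instead each
photon reaching the ring is detected with probability $\varepsilon$,
which directly sets the correlated-singles fraction
($\rho/S = \varepsilon/( 2 - \varepsilon)$ for a fully covered source).
The default 0.5 puts one quarter of annihilations in the both-detected
class — a strongly correlated regime where the SR bias is conspicuous.

## What the simulator does and does not emulate

The generator operates at two levels. The *model level*
(`simulateModelStream`) realises the Poisson sources directly and is the
workhorse for estimator ensembles: every event carries a ground-truth
annihilation tag, correlated pair members share a common emission time,
and the activity is constant over the acquisition. The *geometry level*
(`simulateAnnihilationStream`) samples annihilation positions
proportionally to a phantom's activity concentration, emits back-to-back
photon pairs isotropically, and assigns ring crossings to the nearest
detector centre; `deriveRateModel` estimates $(\lambda_i, \rho_{ij})$
from the same classification, and the two code paths agree within
counting error (a property test asserts this).

Not emulated: attenuation, scatter media, positron range, acollinearity,
energy deposition and energy windows, Compton splitting of one photon
into several singles, crystal depth of interaction, axial geometry, and
isotope decay during the acquisition. Gaussian time jitter and
paralysable dead time exist as opt-in stressors (`applyTimeJitter`,
`applyDeadTime`) but are off by default. Consequently, passing tests
demonstrate the statistical behaviour of the estimators under the ideal
detection model — unbiasedness, variance, pile-up response — not their
accuracy under the full physics of a real scanner. One concrete example:
with jitter off, correlated pair members are exactly simultaneous, so in
the delayed-window channel a delayed pair always forms a multiple and is
discarded; the DW overestimation caused by correlated singles in real
scanners is therefore only visible here when jitter is enabled.

A 2D single-ring reduction replaces the full multi-ring scanner. The
estimators consume only $(S_i, P_{ij})$ and are geometry-agnostic, so the
reduction preserves their statistics while keeping every ensemble
desk-scale (10,878 LoRs for 148 detectors).

The "source outside the field of view" phantom — which can produce only
uncorrelated singles because at most one photon of each pair reaches the
detectors — is represented by a flag that forces $\rho \equiv 0$ with a
uniform $\lambda_i$ profile, since a 2D ring has no axial outside to
trace photons from.

## Numerical choices

* **Event times.** Uniform arrival times are dithered by one RNG lattice
  cell ($2^{-32}$) before scaling to the acquisition window. Base
  `runif()` values over seconds-long acquisitions are quantised at the
  sub-nanosecond level — the same order as $\tau$ — which measurably
  distorts small-gap statistics (a ~2% deficit of sub-$\tau$ gaps in a
  4 s acquisition); dithering restores an exactly continuous uniform law.
* **Window boundary.** Membership uses the closed condition
  $\Delta t \le \tau$; a measure-zero choice for continuous times, fixed
  for determinism.
* **Ties.** Merged streams are ordered by (time, detector, annihilation
  id) so equal seeds give bit-identical streams.
* **Root finding.** The pile-up equation is bracketed on a 257-point grid
  over $[0,\ S(1 + 8\tau S)]$ and polished by Newton iteration to
  relative tolerance $10^{-12}$. The upper end deliberately exceeds the
  model bound $\lambda \le S$: with few or no observed prompts the root
  lies above $S$ by a factor of order $1 + 2\tau S$, and clamping at $S$
  would bias the estimator. If several roots exist, the one continuous
  with the $\tau \to 0$ limit $\lambda = S - P$ is selected.
* **Clamping.** Negative effective singles rates $\bar S_k$ (possible
  under sampling noise) are floored at zero and counted in the SP
  diagnostics.
* **Delayed-window orientation.** The SW walk on the merged
  original-plus-delayed stream retains mixed pairs whose window *opener*
  is a delayed single. Keeping both orientations would count the
  (original-$i$, delayed-$j$) and (original-$j$, delayed-$i$) families
  separately and double the estimate relative to the prompt randoms
  rate; a hardware delayed channel gates one direction only. Windows with
  two or more candidates are rejected, mirroring the prompt sorter.
* **Same-detector prompts** define no LoR; they are discarded and
  counted separately.
* **ML-EM.** Forward projections are floored at $10^{-12}$ where a
  measured LoR would otherwise divide by zero; non-negativity then holds
  at every iteration. The system matrix is exact chord–pixel intersection
  lengths, deterministic, with row sums equal to the in-grid chord
  length.
* **Figures of merit.** Contrast, CRC and SOR are scale-free; for the
  regional bias the true image is first rescaled to the reconstruction's
  total intensity, so RB measures regional misallocation rather than the
  arbitrary counts-versus-concentration unit mismatch.

## Image-quality study design

The toy image-quality phantom is the transaxial section of the classic
cylinder: a 48 mm warm background disc with two 16 mm inserts, hot at 4×
the background concentration and cold at zero. Regions of interest are
circles of 0.6× the insert radius at the insert centres plus a warm
region at least 3 mm clear of the inserts and inside 85% of the
background radius — all strictly interior to homogeneous regions, so
border and resolution effects do not leak into the means. The exact RoI
rule is this package's own choice; published studies typically state only
that RoIs avoid borders.

Reconstruction uses ML-EM with the per-LoR expected randoms counts
$r_l = R^{mth}_l \cdot T$ as the additive term in the forward projection.
A 64×64 grid over a 64 mm field of view (1 mm pixels) is the default;
figures of merit are read at 40 iterations, where the contrast has
converged, and can be logged per iteration up to any budget. Four
compensation arms are compared: ideal, SP, SR, and none ($r \equiv 0$,
which is also what DW degenerates to in low-statistics frames where the
best available integer count is zero — SP's real-valued $r_l$ is exactly
what survives that regime). Overestimated randoms (SR) inflate the
recovered contrast; missing compensation depresses it.

## Problem sizes

The shipped ensembles are sized for a desk machine. Estimator properties
use the 148-detector ring with total singles rates of $2$–$4\times10^5$
counts/s over 1 s per replicate — $\Lambda\tau$ of a few $10^{-3}$, the
"low-activity" regime where all methods are expected to work — with 100
replicates for bias checks (standard error of the SP-to-ideal ratio
below 1%, the conventional precision criterion) and 250–1000 replicates
for Fano factors (the Fano estimate itself has standard deviation
$\sqrt{2/n}$). The pile-up sweep pushes $\Lambda\tau$ to 0.05 with
shorter acquisitions. The image study uses 2 MBq for 2 s
($\approx 4\times10^6$ singles, $\approx 10^6$ prompts), high enough
statistics that the 40-iteration contrast sits within a few percent of
its ideal value of 3.

## Known limitations

* SP accuracy under dead time is not characterised; dead time is exposed
  as a stressor only, and no accuracy claim is made when it distorts the
  Poisson assumption.
* The NECR implementation defines the phantom term by summing estimated
  randoms over LoRs whose chords intersect the phantom; other definitions
  exist, and comparisons are only meaningful with one definition applied
  to all methods, which `necrCurve` guarantees.
* The multiple-window sorter is not implemented; for double coincidences
  its output is known to be close to the SW sorter's.
* The point phantom concentrates activity at a geometric point; LoR
  masks over it are near-degenerate, so NECR masks are most meaningful
  for extended phantoms.
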