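# randcoinc

Random (accidental) coincidences are one of the main sources of image
degradation in positron emission tomography: two photons from *different*
annihilations detected within the time coincidence window (TCW) are
mistaken for a true coincidence, adding noise and biasing quantification.
Compensating for them requires an estimate of the randoms rate in every
line of response (LoR), and the two workhorse methods both have known
defects: the **singles-rate (SR)** estimate `R_ij = 2 τ S_i S_j`
overestimates whenever correlated singles or pile-up are present, while
the **delayed-window (DW)** estimate is noisy (it counts coincidences, not
singles) and can only produce integer counts per LoR.

`randcoinc` implements and assesses the **singles–prompts (SP)**
estimator, which fixes both defects of SR at no extra measurement cost.
Writing `λ_i` for the uncorrelated-singles rate of detector i,
`S_i` for its measured singles rate, `P_i` for its measured prompts rate,
`S = Σ S_i`, and `P = Σ P_i` (twice the scanner prompts rate), the SP
estimate is

    R_ij = 2 τ̄ S̄_i S̄_j,
    τ̄   = τ e^(−τ(λ+S)) / (1 − 2τλ)²,
    S̄_k  = S_k − P_k e^(τ(λ+S)),

where the total uncorrelated rate λ solves the pile-up equation

    2τλ² − λ + S − P e^((λ+S)τ) = 0 .

It has the same `2 τ S_i S_j` structure as SR — with an *effective* window
and *effective* singles rates — so it can drop in wherever SR is used.

The package is aimed at PET instrumentation and reconstruction researchers
who want a desk-scale, fully controlled testbed for randoms-estimation
methods: it simulates ground-truth-labelled singles list-mode streams from
Poisson source models or from annihilation sampling in a 2D detector ring,
sorts prompts with a single-window (SW) sorter, computes SR / DW / SP /
ideal (ground-truth) estimates, and carries the comparison through to
count-rate metrics (Fano factors, randoms fraction, NECR) and a toy 2D
ML-EM reconstruction with per-LoR additive randoms compensation and
standard image-quality figures of merit (contrast, CRC, SOR, image
roughness, regional bias, correlation coefficient).

## Worked example

Simulate one acquisition of a 148-detector ring (τ = 10 ns) with a 25%
correlated-singles fraction, sort, and compare the four estimates against
the analytic model prediction:

```r
library(randcoinc)

ring <- makeRing()                      # 148 detectors, 94.2 mm, tau 10 ns
n    <- nDetectors(ring)
rho  <- matrix(0, n, n)
rho[upper.tri(rho)] <- 5e4 / nLors(n)   # correlated pairs, 5e4 pairs/s total
model  <- rateModel(rep(3e5 / n, n), rho)
stream <- simulateModelStream(model, duration = 1, seed = 1)

prompts <- classifyPrompts(swSort(stream, tcw(ring)))
singles <- singlesRates(stream)

c(SR    = totalRate(estimateSR(singles, tcw(ring))),
  DW    = totalRate(dwSort(stream, tcw(ring), dwDelay(ring))),
  SP    = totalRate(estimateSP(singles, prompts)),
  ideal = totalRate(estimateIdeal(prompts)),
  model = totalRate(modelRandomsRate(model, tcw(ring))))
```

```
       SR        DW        SP     ideal     model
1590.4974  890.0000  888.0260  857.0000  887.6833
```

The ground-truth (ideal) total randoms rate in this acquisition is
857 counts/s against an analytic model prediction of 888 counts/s (the
difference is one acquisition's counting noise, about ±29 counts/s). SP
(888.0) and DW (890.0) agree with the prediction, while SR (1590)
overestimates by the expected `(S/λ)² = (4/3)² ≈ 1.78` factor caused by
counting correlated singles as if they were uncorrelated. Across
replicate ensembles the mean SP-to-ideal ratio is 1 within a fraction of
a percent (see the test suite), with a variance far below DW's.

The same pipeline runs end to end from a YAML config:

```r
runPipeline("config.yaml", "out/")        # or: inst/scripts/randcoinc run
```

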