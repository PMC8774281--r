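# lysotraj

Wavelet-based analysis of intermittent ("stop-and-go") organelle transport
from 2D single-particle tracking data — active-run segmentation, run/flight
statistics, organelle–cargo co-movement classification, MSD scaling, and
heavy-tailed length-model selection, plus a seeded synthetic trajectory
generator so the whole pipeline is testable without imaging data.

**Who it is for.** Cell biologists and biophysicists who track lysosomes,
endosomes, or other vesicles (and optionally a cargo channel — e.g.
nanoparticle aggregates imaged by confocal reflection) and want the
transport phenotype quantified per cell: percent time in active transport,
run/flight length distributions and their best-supported model, anomalous
diffusion exponents, and which organelles carry cargo.

## The method in brief

Each coordinate series of a track is transformed with the Haar wavelet over
scales a = 1..50 (prefactor 1/a, kernel centered at t0):

    C(t0, a) = (1/a) Σ_k s(k) ψ((k − t0)/a + 1/2),   ψ = +1 / −1 on the two half-supports

Active transport is detected at scale ã = 20 by the universal threshold
projected from scale 2,

    δ = r · σ₂ · √(2 ln N) · √(ã/2),   σ₂ = medianᵢ|C(i, 2)| / 0.6745,  r = 0.8,

with the first/last ã/2 points excluded; a point is active if either axis
exceeds its threshold. Maximal active stretches are **runs** (length l =
start→end chord); consecutive runs merge into **flights** when their
turning angle is ≤ 120° and the candidate run stays inside a corridor of
width max(1.27·W, 0.4 µm) about the flight's chord. An organelle–cargo
pair is **co-moving** when the Pearson correlations of their wavelet maps
over the temporal overlap satisfy Px > 0.7 and Py > 0.7 and the mean
center-to-center distance is < 1 µm. Pooled time-averaged MSD curves are
fitted as MSD = 4 D t^α over 0–4 s; run/flight lengths are fitted by
maximum likelihood with five candidate models (lognormal, power law,
truncated power law, stretched exponential, exponential) compared through
Akaike weights; group differences use the two-sample Cramér–von Mises,
Wilcoxon–Mann–Whitney, and paired t tests.

The methods vignette (`vignettes/lysotraj-methods.Rmd`) derives and
motivates every constant above, the normalization and anchoring of the
transform, the detectability floor of threshold-based run detection, and
the nesting structure that bounds Akaike weights among these five models.

## Worked example

Simulate one "cell" with ten organelle tracks — six having a co-tracked
cargo partner of which three are truly co-transported — and run the whole
pipeline:

```r
library(lysotraj)

lyso <- list(); cargo <- list()
for (i in 1:6) {
  cfg <- simConfig(seed = 500 + i, n_steps = 400,
                   track_id = sprintf("pair%02d", i))
  p <- simPair(cfg, comoving = i <= 3)
  lyso[[i]] <- p$lyso; cargo[[i]] <- p$cargo
}
for (i in 7:10) {
  cfg <- simConfig(seed = 600 + i, n_steps = 400,
                   track_id = sprintf("solo%02d", i))
  lyso[[i]] <- simStopAndGo(cfg)$trajectory
}
lyso  <- trackSet(lyso,  cell_id = "cellA", channel = "organelle")
cargo <- trackSet(cargo, cell_id = "cellA", channel = "cargo")

res <- runPipeline(lyso, cargo, out_dir = "cellA_out")
res
#> PipelineResult 'cellA': 10 tracks, 27 runs, 23 flights
#>   alpha = 1.261, D = 0.02342 um^2/s, 8.1% time active
```

The exponent α = 1.26 flags the superdiffusive stop-and-go mixture; 8.1%
of (non-excluded) time is classified active. Exactly the three planted
co-moving pairs are recovered, each passing both correlation gates and the
distance gate:

```r
subset(res$pairs, is_comoving)[, c("lyso_id", "Px", "Py", "mean_dist_um")]
#>        lyso_id        Px        Py mean_dist_um
#> 1  pair01_lyso 0.8710180 0.9268314    0.2774110
#> 8  pair02_lyso 0.7690043 0.9778375    0.2702218
#> 15 pair03_lyso 0.9911982 0.9758103    0.2493366
res$summary$pct_cargo_bearing
#> [1] 30
```

With only 27 runs the model comparison is, correctly, inconclusive —
Akaike weights spread across the flexible candidates:

```r
res$length_fits[res$length_fits$kind == "run",
                c("model", "AIC", "weight", "winner")]
#>                   model      AIC       weight winner
#> 1             lognormal 76.86387 4.779919e-02  FALSE
#> 2             power_law 97.18969 1.843847e-06  FALSE
#> 3   truncated_power_law 73.34980 2.770073e-01  FALSE
#> 4 stretched_exponential 72.88502 3.494767e-01   TRUE
#> 5           exponential 73.02585 3.257150e-01  FALSE
```

At realistic sample sizes (thousands of runs pooled over cells) the
generating model separates cleanly; `tests/testthat/test-heavytail.R`
quantifies exactly when.

`runPipeline()` also writes `labels.csv`, `runs.csv`, `flights.csv`,
`pairs.csv`, `msd.csv`, `length_fits.csv`, `summary.csv` and a
`manifest.yaml` (config echo, versions, per-stage counts) to `out_dir`;
`summarizeGroups()` compares per-cell summaries between treatment groups
with the appropriate test.

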