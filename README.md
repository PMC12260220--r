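# rootkin

Kinematic and behavioural analysis of 3D root-tip trajectories.

Growing primary roots circumnutate: the tip traces a helical path about the
growth axis, and both the oscillation and the direction of growth change
when another plant shares the substrate. `rootkin` takes time-stamped 3D
tip trajectories — `(t, x, y, z)` samples every 3 minutes over days, in cm —
and provides the full analysis chain for neighbour-response studies:

* **Feature extraction** — step kinematics (distance, velocity,
  acceleration), segmentation (turning) angles, absolute/relative daily
  growth rate, average hourly tip velocity, nutation amplitude relative to
  the smoothed main growth component, main nutation period and its spectral
  power (FFT of the amplitude series), spectral entropy
  `H = −Σ pᵢ log₂ pᵢ` of the Welch PSD of the horizontal nutation signal,
  curvature `|r′ × r″| / |r′|³` and its total variation, and tortuosity
  (path length / endpoint chord).
* **Condition classification** — standardize, winsorize (|z| ≤ 3), prune
  features correlated above |r| = 0.7, then 5-fold stratified
  cross-validation of an L2 logistic regression and a linear SVM to
  discriminate plants grown alone from plants grown with a neighbour, with
  signed coefficient-based feature importance.
* **Behaviour taxonomy** — per hour, the angle θ_gh between the
  plant→neighbour direction and the displacement of the growth main
  component gives a signed displacement (+ toward, − away). First crossing
  of ±1.2 cm of cumulative displacement calls **aggregative**/**avoidant**;
  otherwise a 35% dominance margin decides, defaulting to **neutral**.
* **Directional statistics** — the signed global growth angle θ_g of
  aggregative plants (range ±180°, 0° = straight at the neighbour),
  Shapiro–Wilk normality of θ_g, and a Yates-corrected χ² test of
  aggregative behaviour vs neighbour identity (conspecific vs
  heterospecific).
* **Synthetic cohorts** — a seeded generator of circumnutating trajectories
  (controllable amplitude, period, jitter, lateral bias, noise) and
  study-structured cohorts, so the whole pipeline is testable with no
  recorded data.

## Worked example

```r
library(rootkin)

# one synthetic maize plant: 7 days at 3-min sampling
params <- growth_params(nutation_period = 80, nutation_amplitude = 0.15,
                        axial_rate = 2, seed = 101)
tr <- generate_trajectory(params, plant_id = "demo", species = "maize")
tr
#> <root_trajectory> demo (maize): 3361 samples over 168.00 h

fv <- extract_features(tr)
round(unlist(fv[c("tortuosity", "main_nutation_period",
                  "mean_nutation_amplitude", "relative_growth_rate",
                  "spectral_entropy")]), 4)
#>              tortuosity    main_nutation_period mean_nutation_amplitude
#>                 10.7098                 80.6640                  0.1455
#>    relative_growth_rate        spectral_entropy
#>                  1.0957                  3.5394
```

The planted 80-min period is recovered to Fourier-bin resolution and the
0.15 cm orbit radius to a few percent; tortuosity ≈ 10 says the tip
travelled ten times its net displacement — circumnutation dominates the
path length.

```r
# a pair 5 cm apart, with a planted approach drift of 0.6 cm/day
pair <- generate_pair(growth_params(lateral_bias = 0.6),
                      behaviour = "aggregative", seed = 7)
call_behaviour(pair)
#> <behaviour_call> aggregative (threshold_positive, onset hour 35)

# association between neighbour identity and aggregative behaviour,
# on tabled counts (conspecific 15/7, heterospecific 3/13)
chi_square_yates(matrix(c(15, 3, 7, 13), 2))
#> <contingency_stat> X-squared (Yates) = 7.2045, df = 1, p = 0.007272
```

The cumulative toward-displacement crossed 1.2 cm (a quarter of the
separation) at hour 35, so the plant is called aggregative there; the χ²
of 7.204 (p ≈ .007) says aggregative behaviour is far more frequent with a
conspecific neighbour.

For a full cohort: `generate_cohort(cohort_spec(), dir, seed)` writes
trajectories plus a manifest, `read_cohort()` loads them,
`feature_table()` → `standardize_features()` → `clip_outliers()` →
`prune_correlated()` → `crossval_classify()` classify the growth condition,
and `cohort_pairs()` → `call_behaviour()` → `directional_report()` run the
behaviour and directionality analyses. The methods vignette
(`vignettes/root-trajectory-analysis.Rmd`) documents the models, defaults
and design decisions.

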