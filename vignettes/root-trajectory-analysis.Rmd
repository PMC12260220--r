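---
title: "Kinematics and behaviour of root-tip trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematics and behaviour of root-tip trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootkin)
```

## The problem

Primary roots of young plants do not grow straight down: the tip
circumnutates, tracing a helical path around its main growth axis, and the
character of that movement changes when another plant shares the substrate.
`rootkin` analyses time-stamped 3D root-tip trajectories — one `(t, x, y, z)`
sample every 3 minutes for up to a week, in centimetres — and asks three
questions:

1. Do the kinematic and oscillatory features of the movement discriminate
   plants grown alone from plants grown with a neighbour?
2. Does a plant's root grow towards its neighbour (aggregative), away from
   it (avoidant), or neither (neutral)?
3. When roots aggregate, how precisely do they aim at the neighbour?

Everything runs on a synthetic cohort generator, so the full pipeline is
testable without any recorded data.

## The data model

A `root_trajectory` holds strictly increasing timestamps (first sample is
t = 0) and finite coordinates; at least 3 samples are required (the minimum
for one turning angle). Irregular spacing is tolerated; gaps over 30 min are
flagged as warnings because tracking dropouts are common in practice and
silently interpolating them would fabricate movement.

Axis conventions differ between acquisition rigs, so a `plane_convention`
names the vertical axis (default `y`) and derives the horizontal
"interaction plane" (default `x`–`z`, in fixed order). All plane-dependent
quantities — hourly displacements, growth angles, the spectral-entropy
signal — are computed in that plane. Published descriptions of such setups
sometimes name the horizontal plane inconsistently between equations; making
the convention an explicit object removes the ambiguity.

## Feature battery

For each trajectory the package computes:

* **Step kinematics** (`step_kinematics`): Euclidean step length, step
  velocity, and forward-difference acceleration between all consecutive
  samples, deliberately unsmoothed.
* **Segmentation angles** (`segmentation_angles`): the angle at each
  interior point between the incoming and outgoing segment, via the clamped
  arccos of the normalised dot product. Under this formula 0° is a straight
  continuation and 180° a reversal, so *larger* angles are sharper turns;
  verbal descriptions sometimes invert this, the formula is authoritative
  here.
* **Growth rates** (`growth_rates`): root elongation is approximated by the
  cumulative tip path length, offset by the initial root length (metadata;
  default 4 cm, the selection criterion for 4-day-old seedlings). Absolute
  rate is the mean day-over-day increment; relative rate divides each
  increment by the length at the start of that day. This is an
  approximation — a tip trajectory measures displacement, not elongation —
  and is documented as such.
* **Main growth component** (`main_growth_component`): a centred moving
  average of the 3D path. The reference procedure for separating nutation
  from growth is not fully specified in the literature this package follows;
  a moving average whose window equals one nutation period is the simplest
  estimator that removes the oscillation (a full revolution averages to its
  centre). The window shrinks symmetrically at the edges, so endpoints are
  preserved and the output length equals the input length.
  `extract_features` runs two passes: a 2 h first-pass window yields a
  period estimate, and the component is re-estimated with that period as the
  window.
* **Nutation amplitude** (`nutation_amplitude`): per-sample 3D distance
  between the raw path and the main component.
* **Main nutation period** (`main_nutation_period`): plain FFT of the
  mean-removed amplitude series (no zero padding, no further detrending);
  the period is the inverse of the non-zero frequency with maximal power, so
  resolution is one Fourier bin (about 1.5 min at a 90 min period over
  7 days). The power at that peak is itself a feature ("amplitude of the
  main frequency in the power spectrum").
* **Spectral entropy** (`spectral_entropy`): Shannon entropy (bits) of the
  Welch PSD — Hann window, segment length `min(256, N/2)`, 50% overlap,
  segment-mean removal — of the horizontal-plane distance between path and
  main component. Low entropy means regular oscillation; the maximum is
  `log2(nbins)`.
* **Curvature and its total variation** (`curvature_series`,
  `total_variation_curvature`): curvature of the time-parameterised path,
  `|r' × r''| / |r'|^3`, by central differences on the (possibly
  non-uniform) time grid; the total variation sums absolute successive
  curvature changes, zero for lines and circles.
* **Tortuosity** (`tortuosity`): path length over endpoint chord, ≥ 1.

`core_feature_names()` lists the ten features used for condition
classification: mean and minimum speed, tortuosity, mean nutation amplitude,
main nutation period, total variation of curvature, relative growth rate,
main-frequency power, spectral entropy, mean segmentation angle.

## Synthetic cohorts

`generate_trajectory` builds a tip path as vertical growth at `axial_rate` +
circumnutation in the horizontal plane + optional lateral drift + i.i.d.
Gaussian noise per axis, fully determined by its seed.

Nutation is rotation at constant phase velocity whose radius is modulated
once per cycle: `r(φ) = a (1 + m cos(φ + ψ))`, with `m = 0.5` by default. The
modulation is essential, not cosmetic: a perfect circle stays at constant
distance from every smoothed centreline (smoothing a signal
`m(t) + a e^{iφ}` leaves a residual proportional to `e^{iφ}`), so its
amplitude series is flat and carries no period information. Real nutation
orbits are far from circular; the radial swing is what makes the rotation
period measurable from the amplitude spectrum, here as in recorded data.
Amplitude and period are additionally multiplied by per-revolution
log-normal jitter factors (mean 1).

Choices a user should know about:

* **Period jitter accumulates.** Independent per-revolution period factors
  make the phase wander like a random walk; with sd 0.25 the oscillation
  decoheres within a couple of days and no spectral line survives. Defaults
  keep period jitter at 0.1 (individual) and 0.05 (social), where the line
  is stable over a week.
* **Study conditions.** `cohort_spec()` defaults mirror the reference cohort
  structure: 19 individually grown maize, 10 maize with a conspecific
  (5 pairs), 12 pea with a conspecific (6 pairs), 8 maize–pea pairs, plants
  5 cm apart. Individual plants grow at 1.5 cm/day with 0.1 cm, 90 min
  nutation; social plants at 2.5 cm/day with 0.2 cm, 60 min nutation,
  stronger amplitude jitter (0.2 vs 0.1) and a 0.6 cm/day lateral bias
  towards or away from the neighbour according to a planted behaviour mix
  (50% aggregative / 25% avoidant / 25% neutral). The social settings plant
  the four headline condition effects — more main-frequency power, faster
  relative growth, higher tortuosity, shorter nutation period — with
  magnitudes chosen so each is a measurable property of every generated
  plant; no published effect sizes exist for these features, so the
  magnitudes are the package's own choice.
* **What the generator does not emulate:** gravitropic curvature of the
  axis, elliptical or planar-pendulum nutation modes, temporally correlated
  tracking noise, dropouts, or any mechanistic growth response. Passing
  tests therefore demonstrate that the estimators and rules recover planted
  structure of this phenomenological kind — not that real roots behave this
  way.

## Condition classification

`feature_table` assembles per-plant features with `individual`/`social`
labels. The pipeline standardizes each feature to mean 0, population sd 1
(`standardize_features`; parameters stored for reuse), winsorizes
standardized values at |z| = 3 (`clip_outliers`; clipping rather than row
removal keeps the cohort size, and the step can be skipped), and prunes
multicollinearity (`prune_correlated`): while any pair of features has
|r| > 0.7, the member with the larger mean absolute correlation to the rest
is dropped, ties broken by name order so the result is deterministic. A
`protect` argument can force a canonical retained set.

`crossval_classify` runs seeded stratified 5-fold cross-validation of two
linear models: L2-penalised logistic regression (ridge `glmnet` with
λ = 1/(n·C), the unit-cost penalised log-loss) and a linear-kernel SVM at
cost 1 (`e1071`). With 37 plants stratified folds hold 7–8. Standardization
is global by default (`standardize_in_fold = TRUE` refits it inside each
fold). Accuracy is the reported metric; coefficients come from a full-data
fit, oriented so positive values push toward the `social` label, and
`feature_importance` ranks them by magnitude. `permutation_accuracy`
supplies the chance-level null.

## Behaviour taxonomy

For a `plant_pair`, the neighbour direction is the horizontal vector between
the initial tips (`neighbour_vector`). Some printed formulations of this
procedure give both that vector and the hourly displacement reversed; since
angles are invariant under joint negation, the forward convention
(plant → neighbour, earlier → later) is implemented, matching the stated
semantics that 0° means growth towards the neighbour (a numeric test asserts
the equivalence).

`hourly_motion` smooths the focal trajectory to its main component,
subsamples to whole hours (nearest sample to each hour), and per hourly step
records the angle `theta_gh` to the neighbour direction and a signed
displacement: the full step magnitude, positive when `theta_gh` < 90°,
negative when > 90°, zero at exactly 90° (a measure-zero case that would
otherwise flap sign) or for zero steps.

`classify_behaviour` scans the cumulative signed displacement: the first
crossing of +1.2 cm calls aggregative, of −1.2 cm avoidant (first behaviour
wins; crossing means strictly exceeding). The 1.2 cm default is about a
quarter of the 5 cm separation and is used literally. If no threshold is
crossed, dominance decides: the toward-fraction must exceed the
away-fraction (or vice versa) by more than 0.35 of all hours — the margin
reading of the dominance rule; zero-displacement hours count in the
denominator. Otherwise the plant is neutral. The position at which the
behaviour was identified (`rp_end`) is the tip position at the onset hour
for threshold calls, else the final sample.

## Directional statistics

`global_growth_angle` measures the signed angle between the neighbour
direction and the horizontal displacement from the initial tip to `rp_end`.
The arccos form of the angle is unsigned; the stated range of ±180° requires
an orientation, which the horizontal 2D cross product provides
(counter-clockwise positive in the fixed axis order; the −180° boundary maps
to +180°). Mirror symmetry across the inter-plant axis flips the sign and
leaves the magnitude, so the orientation choice cannot affect a normality
test centred on 0°.

`directional_report` collects the angles of aggregative plants, tests
normality (Shapiro–Wilk, pooled and per species, skipped below n = 3 or for
constant samples), emits histogram counts (10 bins over ±180°, an arbitrary
plotting choice) and Blom-position QQ points, and tests the association
between neighbour identity and aggregative behaviour with the
Yates-corrected chi-squared test (`chi_square_yates`): expected counts from
the marginals, continuity correction capped at |O − E| so a cell at its
expectation contributes nothing, df = 1. On the reference behaviour counts
(15/7 conspecific, 3/13 heterospecific) this gives 7.204, p ≈ .007.

## Numerical choices and degenerate inputs

* arccos arguments are clamped to [−1, 1] before the call.
* Zero-length segments (stalled tip) yield NA angles; zero-speed points
  yield NA curvature; both are logged, and downstream statistics use valid
  values only.
* A constant amplitude series has no defined period and errors; an all-zero
  entropy signal warns and returns 0.
* Welch settings, smoothing windows, thresholds, the dominance margin and
  the winsorizing bound are all exposed as arguments with the defaults
  documented above.
* Period estimates are Fourier-bin-limited; tests compare frequencies, not
  periods, against a one-bin tolerance.

## Problem sizes used in the test-suite

The suite exercises full-length cohorts (7-day, 3-min trajectories; one
37-plant maize cohort shared across tests), 30-trajectory parameter-recovery
and 30-pair behaviour-recovery batches, 100 label permutations, 200
simulated angle cohorts for the normality branch, and 1000 random tables for
the chi-squared oracle — sizes at which every stochastic check is stable
under its fixed seed while the whole suite stays fast.

## Known limitations

* The main-component window interacts with the period estimate; for signals
  whose amplitude spectrum has no clear line (heavy period jitter, long
  gaps) the two-pass estimate can lock onto low-frequency power. The
  estimator follows the stated argmax definition and inherits its
  fragility.
* Relative growth rate depends on the initial-length metadata; with the
  default 4 cm it is comparable across plants but not an absolute
  physiological rate.
* Only the first behaviour is called; multi-phase responses and the joint
  dynamics of both plants in a pair are out of scope.
* Angles are tested for linear normality, as in the reference analysis;
  circular statistics (Rayleigh, von Mises) are a documented extension
  point, not implemented.
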