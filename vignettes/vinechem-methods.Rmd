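---
title: "Methods: Vis-NIR chemometric calibration for grape quality indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Vis-NIR chemometric calibration for grape quality indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Harvest decisions for wine grapes hinge on indicators that are slow and
destructive to measure: pH, total soluble solids (TSS, degrees Brix), titratable
acidity (TA, g/L), reducing sugars (RS, g/L), and the total phenolic content of
skin and seed (TPCN, TPCD, mg gallic-acid equivalents per g). Visible/near-
infrared diffuse reflectance (400-1100 nm here) responds to the pigment and
water/carbohydrate absorption changes that accompany ripening, so a calibrated
regression from spectrum to indicator allows non-destructive monitoring.

`vinechem` implements the full calibration workflow: replicate-representative
selection, six spectral preprocessing operators, SPXY sample partitioning, SPA
feature-wavelength selection scored by Monte-Carlo cross-validation, three
regression engines (PLS, SVR, a one-dimensional CNN) behind one train/predict
contract, R2/RMSE/RPD evaluation, and a config-driven experiment grid with an
explicit best-model rule. Because no public dataset accompanies the workflow,
the package ships a first-class synthetic generator with known ground truth;
every stage is tested against it.

## The synthetic generator

`default_grape_config()` emulates the study conditions: 192 samples on a
1507-point grid over 400-1100 nm. (Published descriptions of such setups
sometimes quote a "400-1507 nm" range; we read 1507 as the variable count,
since the instrument class tops out near 1100 nm, and keep the axis internally
consistent.) Each indicator k expresses itself through Gaussian absorption
bands:

    clean_i(lambda) = baseline(lambda) + sum_k link_k(c_ik) * sum_b A_b * exp(-(lambda - mu_b)^2 / (2 w_b^2))

with `link` either linear or quadratic in the concentration. Bands sit in the
400-1000 nm pigment region and the 800-920 nm absorption region, mirroring
where ripening-driven differences and carbohydrate/phenolic bands are seen in
real grape spectra. Observed spectra add the artifacts the preprocessing stack
is designed to remove:

    x_i = m_i * clean_i + o_i + p_i(lambda) + eps_i

with log-normal multiplicative scatter `m_i` (sd 0.08 on the log scale),
additive offset `o_i` (sd 0.01), a random per-spectrum polynomial baseline
`p_i` (constant/linear/quadratic coefficient sds 0.01/0.008/0.005 on a [-1, 1]
wavelength scale), and i.i.d. channel noise (sd 0.002, giving per-indicator
spectral signal-to-noise of roughly 10-20). Concentrations are uniform over
plausible ranges (pH 2.5-3.8, TSS 8-25 Brix, TA 3-16 g/L, RS 40-240 g/L, TPCN
0.5-4, TPCD 5-45 mg/g) and share a latent "maturity" factor through a Gaussian
copula (correlation 0.5) to mimic coordinated ripening. No distributional
summary of the real indicators is published, so these ranges are plausible
rather than matched; conclusions from synthetic tests are about the machinery
(recovery of planted signal under realistic artifacts), not about real grapes.

What the generator does not emulate: instrument response functions,
temperature effects, wavelength-dependent noise, radiative-transfer scattering
physics, and the detector roll-off at range edges. Passing tests therefore
demonstrate correct algorithmic behavior under controlled distortions, not
field performance.

The generator is deterministic: a config (including its seed) maps to one
dataset, and the `truth` slot stores the clean spectra and every artifact
realization so that `m * clean + o + baseline + noise` reproduces the observed
matrix exactly.

## Replicate representative and partitioning

Repeated measurements of one sample are reduced to the spectrum with the least
deviation from the others, formalized as the Euclidean-distance medoid (the
row minimizing the summed distance to all other rows; ties to the lowest
index). Aggregating by sum is the standard reading of "least deviation";
replicates from different fruit sides are pooled.

SPXY partitioning uses the joint distance
`d(i,j) = d_x(i,j)/max d_x + d_y(i,j)/max d_y` (Euclidean in spectrum space,
absolute difference in the response), seeds the calibration set with the pair
at maximal joint distance, and grows it by Kennard-Stone max-min accretion to
`round(0.7 N)` samples (134 of 192). The max-normalization makes the split
invariant to rescaling either space, so the response can stay in its native
units. The split runs per indicator - y enters the distance - and on raw
spectra, before preprocessing, so one split serves all preprocessing arms; a
per-arm split is available by simply calling `spxy_split` on transformed
spectra. Ties anywhere resolve to the lowest index, making the procedure
deterministic without randomness.

## Preprocessing

Six operators, each with the strict contract fit-on-train / apply-to-both:

* **SNV** - per spectrum, subtract the mean and divide by the (n-1) standard
  deviation. Removes affine scatter exactly; idempotent; errors on constant
  rows.
* **MSC** - regress each spectrum on a reference (the training mean spectrum,
  the standard, leakage-safe choice) and return `(x - a)/b`; slopes below
  1e-12 in absolute value are errors rather than near-singular divisions.
* **SG / FD** - Savitzky-Golay least-squares smoothing or first derivative,
  window 11, polynomial order 2 by default. The output keeps the input length:
  within half a window of either edge the window is truncated to the available
  points (widened inward if the fit would be underdetermined) and the local
  polynomial refitted. Same-length output keeps SPA index bookkeeping trivial.
  FD divides by the median wavelength step, giving reflectance per nm, and
  uses the derivative filter rather than simple differencing for noise
  robustness.
* **DT** - subtract the per-spectrum least-squares polynomial in wavelength
  (order 2 default), computed through an orthonormalized basis for stability.
* **SS** - column-wise standardization by training means and (n-1) sds; a
  zero-variance training column is an error naming the column.

One method is applied at a time (no stacking), matching the workflow being
replicated. SS appears only as a named method; the CNN additionally
standardizes its inputs internally (below), which is an implementation detail
of that engine, not a preprocessing arm.

## SPA wavelength selection

The successive projections algorithm grows a chain of minimally collinear
columns: starting from the column most correlated with the response (a full
start-column sweep is deliberately omitted - it multiplies cost roughly
1500-fold and the described protocol does not sweep), each step projects all
unselected columns onto the orthogonal complement of the selected span and
appends the largest residual (ties to the lowest index). Residual norms below
1e-12 terminate the chain (rank exhaustion).

Candidate subset sizes m = 1..50 (the chain's prefixes - SPA chains are
nested, so one chain yields all candidate subsets) are scored by RMSECV:
10-fold cross-validation of an inner MLR model (PLS1 available by config),
averaged over 80 Monte-Carlo resampled fold assignments under the configured
seed. Singular inner fits score +Inf. The chosen size is the RMSECV minimum
(ties to the smaller size); `force_size = TRUE` fixes it at 50, reproducing
the protocol that reports exactly 50 wavelengths per indicator - an identical
size across six indicators indicates a fixed cap rather than six independent
minima, so both modes are supported. The per-size coefficient paths are
retained for selection plots. Implementation detail: each fold's predictions
for every prefix size come from one QR factorization of the fold's design
matrix, making the 80 x 10 x 50 scoring loop affordable (seconds at n = 134,
p = 1507).

## Regression engines

**PLS** is canonical single-response NIPALS with deflation of X only. The
latent dimension is chosen by 5-fold CV RMSE over 1..min(n, p) (bounded by the
achievable rank inside folds); coefficients are exposed on the original
wavelength scale for the influence-band plots. With full rank and all
components, PLS1 equals ordinary least squares - the tests assert this against
a normal-equations oracle.

**SVR** is epsilon-SVR (via `e1071`), searched by sampling exactly 10 distinct
configurations from the grid C in {0.1, 1, 10, 100}, gamma in {scale, auto,
0.01, 0.1, 1}, kernel in {linear, rbf, sigmoid}, scored by 5-fold CV RMSE.
The `scale`/`auto` tokens resolve to `1/(p var(X))` and `1/p`, the
conventional kernel-coefficient heuristics those tokens denote.

**CNN**: conv(16 channels, kernel 5, stride 2) -> batch-norm -> ReLU ->
maxpool(2, stride 1) -> conv(32, 3, 2) -> BN -> ReLU -> maxpool(2, 1) ->
conv(64, 1, 1) -> BN -> ReLU -> adaptive max-pool to length 1 -> FC 64
(dropout 0.2) -> FC 32 (dropout 0.2) -> FC 1; MSE loss, Adam. The
stride-1 pooling windows shrink the length by exactly one; they are
implemented exactly as printed. Feature-map lengths for a 1507-point spectrum
run 752, 751, 375, 374, 374, 1 (and 23, 22, 10, 9, 9, 1 for 50 selected
wavelengths); the pipeline-minimum input length works out to 15 points. The
network is implemented directly on base-R matrices (im2col convolutions, full
backpropagation) and is seeded end to end: weight initialization (He), batch
shuffling, and dropout masks all derive from the one seed, so training is
bit-reproducible.

Training choices the architecture description leaves open: learning rate
1e-3, batch size 16, no weight decay, no early stopping, 500 epochs (100 in
the grid's desk profile). We add a cosine learning-rate schedule (1e-3
decaying to near zero across the configured epochs, on by default): with the
constant rate, Adam visibly oscillates on small batches without settling -
training loss plateaus two orders of magnitude above the reachable optimum -
and the schedule removes that artifact without changing anything else. Inputs
are standardized per wavelength and the response internally z-scored using
training statistics (batch-norm-friendly scale; predictions return in
original units). A held-out set may be passed for per-epoch loss monitoring
and the loss-curve plots; it never influences weights or stopping. Dropout is
part of the architecture default (0.2); it acts as multiplicative noise, so
exact-fit probes on noiseless fixtures (see the test suite) disable it to
measure optimizer capacity rather than the regularizer's floor.

## Evaluation

R2, RMSE and RPD are computed as

    R2 = 1 - sum(y - yhat)^2 / sum(y - ybar)^2
    RMSE = sqrt(mean((y - yhat)^2))
    RPD = SD(y) / RMSE,  SD with the (n-1) divisor

using the evaluated set's own mean and SD (the literal reading of the
formulas; computing prediction-set R2 against the calibration mean is the
main alternative and changes little on balanced SPXY splits). The three are
algebraically linked: `RPD = sqrt(n / ((n-1)(1-R2)))`, an identity the tests
verify to 1e-9 on random vectors. RPD above 2 reads "robust", 1.4-2.0
"acceptable", below 1.4 "poor". Perfect predictions report RPD = Inf rather
than erroring, so exact synthetic fits don't abort a grid; constant reference
vectors are errors (both R2 and RPD undefined); R2 is never clamped, so
worse-than-mean predictors go negative. Coefficient influence bands rank
wavelengths by absolute PLS coefficient: top 25% high, middle 50% medium,
bottom 25% low, ties at boundaries placing the lower index in the higher band.

## The experiment grid and best-model rule

`run_grid()` crosses indicators x preprocessing x wavelength mode (full or
SPA) x model, with one SPXY split per indicator, train-only fitting of every
learned artifact (preprocessor statistics, SPA selection, model weights), and
metrics on both sets. Each cell's seed derives deterministically from the
config seed, so identical configs reproduce identical grids; failures are
recorded per cell with their reason and never abort the sweep. The tests
verify the leakage guard directly: deleting the prediction rows after the
split leaves every fitted artifact byte-identical.

Because the source narrative describes winners but not the rule, the rule is
explicit here: maximize prediction-set R2; break ties by higher RPD, then
lower prediction RMSE, then model simplicity (PLS before SVR before CNN).

## Problem sizes and runtime

The analysis scripts run the full 192 x 1507 dataset: the PLS/SVR sweeps take
minutes on one CPU; the CNN at 1507 wavelengths costs tens of seconds per 100
epochs, so the scripted grid trains it for a representative indicator rather
than all 36 cells. The test suite exercises the same code paths at reduced
sizes (20-60 wavelengths, 20-48 samples, SPA oracle fixtures of 6 columns)
chosen to keep the suite in the low minutes while still covering every
contract; the two stochastic capability checks (PLS recovery on the full-size
generator, CNN exact-fit) run at full problem size and full epoch count.

## Known limitations

* Synthetic validation only: no deposited spectra exist, so the published
  performance numbers are not reproduction targets and field performance is
  out of scope.
* Gaussian bands and homoscedastic noise are idealizations; derivative
  preprocessing in particular behaves more favorably here than on real
  detector noise.
* The SPA implementation pairs classic projection chains with Monte-Carlo
  RMSECV scoring; selection narratives built around competitive adaptive
  reweighting (CARS) would need a different selector, deliberately out of
  scope.
* The CNN is CPU-bound and shallow by design; deeper architectures and GPU
  training are out of scope.
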