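---
title: "Methods: chamber fluxes, ARQ and respired-carbon isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chamber fluxes, ARQ and respired-carbon isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemresp)
```

## Scope

`stemresp` processes closed-chamber stem gas-exchange campaigns in which
CO₂ efflux and O₂ influx are measured simultaneously on tree stems —
typically in manipulation experiments such as girdling, where interrupting
the phloem stream forces stems onto older reserves and lipid catabolism.
Three measurement streams are supported: 10-s chamber sensor logs, flask
incubations analyzed for δ¹³C and Δ¹⁴C of respired CO₂, and Oil-Red-O
(ORO) stained wood sections. Because raw field data of this kind are rarely
deposited, the package pairs every estimator with a forward simulator of
known ground truth; all validation is parameter recovery on simulated
inputs.

## The chamber measurement model

One measurement cycle closes the chamber for 45 min and then flushes it
with ambient air for 15 min; gas concentrations are logged every 10 s. The
simulator (`simulate_cycle()`) treats the headspace as well mixed at
constant temperature and pressure within a cycle (diel variation is applied
between cycles — the cycles are short and the chambers small), and tracks
molar amounts of CO₂, O₂, H₂O and the inert balance (N₂ + Ar). Per unit
time the enclosed stem adds `resp_flux · A` µmol CO₂, removes
`resp_flux/rq_true · A` µmol O₂, and evaporates `evap_rate · A` µmol H₂O,
capped so the headspace never exceeds Magnus-formula saturation. Reported
mole fractions are component over total (wet), which is what nondispersive
infrared CO₂ sensors and optical O₂ sensors deliver, so the measured O₂
series embeds the dilution effect of accumulating H₂O and CO₂. Flushing is
assumed to reset the headspace completely to ambient air (400 ppm CO₂,
209,500 ppm O₂ by default); partial flushing would shift cycle baselines
but not within-cycle slopes, which is all the estimators use.

The flux equation inverts this model: `F = dC/dt · (V/A) · P/(R·T)` with
`R = 0.008314` m³ kPa K⁻¹ mol⁻¹. Temperature and pressure enter as fit-window
means. Slopes are fitted by ordinary least squares over the half-open
window `[300 s, 1500 s)` — the first 5 min are discarded against
valve-switching pressure artefacts, the following 20 min (120 points) are
used. The boundary convention is tested explicitly: sample 290 s is out,
300 s is in, 1500 s is out.

## Dilution correction of O₂ — a design choice

O₂ is a non-trace gas: at ~209,500 ppm, evaporating water and accumulating
CO₂ change its measured mole fraction without any O₂ exchange. The obvious
rescaling to a H₂O- and CO₂-free matrix, `o2 / (1 − (h2o + co2)/10⁶)`,
removes the bulk dilution of the *level* but not the cross term between the
large O₂ fraction and the CO₂ trend; applied to slope ratios it
overestimates a true respiratory quotient of 1 by roughly 25% (the check is
part of the package's own validation: the measured ARQ becomes ≈ 1.25 on a
simulated equimolar-exchange cycle). `stemresp` therefore defaults to
referencing O₂ to the inert (N₂ + Ar) balance of the air, which is strictly
conserved in a closed chamber:

```
inert(t) = 10⁶ − o2(t) − h2o(t) − co2(t)
o2_corr(t) = o2(t) · inert(t₀) / inert(t)
```

The corrected series is O₂ per mole of inert air, rescaled to the reference
composition, so its slope equals the molar O₂ exchange rate divided by the
headspace amount at the reference sample — exactly, for any respiratory
quotient and evaporation rate. The same renormalization is applied to CO₂
by default (`correct_co2 = TRUE` in `process_cycle()`); for a trace gas the
effect is a fraction of a permil on the slope, but it makes the noise-free
flux round trip exact to numerical precision. The simple ratio form is
retained as `method = "ratio"` for comparison with processing chains that
use it.

A consequence worth knowing: on a humidifying chamber the *uncorrected* O₂
decline is strictly steeper than the corrected one, so skipping the
correction always biases ARQ low. This direction-of-bias property is
asserted across 50 noisy cycles in the test suite.

## Quality control and aggregation

Screening follows common flux-QC practice, with each criterion applied as
its own recorded flag and the cycle retained only if all pass:

* **R² ≥ 0.96** for the regression of each gas separately. The threshold
  is configuration (`r2_min`); setting it to 0 retains every cycle.
* **Mean fit-window RH ≤ 99%.** The mean is used rather than the maximum
  because it is robust to single-sample spikes; the statistic is a config
  choice (`rh_max`).
* **Slope signs**: CO₂ rising and corrected O₂ falling.
* **ARQ outliers**: Tukey fence `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` with type-7
  (linear interpolation) quartiles, applied per tree by default
  (`iqr_group`); with fewer than 4 values the filter passes everything
  through with a warning.

Gaps strictly shorter than 2 h in each tree's hourly cycle series are
filled by linear interpolation (`zoo::na.approx` under the hood) and
flagged; longer gaps stay missing. Aggregation uses 6-h bins aligned at
00/06/12/18 (midnight alignment is a convention choice), and a daily mean
is computed only when all four bins of the calendar day contain data.

## Isotope processing

**Davidson correction.** `davidson_correct()` implements
`δ = (Cs(δs − 4.4) − Ca(δa − 4.4)) / (1.0044 (Cs − Ca))` with ambient
defaults Ca = 400 ppm, δa = −9‰. It requires `Cs > Ca` (otherwise there is
no respired accumulation to correct). Its validation oracle constructs
flasks forward by *exact* molar ¹³C/¹²C bookkeeping — respired CO₂ enters
carrying the steady-state diffusive enrichment (factor 1.0044, shift
+4.4‰) and mixes with ambient air in ratio space, not in the linear δ
approximation — and the correction recovers the source δ¹³C within 0.05‰
for flasks at twice ambient CO₂ or more.

**Radiocarbon age.** `mean_c_age()` inverts the near-linear decline of the
post-bomb atmospheric curve: `age = (Δ¹⁴C_sample − Δ¹⁴C_atm)/4.7`.
Atmospheric records are looked up with linear interpolation, treating
annual growing-season values as mid-year points. Radioactive decay between
fixation and respiration is neglected (< 0.7‰ over 60 years, below
measurement precision). Negative raw ages are clamped to 0 and flagged.
Samples more than 5‰ below the contemporary atmosphere are screened out as
fossil-influenced before age estimation; because the rule could also be
read as an absolute 5‰ floor, both readings are implemented behind
`screen_fossil(mode =)`, defaulting to the relative one — the only reading
under which near-atmosphere samples on the now-negative limb of the curve
survive.

**Substrate mixing.** The two-endmember model uses soluble sugars at
−27.11‰ and neutral lipids at −31.14‰ (both configurable);
`f_lipid = (δ_obs − δ_carb)/(δ_lipid − δ_carb)`, clipped to [0, 1] with an
out-of-range flag, and `expected_arq = 1 − 0.3·f_lipid` from the canonical
substrate quotients (1.0 carbohydrate, 0.7 lipid). Mixing is linear in
carbon flux fractions with no kinetic fractionation — endmember signatures
are treated as directly inherited by the respired CO₂. The flask simulator
emits the source δ¹³C itself (the Davidson step applies to real flasks that
contain ambient admixture, not to these simulated source values).

## ORO image quantification

The simulator places non-overlapping red disks (radii uniform in a
configured range) on a pale background until pixel coverage is within 0.02
percentage points of target, recording the realized pixel count as ground
truth; an unreachable target (disk packing) is an error. Masking uses red
dominance, `R − max(G, B) > 50` on 8-bit channels — the stain is strongly
red against pale wood tissue, and the threshold is exposed for real
captures with different illumination.

The coverage estimator mirrors the field protocol: ten contiguous 3-mm
sections along the bark-to-pith axis, 50 ROIs of 0.25 mm² per section, 500
ROIs total, estimate = mean over all ROIs. ROIs are squares (side 0.5 mm;
the protocol does not fix a shape) placed independently and uniformly, so
they may overlap; ROI pixel sums use a summed-area table. The sampling
error of the estimate is quantified by the standard error of the ROI mean
(`sd(ROI values)/sqrt(n)`): a pixel-level binomial error would understate
it badly, since droplets make stained pixels spatially clustered, and the
recovery tests use the ROI-level standard error accordingly.

## What the simulator does and does not emulate

Emulated: well-mixed headspace gas dynamics with O₂ self- and
cross-dilution, Magnus-capped humidification, diel temperature (sinusoid,
peak 15:00), Gaussian sensor noise, linear CO₂ sensor drift, complete
flushes; flask isotopes from a stated mixture and fixation age; stained
sections as disks of pure stain color.

Not emulated: stem photosynthesis, axial CO₂ diffusion and xylem transport
of dissolved CO₂ (the processes that make a field ARQ "apparent"), partial
flushing, sensor nonlinearity and recalibration events, within-cycle
temperature drift, illumination gradients and stain-intensity variation in
histology. Passing recovery tests therefore demonstrates correctness of
the estimators under the stated measurement model, not robustness to every
field artefact; in particular, real ARQ departures from substrate
stoichiometry carry physiological signal that no amount of chamber QC
removes.

## Numerical conventions and validation sizes

* Noise-free round trips are asserted tightly: flux recovery < 0.1%
  relative over effluxes 0.1–10 µmol m⁻² s⁻¹; ARQ recovery to 3 decimals
  over quotients 0.6–1.0; substrate fractions and ages to 1e-9 through the
  flask simulator.
* Constant concentration series report slope 0 with R² = 0 (then rejected
  by QC); constant time vectors and fits with fewer than 3 points are
  errors.
* Seeded reproducibility is bit-exact for every stochastic generator; a
  campaign draws all chambers from one seeded stream, so chambers have
  mutually independent noise but the whole campaign replays from one seed.
* Validation problem sizes: single cycles of 270 samples; noisy-recovery
  campaigns of 1 chamber × 5 days (120 cycles); the end-to-end
  two-treatment campaign of 6 chambers × 5 days (720 cycles) with flasks
  carrying 0.3‰ δ¹³C and 2‰ Δ¹⁴C measurement noise (typical IRMS and AMS
  precisions); images of 3000 × 600 px at 10 µm px⁻¹ (the full 30-mm,
  500-ROI protocol). These sizes make every recovery property
  statistically decisive while keeping the whole suite fast.

## Known limitations

* The flux equation assumes constant headspace molar content at the
  ideal-gas value; evaporation and non-unity quotients change the total by
  ~0.1% over a window, which is the dominant (and accepted) error term in
  the noise-free flux round trip.
* The inert-reference dilution correction assumes the inert fraction is
  known from the measured channels; O₂ channel noise therefore leaks
  (attenuated by ~4×) into the corrected CO₂ series when `correct_co2` is
  on.
* Group summaries are means ± sample SD; the package deliberately stops
  short of mixed-effects inference on treatment contrasts.
* The ORO estimator quantifies areal coverage of a binary mask; it does not
  grade stain intensity or resolve overlapping droplets in depth.
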