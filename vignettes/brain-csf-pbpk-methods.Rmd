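---
title: "Methods: a pediatric whole-body PBPK model with a four-compartment brain/CSF sub-model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a pediatric whole-body PBPK model with a four-compartment brain/CSF sub-model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainpbpk)
```

## The model

`brainpbpk` simulates plasma and cerebrospinal-fluid (CSF) drug
concentration-time profiles from preterm neonates to adults.  The whole body
is represented by 14 compartments (lung, brain, adipose, bone, heart,
kidney, muscle, skin, liver, gut, spleen, a lumped "rest" tissue, and
arterial and venous blood).  Non-brain organs are perfusion-limited and
well-stirred,

$$\frac{dA_t}{dt} = Q_t\left(C_{art} - \frac{C_t\,BP}{K_{p,t}}\right),$$

with venous &rarr; lung &rarr; arterial circulation, portal inflow to the
liver from gut, spleen and the hepatic artery, and whole-body clearance
acting on venous plasma (elimination is not attributed to specific organs;
the site is isolated behind one switch in the assembly code).

The brain is subdivided into four compartments — brain blood, brain mass,
cranial CSF and spinal CSF.  Unbound drug crosses the blood–brain barrier
(BBB, brain blood &harr; brain mass) and the blood–CSF barrier (BCSFB,
brain blood &harr; cranial CSF) passively, with permeability–surface-area
products $PS_b$ and $PS_c = PS_b/2$.  The brain-mass/cranial-CSF interface
has no real barrier and uses $PS_e = 1000 \cdot PS_b$ by default
(configurable per drug file); with the whole system being linear, any value
large relative to the CSF flows behaves as a no-barrier interface, and tying
it to $PS_b$ keeps the stiffness of the system proportionate to the drug's
own permeability.  CSF flows connect the compartments: bulk flow from brain
mass to cranial CSF ($Q_{bulk} = 0.25\,Q_{prod}$), shuttle flows between
cranial and spinal CSF ($Q_{sin} = Q_{ssink} + Q_{sout}$,
$Q_{sout} = 0.9\,Q_{ssink}$), and reabsorption to blood
($Q_{ssink} = 0.38(0.75\,Q_{prod} + Q_{bulk})$,
$Q_{csink} = 0.75\,Q_{prod} + Q_{bulk} - Q_{sin} + Q_{sout}$), which closes
the balance $Q_{csink} + Q_{ssink} = Q_{prod}$ exactly.  Transporters are
not modeled: the supported compounds transfer passively.

Because every transfer term appears with opposite sign in exactly two
equations, the assembled rate matrix conserves mass structurally; the test
suite asserts this at machine precision and checks total mass balance
against the administered dose on every simulation.

## Age-dependent physiology

* **Brain volume.** Brain weight (kg) follows the saturating relation
  $(10a + 0.315)/(9 + 6.92a)$ with $a$ in years, converted to volume with a
  brain density of 1.04 kg/L.  We evaluate $a$ as age *since conception*
  (postnatal age + 0.75 y).  This was a genuinely open reading: with purely
  postnatal age the relation yields a 35 g brain at birth — smaller than the
  fixed 0.143 L cranial CSF volume, which makes the neonatal brain-mass
  volume negative and the model infeasible — whereas the conception basis
  gives ~0.53 kg at term birth and ~1.39 kg in adults, both physiological.
  The relation is isolated in `brain_volume_total()` with an `age_basis`
  argument, and pinned by a regression test.
* **CSF production.** 0.024 L/h from 3 months onward; below 3 months
  $(4.007 \ln(\text{age in days}) + 7.088)/1000$ L/h.  Natural log and
  postnatal days were chosen because they render the piecewise relation
  continuous (0.0251 L/h at 90 days, within 5% of the constant branch).
  Spinal ketamine anesthesia doubles the production rate, and all dependent
  flows are re-derived from the doubled rate.
* **CSF volumes.** Cranial CSF is 0.143 L at every age (it does not grow
  after birth).  Spinal CSF is $(1.94\,BW + 0.13)/1000$ L, capped at 20% of
  total CSF volume; with cranial CSF being 80% of the total as in adults the
  cap equals $0.25 \times 0.143 = 0.0358$ L, reached near 18 kg.
* **Brain blood flow.** The fraction of cardiac output perfusing the brain
  is $(10 + 2290(10^{-0.608a} - 10^{-0.639a}))/100$ with postnatal age $a$:
  10% in adults and ~50% in late infancy.
* **BBB surface area.** Surface per gram of brain is age-invariant, so the
  adult reference surface (15 m², mid-range of adult literature values)
  scales with the child/adult brain-volume ratio; the adult reference volume
  is evaluated at 35 y.
* **Growth and whole-body parameters.** Weight and height come from
  condensed sex-specific growth references interpolated with monotone
  splines (log-normal residuals, CV 13% and 3.5%); body surface area uses
  Du Bois; cardiac output is cardiac index (4.2 &rarr; 3.2 L/min/m² from
  infancy to adulthood) times BSA; organ volumes are adult fractions of body
  weight with muscle and adipose ramping from neonatal to adult fractions,
  the brain following its own relation, and "rest" closing the volume
  balance; tissue flows are adult fractions of cardiac output renormalised
  to $1 - f_{brain}(a)$ so that flow closure is exact at every age.  For
  individuals drawn light-for-age, the weight-proportional tissues are
  shrunk proportionally so the fixed-size brain still fits the body volume
  (a degenerate-input safeguard, not a growth model).

## Inter-individual variability

Residual variability is log-normal, $P_i = P_{pop} e^{Z\eta}$.  We treat
$\eta$ as the log-scale *standard deviation*,
$\eta = \sqrt{\ln(1 + (CV/100)^2)}$, so that the stated CVs are reproduced
on the natural scale (a Monte-Carlo test checks the empirical CV to within
2 points); the alternative variance reading would square a quantity that is
already dimensionless and fail that check.  Stated CVs: CSF production 10%,
bulk flow 8%, $Q_{sout}$ 100%, $Q_{ssink}$ 30%, plus per-drug clearance and
absorption CVs from the drug file.  Parameters without a stated CV carry
none.  Correlation between parameters arises only through the shared
covariates (age, sex, weight, height); residual draws are independent.
After variability, $Q_{sin}$ is recomputed as $Q_{ssink} + Q_{sout}$ and
$Q_{csink}$ re-closes the production balance; in the rare extreme draw
(~0.1% of individuals at CV 30%) where the closure would drive $Q_{csink}$
negative, it is floored at $10^{-6}$ L/h with a warning.  All randomness
derives from one top-level seed split deterministically per individual, so
populations are bit-reproducible.

## Drug model

Tissue:plasma partition coefficients use a composition-based
(Poulin–Theil-type) scheme: the pH 7.4 distribution coefficient
(Henderson–Hasselbalch by ionization class; the vegetable-oil correlation
$\log D_{vo} = 1.115 \log D - 1.35$ for adipose) partitions drug into
neutral lipid plus 30% of phospholipid against tissue water, referenced to
plasma, with a tissue/plasma unbound-fraction correction (interstitial
protein at half the plasma concentration).  Neonatal tissues carry more
water and less lipid, fading to adult composition with a ~6-month time
constant.  Per-organ `kp_overrides` in the drug file replace predictions —
used for meropenem, whose extracellular-restricted distribution
(V<sub>ss</sub> ≈ 0.25 L/kg) composition schemes overestimate — and the
uniform `kp_scalar` multiplies every organ (0.33 for flurbiprofen).

$PS_b$ comes either from an in-vitro permeability (dm/h) times the BBB
surface (dm²; stored in m² and converted inside the operation) or directly
as an adult L/h value; either way it is scaled per individual by the
brain-volume ratio.  $PS_c = PS_b/2$ always.  Clearance is a whole-body
input: adults use the adult value, children a body-weight relation (linear,
allometric or power) from the drug file; weights outside the relation's
validated range are extrapolated with a warning, never refused.  State
variables are tracked as amounts; blood-side transfer uses the
blood:plasma ratio, and the unbound fraction in brain blood is
$fu_{plasma}/BP$.  CSF unbound fractions default to 1 (negligible CSF
protein).

## Numerical choices

The system is linear, so it is assembled once as a rate matrix and
integrated with `deSolve::lsoda` using the constant analytic Jacobian,
relative tolerance 1e-8 and absolute tolerance 1e-10.  Doses are handled as
events: the integrator restarts at every bolus time, infusion start and
infusion end, so discontinuities are exact.  The output grid is decoupled
from solver steps.  Initial conditions are zero.  Oral dosing is a
first-order depot into the gut compartment with bioavailability applied at
dose time.  A one-compartment reduction is checked against the closed-form
solution to 1e-6 relative.

## Meningitis permeability estimation

No mechanistic meningitis permeability being available, $PS_b$ and its CV
are estimated empirically from adult CSF data: a two-parameter grid search
(median $PS_b$ on a log grid, CV on a linear grid) minimising the squared
log-distance between the simulated median spinal-CSF profile and the pooled
observed CSF points, plus a dispersion term matching the simulated 90% band
width (per 1.645 log-SD) to the observed residual spread, with a
configurable weight (default 1).  The same virtual individuals (common
random numbers) are used for every candidate, making the fit deterministic
given the seed.  The objective is a reconstruction — the original
"empirical optimization" is not further specified — and is isolated behind
the function interface so alternatives (e.g. quantile matching) can be
swapped.  Plasma-side parameters are never touched.  Steady-state
"time after dose" observations should be aligned to the simulation clock
(24 h + time after dose) before fitting.  The estimate propagates to
children by brain-volume scaling, with the fitted CV applied per individual.

## What the synthetic-data generator emulates

`generate_fixture_observed()` mimics lumbar-puncture study designs: richer
plasma sampling, one CSF sample per subject at a random time, multiplicative
log-normal residual noise, and known truth parameters recorded alongside.
It draws from the simulator itself, so parameter-recovery tests demonstrate
internal consistency of the estimation machinery — identifiability of
$(PS_b, CV)$ under realistic sparsity and noise — not agreement with real
clinical data.  Real observations add model misspecification, assay error
structure, dosing-history uncertainty and disease heterogeneity that the
generator does not emulate.

## Study conditions and problem sizes

The packaged scenario configurations mirror the validation study designs:
pediatric paracetamol (15 mg/kg IV, ages 0.25–13 y, 59% male) is simulated
with the ketamine flag on, because the pediatric lumbar-puncture studies
administered spinal ketamine anesthesia — that flag is exactly what the
doubled CSF production represents — while the adult volunteer scenario
(1000 mg IV, 19–44 y) runs without it.  Meropenem scenarios use 0.5-h
infusions q8h (duration unstated in the sources; it affects C<sub>max</sub>,
negligibly AUC), a 5-day treatment-course horizon (15 doses, 120 h) and
AUC(0–last) of the median profiles, reflecting sampling spread across
multi-day courses in meningitis studies.  The acceptance script simulates
1000 virtual individuals per paracetamol arm and 300 per meropenem
scenario; the test suite uses 120–250 per arm and 30–40 individuals per
grid candidate in the permeability fit, sizes at which the median-profile
summaries are stable.

## Known limitations

* Cranial CSF volume is fixed at the adult 0.143 L from birth.  This
  follows the source physiology table, but it is anatomically generous for
  neonates and gives them a CSF equilibration time constant of tens of
  hours; simulated neonatal CSF/serum exposure ratios for low-permeability
  drugs are therefore sensitive to the AUC window and sit below
  adult values in our scenario set.
* Clearance is a whole-body input; there is no organ-level metabolic
  ontogeny or in-vitro-to-in-vivo clearance extrapolation.
* No transporter kinetics, no intracellular/extracellular brain
  subdivision, no time-varying permeability during antibiotic recovery,
  no fetal/pregnancy physiology.
* Growth references are healthy-population medians; disease-related
  anthropometry (e.g. preterm weight-for-age) is not modeled beyond the
  sampled variability.
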