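---
title: "Modelling blueberry fruit growth with berryflux: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling blueberry fruit growth with berryflux: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(berryflux)
```

## The model

`berryflux` simulates the growth of a single blueberry fruit as a
biophysical compartment — one large "cell" behind a composite membrane
separating it from the xylem and the phloem. Two state variables are
integrated hourly: dry mass $s$ (mg) and water mass $w$ (mg); fresh mass
is their sum (seed mass, below ~1 % of the total in highbush blueberry,
is ignored).

The carbon balance is
$$\frac{ds}{dt} = U_s - R_f,$$
where total sugar uptake $U_s$ is the sum of active transport across the
apoplast, mass flow with the phloem water stream, and passive diffusion,
and respiration $R_f$ has growth, maintenance and *ripening* components.
The water balance is
$$\frac{dw}{dt} = U_x + U_p - T_f,$$
with xylem and phloem uptake driven by water-potential gradients across
the membrane and transpiration $T_f$ through the fruit skin.

What distinguishes the model from its peach/grape ancestors is the
hormonal control layer: endogenous abscisic acid (ABA), the ripening
signal of non-climacteric fruit, modulates four processes. ABA
concentration is an empirical beta-growth function of cumulative growing
degree hours,
$$\mathrm{cGDH}(t) = \sum_{\text{hours}} \max\{0,\ \min(T, T_o) - T_b\},
\qquad
\mathrm{ABA}(x) = \mathrm{ABA}_0 + (\mathrm{ABA}_f - \mathrm{ABA}_0)\,
g(x),$$
$$g(x) = \Bigl(1 + \frac{\mathrm{ABA}_e - x}{\mathrm{ABA}_e -
\mathrm{ABA}_m}\Bigr)\Bigl(\frac{x}{\mathrm{ABA}_e}\Bigr)^{\mathrm{ABA}_e
/(\mathrm{ABA}_e - \mathrm{ABA}_m)},$$
clamped at zero. $g$ rises sigmoidally, peaks at exactly 1 when
$x = \mathrm{ABA}_e$ (so the concentration attains $\mathrm{ABA}_f$
there) and declines beyond — the surge–peak–decline course measured in
blueberry, grape and strawberry. The normalised signal
$u = (\mathrm{ABA} - \mathrm{ABA}_0)/(\mathrm{ABA}_f - \mathrm{ABA}_0)
\in [0, 1]$ then enters:

* **active sugar uptake** — $U_a = k_\mathrm{ABA} B(u)\, v_m\, s\,
  \frac{C_p}{K_m + C_p}\, \frac{1}{1 + e^{(t - t^*)/\tau}}$, where
  $B(u)$ is a second beta-growth bump anchored at the thresholds
  $STP_m$ (below which ABA barely promotes uptake) and $STP_e$ (the
  optimum), and the logistic factor is the classical transport
  "inhibitor" that shuts active uptake down late in the season;
* **ripening respiration** — $R_f$ gains the term $q_r\, u$ (mg h⁻¹)
  on top of $q_g \max(0, ds/dt)$ and $q_m(T)\, s$ with
  $q_m(T) = q_{m,\mathrm{ref}} Q_{10}^{(T - T_\mathrm{ref})/10}$;
* **hydraulic conductivity** — $L = L_{\max} e^{-k_L u}$, shared by the
  xylem and phloem pathways;
* **skin permeability** — $\rho = \rho_{\min} + \rho_0 e^{-k_p u}$,
  which multiplies the transpiration flux
  $T_f = A_f\, \alpha(T)\, \rho(u)\, \max(0, H_f - H_a) \times 1000$
  and so lets a ripening (or stressed) fruit seal itself against water
  loss.

The water side closes with standard biophysical bookkeeping: volume
$V = w/\rho_\mathrm{water} + s/\rho_\mathrm{dry}$; surface area
$A_f = c_\mathrm{area} (\mathrm{fresh}/1000)^{2/3}$ and membrane area
$A_m = a_\mathrm{mem} A_f$; van't Hoff osmotic pressures
$\pi = RTC \times 10^{-6}$ MPa, with the fruit-side solute equal to the
soluble-sugar pool ($ssr \cdot s/w$, converted to molarity) plus a fixed
non-sugar contribution; and a Lockhart turgor closure. Boundary
conditions: the xylem runs at the stem water potential with negligible
osmotic content ($P_x = \Psi_\mathrm{stem}$, $\pi_x \approx 0$), and the
phloem is in water-potential equilibrium with the stem
($P_p = \Psi_\mathrm{stem} + \pi_p(C_p)$). The turgor $P_f$ solves the
linear balance
$$A_m L \bigl[(P_x - P_f - \sigma_x(\pi_x - \pi_f)) +
(P_p - P_f - \sigma_p(\pi_p - \pi_f))\bigr] - T_f =
\rho_\mathrm{water}\, V\, \phi(t)\, (P_f - Y)$$
when the solution exceeds the yield threshold $Y$ (plastic growth at
rate $V\phi(P_f - Y)$); otherwise the growth term is dropped and $P_f$
(clamped at 0) simply sets the net water exchange. The two branches meet
continuously at $P_f = Y$. Cell-wall extensibility decays
logistically, $\phi(t) = \phi_{\max}/(1 + e^{(t - t_\phi)/s_\phi})$.
Elastic volume change and the dry-matter contribution to $dV/dt$ are
neglected in the closure (water dominates volume change), consistent
with the single-cell framework the model inherits.

## Drivers and the synthetic season

The model is forced by hourly air temperature and relative humidity.
Two within-plant drivers are generated internally:

* stem water potential oscillates diurnally between −0.10 MPa
  (pre-dawn, phased at 03:00) and −1.8 MPa (mid-afternoon, 15:00) as a
  24 h sinusoid — the bounds are physiological observations, the phase a
  standard micrometeorological convention;
* phloem sucrose ramps seasonally from 15 mM at anthesis to 100 mM at
  the end of the simulated period as a half-cosine — the bounds are
  standard for fruit phloem sap; the within-season shape is a package
  default, not a measured profile.

`generate_synthetic_weather()` emulates a temperate continental growing
season: an annual sinusoid (amplitude 14 K around an 12 °C mean, peaking
mid-July), an asymmetric diurnal wave built from two half-cosine arcs
(minimum 05:00, maximum 14:00 — a single sinusoid cannot place extremes
9 h apart), anti-phase relative humidity, and seeded Gaussian noise
(SD 1.2 K and 0.04 RH). `synthetic_season()` fixes anthesis at 10 May, the
conditions under which the packaged parameter set was tuned. The
generator does **not** emulate weather fronts, rain, multi-day heat
waves or humidity–temperature correlation beyond the diurnal cycle, so
passing tests demonstrate internal consistency and qualitative
behaviour, not predictive skill on real orchard data.

Saturated vapour density uses the Magnus formula (Alduchov–Eskridge
coefficients) with the ideal gas law; at 20 °C it gives
$1.73\times10^{-5}$ g cm⁻³.

## Parameters

`describe_parameters()` prints the full set with units, bounds and
provenance. Thirteen parameters are flagged `calibrated` — the
thermal-time anchors $\mathrm{ABA}_m, \mathrm{ABA}_e$, the membrane-area
coefficient $a_\mathrm{mem}$, the skin-permeability triple
$\rho_0, \rho_{\min}, k_p$, the conductivity sensitivity $k_L$, the
yield threshold $Y$, the sugar-uptake group $v_m, k_\mathrm{ABA},
STP_m, STP_e$, and the ripening coefficient $q_r$. Their packaged values
were calibrated against the qualitative season dynamics the model is
built to reproduce — an ABA surge to a 32.30 µg g⁻¹ peak near 59 days
after anthesis followed by decline; dry mass rising to a maximum around
70 DAA and then declining as sugar uptake falls below respiration; water
mass rising through a fast phase and then flattening; fresh mass around
1.4 g with ~15 % dry matter; and the warming orderings (earlier, lower
dry-mass peaks under +3/+5 K offsets). Values flagged `literature` are
standard magnitudes from the peach/grape biophysical fruit-model
lineage (e.g. $K_m = 0.08$ mass fraction, $Q_{10} \approx 2$,
$H_f = 0.996$). They are defaults to calibrate from, not measurements;
none should be quoted as a measured property of 'Bluecrop' blueberry.

Units are fixed internally — K, MPa, mM (≡ mol m⁻³), mg, h — with all
conversions (°C, %RH) at the I/O boundary, because mixed units are the
dominant bug source in this model family.

## Numerical choices

* **Integrator**: explicit Euler at the native 1 h weather resolution,
  with optional integer substepping (drivers held constant within the
  hour). The dynamics are smooth and slow relative to 1 h; adequacy is
  *tested*, not assumed — halving the step moves the final fresh mass by
  well under 1 % on the default season.
* **Turgor solve**: closed-form solution of the linear flux balance; the
  residual of the solved equation is recorded per hour and checked to
  be below $10^{-10}$.
* **Clamps**: negative transpiration (condensation) is clamped to 0;
  reverse sugar mass flow is clamped to 0 (no sugar returns to the
  phloem); state masses are clamped at zero (water at $10^{-9}$ mg so
  concentrations stay defined) with a warning — degenerate
  parameterisations are a calibration reality and should not crash an
  optimiser.
* **Peak reporting**: peaks are located on the hourly grid; the sampled
  ABA peak is within ~$10^{-5}$ of its analytic height.

## Calibration design

Calibration follows the two-stage protocol: stage `"aba"` fits the
thermal-time anchors ($\mathrm{ABA}_m, \mathrm{ABA}_e$) to ABA
observations; stage `"full"` then fits model parameters (default:
$v_m, k_\mathrm{ABA}$) to fresh-mass observations with the ABA stage
frozen. The optimiser is a seeded differential-evolution-style bounded
global search (rand/1/bin, strict-improvement acceptance) followed by a
deterministic `nlminb` polish on bound-normalised coordinates; the seed
makes every fit reproducible.

One structural fact shapes the design: $v_m$ and $k_\mathrm{ABA}$ enter
the model *only* as a product, so they are exactly non-identifiable from
mass data — the likelihood has a flat ridge. The objective therefore
adds a weak quadratic penalty on the relative deviation from the
starting values (`prior_weight = 0.05`, scaled by the observation
spread). Along identifiable directions the penalty is negligible (the
noise-free optimum is a cone, which the penalty cannot displace); along
a flat ridge it anchors the solution at the starting split, which is the
only information available there. Consequently a reported $v_m$ is only
as good as its prior; the product $v_m k_\mathrm{ABA}$ is the quantity
the data actually constrain. `at_bounds` flags estimates pinned at a
bound.

Censored ABA observations (below the 0.01 µg mg⁻¹ = 10 µg g⁻¹ assay
detection threshold) are excluded from ABA pairing and objectives.

## Evaluation toolkit

`fit_metrics()` implements MAE, RMSE, range-normalised RMSE, the
Nash–Sutcliffe efficiency $EF = 1 - \sum(y-\hat y)^2/\sum(y-\bar y)^2$
and Willmott's *refined* index of agreement
$$d_r = \begin{cases}
1 - \dfrac{\sum|y - \hat y|}{2\sum|y - \bar y|}, &
\sum|y-\hat y| \le 2\sum|y-\bar y| \\[2ex]
\dfrac{2\sum|y - \bar y|}{\sum|y - \hat y|} - 1, & \text{otherwise,}
\end{cases}$$
chosen as the standard bounded "index of agreement" whose values near 1
signal good fit. Metrics are computed on paired observation times (the
simulated hour nearest each observation day), not on the full hourly
trajectory. `sensitivity_analysis()` is strictly local one-at-a-time:
each of the 13 calibrated parameters is raised 10 % in turn and the
normalised coefficient $S = 10\,(\Delta W/W)/(\Delta P/P)$ (percent per
standardised +10 %) is reported for final dry, water and fresh mass —
$n+1$ simulations, baseline reused.

## What-if scenarios

`scenario_temperature_offset()` re-runs the season with every hourly
temperature shifted (+3 K, +5 K in the packaged experiments) and
humidity untouched; on the default configuration the ABA peak and the
dry-mass maximum arrive earlier and the dry-mass peak is lower under
warming — thermal time accrues faster while maintenance respiration
(Q10) rises and the ABA-modulated uptake window shifts against the
fixed-clock inhibitor. `scenario_anthesis_shift()` slides the anthesis
date across a fixed weather record and reports fruit mass at 80 days
after anthesis per date. `harvest_summary()` aggregates masses over a
calendar window (default July 25 – August 31).

## Known limitations

* ABA accumulation is empirical (thermal-time driven), not a
  biosynthesis/degradation/transport model; the post-peak decline to the
  baseline is a property of the beta form, and very warm scenarios can
  drive the late-season signal back to near zero, re-opening the skin
  and membrane pathways.
* Early in the season (first ~10 days) the default configuration loses a
  few mg of water before sustained growth begins: with a tiny fruit
  volume the nocturnal growth sink is small while midday backflow under
  a −1.8 MPa stem potential is not. Observed series typically start at
  10 DAA, where the simulated trajectory is already rising.
* No whole-plant carbon source, no canopy microclimate, no fruit
  temperature distinct from air, no cracking or wax-composition
  mechanics; a single composite membrane with one conductivity for both
  pathways.
* The simulator's problem sizes in tests (one 80-day hourly season;
  8-point observation sets; 5 calibration replicates) were chosen as the
  smallest configurations that exercise every pathway meaningfully.

## Reproducing a run

```{r example, eval = FALSE}
weather <- synthetic_season()
params <- default_parameters()
run <- simulate_fruit(weather, params)
print(run)
peak_times(run)
sensitivity_analysis(weather, params)
```
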