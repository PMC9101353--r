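---
title: "Stress-fiber mechanics: model, estimation and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-fiber mechanics: model, estimation and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
```

```{r setup}
library(sfmech)
```

## The physical picture

Peripheral actin stress fibers of a cell spanning non-adhesive gaps bow
inward under the cortical tension `sigma` (nN/µm) while carrying a line
tension `lambda` (nN) along their length. Force balance on a fiber element
gives a circular arc of radius

    R = lambda / sigma,

so the easily measured radius of curvature is a direct readout of the
tension ratio. When the substrate is stretched (or compressed) by a strain
`eps`, the fiber's anchoring distance changes, the line tension changes,
and `R` responds — first elastically, then with slow active adaptation.

## The three-element bundle model

The fiber plus its actin cortex anchoring is modelled as a series
arrangement: an external spring `K` (the fresh cortex/adhesion compliance,
extension `delta1`) in series with a parallel unit consisting of a spring
`k` (crosslinked bundle elasticity), a dashpot `gamma` and an active motor
element (extension `delta2`):

    lambda = K * delta1 + lambda0
    k * delta2 + gamma * ddelta2/dt + lambda0 * exp(-(ddelta2/dt)^2 / V^2) = lambda
    delta1 + delta2 = delta_l(t)

The motor force is maximal at stall (`lambda0`, the prestress that sets the
resting radius `R0 = lambda0 / sigma`) and falls off as a Gaussian in the
sliding rate with scale `V`. `delta_l(t)` is imposed by the stretch
protocol.

Two closed-form limits anchor everything:

* **Short time** (dashpot rigid): `R(0+) = R0 + (K0 L0 / sigma) * eps`.
  The initial slope of `DeltaR` versus strain measures `K0 L0 / sigma`.
* **Long time** (dashpot fully relaxed, springs in series):
  `DeltaR_inf = [k K0/(k+K0)] (L0/sigma) (1 - alpha * k/(k+K0) * eps) * eps`.
  The linear coefficient of the plateau slope measures the series
  combination, and the quadratic correction carries the adaptation index
  `alpha` (see below).

With an independent estimate of the fiber's elastic modulus (`E`, MPa) and
cross-section amplitude factor (`A`), the two measured slopes invert to
`sigma`, `lambda0 = sigma R0`, `K0`, `k` and the ratio `K0/k` — this is
`derived_mechanics()`.

### Strain gating and adaptation

The response is strongly asymmetric:

* **Compression** (`eps < 0`): the crosslinker spring disengages (`k = 0`),
  leaving a Maxwell element. The radius relaxes completely back to `R0`
  with the global time constant `gamma / K0`. `radius_long_time()` returns
  `R0` for `eps < 0`.
* **Extension** (`eps > 0`): fresh actin is recruited into the external
  spring, softening it over time:

      K(eps, t) = K0 * (1 - alpha * eps * (1 - exp(-t / t_star)))

  The recruitment index `alpha` and time scale `t_star` are measured
  independently from fluorescence intensity: the steady-state intensity
  gain is `alpha * eps` and the initial rate is `(alpha / t_star) * eps`
  (`fit_recruitment()` regresses both against strain).

```{r global-sim}
p <- mech_params(K0 = 0.186, k = 0.231, gamma = 2 * 0.186 * 300,
                 lambda0 = 2.347, V = 0.1, sigma = 0.03578,
                 E = 11.3, A = 0.6, alpha = 0.64, t_star = 427)
tr <- simulate_global(stretch_protocol(0.2), p, seq(-60, 1800, 5))
head(tr, 3)
```

## The local segment dynamics

Zooming into a 5-µm segment of the fiber, the same force balance holds
locally with segment tension `sigma_l`. Writing
`xi = Delta sigma_l / sigma0` and substituting `chi = tau * xi`, the
dynamics collapse onto a dimensionless first-order implicit ODE:

    dchi/dt = f/Gamma - nu * chi - (1/(2 Gamma)) * (1 - exp(-(dchi/dt)^2))

with the parameter groups

    nu = 2 K0 / gamma,   tau = sigma0 R0 / (K0 V),
    f  = K0 eps_l / (2 sigma0),   Gamma = gamma V / (2 sigma0 R0).

The steady state is `chi_ss = f / (nu Gamma)`. Differentiating once gives
an equivalent explicit second-order form, which the package integrates with
a stiff solver purely as a cross-check (`method = "second_order"`); the two
agree to better than 1e-6 in relative sup-norm.

### The structural identity and what the data identify

The four groups are not independent: for **any** physical parameter tuple

    Gamma * nu * tau = (gamma V / 2 sigma0 R0) (2 K0 / gamma) (sigma0 R0 / K0 V) = 1.

This identity has a practical consequence for fitting. At weak drive
(`f` of order 0.5), the solution of the ODE is numerically indistinguishable
from a trace parameterised by only two combinations: the relaxation rate
`nu` and the plateau `xi_ss = f / (nu Gamma tau)`. The raw `f` direction of
the objective is flat over more than an order of magnitude at realistic
noise levels — we verified that the profiled sum of squares at the edge of
the search box is *below* its value at the generating truth, the signature
of structural non-identifiability (not an optimizer failure).

`fit_local_ode()` therefore reports two mappings to the cortical tension:

* `sigma0` — the raw mapping `K0 eps_l / (2 f_hat)`. Meaningful only at
  strong drive where the motor nonlinearity pins `f` individually.
* `sigma0_identified` — through the identified functional
  `f_id = f_hat / (Gamma_hat nu_hat tau_hat)`. Because the truth satisfies
  `Gamma nu tau = 1` for every physical system, `f_id = f` in exact
  arithmetic, but `f_id` is estimated from an identified combination of the
  data and is stable at any drive. **Caveat:** if a trace were generated
  from a *non-physical* parameter tuple with `Gamma nu tau = c != 1`, the
  identified estimate converges to `sigma0 * c` — the estimator recovers
  the physically realisable system closest to the data, and the
  discrepancy factor is exactly the identity violation `c`.

```{r local-fit}
lp <- local_ode_params(nu = 1 / 320, tau = 240, f = 3, Gamma = 0.8)
tr_l <- simulate_local_chi(lp, t_grid = seq(0, 1500, 10))
ft <- fit_local_ode(data.frame(t = tr_l$t, y = tr_l$xi))
unlist(ft$estimates[c("nu_inv", "tau", "f", "Gamma")])
```

## Measurement operators

* `fit_circle_arc()` — Kasa algebraic circle fit refined by Gauss–Newton
  orthogonal-distance minimisation, followed by a leading-order
  nonlinear-least-squares bias correction (Box-type) computed from the
  fit's own Jacobian, curvature terms and residual variance. Short shallow
  arcs otherwise overestimate the radius by ~0.7% at study geometry and
  0.5 µm edge noise; the correction is deterministic and vanishes exactly
  on noiseless data, so the fit remains exact on ideal arcs and invariant
  under rotation and translation.
* `extract_kymograph()` — bilinear sampling along a user path,
  `photobleach_correct()` — global mono-exponential bleach estimated on a
  quiescent window and divided out, `normalize_relative()` — per-position
  (or per-region) `DeltaI / I0` relative to a baseline window,
  `segment_average()` — 5-µm segment tiling with small-remainder merging,
  `locate_landmarks()` — focal-adhesion end peaks and mid-fiber valley.

## Synthetic data

`generator_config()` centralises the population spread (anchoring distance,
radius, amplitude factor), measurement noise (radius SD, edge noise,
intensity CV), photobleaching and camera model. Generators return both the
noisy observable and the exact truth so estimator bias can be measured:

* `generate_radius_trace()` — radius time series through a stretch protocol;
* `generate_recruitment_cohort()` — intensity traces across strain levels;
* `generate_kymograph()` — spatially structured kymographs with bleaching;
* `generate_arc_stack()` — image stacks of drawn arcs with camera noise.

## Numerical choices

* **Implicit rate solve** (compiled): warm-started Newton with bisection
  fallback. The rate equation is monotone iff
  `gamma V >= sqrt(2) exp(-1/2) lambda0`; below that bound all roots are
  scanned and the one nearest the previous rate is taken (continuation),
  with a warning.
* **Windowed root scan:** during chi integration, a narrow window around
  the previous rate is scanned first and the nearest root accepted only
  when it is provably the global nearest; the full scan runs otherwise.
  Identical results, ~13x faster fitting.
* **Global integrator:** Heun scheme on an adaptive base grid with
  step-halving refinement against a 1e-6 relative tolerance.
* **Local fitting:** 81-point log-space multi-start grid screened by a
  single objective evaluation; the best 6 starts are polished with
  `nlminb`. Standard errors come from a finite-difference Gauss–Newton
  approximation on log-parameters; `sigma0_identified` errors propagate
  through the delta method.
* **Exponential fits** use `minpack.lm::nls.lm` directly because the
  `nlsLM` wrapper rejects zero-residual (exact) data.
* **Savitzky–Golay smoothing** (from `signal`) provides derivative
  estimates where needed without phase lag.

## Limitations and open choices

* The bleach correction assumes a global mono-exponential; spatially
  varying bleaching would need a per-position model.
* The local-ODE raw `f` (and hence raw `sigma0`) is reported even in the
  weak-drive regime where it is non-identifiable; consult its standard
  error and prefer `sigma0_identified`.
* The second-order cross-check integrator amplifies solver residual by
  `1/nu` near steady state; it runs at very tight tolerances and is not
  meant for production use.
* Landmark detection assumes a two-peak (adhesion) one-valley (mid-fiber)
  profile; monotone profiles yield a warning and ambiguous landmarks.
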