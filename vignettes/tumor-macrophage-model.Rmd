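---
title: "Tumor-macrophage dynamics, radiotherapy, and digital-twin trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-macrophage dynamics, radiotherapy, and digital-twin trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomatwin)
```

## The model

`gliomatwin` simulates glioma growth as an ecological interaction between
three live cell populations — tumor cells $T$, anti-tumor (M1-like)
macrophages $A$, and pro-tumor (M2-like) macrophages $P$ — plus two
damaged pools created by irradiation. The core is a cooperative
Gompertzian system: each population proliferates in proportion to its
partner population and to $\ln(K/V)$, so growth stalls as the total
volume $V$ approaches the carrying capacity $K$.

$$
\begin{aligned}
\frac{dT}{dt} &= \rho_T\, T P \ln\frac{K}{V} - \mu T A\\
\frac{dP}{dt} &= \rho_P\, P T \ln\frac{K}{V}
  + \lambda A \frac{T K_\lambda}{K_\lambda + T} + \phi T
  - \frac{P}{\tau_M}\\
\frac{dA}{dt} &= \rho_A\, A T \ln\frac{K}{V}
  - \lambda A \frac{T K_\lambda}{K_\lambda + T}
  + \xi \left(\frac{dT}{dt}\right)_{\!+}
  + [\mathrm{IR}]\,\phi_D (T_D + M_D) - \frac{A}{\tau_M}
\end{aligned}
$$

with $V = v_T (T + T_D) + v_M (P + A + M_D)$. Anti-tumor macrophages kill
tumor cells at rate $\mu$; tumor cells convert microglia to the pro-tumor
phenotype through a saturating Michaelis–Menten term (only a limited
microglial pool can switch, hence the saturation constant $K_\lambda$);
monocyte-derived macrophages (MDMs) infiltrate from the vasculature at
rate $\phi T$; tumor expansion recruits fresh microglia
($\xi\,dT/dt$); and macrophages turn over with lifespan $\tau_M$.

The pro-tumor pool is tracked as two provenance subpools, $P = P_1 + P_2$:
conversion feeds $P_1$ (microglia-derived), vascular influx feeds $P_2$
(MDM-derived), and proliferation and decay act pro rata on each subpool.
This attribution leaves the pooled dynamics exactly unchanged (a
property-tested invariant) while letting the package report the
microglia/MDM split that flow cytometry measures.

### Radiation as an impulsive map

Each radiation fraction at time $t_j$ is an instantaneous transfer:
a fraction $(1-S_T)$ of tumor cells moves to a damaged pool $T_D$, and
$(1-S_M)$ of all live macrophages moves to $M_D$. Damaged cells still
occupy volume but are functionally inert, clearing exponentially with
time constants $\tau_{TD}$ and $\tau_{MD}$. Total cell count is conserved
at the instant of each impulse. Two microenvironmental effects accompany
the damage: the MDM influx coefficient escalates by $1/S_T$ per fraction
(compounding across the course, with no cap — none is biologically
established), and from the first fraction onward an inflammation flux
$\phi_D (T_D + M_D)$ recruits anti-tumor macrophages to clear debris.
Numerically, integration stops at each fraction, the impulse map is
applied, and integration restarts from the mapped state.

### Therapies as windowed parameter modifiers

Three myeloid-targeted interventions are modelled as modifiers active on
half-open windows $[start, end)$:

* **anti-CD47** — multiplies the killing rate $\mu$ (default 3, a
  deliberately conservative reading of the roughly 5-fold phagocytosis
  increase reported for xenografts). No duration is established, so the
  default window is open-ended from its start.
* **α-CD49d** — attenuates the IR-induced escalation of $\phi$ to
  $1 + a(1/S_T - 1)$. The default $a = 0$ is the strongest reading (full
  blockade); baseline influx $\phi T$ is never blocked, because only the
  irradiation-induced increase is targeted by the antibody's
  anti-trafficking action.
* **CSF-1R inhibition** — combines three effects: the anti-CD47-style
  $\mu$ multiplier (default 3, flagged as an assumption — no number is
  established for this agent), full blockade of the IR escalation of
  $\phi$, and reversal of macrophage polarization by negating $\lambda$
  (equal magnitude, opposite sign, so the same saturating term now moves
  cells from the pro-tumor to the anti-tumor pool). The standard course
  is 12 days; continuous administration uses an open-ended window.

Neutral settings of every therapy reproduce the baseline model exactly,
and anti-CD47 and α-CD49d compose commutatively because they touch
disjoint parameters.

## Parameters

| symbol | argument | default | units | role |
|---|---|---|---|---|
| $\rho_T$ | `rho_T` | 1.6e-4 | /d/cell | tumor proliferation; *the* per-subject free parameter |
| $\rho_P$, $\rho_A$ | `rho_P`, `rho_A` | 5e-10, 1e-10 | /d/cell | macrophage proliferation |
| $\mu$ | `mu` | preset | /d/cell | killing rate; 1.2e-4 (control) or 5e-7 (irradiated group) |
| $\lambda$, $K_\lambda$ | `lam`, `K_lam` | 2e-7, 1e5 | /d/cell, cells | saturating microglia conversion |
| $\phi$ | `phi` | 7e-5 | /d | MDM influx; escalates under IR |
| $\xi$ | `xi` | 1e-5 | cells/cell | microglia recruitment per new tumor cell |
| $\tau_M$ | `tau_M` | 15 | d | macrophage lifespan |
| $K$ | `K` | 1000 | mm³ | carrying capacity |
| $v_T$, $v_M$ | `v_T`, `v_M` | 1e-6, 5e-6 | mm³ | unit cell volumes |
| $\tau_{TD}$, $\tau_{MD}$ | `tau_TD`, `tau_MD` | 3, 3 | d | damaged-pool clearance |
| $S_M$ | `S_M` | 0.9 | — | macrophage survival per fraction |
| $\phi_D$ | `phi_D` | 1e-3 | /d | inflammation flux coefficient |

The two $\mu$ presets implement a regime switch between experimental
groups: small early control tumors sit in a microenvironment where
microglia oppose growth effectively, whereas the much larger irradiated
tumors are immunosuppressed. The presets are selected by group through
`mu_preset()`, never silently.

Most of the remaining fixed values are not identifiable from volumetric
curves alone, and the package treats them as calibration inputs. The
shipped defaults were chosen once so that, together with the printed
initial fractions ($f_T = 0.96$, $f_A = 0.035$, $f_P = 0.005$) and the
control-group $\mu$, an untreated tumor starting at 3 mm³ passes through
a short balanced phase (proliferative drive against microglial killing)
and then grows sigmoidally toward $K$ within one to two weeks, while an
irradiated tumor first observed near 41.5 mm³ shrinks during a 5-fraction
course and recurs within a few weeks with an MDM-dominated macrophage
pool. A larger macrophage unit volume ($v_M = 5 v_T$) keeps the initial
microglial count — and with it the early killing pressure — at a level
the balance can sustain. Changing these defaults is supported and
documented rather than discouraged: they live in `model_params()` and in
config files, and every fit and trial records the set it used.

### Two readings of the conversion term

The saturating conversion can be read two ways; both are implemented.
The default, `conversion_form = "saturated"`,
is $\lambda A\,T K_\lambda/(K_\lambda+T)$, which saturates at
$\lambda A K_\lambda$ for large tumors and matches the biological reading
that a fixed-size microglial pool limits conversion. The alternative
`"michaelis"` form $\lambda A\,T/(K_\lambda+T)$ saturates at $\lambda A$.
They differ only by the factor $K_\lambda$, so calibrated $\lambda$
values are not transferable between forms.

### Recruitment coupling

The $\xi\,dT/dt$ recruitment inside $dA/dt$ is resolved by substituting
the analytic right-hand side of the tumor equation, keeping the system an
explicit ODE; impulsive jumps at fraction times do not feed it. Because
recruitment is driven by invasion of new brain territory, a shrinking
tumor does not "de-recruit" microglia: negative $dT/dt$ is clamped to
zero by default (`clamp_recruitment = FALSE` disables this).

## Fitting

Initial conditions distribute the first observed volume over the pools
by volume fractions (equations implemented in
`allocate_initial_state()`), splitting the pro-tumor count equally
between $P_1$ and $P_2$. Control subjects use the early-tumor fractions
above. Treated subjects are first observed at volumes far beyond the
early-tumor stage, so their fractions come from pooled ordinary
least-squares regressions of each population's volume fraction on the
relative volume $V/V_{\max}$ along the fitted control trajectories,
evaluated at the subject's first volume relative to the largest observed
control volume (the reference-control rule; predictions are clipped to
$[0,1]$ and renormalized).

Each control subject is fitted by minimizing the RMSE between model and
observed volumes over $\log\rho_T$; each treated subject jointly over
$(\log\rho_T, \mathrm{logit}\,S_T)$. The optimizer is Nelder–Mead with
three fixed multi-starts and a restart-from-incumbent polish — the
restart rebuilds a simplex that has collapsed along one direction, the
standard remedy for premature convergence. Multi-start is an engineering
addition over a single-start search and is reported as such. Proposals
that blow the state up are penalized with a large objective value rather
than aborting; far above the carrying capacity (volume $> 3K$,
unreachable for any legitimate state because growth reverses at $K$) the
integrator freezes the state so runaway proposals cannot exhaust the
step budget.

Solver: adaptive Runge–Kutta 4(5) (`deSolve` with a compiled C
right-hand side, the standard idiom for compiled deSolve models),
integrated piecewise between event times. The default tolerances are
relative $10^{-10}$ and absolute $10^{-6}$ cells: the cooperative
feedback produces growth ramps with per-capita rates of tens per day,
through which looser tolerances (e.g. $10^{-8}$) amplify to volume
errors of several tenths of a percent against a self-converged
fixed-step RK4 reference. Between events the damaged pools follow exact
exponentials, which the tests verify to $10^{-6}$ relative error.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of the small-animal dataset
the model targets: 4 untreated subjects with initial volumes lognormal
around 3 mm³, 10 irradiated subjects with lognormal initial volumes of
mean 41.5 mm³, 4–7 irregular observation times per subject, and
multiplicative lognormal measurement noise with $\sigma = 0.1$ (about
10% volumetric error, typical of caliper or MRI small-animal volumetry).
Heterogeneity is concentrated in $\rho_T$ (lognormal; control median
1.6e-4, treated median 6e-7, reflecting the killing-rate regime switch)
with radiosensitivity $S_T$ uniform on $(0.45, 0.7)$. Control follow-up
spans 8 days and treated follow-up 22 days, windows in which the
respective dynamics are informative about the fitted parameters under
the default calibration. Treated initial states are allocated exactly as
the fitting pipeline allocates them (through the proportion regressions
built from the true control trajectories), so noiseless round-trip
recovery is well defined.

What the generator does *not* emulate: real measurement error structure
(heteroscedasticity, detection limits), biological deviations from the
model family (it draws from the model itself), and the specific curve
shapes of any real animal. Passing recovery tests therefore demonstrates
the estimator's correctness and stability, not the model's adequacy for
real data.

## Digital twins and trials

A digital twin couples a subject's fitted $(\rho_T, S_T)$ with the shared
fixed parameters, its allocated initial state, and a death threshold of
1.2 times its last observed volume. The threshold is additionally kept
above the initial volume so death cannot precede the start of a
simulation — relevant for twins whose tumors shrank below their starting
volume during follow-up. Death is the first crossing of the threshold,
bracketed on the trajectory grid and refined by bisection on the
log-interpolated volume to 0.01-day precision; twins that never cross are
censored at the horizon, which defaults to three times the latest
observation time. Twins whose threshold exceeds the carrying capacity can
never cross it; they appear as censored in both arms and contribute zero
paired gain.

`run_trial()` simulates every twin under both arms and reports per-twin
paired gains alongside Kaplan–Meier curves (product-limit, Greenwood
variance, log-log 95% bounds, via the survival package), the two-group
log-rank test, and medians. The paired gains are first-class output: the
arms contain identical twins, so a consistent per-twin difference is
meaningful even when the unpaired log-rank — designed for randomized
groups — is not significant. Effect sizes use Cohen's d (pooled SD,
first-minus-second sign convention) with a 95% CI from noncentral-t
inversion, labelled `"inc"` when the interval spans zero. The benefit
predictor regresses gains on $\log\rho_T$ (R², F-test) and reports the
ROC AUC of $\rho_T$ as the normalized Mann–Whitney rank statistic —
median split of gains for therapy analyses, sign split for protraction.

## Biomarker panel

The experimental panel (Ki67⁺, Iba1⁺, CC3⁺, CD49d⁻/⁺) is mirrored by
count-based analogues, which are this package's own definitions (the
exact experimental conversion is not uniquely determined by the data):

* macrophage % $= 100\,(P_1+P_2+A+M_D)/\text{total cells}$;
* apoptosis % $= 100\,(T_D+M_D)/\text{total}$;
* proliferation % $= 100\,\rho_T P \ln(K/V)\,\tau_{cycle}$, clipped to
  $[0,100]$, with $\tau_{cycle} = 1$ d converting a per-cell growth rate
  into a labelled fraction;
* killing %/d $= 100\,\mu_{\mathrm{eff}} A$;
* MG % uses $A + P_1$ and MDM % uses $P_2$ of the live macrophage pool
  (they sum to 100 exactly).

Epochs mirror the experimental sampling: first observation, end of the
course, 21 days after the first fraction, and recurrence (first
post-course time the volume re-attains its pre-course value).

## Numerical choices and degenerate inputs

* All-zero states have undefined $\ln(K/V)$; growth terms are defined as
  0 there.
* Tiny negative undershoots within ten times the absolute solver
  tolerance are clamped to zero between segments; larger negativity is a
  genuine failure and raises an error.
* Death-time bisection terminates at 0.01 days; KM medians follow the
  standard convention of the first time survival drops to or below 0.5.
* Reported problem sizes: the test suite and the acceptance script use
  the default 4 + 10 cohort, horizons of roughly 60–100 days, and
  trajectory grids of 0.25 days, sizes at which a full
  generate–fit–trial round trip completes in a few minutes on one CPU.

## Known limitations

* The model is non-spatial and binary in macrophage phenotype; monocytes
  and lymphocytes are absent.
* Radiation dose is not modelled — fractions differ only in their
  survival fractions, so linear-quadratic dose questions are out of
  scope.
* The biomarker formulas are definitional analogues; quantitative
  agreement with staining percentages is not claimed, only qualitative
  directions.
* The fixed-parameter defaults are one self-consistent calibration, not
  a validated parametrization of any specific experiment; per-subject
  conclusions transfer only through refitting to real data.
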