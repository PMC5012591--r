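---
title: "Models and methods behind motilitymap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind motilitymap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`motilitymap` is an in-silico reconstruction of a single-cell analysis
chain for *Escherichia coli* chemotaxis: it simulates run-and-tumble
swimming controlled by the phosphorylated response regulator CheY-P,
detects tumbles with a mixture-model classifier, estimates effective
diffusion coefficients, models how the receptor-modification enzymes CheR
and CheB set the tumble bias (including CheB's second role as a receptor
deamidase), and maps the mean and residual variability of the tumble bias
over (CheR, CheB) copy numbers. This vignette documents the models, the
parameter choices, the numerical decisions, and what the synthetic data can
and cannot establish.

## 1. The run-and-tumble simulator

A cell swims at constant speed (default 20 um/s) along a 3D heading that
undergoes rotational diffusion (0.062 rad^2/s), in a chamber bounded in z
by reflecting walls 10 um apart. Each flagellar motor is a two-state
(CW/CCW) switch with rates

$$k_\pm = \epsilon\,\exp\{\pm[\tfrac{g}{2}(\tfrac12 - Y_p/(Y_p+K_D))]\}$$

with $\epsilon = 1.3\,\mathrm{s^{-1}}$, $g = 40$, $K_D = 3.06$ uM. The sign
convention is chosen so that the clockwise (tumble) rate *increases* with
CheY-P, which is the direction the biology dictates (CheY-P binding to FliM
promotes CW rotation); the literal printed formula has the opposite sign.
Motor switching is integrated by exact event sampling (exponential dwell
times), so there is no discretization bias at high switching rates; the
heading random walk uses a 10 ms internal step. Tumbling cells are
stationary and re-emerge with a heading drawn uniformly on the sphere.
Positions are sampled at 10 Hz, projected to 2D, and perturbed with 0.2 um
Gaussian localization noise — about a third of a camera pixel at 10x
magnification, the accuracy of centroid detection in the tracking
experiment this emulates. Clean-kinematics tests set `loc_noise = 0`.

Each sample interval also records its exact *tumble occupancy* (fraction
of the interval spent with a CW motor), which is the ground truth used to
validate estimators: the mean occupancy of a long trajectory converges to
the stationary CW bias $k_+/(k_+ + k_-)$.

Multi-flagella coordination is only available as the independent-motor
"any motor CW implies tumble" approximation; the exact coordination model
the original study relied on is not described there, so single-motor
readout (`n_flagella = 1`) is the validated default.

## 2. Tumble classification

Per frame, the classifier uses instantaneous speed $v_i$, acceleration
$a_i$, and angular acceleration $\alpha_i$ computed exactly as

$$v_i = |r_{i+1}-r_i|/\Delta t,\quad a_i = (v_{i+1}-v_i)/\Delta t,\quad
\alpha_i = ((\theta_{i+1}-\theta_i)-(\theta_i-\theta_{i-1}))/\Delta t^2,$$

with $\theta_i$ the signed angle between consecutive velocity vectors.
Speed and acceleration are normalized per cell by the mean swimming-state
speed (first pass: the 95th percentile of speeds); $\alpha$ stays in
absolute units. A mixture of three trivariate Gaussians is fitted to the
pooled features by EM (k-means initialization, deterministic under a
seed), and an outer loop alternates normalization, refitting, and state
assignment until fewer than 1% of frames change state (typically 2-4
iterations). Components map to states by mean normalized speed: lowest =
tumble (T), highest = swimming (S), middle = intermediate (I). Ties in the
posterior are broken in the fixed order S < I < T.

**Tumble-bias counting.** Simply counting argmax-T frames is biased low at
10 Hz: a tumble shorter than two frames leaves one or two frames of
*partial* occupancy whose features land in the intermediate state. Because
a frame spent fraction $q$ of its time tumbling moves the cell a fraction
$(1-q)$ of a run frame, the frame's normalized speed encodes its
occupancy. The default estimator therefore weights T frames and
T-adjacent, low-speed I frames by the inferred occupancy
$1-\sqrt{\max(v_n^2 - v_{floor}^2,\,0)}$, where $v_{floor}$ is the tumble
component's mean normalized speed (the localization-noise floor); speeds
add in quadrature with that floor. This estimator was validated against
simulator ground truth across tumble biases 0.1-0.5 and trajectory lengths
down to 10 s; the strict argmax rule and the count-I-as-tumbling rule
remain available (`counting = "strict"` / `"with_intermediate"`).

Known limitation: cells swimming nearly parallel to the optical axis
produce seconds-long low-projected-speed stretches that are frame-wise
indistinguishable from tumbles. This inflates the estimate by up to
+0.03-0.04 at tumble bias 0.1 and is the accuracy floor of the pipeline in
this geometry; in the real experiment, surface interactions keep cells
closer to the focal plane, which the simulator deliberately does not model.

## 3. Diffusion estimation

The time-averaged velocity autocorrelation and mean-square displacement of
each 2D track are fitted jointly to

$$C_v(t) = v_0^2 e^{-t/\tau}\cos(\omega t),\qquad
MSD(t) = 2\int_0^t (t-u)\,C_v(u)\,du,$$

where $\omega$ captures circular swimming near the glass surface. The MSD
closed form is evaluated with complex exponentials
($s = -1/\tau + i\omega$): $MSD = 2v_0^2\,\mathrm{Re}[-t/s +
(e^{st}-1)/s^2]$, which reduces to the classic persistent-random-walk
expression for $\omega = 0$ and is verified against numerical quadrature
to $10^{-6}$ relative tolerance. Residuals of the two curves are
normalized by $C_v(0)$ and $MSD(t_{max})$ respectively so neither
dominates; the fit runs on $(\log v_0, \log\tau, \omega)$ with $\omega$
pinned to 0 when the autocorrelation never changes sign. Lags run to
$\min(10\,\mathrm{s}, T/4)$. The effective diffusion coefficient is
$D_{eff} = v_0^2\tau/2$, and the run-time approximation
$D_{apx} = v^2 T/(d(1-\theta))$ uses the classifier's mean run time and
mean cosine of tumble angles.

## 4. The signaling model with receptor deamidation

State: glutamine residues $Q$, methylated glutamates $M$, and the
phospho-forms $A_P$, $B_P$, $Y_P$ (all uM). Receptors are synthesized with
two glutamines out of four methylation sites (QEQE); CheB-P deamidates
them irreversibly ($Q \to E$), which both matures sites for reversible
methylation and removes the glutamines' partial free-energy contribution:

$$\frac{dQ}{dt} = -a\,k_Q [B_P]\frac{Q}{K_B+Q} + 2r\,T_{tot} - rQ$$
$$\frac{dM}{dt} = (1-a)k_R [R]\frac{4T_{tot}-M-Q}{K_R+4T_{tot}-M-Q}
  - a\,k_B [B_P]\frac{M}{K_B+M} - rM$$

with receptor-cluster activity
$a = (1+\exp[\epsilon_0 + 2N(\epsilon_1 \bar m + \epsilon_2 \bar q)])^{-1}$,
$\bar m = M/4T_{tot}$, $\bar q = Q/4T_{tot}$, and $\epsilon_2 =
\epsilon_1/2$ (a glutamine contributes half the free-energy change of a
methylated glutamate). The phospho-relay follows mass action:
autophosphorylation $a\,a_P(A_{tot}-A_P)$, transfer to CheB and CheY,
CheB-P autodephosphorylation, and CheZ-mediated CheY-P hydrolysis. The
deamidation rate is half the demethylation rate ($k_Q = k_B/2$), the value
inferred from the growth-arrest experiment. Doubling once per hour is read
as $r = \ln 2/3600\,\mathrm{s^{-1}}$.

### Parameter regime (and why it matters)

The original parameter table is not available, so defaults were assembled
once from measured copy numbers (CheA 6700, CheB 240, CheY 8200, CheZ
3200, CheR 140, ~15,000 receptor monomers; cell volume 1.4 fL) and from
antecedent pathway models, then calibrated against three facts the study
states: wild-type tumble bias near 0.2, a CheB-deamidation asymmetry in
the phenotype map, and an hour-scale tumble-bias decay after growth arrest
when CheB is scarce. Two regime requirements emerged from analysis:

* **First-order demethylation** ($K_B = 40$ uM, large compared to $M$). If
  demethylation is saturated, the steady-state activity is pinned by the
  methylation/demethylation flux ratio and the glutamine load is *exactly*
  absorbed by a compensating shift in $M$ (the Q free-energy term has zero
  net effect at any interior steady state). Differentiating the joint
  steady state shows the activity shift per unit Q is proportional to
  $\gamma_M - \gamma_R$, where $\gamma$ are the logarithmic substrate
  sensitivities of the two modification fluxes; only $\gamma_M$
  substantially positive (first-order CheB kinetics, and tethered,
  saturated CheR with $K_R = 2$ uM) lets incomplete deamidation raise the
  tumble bias.
* **Slow methylation** ($k_R = 0.03\,\mathrm{s^{-1}}$, within the reported
  range for the CheR methyltransferase; $k_B = 0.6$, $k_Q = 0.3$). After
  growth arrest the glutamine pool decays on the CheB-limited deamidation
  timescale (~1 h at 60 CheB molecules); methylation must be slow enough
  not to re-compensate instantly, or the transient amplitude collapses.

With $\epsilon_0 = 1.7$, $\epsilon_1 = -1$, $N = 6$, the wild type sits at
activity 0.35, CheY-P 2.56 uM, adaptation timescale ~20 min, and the
phenotype-map fit $TB = a + b\log_{10}(N_R/N_B^c)$ gives $c \approx 2.3$
with deamidation on and $c \approx 1.0$ with the extension ablated
($Q\equiv 0$, $r = 0$) — the direction the study reports (its experimental
value is 1.60). No CheZ reduction was needed (`chez_mult = 1`).

### Motor readout for population work

The fast-switching motor curve above has an effective Hill coefficient of
about $g/4 = 10$; pushed through it, the model's cell-to-cell CheY-P
spread would make the population tumble bias essentially binary, which is
not what single-cell data show. Motors adapt: FliM remodeling absorbs most
of a sustained CheY-P change, so the *steady-state* response is a much
shallower logistic. `tumble_bias_from_Yp()` therefore defaults to an
adapted readout with effective gain $g_{ss} = 9.5$ and midpoint 4.66 uM,
calibrated once so the wild-type operating point maps to tumble bias 0.2
and the panel spans tumble biases ~0-0.65 (the observed range is 0-0.6).
The printed fast-switching form remains as `motor = "direct"` and is what
the trajectory simulator uses, where switching is simulated explicitly.

### Numerics

Steady states are found by damped Newton iteration on the active state
variables (Q is dropped when deamidation is ablated, keeping the Jacobian
non-singular), started from a nested fixed point: for a trial activity the
phospho-relay quasi-steady state is a 1-D root, steady Q is the positive
root of a quadratic, and steady M a monotone 1-D root. Solutions satisfy
$|\dot y| < 10^{-10}$ in relative units and are checked for linear
stability; long-time integration is the fallback and serves as an
independent oracle in the tests. Because no stiff ODE solver package is
available in the target environment, the package ships a small adaptive
semi-implicit integrator (backward Euler with Richardson extrapolation,
A-stable, second order on accepted steps) used for transients.

## 5. Population noise machinery

Protein numbers are sampled per cell as
$\ln N = \ln(\text{mean}) + \eta_{ext} z_{operon} + \eta_{int} z_{protein}$
with $\eta_{ext} = 0.26$, $\eta_{int} = 0.125$ for CheR and CheB (which
share the *meche* operon's extrinsic deviate) and one tenth of those
values for the other proteins, as the study prescribes. The
slow-fluctuation machinery linearizes the reaction network (11 elementary
reactions whose stoichiometry-times-propensity product reproduces the
deterministic equations term for term, with Michaelis-Menten aggregates
treated as elementary events) at the steady state and solves the Lyapunov
equation $AC + CA^T + S\,\mathrm{diag}(v)S^T = 0$ in molecule numbers for
the stationary covariance. The variance of CheY-P, the slowest relaxation
time $\tau = -1/\max\mathrm{Re}\,\lambda(A)$, and
$n_{eff} = \max(1, \mathrm{round}(T_{obs}/\tau))$ with $T_{obs} = 100$ s
give the effective CheY-P of a tracked cell: one Gaussian draw with
variance $\mathrm{var}(Y_P)/n_{eff}$, clipped at zero (clips are counted).
An exact event-driven (Gillespie) simulation of the same network exists
solely as a test oracle; at default copy numbers its time-averaged CheY-P
variance agrees with the linear noise approximation within a few percent.

The induction-panel generator draws CheR and CheB log-uniformly over
10-3000 molecules (the experimental coverage) while the other proteins
keep their reduced natural noise. In this parameter regime the signaling
noise is strongly CheB-controlled — the adaptation timescale correlates
with $\log N_B$ at about $-0.99$ and the per-cell noise SD at about
$-0.66$ (versus $+0.19$ for $\log N_R$) — which is the mechanism the
study describes. The *gradient-orientation* contrast of the residual-SD
surface, however, does not emerge here: the slow Q/M modes make
$\tau > T_{obs}$ for every cell, so $n_{eff}$ clamps to 1 and loses its
CheB dependence, and the surviving noise surface is modulated mainly by
the motor-curve sensitivity envelope $\partial TB/\partial Y_p$, which
follows the mean-TB gradient. The corresponding acceptance assertion is
left failing, with this analysis, rather than weakened: reproducing the
original orientation contrast appears to require a regime with larger
activity fluctuations and a shorter adaptation timescale than the one
that reproduces the deamidation asymmetry and the growth-arrest
transient with the deamidation rate tied to half the demethylation rate.

## 6. Phenotype maps

Local linear regression is classical LOESS: tricube weights over the
nearest 20% of points (distances Euclidean after standardizing each log
axis by its SD), degree-1 weighted least squares on a 50x50 grid over the
data's bounding box, support requiring at least 10 neighbors, collinear
neighborhoods falling back to a flagged local mean. The residual-SD
surface smooths *squared* residuals around the mean map (unbiased for the
variance under the local model) and clips negative fits at zero. The
global fit $TB = a + b(\log_{10}N_R - c\log_{10}N_B)$ profiles $(a, b)$
out by OLS and optimizes $c$ in one dimension; confidence intervals are
percentile bootstrap over cells (default 2000 resamples, seeded), since
the original interval method is unstated. Contour orientation is the
axial (doubled-angle) circular mean of finite-difference gradient
directions over the support.

## 7. What a green test establishes — and what it does not

The synthetic world deliberately mirrors the experiment's geometry and
sampling (10 Hz, 2D projection, 10 um chamber, localization noise), but it
omits: hydrodynamic wall interactions (so no circular swimming is
generated, and headings stay isotropic — the source of the tumble-bias
accuracy floor above), chemoattractant gradients, cell-size and
flagella-number variability, and receptor heterogeneity. The headline
numbers of the original study (mean tumble bias 0.24, SD 0.093, exponent
1.60, the 11% variance share) came from its experimental dataset, which is
not deposited; the package's tests therefore assert *properties* —
closed-form identities, estimator recovery against simulator ground
truth, oracle agreement (quadrature, Gillespie, long-time integration),
ablation directions, and transient shapes — rather than those numbers.
For orientation, pushing the wild-type expression noise through this
package's fitted tumble-bias surface attributes roughly 5% of the observed
population variance to CheR/CheB fluctuations (the study reports 11% with
its experimental surface); the number is computed, not asserted, by
`variance_explained()`.
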