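---
title: "Functionally graded transversely isotropic modeling of soft-tissue transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functionally graded transversely isotropic modeling of soft-tissue transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tigrade)
```

## The problem

Load-bearing soft tissues rarely end abruptly: the chordae tendineae (CT)
of a heart valve blend into the leaflet (LL) on one end and into the
papillary muscle (PM) on the other through transition regions a few
millimeters long, where collagen content, fiber orientation and stiffness
all change gradually. Simulators that assign each "pure" tissue its own
homogeneous material and butt them together produce spurious stress
concentrations and numerical instabilities exactly where injuries localize
in reality. `tigrade` models such transitions as a functionally graded
material (FGM): the two bounding "pure" tissues (the *terminal materials*)
are characterized once, and every layer in between receives an interpolated
parameter set controlled by a *constituent distribution function*
$\phi(X) \in [0,1]$.

## The constitutive model

Each layer is a transversely isotropic (TI) hyperelastic solid in the Weiss
form: a Mooney–Rivlin matrix plus a single fiber family, with decoupled
volumetric response,

$$ W = C_1(\tilde I_1 - 3) + C_2(\tilde I_2 - 3) + \tilde F_2(\tilde\lambda)
   + \tfrac{K}{2}(\ln J)^2, $$

where $\tilde I_1, \tilde I_2$ are deviatoric invariants of the right
Cauchy–Green tensor and $\tilde\lambda = \sqrt{\tilde I_4}$ is the
deviatoric fiber stretch. The fiber stress measure is multi-regime:

$$ \tilde\lambda \frac{\partial \tilde F_2}{\partial \tilde\lambda} =
 \begin{cases}
   0 & \tilde\lambda \le 1 \quad \text{(fibers slack)}\\
   C_3\!\left(e^{C_4(\tilde\lambda - 1)} - 1\right) & 1 < \tilde\lambda \le \lambda^* \quad \text{(uncrimping toe)}\\
   C_5\tilde\lambda + C_6 & \tilde\lambda > \lambda^* \quad \text{(straightened)}.
 \end{cases} $$

$C_6$ always follows from value continuity at $\lambda^*$
(`c6_from_c0()`). Slope continuity is *not* assumed; the ratio of $C_5$ to
the toe-branch slope at $\lambda^*$,

$$ f = \frac{C_5}{C_3 C_4 e^{C_4(\lambda^* - 1)}}, $$

is the *discontinuity index* (`discontinuity_index()`): $f = 1$ means a
smooth regime change, and fitted tissues can sit noticeably away from 1
(the tricuspid leaflet preset has $f \approx 0.81$).

Grading is steered by a scalar *grading stiffness*
$k_g = \partial(a^\mathsf{T}\sigma a)/\partial\tilde\lambda$, the rate of
change of the fiber-direction traction. On the incompressible uniaxial path
it reduces to
$k_g = C_1\gamma_1 + C_2\gamma_2 + \tfrac{2}{3}\,
\partial_{\tilde\lambda}(\tilde\lambda\,\partial\tilde F_2/\partial\tilde\lambda)$
with closed-form path factors $\gamma_1 = \tfrac83\tilde\lambda +
\tfrac43\tilde\lambda^{-2}$, $\gamma_2 = \tfrac43 +
\tfrac83\tilde\lambda^{-3}$; in the straightened regime of a
fiber-dominated tissue $k_g \to \tfrac23 C_5$. `grading_stiffness()`
evaluates both this closed form and an independent finite-difference of the
traction stress; the two agree to $10^{-4}$ relative away from regime
boundaries (tested).

### A note on the deformation path

$\gamma_1, \gamma_2$ depend on the deformation state, which the grading
metric does not pin down by itself. We evaluate them on the
strict-incompressible uniaxial-stretch-along-fiber path ($J = 1$,
transverse stretches $\tilde\lambda^{-1/2}$), consistent with
near-incompressibility of hydrated tissue and with the uniaxial experiments
that inform the terminal fits. The full stress evaluation
(`cauchy_stress()`) stays compressible with pressure $K\ln J / J$; a
strict-incompressible helper (`uniaxial_response()`) eliminates the
pressure through the traction-free lateral condition and is what the chain
simulator and the inverse problems use.

## The interpolation law

Naively blending all seven coefficients between two terminal fits fails
when their $C_4$ and $\lambda^*$ differ, because $C_4$ enters an
exponential. `generate_fgm()` implements the full law:

1. $C_1, C_2, C_3, C_5$ (and $K$) blend linearly under $\phi$;
2. $\lambda^*$ and the discontinuity index $f$ blend under a monotone
   $\psi$ (we take $\psi \equiv \phi$ whenever $\phi$ is monotone, the only
   configuration exercised here);
3. each layer's $C_4$ is recovered by solving
   $f_t C_{3,t} C_4 e^{C_4(\lambda^*_t - 1)} = C_{5,t}$ — strictly
   increasing in $C_4$, so bracketing + `uniroot` + Newton polish is
   globally convergent (`solve_C4()`);
4. each layer's $C_6$ restores value continuity.

Two special cases. A terminal whose experiment never reached the linear
fiber regime ($\lambda_{\max} < \lambda^*$) carries an ill-identified
$C_5$; it is replaced by the slope-continuity value with $f := 1$ before
grading. An isotropic terminal has no fiber regime at all: its $f$ and
$\lambda^*$ are set to 1 and then graded under $\phi$, and $C_3, C_5$ blend
up from zero. Layers at the isotropic end, where $C_3 = C_5 = 0$ make $C_4$
inert, inherit the anisotropic terminal's $C_4$ so the parameter table
stays continuous — a presentation choice with no mechanical effect.

`case_study()` contrasts the full law (variant 3) with the two naive
schemes on the tricuspid CT–LL terminals across 8 layers:

```{r case-study}
res <- run_demo_case3()
data.frame(case = 1:3,
           bounded = sapply(res, `[[`, "bounded"),
           max_violation = sapply(res, `[[`, "max_violation"),
           slope_jump = sapply(res, `[[`, "slope_jump"))
```

Variant 1 (slope continuity forced on blended parameters) overshoots the
stiff terminal's response by an order of magnitude of the envelope width;
variant 2 (everything blended independently) shows a regime-change slope
jump ($|f - 1| \approx 0.97$) several times the largest jump the full law
ever produces ($\le 0.19$, bounded by the terminal indices); variant 3
stays inside the terminal envelope at every stretch on $[1, 1.3]$.

## Distribution functions

Constituent fractions come from one of several families (`dist_spec()`),
all mapping the normalized transition coordinate
$\bar X \in [-0.5, 0.5]$ into $[0,1]$:

* `symmetric_sigmoid` — piecewise power law crossing 0.5 at the midpoint;
  exponents $p_5, p_6$ default to 2 in the demonstration case study (the
  canonical smooth sigmoid; any monotone choice gives the same qualitative
  conclusions, which is what the tests assert);
* `tanh_modified` and `bidirectional` — for regions whose composition also
  varies transverse to the main grading direction; the tanh factor is
  evaluated in shifted-exponential form so saturation never overflows, and
  clamping to $[0,1]$ happens after the product, as defined;
* `asymmetric_sigmoid` — the crossover sits at $\bar X = p_1$ instead of
  0, with upper-branch exponent $p_2$; the remaining five constants are
  determined by value, crossover and slope-matching constraints. The
  constraint system factorizes in closed form (the slope match alone fixes
  the lower exponent $w = p_2(1+2p_1)/(1-2p_1)$), which we use directly;
  all five residuals are still verified to $10^{-8}$ on construction.

## The serial-chain simulator

Full 3-D finite-element analysis of a graded specimen is out of scope;
validation-scale questions here are essentially one-dimensional along the
loading axis. `chain_equilibrium()` treats the specimen as serial TI unit
cells: the nominal force (stress × reference area) is uniform along the
chain and layer elongations sum to the applied elongation. The force level
is found by bracketing + `uniroot`; inside each residual evaluation every
layer's uniaxial response is inverted simultaneously by a vectorized,
bracket-safeguarded Newton iteration. Both equilibrium invariants are
enforced to $10^{-8}$ relative on return. Engineering strains are read at
fiducial markers (`fiducial_strains()`), and profiles are compared only
after max-normalization at the top load step, which removes
specimen-to-specimen scale (including the known ~0.4 molecular-to-
macroscopic strain conversion).

The chain's geometry is a user input; `ct_pm_geometry()` provides a
CT–PM-like preset (2.7 mm total length, cross-section tapering 3 →
0.6 mm², ten fiducials at layer midpoints). Absolute strains depend on
that area profile, so only normalized profiles are meaningful — one reason
the inverse problem below is formulated on normalized strains.

## Inverse problems

**Terminal fitting** (`fit_terminal_ti()`): recovers
$\{C_1, C_3, C_4, \lambda^*, C_5\}$ from a force–displacement curve with
$K$ fixed at $1.464\times10^8$ Pa (a standard ligament-fit value giving
slight compressibility) and $C_2 = 0$, minimizing squared force residuals.
The optimizer is a compact seeded differential-evolution search
(population 40, 200 generations, stiffnesses searched in log space)
followed by a Nelder–Mead polish. $C_3$ and $C_4$ trade off on toe-only
data, so recovery is judged in response space: noiseless self-generated
curves are re-fitted to $< 2\%$ force error with $R^2 \ge 0.999$ (tested).

**Shape estimation** (`estimate_shape_parameters()`): recovers the
asymmetric-sigmoid parameters $(p_1, p_2)$ from a normalized fiducial
strain profile by embedding the entire forward pipeline — constraint
solve, grading, chain equilibrium, normalization — in the objective
$\sum_i (\bar\epsilon^{exp}_i - \bar\epsilon^{sim}_i)^2$, evaluated at the
maximum load step only (where fibers are straightened and the
molecular-to-macroscopic strain relation is linear). The 2-parameter
search uses population 20 / 40 generations, sized for its dimension.
Infeasible candidates are penalized, not fatal; a flatness probe flags
non-identifiable inputs (e.g. a homogeneous chain). Noiseless interior
truths are recovered to $< 2\%$ with residuals $\sim 10^{-20}$, and the
median recovery error under 1% multiplicative strain noise stays under
10% (tested with a reduced search across seeded replicates).

## Synthetic data

All experimental inputs have seeded generators (`make_fd_curve()`,
`make_strain_profile()`, `make_intensity_grid()`,
`make_orientation_field()`) that emulate the *statistical structure* of
diffraction-derived data: intensity fractions with additive Gaussian noise
clamped to $[0,1]$, strain profiles with multiplicative noise before
normalization, in-plane fiber angles rotating from 0° (along load) at
$\phi = 0$ to 90° at $\phi = 1$ with 5° wrapped-normal angular noise.
They are exactly invertible at zero noise and bit-reproducible under a
fixed seed. What they do *not* emulate: real fits have correlated,
heteroscedastic errors, secondary fiber populations, registration error
between specimen and model frames, and genuinely 3-D strain fields — so
passing recovery tests demonstrates correctness of the estimation
machinery, not field accuracy on real tissue.

## Numerical choices and limitations

* Regime ties: $\tilde\lambda = 1$ uses the slack branch,
  $\tilde\lambda = \lambda^*$ the exponential branch (identical value
  under the $C_6$ construction); the finite-difference stiffness mode
  warns when its stencil straddles a boundary.
* Problem sizes: the shipped studies use $T = 8$–10 layers, 60-point
  stretch grids, 10 fiducials, 6 load steps, and curves of ~30 points —
  the scale at which the behavior of interest (envelope boundedness,
  localization, recovery) is already fully expressed.
* $K$ grades linearly under $\phi$; all shipped presets share one $K$, so
  this is degenerate there by construction.
* Scope: one fiber family, passive hyperelasticity. Strongly orthotropic
  tissue (myocardium) or two-family walls (arteries) need a different
  constitutive core; non-monotone transitions (bone–tendon) would need a
  non-monotone $\phi$ plus a $\psi$ chosen separately, which the API
  permits but nothing here exercises.
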