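---
title: "Methods: probabilistic fatigue life of dental implants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic fatigue life of dental implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implantfatigue)
```

## The problem

An osseointegrated dental implant is loaded by mastication roughly a
million times per year. Fatigue life under such loading is intrinsically
random: bite forces differ between patients and meals, and the elastic
modulus of the titanium alloy varies between lots. A deterministic finite
element analysis answers "what is the stress", not "what is the
probability that this implant survives 10 years". This package chains a
deterministic elastic model with first-order uncertainty propagation,
strain-life fatigue mechanics, and a Markov cumulative damage model into
failure-probability-versus-cycles curves.

## Stage 1: the elastic surrogate

The geometry is a 2D plane-strain buccolingual cross-section: a
rectangular bone block (default 15 × 22 mm) with a cortical band (2 mm,
D2 bone quality) over a trabecular core, and a 3.5 × 8 mm titanium
implant bonded into the crest. Bonding is modelled by shared nodes — the
osseointegrated assumption — with no contact or friction. Boundary
conditions: the inferior border is fully fixed; the mesial and distal cut
borders are fixed only normal to the surface (symmetry-type rollers).

Two modelling choices deserve emphasis because the design here was
genuinely open:

* **Abutment column.** The occlusal force acts on the crown, several
  millimetres above the bone crest. The surrogate carries a titanium
  column of height `abutment_height` (default 7 mm, a typical posterior
  abutment-plus-crown occlusal height) above the crest and applies the
  load as a uniform traction on its top face. Without this moment arm the
  transverse force component produces no neck bending and the model
  concentrates stress at the (artificial) apex corner instead of the
  neck; with it, the critical von Mises element sits at the implant neck,
  where implant fractures are actually observed.
* **Connection as a neck notch.** True hexagon connection geometry is
  proprietary. The surrogate encodes the connection type as a chamfered
  trapezoidal narrowing of the implant between 0.5 and 1.5 mm below the
  crest: 0.6 mm deep per side for the external hexagon, 0.3 mm for the
  internal one, reflecting the external connection's weaker resistance to
  oblique loads. The 45° chamfers avoid the square re-entrant corner a
  plain slot would create; a sharp corner's stress is mesh-divergent,
  whereas the chamfered notch's critical von Mises value changes by well
  under 5% between successive mesh halvings (the package's convergence
  criterion, tested at element sizes 0.5 → 0.25 mm).

Elements are linear (constant-strain) triangles on a structured grid with
all material interfaces aligned to grid lines; element size is
`mesh_density` (default 0.5 mm, about 3,400 elements — sizes chosen so a
full pipeline run takes about a second). Stress output is
element-constant; plane strain supplies σzz = ν(σxx + σyy), which enters
both invariants. The implant is assessed by von Mises stress, the bone by
maximum principal stress, and the critical point is the arg-max element
over a region with ties broken toward the lowest element index.

With the default loading (resultant 118.2 N at 75° to the occlusal
plane) the surrogate gives ~176 MPa (external) and ~104 MPa (internal) at
the implant neck and ~29/27 MPa maximum principal stress in cortical
bone. The ordering and location match what thread-resolved 3D models
report, but the absolute implant values are lower — a 2D section cannot
reproduce thread-root concentrations — which is why no absolute stress
from the surrogate should be compared against 3D results, and why the
fatigue stage admits externally supplied stress statistics.

## Stage 2: first-order second-moment propagation

The random inputs are the load magnitude (118 ± 30 N) and the titanium
modulus (100 ± 20 GPa), treated as independent; each is summarised by its
first two moments only. For a response g (von Mises stress or equivalent
elastic strain ε = σ_vm/E at the critical element),

E[g] ≈ g(μ),  var[g] ≈ Σᵢ (∂g/∂Xᵢ)² σᵢ²,

with central finite differences (relative step 1e-3, configurable) and
the critical element pinned at its mean-input location. Stiffness is
assembled once per part — the titanium block scales linearly in E — and a
cached symbolic Cholesky factorisation is updated per evaluation, which
is what makes the included Monte Carlo oracle (zero-truncated Gaussian
sampling) affordable as a cross-check: on the default surrogate the FOSM
stress variance agrees with a 2,000-draw Monte Carlo run within ~1%.

First-order propagation is only trustworthy for narrow input spreads;
`random_variable()` warns above a coefficient of variation of 0.3. The
load CoV of 0.254 sits near that edge, and the consequences surface in
stage 3.

## Stage 3: Neuber correction and strain-life inversion

The elastic stress at the critical point overestimates nothing as long as
the material stays elastic; at a concentrator the local response is
elastic-plastic. Neuber's rule estimates it by intersecting the
Ramberg–Osgood cyclic curve with the Neuber hyperbola
σ_ep ε_ep = σ_el ε_el, i.e. solving

σ_ep/E + (σ_ep/k)^(1/n′) − ε_el² E/σ_ep = 0.

The residual is strictly increasing in σ_ep on (0, σ_el], negative near
zero and non-negative at σ_el, so a unique bracketed root exists and
Brent's method finds it. Two numerical details matter. First, the
elastic terms are grouped as (σ² − σ_el²)/(Eσ): evaluated naively they
cancel catastrophically near the elastic limit and can drown the tiny
plastic term, flipping the bracket sign. Second, the plastic term is
evaluated through exp/log to avoid overflow at large 1/n′.

The fatigue life then comes from inverting the Coffin–Basquin–Manson
relation Δε_ep/2 = (σf′/E)(2N_f)^b + εf′(2N_f)^c, whose right side is
strictly decreasing (b, c < 0); the root is bracketed on
log10(2N_f) ∈ [0, 12] by default (the pipeline widens this to [0, 16]
because the surrogate's lower stresses produce longer lives) and
out-of-bracket amplitudes raise errors rather than clamping.

The loading cycle is taken as zero-to-peak (each mastication event loads
and unloads), with strain range Δε_ep = 2·ε_ep(peak) by default
(`delta_eps_factor`); no mean-stress correction is applied. The shipped
fatigue constants (k = 1100 MPa, n′ = 0.05, σf′ = 2030 MPa, εf′ = 0.841,
b = −0.104, c = −0.69) are literature-style values for wrought Ti6Al4V
and should be overridden with lot-specific data when available.

Life moments are produced by the same FOSM machinery applied to the
composed map (E, P) → σ_el → Neuber → N_f. A caveat the package does not
hide: N_f scales roughly as load^(1/b) ≈ load^−9.6, so the life
distribution is extremely heavy-tailed in the load. At the default load
CoV the exact moments of N_f under a zero-truncated Gaussian do not even
exist (the integrand diverges at zero load), so the first-order variance
should be read as a local sensitivity summary, not as the variance of a
well-behaved distribution; Monte Carlo validation of the composed map is
therefore performed in the narrow-spread regime (input CoV ~2%), where
the method is meaningful and simulation agrees with it.

## Stage 4: the cumulative damage chain

The Bogdanoff–Kozin B-model discretises damage into levels 1…b with
absorbing failure at b. Under the constant-severity hypothesis each duty
cycle either stays at level j (probability p_j) or jumps one level
(q_j = 1 − p_j); with r_j = p_j/q_j the closed-form moments over the
transient levels are E[N_f] = Σ(1 + r_j) and var[N_f] = Σ r_j(1 + r_j).

Calibration from (mean, variance) uses uniform-r moment matching:
r = var/mean, transient level count m = round(mean/(1 + r)), then r is
re-solved as mean/m − 1 so the mean is preserved exactly; the variance
absorbs the integer rounding (relative error well below 0.1% at
realistic level counts, reported alongside the target).

For a uniform chain started pristine, cycles-to-failure is
(b − 1) + NegBin(b − 1, q): absorption needs exactly b − 1 jumps with
geometric stays interleaved. The failure probability is evaluated through
`pnbinom()` — the regularized incomplete beta function — which is stable
for the thousands-of-levels chains that megacycle lives produce; tests
verify it against dense matrix powers of the transition matrix
exhaustively for all b ≤ 50, r ∈ {0.1, 1, 10}, x ≤ 500, and against
simulated absorption times. Level counts are held as whole-valued
doubles (not 32-bit integers) because calibrated chains from long lives
exceed 2³¹; per-level operations refuse chains beyond 10⁷ levels and the
default point-mass initial distribution is stored symbolically rather
than materialised. A general initial distribution is accepted by the
state-evolution operator but deliberately rejected by the closed-form
moments, which assume a pristine start.

## The synthetic study generator

`default_study_config()` emits the full input set: geometry, materials
(cortical 13.7 GPa, trabecular 4 GPa, titanium 100 GPa, ν = 0.3), the
oblique occlusal force (114.6 N axial, 17.1 N lingual, 23.4 N mesial —
the 2D surrogate collapses the two transverse components into their
in-plane resultant), the two random variables, fatigue constants, and a
failure-curve grid (10–200 million cycles external, 10–550 internal).
The distribution family behind "mean ± sd" is not specified by the
methodology, so sampling uses Gaussians truncated at zero for physical
positivity; the truncation bias is negligible at CoV ≤ 0.25 (the
truncation point lies ~4 sd below the mean). What the generator does
*not* emulate: patient-to-patient bone-quality classes beyond D2,
thread-level geometry, and any correlation between load and modulus —
so passing tests demonstrate the numerical machinery and the model's
internal consistency, not clinical validity on real populations.

Analytic fixtures (`make_analytic_fixture()`) back the solver tests: a
homogeneous patch (exact uniform stress), a compound bar (series
strength-of-materials closed form), and a notched strip. For the notched
strip the pointwise corner maximum is singular — it grows without bound
under refinement, as at any re-entrant bi-material corner — so its
reference quantity is the area-averaged axial stress over the titanium
net section, an equilibrium-anchored functional bounded by F/net-width
that converges cleanly and is Richardson-extrapolated across three mesh
halvings.

## Numerical choices and degenerate inputs

* Root tolerances: Neuber 1e-10 relative; strain-life 1e-12 on
  log10(2N_f). Both roots are verified in tests against dense
  grid/bisection oracles and by round-tripping the governing equations.
* Zero input variances propagate to a zero life variance and a
  deterministic (r = 0) chain whose failure curve is an exact step.
* r = 0 transition rows are deterministic jumps; q = 1 degenerates the
  negative binomial to a point mass, handled exactly by `pnbinom`.
* Cycle grids must be sorted; state-evolution steps must be
  non-negative; geometry invariants (cortical band thinner than the
  bone, implant narrower than the block, notch shallower than the
  radius) are checked at construction with the offending field named.
* Meshing is a deterministic function of the geometry; the `seed`
  argument is stored for interface stability and reserved for future
  unstructured meshing.

## Problem sizes

Defaults were chosen so the whole pipeline runs in about a second
(3,400 elements at 0.5 mm), the full test suite — including the
exhaustive small-chain oracle sweep, a 100,000-walk chain simulation and
a 2,000-draw Monte Carlo cross-check of the FOSM stress moments — in
about a minute, and the calibration round-trip script in well under a
second. Mesh-convergence evidence is part of the test suite rather than
an external study.

## Known limitations

* Absolute surrogate stresses are not comparable to thread-resolved 3D
  models; only orderings, locations and the downstream probabilistic
  machinery transfer.
* First-order life variance is a local sensitivity measure; at load
  CoV ≳ 0.25 the underlying life distribution is so heavy-tailed that
  second-moment summaries lose meaning (see stage 3).
* No mean-stress correction, no multiaxial critical-plane criterion, no
  crack-propagation stage, no contact or preload mechanics.
* The constant-severity (uniform r) hypothesis makes cycles-to-failure
  negative binomial; duty-cycle-dependent severity would need the
  per-level r vector and simulation in place of the closed forms.
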