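---
title: "Modelling still-shot diffraction: geometry, refinement and mosaic estimation"
author: "stillframe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling still-shot diffraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stillframe)
```

## The problem

A still diffraction exposure — an XFEL shot, or a zero-rotation synchrotron
image — samples every Bragg reflection at a single point of its rocking
curve. Two consequences drive everything in this package:

1. **Orientation degeneracy.** The positions of spot centroids on the
   detector respond directly to the rotation $R_z$ about the beam axis
   (the whole pattern turns in lockstep) and to the unit cell, but
   rotations $R_x, R_y$ about the in-plane axes move reciprocal-lattice
   points *through* the Ewald sphere rather than across the detector.
   Their effect on calculated centroids is second order (of order
   $\sin\theta$ at the highest scattering angles, vanishing at low
   resolution), so a positional least-squares target cannot usefully
   refine them.
2. **Off-condition observation.** Spots are recorded even though their
   reciprocal-lattice points do not sit exactly on the Ewald sphere. How
   far off-condition a reflection can be and still diffract is a physical
   property of the crystal, with two distinguishable components: a
   resolution-independent angular spread (the *effective mosaicity*
   $\eta$) and a resolution-proportional term from the finite size of
   coherently diffracting domains (the *effective block size*
   $D_\mathrm{eff}$, with reciprocal spot diameter
   $\alpha = 2/D_\mathrm{eff}$).

Both are handled through one geometric quantity: the signed minimal
rotation angle $\Delta\psi$ that brings a reciprocal-lattice point onto
the Ewald sphere.

## The $\Delta\psi$ construction

Work in a right-handed laboratory frame with the incident beam along
$-z$. The crystal is described by its reciprocal orientation matrix
$A = U B$: $B$ is the upper-triangular reciprocal basis of the cell in a
fixed reference setting ($a^*$ along $x$, $b^*$ in the $x$–$y$ plane,
the Busing–Levy convention) and $U$ a proper rotation. A reflection with
Miller index $\mathbf h$ sits at $\mathbf q = A\mathbf h$, at resolution
$d = 1/|\mathbf q|$.

The Ewald sphere has radius $1/\lambda$ and is centred at
$-\mathbf s_0$, so exact diffraction means
$|\mathbf q + \mathbf s_0| = 1/\lambda$. For an off-sphere point, the
*reflecting position* $\mathbf r$ is the intersection — on the same side
as $\mathbf q$ — of the sphere $|\mathbf r| = |\mathbf q|$ about the
origin with the Ewald sphere, constrained to the plane through the
sphere centre, the origin and $\mathbf q$. Writing $\hat c$ for the unit
vector towards the sphere centre and $\hat n$ for the in-plane direction
of $\mathbf q$'s component perpendicular to it, the construction is two
dimensional: $\mathbf q = (q_\parallel, q_\perp)$ and
$\mathbf r = (a, b)$ with

$$a = \tfrac{\lambda}{2}\,|\mathbf q|^2, \qquad
  b = \sqrt{|\mathbf q|^2 - a^2},$$

both legs of right triangles in that plane. The signed angle follows
from an arctangent of the 2-D cross and dot products,

$$\Delta\psi = \operatorname{atan2}\!\big(b\,q_\parallel - a\,q_\perp,\;
  a\,q_\parallel + b\,q_\perp\big),$$

which is numerically stable near zero and carries the sign convention
automatically: $\Delta\psi < 0$ when the point lies outside the sphere,
$> 0$ inside. The rotation axis $\hat e_1$ is perpendicular to
$\mathbf q$ and to the plane, oriented so the right-hand rotation by
$\Delta\psi$ maps $\mathbf q$ onto $\mathbf r$. The tests validate this
closed form against an independent rotation-scan oracle (grid plus root
polishing of $\,|\,|\mathbf q_\mathrm{rot}+\mathbf s_0| - 1/\lambda\,|$)
to $10^{-8}$ rad on a thousand random reflections.

Degenerate inputs are flagged rather than computed: the origin
reflection, points on or beyond the limiting sphere ($|\mathbf q| \ge
2/\lambda$), and points collinear with the beam (rotation axis
undefined). Flagged records are excluded from every fit.

```{r dpsi-example}
bm <- beam(1.32)
compute_delta_psi(rbind(c(0.05, 0.02, 0.011),
                        c(0.05, 0.02, 0.013)), bm)[, c("delta_psi", "d", "status")]
```

## Refinement targets

Given index-assigned centroids, two targets are available.
`positional_target()` is the classical sum of squared distances (mm$^2$)
between observed centroids and the detector projections of the
reflecting positions. `hybrid_target()` adds the squared angular
offsets, evaluated in units of radians$/(2\pi)$:

$$T_2 \;=\; \sum_i \big\|\mathbf r_i^\mathrm{obs} -
  \mathbf r_i^\mathrm{calc}\big\|^2
  \;+\; \sum_i \Big(\frac{\Delta\psi_i}{2\pi}\Big)^2 .$$

The fixed unit convention (millimetres; radians per turn) puts both
terms on a convenient sub-unit numerical scale; no inverse-variance
weighting is applied, deliberately, so that the objective is exactly the
documented one. The hybrid target is what makes all three orientation
angles identifiable: centroids pin $R_z$ and the cell, the angular term
pins $R_x$ and $R_y$.

### The solver and the degeneracy structure

`refine_model()` minimises either target by damped Gauss–Newton over the
orientation (a lab-frame rotation-vector update composed onto the start
orientation) and the cell degrees of freedom of the active constraint:
nine parameters for triclinic, five for `hexagonal_622` ($a$ and $c$;
angles fixed at 90/90/120).

The refinement objective encodes the degeneracy structure explicitly:
positional residual rows are evaluated with only the $R_z$ component of
the orientation update, while the $\Delta\psi$ rows see the full update.
This matches the physical statement that in-plane rotations do not move
calculated centroids, and it matters numerically: the exact projection
retains a second-order ($\sim\sin\theta$) centroid sensitivity to
$R_x/R_y$ which, summed unweighted over $\sim\!10^3$ spots, would
otherwise out-muscle the radians$/(2\pi)$-weighted angular term and
degrade the in-plane angles to centroid-noise accuracy. With the
structured objective, the angular term alone determines $R_x/R_y$ —
and under the positional target those angles are structurally fixed,
which is exactly the still-shot limitation the hybrid target repairs.

Because the centroid rows freeze the in-plane orientation at the pass's
base orientation, the solver iterates *passes*: after the inner damped
Gauss–Newton loop settles (central-difference Jacobian; SVD solve with
mild Tikhonov filtering of weak singular values; step halving up to ten
times so the objective sequence never increases), the accumulated
rotation is folded into the base and the loop re-entered, until the fold
is below $10^{-7}$ rad. The frozen-base bias shrinks with the remaining
update, so a handful of passes suffice from half-degree starts. Reported
residuals, target values and per-spot tables are always recomputed
exactly at the final model. Convergence is declared on a relative
decrease below $10^{-10}$, a step norm below $10^{-8}$, or a locally
flat objective (no trial changes it by more than $10^{-6}$ relative);
exhausting the damping budget with a genuinely increasing objective is
flagged as divergence, and a rank-deficient Jacobian as a singularity.

### Two-stage protocol

`run_protocol()` reproduces the standard workflow: stage 1 refines an
unconstrained triclinic model; the cell is then projected onto the
Bravais family (for hexagonal: $a, b \mapsto$ their mean, angles set
exactly, orientation kept) and stage 2 re-refines under the constraint.
Each stage's target is selectable, which is precisely the protocol
comparison explored in the acceptance tests: hybrid/hybrid recovers
half-degree misorientations to a few thousandths of a degree, while
positional/positional leaves the in-plane error essentially at the
starting perturbation, and hybrid-then-positional lands in between
(stage 2 cannot improve on stage 1's in-plane accuracy once the angular
term is dropped). Index assignment is not repeated between stages by
default; the command-line interface exposes one reassignment pass.

## Mosaic envelope estimation

After refinement, the residual $(\Delta\psi_i, d_i)$ scatter carries the
crystal's mosaic structure. Reflections are observed out to the
half-width envelope

$$\Delta\psi_\mathrm{model}(d) \;=\; \frac{\eta}{2} + \frac{d}{D_\mathrm{eff}},$$

so the spread widens towards low resolution (large $d$) — the signature
of finite block size — and tapers to $\eta/2$ at high resolution.
`fit_mosaic()` implements both estimators:

* **Binned least squares** (`method = "ls"`): records sorted by
  resolution, grouped 25 per bin (a final partial bin merges into its
  neighbour), each bin contributing (mean $d$, $\max|\Delta\psi|$); the
  line through the bin maxima is solved in closed form from the normal
  equations, with negative estimates clamped at the physical boundary
  and the free parameter refit. Only $1/25$ of the records inform the
  fit.
* **Smoothed top-hat maximum likelihood** (`method = "ml"`): every
  record contributes
  $\log P_i$ with
  $P_i = f\!\big(\varepsilon(u_i+1)\big)\, g\!\big(\varepsilon(1-u_i)\big)
  / (2 W_i)$, where $W_i$ is the local half-width,
  $u_i = \Delta\psi_i / W_i$ the normalised signed offset, and $f = g =$
  the logistic function. The steepness is fixed at $\varepsilon = 10$,
  applied to the *normalised* offset so a single dimensionless constant
  serves all resolutions. A too-narrow envelope pays the steep sigmoid
  penalty for excluded observations; a too-wide one pays the
  $\log(2W_i)$ normalisation; an interior maximum therefore exists, and
  the tests assert unimodality along both axes. Optimisation is BFGS on
  the logs of the intercept and slope (domain kept open by a $10^{-8}$
  offset; components indistinguishable from zero at that scale are
  reported as exactly zero), initialised from the least-squares fit.
  The normalisation uses the hard top-hat width $2W_i$; the smoothing at
  $\varepsilon = 10$ distorts the total mass by under 1% (asserted in
  the tests).

Reporting follows the field's convention: *half-width mosaicity*
$\eta/2$ in degrees, block size in Angstrom; when averaging over images
the block size is combined as $1/\langle 1/D_\mathrm{eff}\rangle$.

```{r mosaic-example}
env <- mosaic_envelope(eta_deg = 0.05, d_eff = 4000)
rec <- simulate_envelope_records(3000, env, seed = 1)
fit <- fit_mosaic(rec, method = "ml")
coef(fit)
```

Two properties deserve note. First, on clean hard-edged data the two
estimators nearly coincide (the 25-bin maximum sits $\sim$4% inside the
true edge; the smoothed-likelihood optimum lands in the same
neighbourhood), and the sign of their difference is noise. The
documented inequality $\eta_\mathrm{ML} \le \eta_\mathrm{LS}$ belongs to
*measured* records, whose offsets carry the angular scatter imprinted by
centroiding error ($\sigma \approx 0.03\,$mm at 129 mm, i.e.
$\sim\!2.3\times10^{-4}$ rad); that Gaussian tail inflates extreme-value
bin maxima much more than the likelihood optimum, and under those
conditions the ordering holds in every tested replicate. Second, the
$\varepsilon = 10$ sigmoid is *not* robust to gross outliers: a few
percent of records drawn from a several-fold widened envelope drag the
ML envelope outward (excluding a point at $3W$ costs $\sim 2\varepsilon$
log-units). Pre-filtering by index assignment is therefore part of the
method, not an optional nicety.

## Prediction and scoring

`predict_spots()` enumerates every lattice point in the resolution range
(the index box $|h_i| \le a_i/d_\mathrm{min}$ is rigorous, since
$h_i = \mathbf q\cdot\mathbf a_i$) and predicts as observable those with
$|\Delta\psi| \le \Delta\psi_\mathrm{model}(d)$, placed at the detector
projection of their reflecting position — the on-sphere point about
which the partial reflection is centred. `score_prediction()` compares
predicted and reference sets by Miller index, pooled and in resolution
shells of equal reciprocal volume (equal increments of $1/d^3$; ten
shells over 15–3.5 Å by default), reporting the falsely-predicted and
unmodeled fractions. Both fractions vanish for the true model and true
envelope on noise-free simulations and increase strictly under
misorientation — the experimentally inaccessible figure of merit that
motivates the protocol comparison.

## The simulator and what it does (not) emulate

`simulate_still()` generates the observed bright-spot list of one still:
a uniformly random orientation (unit-quaternion method), deterministic
envelope acceptance ($|\Delta\psi| \le \Delta\psi_\mathrm{model}(d)$,
hard cutoff), detector projection, optional Gaussian centroid jitter and
optional quantisation to pixel centres. Everything is reproducible
bit-for-bit from the seed, and the caller's RNG stream is left intact.
The reference conditions (`psi_conditions()`) are a hexagonal
photosystem-I-like crystal, $a = b = 281$, $c = 165.2$ Å,
$\gamma = 120^\circ$, $\lambda = 1.32$ Å, a 0.11 mm-pixel detector at
129 mm, zero mosaic spread, $D_\mathrm{eff} = 4850$ Å (a crystallite of
$17 \times 17 \times 30$ cells), analysed over 15–3.5 Å; roughly a
thousand reflections satisfy the envelope per image. The default
centroid noise for validation batches is $\sigma = 0.03$ mm, about a
quarter pixel, standing in for spotfinding centroid error.

What the simulator does *not* model — diffraction intensities and the
taper of intensity towards the envelope edge, solvent background,
inter-Bragg fringes, detector point spread, spectral bandpass — bounds
what recovery tests can show. In particular, every envelope-accepted
reflection is emitted as a "bright spot", so simulated record sets are
larger and more uniformly filled than a spotfinder's intensity-selected
lists; per-image mosaicity estimates on such records absorb a fraction
of the residual orientation error (a few ten-thousandths of a degree at
the accuracy floor reached here), which is visible only because the
simulation is otherwise noiseless.

## Numerical choices, in one place

* Angles are degrees at every user-facing surface, radians internally;
  lengths Å, detector coordinates mm relative to the beam centre.
* The orientation accuracy floor under the hybrid target is set by the
  realization statistics of the uniform-in-envelope offsets
  ($\sigma \approx \bar W/\sqrt{3 n}$ per in-plane axis, about
  $0.002^\circ$ at the reference conditions); no amount of iteration
  moves below it, and the two-stage protocol lands on it exactly.
* Equal-volume shells are computed in $1/d^3$; leftover records in the
  last mosaic bin merge backwards; assignment rejects fractional-index
  deviations above 0.3 (configurable).
* Detector-frame handedness: detector $x, y$ parallel to laboratory
  $x, y$ (right-handed, beam along $-z$); the beam centre is stored in
  mm from the panel corner. Any self-consistent alternative would do;
  this one is fixed in the geometry schema.
* Validation batch sizes (200 stills for accuracy and mosaicity
  recovery, 100 paired scenes for the protocol ordering, 50 replicates
  for estimator comparisons) keep full-suite runs in the tens of
  minutes on one core while leaving Monte-Carlo error well below the
  asserted margins.

## Known limitations

Single flat perpendicular detector panel; monochromatic beam (no
bandpass shell); no intensity or partiality model; no outlier rejection
beyond the assignment cutoff; the Bravais projection handles the
hexagonal family (and the identity projection for triclinic) rather than
all fourteen lattices. These mirror the declared scope of the method
rather than incidental gaps.
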