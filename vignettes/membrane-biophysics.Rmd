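---
title: "Methods: quantitative analysis of drug-membrane interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of drug-membrane interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(membranekit)
```

membranekit implements the four quantitative strands of a typical
drug-membrane interaction study — Langmuir monolayer thermodynamics and
insertion kinetics, polarized ATR-FTIR orientation analysis,
single-frequency impedance capacitance modelling, and molecular-dynamics
trajectory observables — together with seeded generators that produce
every input class with known ground truth. This vignette documents the
models, their assumptions, the tunable parameters, and the design
decisions taken where the methodology literature leaves choices open.

## Monolayer elasticity and phase transitions

A compression isotherm records surface pressure $\pi$ (mN m$^{-1}$)
against area per molecule $A$ (Å$^2$). Film elasticity is quantified by
the elastic compression modulus

$$C_s^{-1} = -A \left(\frac{\partial \pi}{\partial A}\right)_T ,$$

the reciprocal of the isothermal compressibility. First-order
liquid-expanded/liquid-condensed (LE/LC) coexistence appears as a plateau
in $\pi(A)$ and therefore as a deep minimum of $C_s^{-1}$; fluid phases
sit near 10–50 mN m$^{-1}$, condensed phases above 100.

Differentiating measured isotherms amplifies noise, so
`compression_modulus()` fits a local polynomial (default window 11
points, order 3) around each point of the *actual* area grid — which is
generally non-uniform, which is why a fixed-grid convolution smoother is
not used — and takes the analytic derivative of the local fit. The
window/order are exposed because the appropriate amount of smoothing
depends on instrument noise; the defaults suit several-hundred-point
isotherms with $\lesssim 0.1$ mN m$^{-1}$ noise.

`detect_transition()` locates the transition as an interior minimum of
$C_s^{-1}(\pi)$ inside a user-stated search window. Two refinements make
this robust on realistic curves:

* a minimum only counts as a transition if it drops by at least 10 % of
  the largest modulus in the window below the shallower window edge
  (`min_depth`); otherwise a flat single-phase curve would always yield a
  spurious interior argmin from numerical wiggles;
* the reported pressure is the centroid of the contiguous valley floor
  (points within 5 % of the valley depth of the minimum, `floor_frac`),
  not the raw argmin. A coexistence plateau gives a flat-bottomed valley
  whose argmin is arbitrary within the floor and biased toward the edge
  where the smoothed derivative undershoots; the centroid estimates the
  plateau *center* and is deterministic.

## Insertion kinetics and the exclusion pressure

Injecting a solute under a monolayer held at constant area raises the
surface pressure following pseudo-first-order kinetics,

$$\Delta\pi(t) = \Delta\pi_{\max}\,\bigl(1 - e^{-\beta t}\bigr),$$

fitted by unweighted Levenberg–Marquardt least squares
(`fit_insertion_kinetics()`), with starting values from the late-time
plateau and the initial slope. The $t = 0$ point is included and no
injection dead-time correction is applied: the data format carries no
dead-time information, and a correction would be an uncontrolled guess.
A warning is raised when the trace spans less than $2/\beta$, where the
plateau is poorly constrained. Standard errors from the fit are reported
so recovery can be judged in units of uncertainty.

$\Delta\pi_{\max}$ decreases linearly with the initial pressure $\pi_0$;
the abscissa intercept of the OLS line (`exclusion_pressure()`) is the
exclusion surface pressure, the film pressure above which the solute no
longer inserts. A non-negative slope is flagged undefined rather than
extrapolated.

## Polarized ATR and molecular orientation

ATR probes a film at a totally reflecting interface through the
evanescent wave, whose penetration depth is

$$d_p = \frac{\lambda}{2\pi\sqrt{n_1^2\sin^2\beta - n_2^2}},$$

a few hundred nm for Si/water at 60° in the mid-IR — much thicker than a
bilayer, which is the regime in which the thick-film dichroic analysis
below is valid.

The interfacial squared field amplitudes $E_x^2, E_y^2, E_z^2$ are
computed in the standard two-phase thick-film approximation (formulas in
`?interface_field_intensities`). Because published analyses differ in
whether they apply a thin-film correction — and the film refractive index
at each band is rarely known — an optional three-phase mode rescales the
normal component by $(n_2/n_{\rm film})^2$ when `n_film` is supplied.
Both modes are first-class; for the default Si/D$_2$O geometry and a
dichroic ratio near 1 they give effective dipole angles within about half
a degree of each other. Defaults are $n_1 = 3.42$ (Si prism),
$n_2 = 1.42$ (D$_2$O electrolyte), $\beta = 60°$, all overridable.

Band intensities come from a joint deconvolution of the p and s spectra
(`deconvolve_bands()`): a shared set of pseudo-Voigt bands whose centers,
widths and Gaussian/Lorentzian mixes are common to both polarizations
(the same vibration underlies both; only its projection differs), with
independent amplitudes and an independent polynomial baseline (order
0–2) per polarization. Bounded Levenberg–Marquardt is used; a band
collapsing to the width floor (default 0.5 cm$^{-1}$) aborts the fit as
unidentifiable rather than returning a spike.

For each band the dichroic ratio $R = A_p/A_s$ of integrated areas gives
the transition-dipole order parameter under uniaxial symmetry about the
interface normal,

$$S_{dip} = \frac{E_x^2 - R E_y^2 + E_z^2}{E_x^2 - R E_y^2 - 2E_z^2},
\qquad
\theta_{dip} = \arccos\sqrt{\tfrac{2S_{dip}+1}{3}} .$$

$S_{dip}$ is strictly increasing in $R$ (the denominator is negative
throughout the physical range), so more p-absorbing bands are more
normal-aligned; values below $R = E_x^2/E_y^2$ imply $S_{dip} < -1/2$
and are rejected as optics-inconsistent. Numerical excursions beyond
$[-\tfrac12, 1]$ smaller than $10^{-6}$ are clamped with a warning.
$\theta_{dip}$ is an *effective* single-orientation angle: a genuine
orientation distribution with the same $\langle\cos^2\theta\rangle$ is
indistinguishable, which is why the spectrum generator offers a Gaussian
orientation-spread mode to probe this degeneracy.

The symmetric and antisymmetric CH$_2$ stretching dipoles are mutually
perpendicular and perpendicular to the acyl chain axis, so

$$\cos^2\theta_{tilt} = 1 - \cos^2\theta_{sym} - \cos^2\theta_{asym},$$

which `chain_tilt_from_tdm_angles()` evaluates, rejecting inputs whose
squared cosines exceed 1 beyond $10^{-9}$. All angles are carried in
degrees and never rounded internally.

## Impedance pseudocapacitance and the dielectric thickness model

With only the imaginary impedance at a single frequency available, the
film is modelled as a series RC element:
$C_{ps} = 1/(2\pi f |Z''|)$, reported in µF cm$^{-2}$
(`pseudocapacitance_curve()`). No equivalent-circuit (CPE/Randles)
fitting is attempted — that would require spectra over frequency.

Treating the film as a parallel-plate dielectric of unchanged
permittivity, a capacitance drop from $C_{ref}$ to $C_{new}$ corresponds
to a relative thickening $\Delta d/d = C_{ref}/C_{new} - 1$
(`thickness_change_from_capacitance()`). Only the *relative* change is
computed: converting it to Å would require an absolute film thickness or
permittivity that single-frequency data do not determine.

## Trajectory observables

All observables assume a planar bilayer whose normal is the box $z$
axis, orthorhombic periodic boxes, coordinates in Å, and 1-based atom
indices in reports. Displacement vectors (C–H bonds, chain end-to-end
vectors, donor–acceptor separations) use the minimum-image convention,
so the observables are invariant under rigid translations and periodic
wrapping; centers of mass assume whole (unwrapped) molecules.

* `z_distance_distribution()` histograms the signed $z$ separation
  between mass-weighted centers of a probe and a reference selection.
  The reference can be re-selected each frame as the $n$ closest
  reference residues by center-of-mass distance (the "closest
  interacting lipids" convention for adsorption profiles); $n$ is
  configurable, defaulting to the whole selection.
* `hbond_time_fractions()` counts a bond when donor–acceptor distance
  $\le$ 3.5 Å and the D–H···A angle $\ge$ 135°. These geometric cutoffs
  are conventional trajectory-analysis defaults, not universal
  constants, and are configurable. The per-group fraction sums bond
  multiplicity over frames, so a group holding one permanent and one
  half-time bond reports 1.5.
* `scd_profile()` computes
  $S_{CD}(k)=\langle(3\cos^2\theta_{CH}-1)/2\rangle$ per carbon over
  lipids, frames and both C–H bonds. Hydrogens are located by covalent
  distance ($\le$ 1.25 Å within the residue); united-atom chains can be
  handled by `reconstruct_h = TRUE`, which rebuilds ideal tetrahedral
  hydrogens from neighbouring carbons (interior carbons only). Since
  order-parameter profiles are conventionally plotted either signed or
  as $|S_{CD}|$, both presentations are supported via `absolute`.
* `tilt_distribution()` measures the angle between the
  first-to-last-carbon vector of each chain and $+z$. Against a single
  normal a symmetric bilayer is two-peaked on $[0°, 180°]$;
  `fold = TRUE` maps $\theta \mapsto \min(\theta, 180°-\theta)$.
* `pairwise_interaction_energy()` sums Coulomb
  ($k = 332.0636$ kcal Å mol$^{-1}$ e$^{-2}$) and Lennard-Jones terms
  (Lorentz–Berthelot combining) between selection A and the molecules of
  selection B with any atom within the cutoff (default 12 Å) of A. The
  truncation is hard — no switching function — and the cutoff criterion
  is molecule-based, so an included molecule contributes all its atoms;
  these are explicit choices where practice varies, both exposed as
  parameters. Intra-selection energies are never computed and
  overlapping selections are rejected.

## Synthetic data: what it emulates, and what it does not

Each generator produces data whose *statistical structure* matches what
the corresponding analysis assumes, plus a `truth` record, and is
byte-deterministic given its seed (the caller's RNG state is restored).

* `gen_isotherm()`: piecewise constant-modulus segments
  $A(\pi) = A_i e^{-(\pi-\pi_i)/C_i}$, continuous at joins; defaults
  $C = (100, 5, 200)$ mN m$^{-1}$ with the low-modulus plateau spanning
  19–21 mN m$^{-1}$, emulating an LE/LC transition near 20 mN m$^{-1}$;
  an `area_shift` emulates the isotherm displacement caused by a solute
  in the subphase. Gaussian noise is added to $\pi$.
* `gen_insertion_traces()`: exact pseudo-first-order traces with
  $\Delta\pi_{\max}(\pi_0) = m\pi_0 + c$; defaults $m = -0.2$, $c = 10$
  (exclusion pressure 50 mN m$^{-1}$), $\beta = 0.01$ s$^{-1}$, 600
  points over 600 s — a span of $6/\beta$, comfortably constraining the
  plateau.
* `gen_polarized_spectra()`: per band,
  $A_p \propto E_x^2(1-\langle c^2\rangle)/2 + E_z^2\langle c^2\rangle$
  and $A_s \propto E_y^2(1-\langle c^2\rangle)/2$ with
  $\langle c^2\rangle = \cos^2\theta_{dip}$ (delta orientation, the
  default) or the average over a Gaussian tilt distribution; pseudo-Voigt
  shapes, polynomial baselines, Gaussian noise (reference level
  $10^{-4}$ AU).
* `gen_eis_sweep()`: inverts the series-RC relation for a prescribed
  smooth $C(E)$ (constant plus optional Gaussian peak).
* `gen_bilayer_trajectory()`: two mirrored leaflets of ideal all-trans
  zig-zag chains with explicit tetrahedral hydrogens on a lattice;
  per-lipid-per-frame tilt from a folded Gaussian with uniform azimuth
  and uniform self-rotation, so $S_{CD} = (3\sin^2\alpha/2 - 1)/2$ holds
  analytically at fixed tilt $\alpha$; an O–H probe with prescribed
  per-frame $z$ distribution; and a static donor with two acceptors on a
  deterministic schedule (one bonded every frame, one every
  `hbond_period`-th frame). An odd default carbon count (9) keeps the
  end-to-end vector exactly on the chain axis. Defaults (8 lipids per
  leaflet, 200 frames, tilt $33 \pm 5°$) are the reference conditions
  used throughout the tests; they are a deliberately scaled-down but
  statistically faithful stand-in for production bilayer simulations.

These toys deliberately omit solvation, realistic force-field geometry,
inter-lipid correlations, capillary-wave undulations and baseline drift
beyond low-order polynomials. Passing recovery tests therefore
demonstrates the correctness of the *analysis code* under the stated
statistical assumptions, not the validity of those assumptions for any
particular instrument or simulation.

## Numerical choices and degenerate inputs

Tolerances: $S_{dip}$ clamping $10^{-6}$; tilt radicand tolerance
$10^{-9}$; band width floor 0.5 cm$^{-1}$; hydrogen covalent-bond search
1.25 Å; distributions normalize to 1 within $10^{-6}$ by construction
(density histograms). Ties in transition detection resolve through the
valley-floor centroid. Degenerate inputs error early with named causes:
below-critical-angle optics, zero s-area, zero $Z''$, donors without
hydrogens, zero-length chain vectors, overlapping energy selections,
non-monotone area grids.

## Problem sizes

The test suite and the analysis scripts use 300–600-point isotherms and
traces, 401-point spectral grids with 2–6 bands, and trajectories of
~450 atoms × 200 frames (plus a 100-pair × 1000-frame isotropic-sampling
check), sizes at which every recovery tolerance stated above is met with
comfortable statistical margin while the full suite runs in well under a
minute.

## Known limitations

* The dichroic analysis assumes uniaxial symmetry about the normal and a
  film much thinner than $d_p$; in-plane anisotropy or thick films break
  Eq.-level assumptions silently.
* The capacitance model cannot separate thickness from permittivity
  changes; the reported percentage assumes the latter is constant.
* `scd_profile()` indexes carbons by the digits in atom names; exotic
  naming schemes need renaming first.
* Energies are bare force-field pair sums — no polarization, no Ewald
  long-range correction — appropriate for the short-range
  interaction-sphere bookkeeping they implement, not for absolute
  binding energetics.
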