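---
title: "kneesim: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kneesim: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The system being simulated

`kneesim` models a cadaveric-style squat experiment on a posterior-stabilized
total knee arthroplasty (TKA) knee mounted in a physiological joint rig. The
rig constrains the leg as follows:

* the **hip carriage** rides a vertical axis and the femur can rotate in the
  sagittal plane about it (2 degrees of freedom);
* the **ankle** blocks anterior–posterior and vertical translation of the
  distal tibia while leaving medio-lateral translation and all three
  rotations free;
* the **tibiofemoral** and **patellofemoral** joints are entirely governed by
  contact and soft tissue.

A squat is driven by imposing a vertical hip displacement profile. A PID
controller modulates the quadriceps tension so that the vertical reaction
measured at the ankle holds a constant setpoint (default 90 N), and the
medial and lateral hamstrings pull with a constant 50 N each toward the hip
carriage. One protocol cycle flexes the knee from 35° to a peak (default
90°) and back along a raised cosine.

On the ankle constraint set: the rig leaves five of the six distal DOFs
unconstrained *relative to the load cell gimbal*, eliminating
anterior–posterior displacement. Because the vertical ankle load is the
controlled quantity, vertical translation at the ankle is necessarily
reacted by the rig; the model therefore blocks ankle AP **and** vertical
translation and measures the vertical constraint reaction as "ankle load".

# Constitutive models

**Ligaments.** Each bundle is a straight line between two attachment points
(no wrapping, no damping) obeying the piecewise Blankevoort tension–strain
law

$$f(\epsilon) = \begin{cases}
0 & \epsilon < 0\\[2pt]
\tfrac14\,k\,\epsilon^2/\epsilon_l & 0 \le \epsilon \le 2\epsilon_l\\[2pt]
k\,(\epsilon-\epsilon_l) & \epsilon > 2\epsilon_l
\end{cases}$$

with linear strain limit $\epsilon_l = 0.03$ and strain
$\epsilon = (L - L_0)/L_0$. The zero-load length derives from the reference
strain $\epsilon_r$ via $L_0 = L_r/(\epsilon_r + 1)$, where the reference
length $L_r$ is the attachment distance at the settled full-extension pose
(see *Settling* below). The law is $C^0$/$C^1$ continuous at
$\epsilon = 2\epsilon_l$, which the test suite checks numerically.

Default stiffnesses and reference strains (per bundle, shared across a
ligament's bundles):

| ligament | bundles | k (N) | $\epsilon_r$ |
|---|---|---|---|
| MCL | anterior + posterior | 400 | 0.04 |
| LCL | 1 | 650 | 0.08 |
| MPFL | 1 | 6000 | 0.08 |
| LPFL | 1 | 3000 | 0.06 |
| patellar | medial/central/lateral | 25000 | −0.25 |

Whether published per-ligament stiffnesses should be split across bundles is
not standardized; here the tabulated k is interpreted **per bundle** and is
configurable.

The patellar ligament's negative reference strain (−0.25) makes its
zero-load length 1.33× the settled reference length: the tendon is slack at
settling and engages only once the quadriceps has drawn the patella
proximally by roughly a third of the tendon length. The synthetic trochlear
flange is a full cylinder about the condylar axis precisely so that this
load path works: the patella slides circumferentially up the flange until
the tendon engages, after which quadriceps tension transmits to the tibial
tubercle.

**Muscles.** The quadriceps is three bundles from the patella to the hip
carriage carrying a shared tension
$F_q = \alpha e^{\beta\,\mathrm{Quadlength}} + \mathrm{PID} + \mathrm{preload}$,
where *Quadlength* is the excursion of the mean bundle length from its
settled value (mm), $\alpha = 85$ N, $\beta = 0.05\,\mathrm{mm}^{-1}$ and
the preload defaults to 0 N (the preload magnitude at the 35° start position
is not standardized; it is an explicit protocol parameter). The hamstrings
are two constant-force elements (50 N each).

**Contact.** All articular interfaces use the compliant law
$F = k_c\,\delta^{\tau} + C_c\,\dot\delta$ with
$k_c = 5000\ \mathrm{N/mm}$, $\tau = 2.2$, $C_c = 10\ \mathrm{N\,s/mm}$,
where $\delta$ is the penetration depth of an analytic primitive pair:
condyle sphere in insert dish (per compartment), femoral cam capsule against
tibial post capsule, and patellar button sphere against the trochlear flange
cylinder. $\delta$ is the per-pair maximum depth (a volume-based measure
would need the commercial-solver mesh machinery and is out of scope). The
damping term only acts in explicit overlap-rate queries; the quasi-static
solver sees the elastic term alone.

# The synthetic knee

No deposited geometry exists for the experiments this class of model is
built on, so the package generates its own: analytic-primitive implant and
bone shapes tessellated into watertight multi-shell meshes (STL I/O for all
of them), with ligament attachments at literature-typical epicondylar,
fibular and tibial positions scaled to the segment dimensions, plus a
seeded normal jitter (SD 0.3 mm) emulating specimen variability. Default
proportions: condyle spheres r 18 mm spaced 44 mm, insert dishes r 21 mm
(3 mm radial clearance), post/cam capsules r 5/8 mm, trochlear flange
r 26 mm, patellar button r 12 mm, femoral segment 320 mm, tibial segment
280 mm.

Two generator choices are deliberate departures from textbook anatomy and
worth flagging:

* the **collateral bundles run obliquely** (the anterior MCL bundle runs
  anterior–distally with its femoral origin anterior/proximal to the
  flexion axis). This gives the collaterals internal–external rotational
  leverage and a pronounced strain–flexion gradient, so that the joint's
  rotational guidance is ligament-led rather than purely dish-led — the
  regime in which stiffness perturbations measurably move both strains and
  kinematics, as in lax post-TKA specimens. The anterior bundle strain
  consequently rises well above physiological magnitudes at deep flexion;
  this is an accepted artifact of straight-line (non-wrapping) bundles on
  desk-scale geometry.
* the **insert dishes are moderately conforming** (3 mm clearance), again
  so that soft tissue, not conformity, dominates transverse-plane
  equilibrium.

What passing tests on this geometry do *not* show: agreement with any
specific cadaveric knee, physiologic absolute strain levels, or
patellofemoral mechanics beyond a sphere-on-cylinder approximation.

# Quasi-static solution scheme

Everything that loads the system has a potential at fixed actuator tension
(gravity; ligament elastic energy; $T\cdot L$ for constant-tension
elements; $k_c\,\delta^{\tau+1}/(\tau+1)$ for contact; the hip-tracking
spring), so each cycle sample is solved as an energy minimization over the
12 unconstrained pose coordinates (hip height, femur sagittal angle, tibia
3 rotations + medio-lateral shift, patella 6 DOF), warm-started from the
previous sample. Gradients are assembled analytically from the force
elements; BFGS (with one restart if the scaled gradient exceeds
$10^{-3}$ N) does the minimization. A sample whose residual exceeds 1 N or
whose penetration exceeds 5 mm aborts the run with the offending sample
index.

Numerical choices worth recording:

* **Socket treatment of the dishes.** The conforming dish restores the
  condyle centre whenever the centre distance exceeds the radial clearance,
  in *every* direction. Under the squat protocol the joint is always
  compressed, so at the solution this is identical to unilateral dish
  contact; its purpose is to remove the nonphysical low-energy escape
  routes (condyle slipping over the dish rim mid-line-search) that a gated
  unilateral model leaves open. `detect_contacts()`, the reporting
  interface, keeps the strict unilateral semantics.
* **Lead-in.** Near full extension the forward- and backward-buckled
  branches of the hip–knee–ankle chain merge, so the cycle does not start
  from the settled extension pose: the solver is initialized directly in
  the forward-flexed basin at the start flexion, ramping the quadriceps
  tension from 50 N to its initial value over 12 continuation steps.
* **Hip drive.** The hip target height for a given flexion comes from the
  two-link closure of the chain; the proportional tracking gain (500 N/mm)
  holds the RMS tracking error below 1 mm under load.
* **Controller.** The ankle-load PID (kp 1.2, ki 14, kd 0.02, output
  clamped at ±4000 N with integral anti-windup) was tuned on the default
  model from the measured plant gain (≈0.3 N ankle load per N quadriceps
  tension) with conservative margins. Because the rig repeats a fixed
  cycle, `run_squat()` executes the cycle twice by default, feeding each
  cycle's tension profile forward into the next (as a physical repetitive
  rig settles over warm-up cycles); the returned trace is the final cycle.
* **Settling.** Reference lengths are defined *by* the settled pose, so
  ligaments cannot act during settling: the settle solves vertical
  equilibrium of the femur + patella unit under gravity and dish contact
  alone (1-D root find to machine precision, residual < 1e-6 N), with the
  patella carried rigidly on the femur. Settling is idempotent.

Angles are degrees and lengths mm at every interface (radians internally);
forces N; stiffness k carries N because strain is dimensionless.

# Kinematic reporting

Tibiofemoral kinematics follow the Grood–Suntay floating-axis convention:
flexion about the femoral medio-lateral axis, internal–external rotation
about the tibial long axis, varus–valgus about the mutual perpendicular,
implemented as a y–x–z factorization of the relative rotation (singular
exactly at varus–valgus ±90°, where an explicit error is raised).
Translations are the components of the tibial frame origin relative to the
femoral frame origin resolved on the tibial anatomical axes. Signs: flexion,
valgus, external tibial rotation, anterior, medial and proximal are
positive; the test suite audits each direction. Anatomical frames are the
generator's own (X anterior, Y medial, Z proximal; right knees by default,
left knees by mirroring) — no claim of equivalence with any
landmark-digitization protocol is made.

# Calibration

`calibrate()` mirrors the manual fine-tuning such models undergo: minimize
kinematic/load discrepancy against a reference trace while maximizing the
Pearson correlation. Since manual tuning has no canonical scalarization,
the objective is a declared convention:
$\sum_c w_c\,[\mathrm{RMSE}_c/\mathrm{range}_c + (1-\rho_c)/2]$ over the
six DOFs and the two loads, with reference-range normalization and unit
default weights; a constant channel takes the worst-case correlation. The
search is bounded coordinate descent with a golden-section line search per
parameter, accepting only improvements (the objective history is
non-increasing) and scoring failed simulations as +∞. Derivative-free
because the simulator response is only piecewise-smooth across
contact/slack transitions; no global optimality is claimed.

# Sensitivity analysis

Arm A perturbs the stiffness of one collateral ligament until the simulated
strain difference against the nominal run matches the residual error of
ultrasound-based strain estimation (0.27% strain for the MCL, 0.57% for the
LCL), holding reference strains fixed. The strain-difference statistic is
not standardized; the package's default is the **cycle maximum of the
absolute bundle-averaged strain difference** — the most conservative choice
(it yields the narrowest stiffness window); mean and at-peak-flexion
summaries are selectable. The root search is Brent's method on stiffness
within $[k/8,\,8k]$; an unreachable target returns the bound with a
`bound_hit` flag, and a ligament that never carries force returns the `"/"`
sentinel (its stiffness is immaterial, and the test suite checks the
perturbed trace is bit-identical). On the default synthetic model the
increased-stiffness direction reaches the MCL target; the
decreased-stiffness direction saturates below it and reports the bound —
the strain difference obtainable by softening a ligament is capped by how
much force it carried in the first place.

Arm B rotates the tibial baseplate + insert internally/externally by ±3.2°
about the tibial long axis through the baseplate centre (the rotation
centre is a package choice; the dish facets and post rotate, bones and
attachments do not), keeping the nominal ligament parameters and reference
lengths.

Both arms report per-DOF mean ± SD of (optimal − perturbed) across the
cycle, excluding flexion (the drive DOF), plus flexion-resolved difference
curves and the same statistic between the two arms' traces.

# Problem sizes

The shipped protocol discretizes one squat cycle into 101 samples (0–100%)
and runs two feedforward cycles; unit tests use 31-sample single-cycle
variants of the same protocol, and the pipeline test an 11-sample one. The
calibration recovery experiment searches one stiffness over [150, 900] N
with 12 line-search evaluations for 2 sweeps.

# Known limitations

* Straight-line bundles without wrapping over-estimate collateral strain
  excursions (deliberately, see above).
* Quasi-static continuation: no inertia, no contact damping at the
  solution, so rate-dependent phenomena are out of reach.
* The patellofemoral joint is a sphere on a cylinder; patellar tilt/shift
  are resolved only coarsely.
* Single implant family (posterior-stabilized, generic proportions), right
  knees; only internal–external baseplate malrotation is perturbed.
* The acceptance quantities are properties of the synthetic default model,
  not reproductions of any specimen-specific measurement.
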