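---
title: "From wearable sensors to muscle-driven ankle torque: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wearable sensors to muscle-driven ankle torque: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wearlab` turns five body-worn inertial sensors (pelvis, impaired-side thigh
and shank, both feet) and a 64-channel EMG garment on the impaired shank into
gait events, left/right ground reaction forces (GRF), a centre-of-pressure
(CoP) trajectory, sagittal knee and ankle angles, inverse-dynamics ankle
torque, and finally an EMG-driven Hill-type estimate of the ankle
dorsi-plantar flexion torque produced by seven shank muscles. This vignette
explains the models, the tunable parameters, and the design decisions taken
where the underlying methods leave room.

## Frames and conventions

The model frame is x anterior, y vertical (up), z to the participant's
right; gravity is $(0, -9.81, 0)\,$m/s$^2$. Quaternions are scalar-first
(w, x, y, z). Sensor-convention global frames have z up; the fixed transform
between the two is a $-90^\circ$ rotation about x, mapping $(x,y,z) \mapsto
(x,z,-y)$. Positive rotation about +z is knee flexion and ankle
dorsiflexion. Plantar flexors therefore produce negative ankle torque.

## Signal conditioning

All streams pass through a zero-lag (forward–backward) 2nd-order Butterworth
filter: laboratory-grade kinematic/kinetic streams at 6 Hz, sensor-derived
velocities and accelerations at 3 Hz. The lower corner for wearable streams
suppresses soft-tissue motion between sensor and bone. Two passes square the
magnitude response, so a 2nd-order design per pass yields an effective
4th-order zero-phase filter. Edges are handled by odd (point-symmetric)
reflection padding — at least three time constants of the corner period —
with steady-state initial conditions for the edge value, so a constant
passes through exactly and symmetric inputs produce symmetric outputs.

## EMG envelope chain

The garment amplifies each electrode against the average of all 64 inputs
(gain 23, 2000 Hz). The chain is:

1. **Noisy-channel detection.** A channel is flagged when its median
   absolute deviation exceeds `noise_mult` (default 5) times the median
   amplitude across channels — a robust test for the large voltage
   fluctuations of movement artifacts. The criterion used with the original
   garment is described in prior work on that hardware; this robust stand-in
   is deliberately simple and is exercised against labelled synthetic grids.
2. **Re-referencing.** Because the hardware reference is the all-channel
   average, artifacts leak into every channel. The common average is
   rebuilt from clean channels only and removed; flagged channels are
   zeroed. When the recorded signals are exactly $s_i = e_i -
   \operatorname{mean}(e)$ this reconstruction is algebraically exact.
3. **Envelope extraction.** 20 Hz zero-lag high-pass, full rectification,
   then a centred moving median of $\operatorname{round}(0.16\,\mathrm{s}
   \times f_s)$ samples. At 2000 Hz that is 320 samples, which is even; the
   window is forced odd (321) so the median is centred and phase-free — the
   parity rule is a package choice, since a centred even window does not
   exist. The median removes residual artifact spikes that a linear 6 Hz
   low-pass would smear into the envelope.
4. **Normalisation** divides each channel by its maximum envelope value
   across all recorded tasks, and **muscle averaging** takes the mean of
   the channels assigned to each of the seven target muscles (tibialis
   anterior, extensor hallucis longus, medial/lateral gastrocnemius,
   soleus, peroneus brevis and longus). The channel-to-muscle assignment is
   an input: automated muscle localisation on the garment grid is a
   separate problem and out of scope here.

## Gait events

Foot-flat (FF) is detected where all three components of the filtered foot
angular velocity simultaneously stay within $k \cdot \mathrm{sd}$ of their
trial mean (default $k = 0.5$); runs shorter than 50 ms are discarded as
chatter. Initial contact is the local maximum of the angular-velocity
signal-vector magnitude (SVM) immediately before a FF run — the heel-strike
spike — and terminal contact the local maximum immediately after it — the
push-off spike. Two choices deserve comment:

* The FF criterion is sometimes written for linear velocities; the same
  small-variation logic applies to angular velocities, which is also what
  the SVM event picking uses. The implementation defaults to angular
  velocity with a `use_linear_velocity` switch.
* The threshold multiplier $k$ is not standardised. The default 0.5 follows
  from the requirement that FF samples show only a small variation around a
  mean that is itself near zero; it is configurable (`events$k`).

Local-maximum searches are bounded by the neighbouring FF runs so an event
can never be captured from an adjacent cycle; FF runs touching the series
boundary yield no event and are logged. The four phases per impaired cycle
are tiled directly from the two sides' events: double stance 1 (impaired IC
to contralateral TC), single stance (to contralateral IC), double stance 2
(to impaired TC), and swing (to the next impaired IC).

## Kinetics

The generic body model (1.68 m, 75.16 kg, gait2392-style mass fractions and
foot geometry) is scaled by the single factor $s = \mathrm{height}/1.68$;
written as a ratio of heights this could be read either way round, and the
package resolves it so that taller participants get larger models. Segment
masses are mass fractions times body mass; the pelvis lump carries
everything except the impaired thigh, shank and foot and the contralateral
foot, following the inverted-pendulum assumption that the centre of mass is
bound to the pelvis.

Total GRF follows Newton: $F = \sum_i m_i (a_i - g)$ over the five
instrumented segments, assuming feet are the only ground contact. The
accelerometer already measures the specific force $a - g$, so the transform
chain keeps the gravity reaction in the signal and the summation multiplies
the readings directly — the gravity term is applied exactly once, a
convention documented on both functions. The sensors are taken to sit at
the segment centres of mass; lever-arm corrections are out of scope.

The left/right split uses the smooth transition assumption: full load on
the stance foot in single support, zero in swing, and during double support
the trailing foot's share falls along a smooth ramp from its single-stance
value to exactly zero at its terminal contact, the leading foot taking the
remainder (conservation is exact by construction). The component-specific
shapes fitted to instrumented-gait data in the literature are not
reproduced here; the default is the cosine ramp $s(\tau) = (1 + \cos \pi
\tau)/2$, and the share function is injectable for users who want the
fitted shapes.

The CoP model anchors three foot points — heel, calcaneus CoM and toe,
scaled generic offsets relative to the calcaneus CoM — and interpolates
linearly in elapsed time: heel at IC to calcaneus CoM at the contralateral
TC, then calcaneus CoM to toe at the foot's own TC, with the vertical
coordinate set to zero and swing samples undefined. Landmark positions come
from the foot pose series (orientation from the registered sensor, position
from the kinematic model — inertial sensors alone cannot observe absolute
foot position, so the pose series plays the role that a point-kinematics
tool plays in a lab pipeline; in simulation it is the generator's own pose
series).

## Joint mechanics

Sensor-to-segment registration uses a quiet standing trial: the fixed
rotation between the mean sensor orientation and the segment's default-pose
orientation. The participant is assumed to hold the model's neutral pose;
any systematic deviation (a flexed knee is common post-stroke) biases the
downstream angles by exactly that deviation — the bias is reproduced, not
hidden, and is exercised in the tests. Trials with gyro RMS above
0.2 rad/s are rejected.

For a sagittal chain with one sensor per segment, weighted-least-squares
orientation inverse kinematics reduces to relative-orientation
decomposition; knee flexion is the z-twist of thigh→shank, ankle
dorsiflexion the z-twist of shank→foot minus the static offset.

Ankle torque comes from the planar free body of the foot:
$$\tau = I_f \alpha_f + [r_{com-ankle} \times m_f(a_{com} - g)]_z -
  [(p_{cop} - p_{ankle}) \times F]_z,$$
with the foot angular acceleration obtained by twice differentiating the
sagittal foot orientation through the 3 Hz zero-lag filter, and $F = 0$
during swing. Torque is reported in N·m and N·m/kg.

Curves are compared with the squared Pearson correlation ($R^2$, shape
similarity — deliberately invariant to positive affine transforms, which an
SSE-based coefficient would conflate with amplitude) and RMSE (amplitude
similarity); an SSE-based variant is available behind a flag. Cycle
ensembles are resampled to 101 points (0–100 % of the cycle), the field's
convention.

## EMG-driven musculoskeletal model

Each muscle's normalised envelope $u$ maps to activation through
$a = (e^{Au} - 1)/(e^A - 1)$ with shape factor $A \in [-3, 0)$; the mapping
is monotone, fixes both endpoints and approaches the identity as $A \to
0^-$. No additional activation-dynamics filter is applied by default: the
envelopes are already median-smoothed to a 6 Hz-equivalent bandwidth, and
the electromechanical delay is fixed at zero.

Muscle-tendon lengths are polynomials in the ankle angle (plus a linear
knee term for the bi-articular gastrocnemii); moment arms are the analytic
derivative $-\partial L_{mt}/\partial\theta_a$. The shipped coefficients are
a configurable in-code asset with plausible sagittal geometry for the seven
muscles (neutral-angle arms of +4.2 cm for tibialis anterior down to
−5 cm for soleus); a full 3D geometry engine is intentionally out of scope
and users can substitute their own polynomials.

The Hill-type muscle is rigid-tendon: fiber length follows from
$l_m = \sqrt{(L_{mt}-l_{st})^2 + (l_{om}\sin\varphi_0)^2}$
(constant-thickness pennation), fiber velocity is the tendon-projected
muscle-tendon velocity normalised by $10\,l_{om}$/s, and the force along the
tendon is
$F = F_{max}\,[a\, f_l(\tilde l)\, f_v(\tilde v) + f_p(\tilde l)]\cos\varphi$
with a Gaussian active force-length curve ($f_l(1) = 1$), a standard
hyperbolic force-velocity curve ($f_v(0) = 1$, eccentric plateau 1.8) and an
exponential passive curve anchored at $f_p(1) = 0$. A rigid tendon keeps the
model algebraic (no inner equilibrium loop) and is the dominant choice when
tendon compliance is not separately identified.

**Pre-calibration** picks person-specific initial optimal-fiber and
tendon-slack lengths by matching the normalised fiber-length curve of the
scaled geometry to the generic model's curve over an angle grid (least
squares); for uniformly scaled geometry this reproduces the uniformly
scaled lengths exactly. **Calibration** then minimises
$J = \mathrm{MSE}(\tau_{model}, \tau_{ref})/\mathrm{Var}(\tau_{ref})$
over one gait cycle, with $l_{om}$ and $l_{st}$ bounded within ±5 % of
their pre-calibrated values and strength coefficient (default [0.5, 2])
and shape factor ([−3, 0)) within configured ranges. The ±5 % reading
resolves an ambiguous "around 5 % or the values found during scaling" in
the method's description as "of". The optimiser is a seeded differential
evolution (rand/1/bin, population 40, 120 generations by default) followed
by an L-BFGS-B polish; any bounded seeded global scheme would do — the
contract is determinism under a fixed seed and a final objective no worse
than the initial one. The calibrated model then estimates torque on unseen
trials from envelopes and angles alone; trials at other speeds share the
comfortable-speed calibration.

## The synthetic known-answer surface

The generator builds fully self-consistent trials, so every stage has an
oracle:

* **Segment kinematics** are C² piecewise quintic/sinusoid curves with
  analytic first and second derivatives. Each foot is exactly stationary
  during stance and exactly flat on $[IC + r, TC - r]$, where $r$ (default
  0.05 cycle) is the half-width of the heel-strike and push-off rotation
  windows. Those windows are centred on the true IC and TC, so the
  angular-velocity magnitude peaks at the true events — the synthetic
  counterpart of the contact spikes that make the event definitions work on
  real data. Push-off pivots about the planted toe, so the heel rises and
  the CoP progresses monotonically to the toe. Small out-of-plane wobble
  and mediolateral excursions keep all three axes informative.
* **Inertial signals** follow from the kinematics: orientations composed
  with configurable mount offsets, specific force rotated into the sensor
  frame, angular velocity by quaternion differentiation, and seeded
  Gaussian noise (defaults 0.05 m/s², 0.01 rad/s — sensor-grade values
  chosen for testability; field noise characteristics vary with mounting
  and are not modelled).
* **EMG** phase-locks each muscle's activation profile (wrapped Gaussian
  bumps with textbook timing) onto band-limited 20–450 Hz carrier noise
  across a 64-channel grid, 8 channels per muscle plus 8 channels of large
  low-frequency artifact.
* **Ground truth** computes total GRF by direct Newton summation of the
  analytic accelerations, splits it with the smooth cosine hand-off
  evaluated at the *true* phase, lays the CoP along the prescribed
  roll-over, and evaluates ankle torque from the closed-form planar free
  body.

Default conditions: cadence 100 steps/min, 1.1 m/s, duty factor 0.6, ten
cycles (matching the minimum number of recorded cycles per condition in the
motivating protocol), participant 1.775 m / 94.2 kg (the study cohort's
mean height and mass).

What passing tests on this surface do and do not show: they verify the
algebra, the conventions, the boundary behaviour and the parameter
recovery of every stage under known conditions. They do not certify
accuracy on real post-stroke gait — real data add soft-tissue artifact,
asymmetric and atypical foot strikes (an IC that is not a heel strike
breaks the heel-anchored CoP model), imperfect static poses, and EMG
cross-talk, none of which the generator emulates.

## Numerical choices and degenerate inputs

* Filters reject cutoffs at or above Nyquist and series too short for edge
  padding.
* FF detection aborts on zero-variance (constant) inputs; all-noisy EMG
  grids abort rather than re-reference against nothing; all-zero envelope
  channels are left at zero rather than producing NaN.
* Event alternation violations abort with the offending samples; cycles
  missing contralateral events are dropped and logged.
* Geometry polynomials are clamped to their validity range with a warning;
  slack muscle-tendon states produce zero active force and are counted.
* The `.sto` writer stores 15 significant digits (round trips to better
  than 1e-12) and permits missing values only in CoP point columns, where
  they encode swing.
* All randomness flows from explicit integer seeds; repeated runs are
  byte-identical, which the test suite checks on the full pipeline output.

Problem sizes in the shipped tests (five-to-six-cycle trials at 100 Hz,
four-second EMG at 2000 Hz, one-cycle calibrations with a population of 30
for 60 generations) are chosen so the whole suite runs in a few minutes on
a single core; all are configuration parameters, and larger runs only
tighten the statistics.

## Known limitations

* Planar (sagittal) mechanics throughout; frontal/transverse angles and
  non-ankle joints are out of scope.
* The CoP model assumes heel-first contact and anterior progression —
  explicitly wrong for some pathological strikes.
* No walking aids: the GRF model requires feet as the only ground contact.
* Rigid tendon; no activation dynamics or electromechanical delay by
  default.
* The sensors are assumed at segment CoM positions, and the static
  registration assumes the neutral pose is actually held.
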