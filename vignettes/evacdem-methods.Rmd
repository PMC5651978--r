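---
title: "Modelling panic evacuation through guided exits with evacdem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling panic evacuation through guided exits with evacdem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

evacdem simulates a panicked crowd of soft elliptical agents evacuating a
room through a narrow exit flanked by guide walls, and provides the
measurement layer needed to study the *faster-is-slower* (FIS) effect:
the observation that individually faster agents can produce collectively
slower evacuations at a bottleneck. This vignette is the package's own
account of the model, its numerical choices, and its limits.

## The mechanical model

Each agent is a rigid ellipse of semi-axes $a \ge b$ moving in the plane.
Newton's second law is integrated for every agent,

$$ m \ddot{\vec r} = \vec F_{\text{contact}} + \vec F_{\text{psy}}, $$

with two force classes.

**Contact forces.** Collisions are penalty ("soft particle") contacts:
bodies may overlap slightly, and the overlap depth $\delta$ drives a
linear spring-dashpot normal force
$F_n = k\,\delta - \eta\,(\vec v_{rel}\cdot\hat n)$ along the contact
normal $\hat n$ (pointing from the other body toward the subject). The
dashpot coefficient is not free: it is derived from the coefficient of
restitution $e$ by the closed-form relation for the linear model,
$\eta = 2(-\ln e)\sqrt{m_{\text{eff}}k}\,/\sqrt{\pi^2 + \ln^2 e}$, with
$m_{\text{eff}} = m_i m_j/(m_i+m_j)$ for pairs and $m_{\text{eff}} = m$
against immobile walls (`damping_coefficient()`). A tangential spring
accumulates the tangential relative displacement over the life of a
contact and is capped by Coulomb friction at $\mu |F_n|$; at the cap the
stored stretch is truncated (sliding). Walls are segments with two
usable faces, and wall junctions such as the exit-gap doorposts act as
point obstacles with radial penetration, so the force field has no
normal discontinuities at corners.

**Psychological force.** Each agent holds a desired velocity
$\vec v^{\,*}$ set by the behavioural layer and relaxes its current
velocity toward it,
$\vec F_{\text{psy}} = (m/\Delta t_{\text{res}})(\vec v^{\,*} - \vec v)$,
with response time $\Delta t_{\text{res}} = 0.1$ s. In free motion this
gives an exponential approach to the desired speed with time constant
$\Delta t_{\text{res}}$, which is one of the two parameter-level checks
recomputed by `scripts/acceptance.R`. The gain $c = m/\Delta t_{\text{res}}$
is always derived from the agent mass (0.3 kg/s for a 30 g mouse-scale
agent; a human-scale agent of ~50 kg gives the familiar ~500 kg/s).

### Ellipse contact geometry

The overlap of two ellipses is resolved geometrically rather than through
a quartic resultant: the boundary of one ellipse is scanned for crossings
of the other's implicit form (64 samples, bisection refinement, plus a
golden-section refinement of the minimum so grazing lenses between
samples are not missed). The two most distant crossing points define the
intersection chord; $\delta$ is the extent of the overlap lens along the
chord's mid-normal, the contact point is the midpoint of that extent, and
the normal is the mid-normal oriented from the other body toward the
subject. In the circle limit this reduces exactly to $2r - d$. When one
center lies inside the other ellipse the center-to-center direction is
used instead, so the force direction stays defined under extreme
compression; exactly coincident centers raise a degenerate-contact error.
The test suite holds this algorithm to an independent oracle (dense
parametric boundary sampling with `uniroot`/`optimize` refinement) to
within $10^{-4}$ m on hundreds of random pairs.

## The behavioural layer

The panic-state rules produce each agent's desired velocity every
integration step:

1. **Rushing to the exit.** The base direction points at the nearest
   point of the exit segment inset by one semi-minor axis from the
   doorposts. Far from the exit this is indistinguishable from aiming at
   the gap midpoint; close up it points straight through the opening. A
   literal midpoint target is degenerate at close range — an agent just
   below the exit line but off-center receives an almost horizontal
   direction and orbits the midpoint instead of crossing — which is why
   the inset-segment form is used.
2. **Overtaking.** If the nearest agent in the front sector (half-width
   $\pi/6$, radius four semi-major axes) is *walking in the same
   direction* and is slower, the agent tries to pass: it checks its
   preferred side first (90% of agents are right-first, 10% left-first,
   assigned exactly and shuffled by seed) and steers $\pm\pi/6$ into the
   first side sector whose density is strictly below the critical
   density. Sector density is the count of other agents in the circular
   sector divided by its area $\pi R^2/6$. Two readings deserve note:
   the front target itself is excluded from the side-sector counts
   (the side wedges overlap the front wedge, so a dead-ahead leader
   would otherwise veto its own overtake), and a target that is
   essentially stationary (below 0.01 m/s) or moving against the
   agent's heading is *not* engaged by this rule — a jammed or opposing
   crowd is an obstacle to push against, not a leader to follow.
3. **Slow-and-follow.** If both side sectors are at or above the
   critical density, the agent adopts the front target's current speed
   (never more than its own desired speed) and heads toward it.
4. **Stepping away from walls.** A lateral steering adjustment
   (perpendicular to the desired direction, so it never cancels forward
   progress) pushes away from the nearest wall *face* within the
   avoidance range, weighted by $1 - d/d_{\text{avoid}}$. Face distance
   means the perpendicular projection must fall within the segment, so
   the exit doorposts do not deflect an agent already in the opening.

Side-avoidance of parallel walkers is realized implicitly by the density
checks and the contact forces; no separate lateral force is added.

**Critical density.** The human-scale rule uses 0.78 agents/m².
Preserving the occupied-area fraction for a 6 cm × 3 cm elliptical agent
gives the mouse-scale default of 77 agents/m² (the spirit of the rule is
"is there room for a body of my size in that sector"). With the default
sector radius this threshold means a single occupant already blocks a
sector, which matches the human-scale numbers as well.

**Repositioning (jostle).** The rules above are fully deterministic, and
a deterministic granular packing can reach exact static equilibrium: a
dome of agents over the gap, held by wall reactions, that no amount of
steady pushing rearranges. Blocked animals visibly shift their footing;
to give the model the same escape route, an agent whose speed stays
below 0.01 m/s for `block_time` (1 s) sidesteps for `reposition_time`
(0.5 s) — its desired direction rotates a quarter turn toward its handed
side at full desired speed — then resumes the normal rules. The rule is
deterministic, seed-free and mirror-symmetric; setting `block_time = 0`
disables it.

## Arena

The room is a `width` × `length` rectangle (defaults 0.25 m × 0.85 m),
with the exit gap (default 0.06 m) centered in the far wall and the
waiting strip (default 0.30 m deep) at the near end. The guide walls are
hinged at the exit-gap edges, rotated by $\theta$ from the exit-wall
plane into the room, and span to the side walls — the boundary is closed
with no gap except the exit, mirroring an apparatus in which angled
walls connect the corridor sides to the exit. At $\theta = 0$ they are
collinear with the exit wall (a flat wall with a plain opening); the
funnel depth grows as $\tan\theta\,(W - e)/2$. Fixed-length guide walls
hinged at the gap would leave wedge-shaped dead pockets between their
outer faces and the exit wall at steep angles, which is why the
full-span form is the default.

## Study conditions and the generator

A single trial places `n_agents` (default 20) non-overlapping agents in
the waiting strip by seeded rejection sampling, draws desired speeds
from a normal distribution redrawn below a floor of 0.05 m/s (a realism
bound: a foot-shocked animal does not crawl at centimeters per second),
assigns handedness, and integrates until everyone has exited or
`max_time` (120 s) elapses.

The angle sweep (`sim_sweep()`) reproduces the two experimental
conditions at desk scale — six angles 0–75°, three cases per angle,
20 agents per case:

* **`smice`** (measured dispersion): each angle draws from its own
  speed distribution, with means falling 0.45 → 0.20 m/s and standard
  deviations 0.20 → 0.05 m/s linearly in $\theta$ (`fis_speed_profile()`),
  emulating the observation that animals run slower and more uniformly
  once lane formation sets in at steep guide walls.
* **`suni`** (uniform dispersion): every angle draws from the single
  across-angle distribution (mean of the means, mean of the sds). This
  is the manipulation that removes the angle dependence of the speed
  inputs.

The synthetic-track module (`generate_tracks()`, `fis_track_preset()`)
is independent of the simulator: it emits straight-line,
video-rate-sampled trajectories with known speeds and exit times in the
same CSV dialect a tracking-software export would produce, together
with closed-form expected metrics computed directly from the speed
values. It makes the entire measurement layer testable to $10^{-9}$
without any experimental data, at the experiment's own scale (50
agents, 3 cases, 6 angles). What it does *not* emulate: tracking noise
beyond optional omissions, curved paths, occlusions, or identity swaps
— so exactness there validates the metrics arithmetic, not robustness
to real tracking artifacts.

## Measurement layer

From per-frame positions the package computes instantaneous speeds by
finite differences (central in the interior, one-sided at the ends),
per-agent mean speeds from start to exit, their per-trial mean, the
per-angle mean over cases (the total average velocity), the per-trial
evacuation span `T_evc` (last exit minus first start), the mean
individual evacuation time `t_evc`, and the velocity dispersion: per
trial the population standard deviation (divisor $N$, switchable) of
per-agent mean speeds about the trial mean, averaged over cases per
angle, and averaged across angles to a single uniform value. The
printed form of the dispersion in the source literature nests an
integral inside sums in a way that is not dimensionally coherent; the
implementation follows the prose — a double average over agents and
cases of the spread of per-agent mean speeds.

Exit-event streams reduce to bursts: consecutive exits closer than a
gap threshold (default ten output frames, 0.333 s at the default
30 fps stride) form one burst. Burst sizes always sum to the exit
count; the size-frequency table normalized by the number of pooled runs
is fitted in log-log coordinates, where a negative slope expresses the
inverse relation between escape-burst scale and frequency.

## Numerical choices

* **Integrator.** Semi-implicit Euler. The default step is
  $10^{-4}$ s: with the tabulated stiffness ($5\times10^4$ N/m),
  restitution 0.1 and a 30 g mass, the damping derived for a pair
  contact gives $\eta\,\Delta t/m_{\text{eff}} \approx 2.15$ at a
  $10^{-3}$ s step — beyond the explicit-update stability bound of 2 —
  so contacts would pump energy instead of dissipating it. (At human
  scale, with $m_{\text{eff}}$ three orders larger, the
  $10^{-3}$ s step is comfortably stable, which is why that value is
  natural in human-scale work.) The restitution check in the test
  suite integrates at $10^{-6}$ s to resolve the ~2 ms contact.
* **Orientation.** No torque balance is integrated (the source model
  prints none); the body axis relaxes toward the heading — the desired
  velocity direction, or the velocity direction when the psychological
  force is off — at a bounded angular rate (default a quarter turn per
  response time). Instantaneous slaving of orientation to velocity is
  *unstable in contact*: velocity swings spin the ellipse in place,
  each rotation jumps the overlap depth, and the spring does work from
  nothing.
* **Determinism.** All randomness (placement, speeds, handedness) is
  drawn in R under derived seeds; the compiled core is purely
  arithmetic. Identical configuration and seed reproduce bit-identical
  trajectories and exit lists.
* **Degenerate inputs.** Coincident ellipse centers raise a
  degenerate-contact error; non-finite states name the agent and step;
  a waiting area too small for the requested crowd suggests enlarging
  it; exit widths below one agent minor diameter are rejected.

## Problem sizes

The bundled checks run at desk scale, chosen so the full suite and the
acceptance sweep complete comfortably on one CPU: 20 agents per trial,
six angles, three cases per mode for the FIS contrast (about 36
trajectory-recorded runs), 200 random pairs for the geometry oracle,
and the 50 × 3 × 6 synthetic fixture for the metrics layer.

## Known limitations

* **Speed-congestion coupling in the uniform mode.** The per-agent mean
  speed from start to exit equals path length over in-room time, so
  under heavy congestion it is inversely tied to the evacuation time.
  In the uniform-dispersion sweep at desk scale (20 agents through a
  0.06 m exit) this gives the measured mean speed a systematic *rising*
  tendency with the guide-wall angle as congestion relaxes. With six
  angle means and three cases the tendency is usually, but not always,
  below the significance threshold of a Spearman rank test — "flat"
  here means only that the input-driven decline is gone, not that the
  measured speed is free of angle dependence. The angle-dependent mode
  recovers the falling speed trend because the inputs carry it. A
  genuinely flat speed profile under uniform inputs would require
  congestion to occupy a smaller share of each agent's in-room time
  than this desk-scale geometry produces.
* Torque-free bodies: agents cannot be pinned broadside in a way that
  resists rotation, and contact-driven spin is excluded by
  construction.
* No herding/panic-probability parameter, no memory or learning, and no
  climbing over conspecifics.
* The repositioning rule is a closure the source rules do not state; it
  matters only in configurations that would otherwise freeze, but its
  two time constants are conventions.
* Human-scale parameterization is untested here; only the mouse-scale
  instance is exercised.
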