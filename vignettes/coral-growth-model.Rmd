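---
title: "An agent-based model of clonal growth in stony coral colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of clonal growth in stony coral colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`coralclone` simulates a scleractinian coral colony as a triangular surface
mesh in which **every vertex is one polyp**. The mesh is the living tissue
layer (the coenosarc); the volume it encloses stands for the calcium
carbonate skeleton the polyps deposit. The colony starts from a *hexacone*
seed — a hexagonal pyramid whose apex is the founder polyp and whose six
substrate-bound base vertices are its first clone generation (hexacorals
organize in multiples of six) — and evolves by iterating, every time step
$\Delta t$ (fixed at 0.1 yr):

1. **Surface accretion.** Each polyp carries a unit surface normal
   $\hat n = (n_x, n_y, n_z)$ (the area-weighted mean of incident-face
   normals). Its normalized elevation
   $$\xi(\hat n) = \frac{2}{\pi}\,
     \arctan\!\Big(\frac{n_z}{\sqrt{n_x^2 + n_y^2}}\Big) \in [-1, 1]$$
   is 1 for a vertically-up normal, 0 for a horizontal one. The **growth
   mode** $s = [s_{\min}, s_{\max}]$ gates accretion: a polyp relocates by
   $V \to V + \alpha\,\hat n$ with $\alpha = \nu\,\Delta t$ only when
   $s_{\min} \le \xi \le s_{\max}$ (closed interval). Base polyps use the
   horizontal projection of their normal (so $\xi = 0$ always): they can
   spread along the substrate but never leave it, which anchors the colony.
2. **Cloning (asexual budding).** Any edge longer than the subdivision
   distance $\delta_{sub}$ is split — longest first, iterated to quiescence —
   at the $t = 0.5$ point of a cubic Bézier interpolant of the local
   surface, so the new polyp bulges with the curvature instead of sitting on
   the chord. Edges shorter than $\delta_{fuse} = 0.2\,\delta_{sub}$ are
   collapsed (polyp death/reabsorption), which smooths elongated triangles.
3. **Self-regulated branching** (optional; apical dominance as in
   *Acropora*). Polyps at Euclidean distance
   $l_{br} \pm \epsilon$ ($\epsilon = 0.25\,l_{br}$) from every existing
   branching node are candidates; each is promoted to a **branch leader**
   with per-step probability $\min(1, p_{br}\,\Delta t)$ where
   $p_{br} = \nu\,(l_{br} N_{br})^{-1}$ and $N_{br}$ counts existing
   branches (the trunk included). A new leader is kicked $4\alpha$ along its
   branch axis $\hat n_{br}$ — at angle $\theta$ from the parent branch
   axis, tilted toward the polyp's own normal — and thereafter elongates
   $\alpha$ per step along that axis, bypassing the $\xi$-gate.

Five parameters therefore span the morphospace: $s_{\min}, s_{\max}$
(dimensionless), $\nu$ (mm/yr), $\delta_{sub}$ (mm), $l_{br}$ (mm) and
$\theta$ (degrees). Units are millimetres and years everywhere; the
substrate is the plane $z = 0$.

## Morphotype presets

| preset | gate $s$ | other | behaviour |
|---|---|---|---|
| `massive` | $[0, 1]$ | | uniform accretion, hemisphere |
| `cauliflower` | $[0.01, 1]$ | | base anchored, inverted cone |
| `columnar` | $[0.375, 1]$ | | vertical pillar |
| `branching` | $[0.375, 1]$ | $l_{br} = 40$ mm, $\theta = 30^\circ$ | ramified, 32 yr |
| `tabular` | $[0.30, 1]$, then $[0, 0.24]$ from $t = 3$ yr | | stem, then spreading table |
| `encrusting` | $[0, 0]$ | | exclusively horizontal sheet |

All presets use $\nu = 10$ mm/yr and $\delta_{sub} = 10$ mm.

```{r, eval = FALSE}
library(coralclone)
run <- run_colony(preset_config("massive"))
run$metrics
export_mesh(run$final, "massive_t6.ply")
```

## Design choices

**The elevation functional.** The gate functional is the normalized
elevation angle $(2/\pi)\arctan\!\big(n_z/\sqrt{n_x^2+n_y^2}\big)$, the
unique form meeting both defining limits ($\xi = 1$ vertical-up, $\xi = 0$
horizontal) while strictly increasing in $n_z$; it yields every documented
morphotype. A variant sometimes written as
$(2/\pi)\arctan\big((1 - n_z)/\sqrt{n_x^2+n_y^2}\big)$ is kept available
(`xi_variant = "as_printed"`) for comparison, but it returns 0 for a
vertical-up normal and 0.5 for a horizontal one — it does not satisfy the
limits above and no preset uses it.

**Gate semantics.** The closed interval $[s_{\min}, s_{\max}]$ is used
(boundary values grow). It subsumes the alternative one-sided reading
$\xi < s$ and matches all preset parameterizations.

**Synchronous update.** All normals are frozen at step start and every gated
polyp then moves; the result is independent of vertex ordering, which makes
runs bit-reproducible across platforms.

**Sub-step order.** Accretion → leader elongation → cloning → fusion →
branching. Cloning before fusion means fusion never acts on a
density-starved mesh; branching last means a fresh $4\alpha$ kick is
consolidated by subdivision on the next step.

**Bézier handles.** The control points are $P_1 = A + (L/3)\,t_A$,
$P_2 = B + (L/3)\,t_B$, with $t_A, t_B$ the unit projections of the chord
onto the endpoint tangent planes. The $L/3$ handle length reproduces a
circular arc's bulge to second order, and on flat regions the handles cancel
exactly, leaving the Euclidean midpoint. Degenerate projections (edge
parallel to a normal) drop their handle.

**Collapse rules.** A collapse places the survivor at the edge midpoint,
except that a base vertex survives in place when fused with a non-base
vertex (the substrate rim stays intact) and a branch leader always survives
in place (apical polyps are never absorbed). Collapses that would break
manifoldness are refused, not fatal: the link condition (common neighbours
must be exactly the vertices opposite the edge), a boundary-pinch guard for
interior edges between boundary vertices, and a guard against isolating an
opposite vertex.

**Trunk registration.** With branching enabled the seed apex is registered
as leader of branch 1 with a vertical axis, so $N_{br} \ge 1$ and
$p_{br}$ is always defined. Leaders are excluded from candidacy and never
stop elongating.

**Branching probability.** $p_{br}$ has units of 1/yr and is applied per
candidate per step as $\min(1, p_{br}\Delta t)$; with the $1/N_{br}$
damping this keeps expected internode spacing near $l_{br}$.

**Distances are Euclidean.** The candidate band is a physical (not
geodesic) distance from node origins, and the parent of a new branch is its
nearest node, so every internode distance lies in
$[l_{br} - \epsilon,\, l_{br} + \epsilon]$ by construction.

**Stabilization rule.** For sensitivity sweeps a run is *stabilized* when
the mean inter-polyp distance changes by less than 1% over 10 consecutive
steps. A fixed 20-step burn-in skips the seed transient (the first splits
produce large early swings), and a hard cap `max_t` (30 yr by default)
bounds every run. These values were fixed before any sweep was measured.

**Branch diameters** are measured by slicing the mesh with planes
perpendicular to a branch axis at evenly spaced stations (one
$\delta_{sub}$ margin at each end), keeping the intersection loop nearest
the axis, and averaging twice the mean radial distance of loop points.
Vertices lying exactly on a section plane are nudged by $10^{-9}$ mm so
crossings stay strict. Note that the whole-branch mean stretches its
stations with the elongating branch and therefore mixes in young, thinner
tip sections; the steady-state property of branch thickness (set by the
inter-polyp spacing, not by simulation duration) holds exactly at fixed
sections once the growth gate has frozen the flank polyps.

## What the generator does and does not emulate

The simulator *is* the stated world: there is no external data, and the
synthetic colonies are the object of study. The defaults encode the
documented conditions ($\Delta t = 0.1$ yr, $\nu = 10$ mm/yr,
$\delta_{sub} = 10$ mm, preset gates). Real colonies differ in ways that
are deliberately out of scope: environmental modulation (light, flow,
nutrients), parameter stochasticity producing irregular shapes, branch
collision and anastomosis, and the leaderless ramification of cauliflower
corals. A green test therefore establishes internal consistency of the
model and agreement with the published sensitivity analysis — not fidelity
to any particular living colony.

Randomness enters only through branching (leader selection and the rare
degenerate-direction tie-break); all other morphotypes are exactly
deterministic, which the test suite checks by comparing runs across seeds.

## Numerical edge cases

* Non-unit normals passed to `xi()` are an error — never silently
  renormalized.
* A base vertex with a vertical normal (horizontal part below $10^{-9}$)
  grows radially outward from the colony axis; on the axis itself the
  direction is fixed to $(1, 0, 0)$.
* Cloning iterates at most 20 passes; over-long edges after that raise an
  error (runaway geometry).
* Vertex ids are stable and never reused after fusion, so snapshots can be
  compared across time.

## Known limitations

* Branches do not collide or fuse; densely packed colonies
  ($l_{br} \lesssim 10$ mm at long times) will self-intersect.
* The open-base disk topology means colony "volume" is not directly
  measurable from the mesh.
* Mean interior degree slightly exceeds the planar-hexagonal limit on
  coarse meshes ($\delta_{sub}$ comparable to the colony radius), where few
  interior vertices exist.
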