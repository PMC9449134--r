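---
title: "Quantifying subclonal interactions in spheroid invasion assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying subclonal interactions in spheroid invasion assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Diffuse midline gliomas infiltrate the brain parenchyma rather than growing
as compact masses, and they are heterogeneous: single-cell-derived subclones
from the same tumour can differ markedly in how fast they proliferate and
move. When two such subclones are grown together, the invasion of one can be
enhanced or suppressed by the presence of the other — a *spatial subclonal
interaction*. The experimental readout is an invasion assay: a labelled
spheroid embedded in extracellular matrix, imaged daily per fluorescence
channel, and segmented into per-clone binary masks.

`spheroidABC` implements the computational side of that assay end to end:

1. a stochastic 3D cellular-automaton (CA) model of spheroid growth and
   invasion for one or two clones, advanced by Gillespie's stochastic
   simulation algorithm (SSA);
2. mask-based invasion summary statistics;
3. a two-stage rejection approximate-Bayesian-computation (ABC) pipeline that
   first recovers each clone's proliferation and motility rates from
   mono-cultures and then recovers the interaction strength each clone
   receives in co-culture.

# The cellular-automaton model

Cells live on an `L × L × L` lattice; a site is empty or holds one cell of
clone A or clone B. A simulation starts from a well-mixed ball of cells of
radius `seed_radius` (default 5 lattice units, which is 515 occupied sites)
at the lattice centre, each seeded cell assigned to clone A independently
with probability equal to the seeding ratio.

Each cell undergoes three processes, as independent exponential clocks:

* **division** at the proliferation rate `p` (divisions/day). The daughter
  occupies an empty site of the 26-site 3D Moore neighbourhood; if the
  neighbourhood is full and the *aggression* parameter `a ≥ 2`, the cell may
  instead push the contiguous run of cells along one of the 26 lattice rays
  outward by one step, provided an empty site exists within Chebyshev
  distance `a` on that ray. A nearest such empty site wins; ties among rays
  are broken uniformly at random.
* **movement** at the motility rate `m` (cell widths/day) to an empty Moore
  neighbour chosen uniformly at random.
* **death** at `0.1 p`. There is no experimental readout of cell death in
  the assay, so the death rate is pinned to 10% of the division rate: enough
  turnover to matter, guaranteed net growth, and one parameter fewer to
  infer.

The SSA draws the waiting time to the next event from an exponential
distribution with the summed rate of all clocks, picks one cell-process pair
with probability proportional to its rate, and executes it. This yields
statistically exact trajectories of the underlying continuous-time Markov
process.

Interactions modify motility only. The effective motility of clone *i* is

    M_i = max(0, m_i + r_j · I_ij)

where `r_j` is the proportion of the other clone among living cells and
`I_ij` the interaction strength received by *i* from *j* (x/day per unit
proportion). By default proportions are computed over the entire lattice — a
*global* neighbourhood, the natural regime for diffusible-factor
(chemokine-like) signalling; a finite Moore-radius neighbourhood is
implemented for contact-range interactions but is off by default (it forces
per-cell propensity recomputation and is far more expensive).

At each snapshot time the 3D state is collapsed to one 2D binary mask per
clone — pixel `(x, y)` is set iff any z-column site holds that clone —
mirroring what a microscope records of a 3D system.

## Choices the model description leaves open

These points are underdetermined by the biology and were fixed once, as
package defaults:

* **Lattice size and boundary.** Default edge `L = 120`. The frame is
  treated as permanently occupied (no flux); any cell that reaches it
  triggers a warning, because a trustworthy assay simulation should never
  let the spheroid touch the frame. A completely full lattice aborts with a
  diagnostic.
* **Blocked events consume the SSA step.** A division or move with no
  available target is a null event: time advances, the state does not. This
  keeps per-cell rates state-independent and the SSA exact without
  neighbourhood-dependent bookkeeping. Event tallies record selections and
  realized outcomes separately.
* **A move is one lattice step** regardless of direction; diagonal Moore
  moves count as one cell width, since motility is specified as events per
  day rather than path length.
* **Negative effective motility is clamped to zero** — rates cannot be
  negative, and strongly negative inferred interactions would otherwise
  break the algorithm.
* **Aggression default is 1**, i.e. no pushing: pushes only become possible
  at `a ≥ 2` (distance-1 targets are already the ordinary division rule).
* **Dead cells vacate their site immediately**; there is no corpse state.
* **Clone assignment at seeding is i.i.d. per site** (a well-mixed
  spheroid), not spatially sorted.
* **One seeded RNG per simulation**; identical configuration and seed give
  bit-identical snapshot stacks.

# Invasion summary statistics

Four statistics reduce a mask to numbers comparable across experiments and
simulations:

* **Radial occupancy profile and travelling-wave fit.** Pixels are binned
  into 1-pixel annuli around the spheroid centre (the lattice centre for
  simulations; for experimental stacks the day-0 centroid). The occupancy
  fraction `C(r)` is fitted with the logistic wave
  `C(r) = 1 / (1 + exp((r − w) / (2a)))` by nonlinear least squares, with
  `a > 0` enforced on the log scale and the initial wave-front guess taken
  from the half-occupancy crossing. `w` (the **wave-front coefficient**,
  pixels) measures the extent of the dense core; `a` (the **diffusion
  coefficient**, density/distance) measures how shallow the invasion front
  is. They are static descriptors of a configuration, not literal
  reaction-diffusion constants. Occupancy is bounded by 1, matching the
  logistic's upper plateau. Non-convergence is flagged on the returned
  object rather than failing silently; inside databank forward models a
  degenerate (constant-occupancy) profile falls back to the profile's
  radius, so a single pathological draw cannot abort a databank.
* **Invaded area**: the convex-hull area of occupied pixel centres
  (pixels²). Raw pixel count is available as an alternative but the hull is
  the default notion of "area invaded".
* **Cell density**: cells per pixel² — set pixels divided by hull area by
  default, or the true 3D count when summarizing a simulation snapshot (the
  z-collapse merges columns, so the 3D count is never smaller).
* **Normalized ratio curve and AUC.** For a focal clone cultured at several
  seeding ratios, its mean co-culture invaded area at each ratio is divided
  by its mean same-day mono-culture area; the point (1, 1) is appended by
  construction and an ordinary quadratic is fitted across ratios. Without
  interactions the curve falls as the focal seeding ratio falls; a positive
  received interaction bends it into a parabola with an interior peak above
  1. The analytic integral of the fitted quadratic over ratio ∈ [0, 1] — the
  **AUC** — grows with the received interaction strength and is the summary
  statistic of the co-culture inference stage.

Day-0 masks are excluded from ABC summary vectors: every culture starts from
the same seeded ball, whose constant-occupancy profile carries no wave front
and no information.

# The two-stage ABC pipeline

**Stage 1 (mono-cultures).** A databank of simulations is built by drawing
(proliferation, motility) from uniform priors — defaults 0.05–2 d/day and
0–20 x/day, wide enough to contain the posteriors in practice — and
recording the per-day summary vector of each seeded run. The observed
summary vector is compared with every row by a weighted Euclidean distance
and the closest draws are accepted (default threshold: the 0.5% distance
quantile, floored at 200 accepted rows). Summaries are standardized by their
databank standard deviations before weighting, so that weights express
information content rather than units — raw areas in pixels² would otherwise
dominate densities. Truncated normal distributions (bounded by the prior)
are fitted to the accepted samples by maximum likelihood.

**Summary-statistic weights** can be optimized with a genetic algorithm on
validation cases with known ground truth: the fitness of a weight vector is
the squared prior-width-normalized distance between the truth and the
posterior point estimate (the accepted-sample median) summed over validation
cases. The GA uses tournament selection, blend crossover, Gaussian mutation
projected back onto the simplex, elitism and random restarts; the
equal-weight vector is always in the initial population, so the optimum can
never be worse than equal weighting on the validation set. The returned
weights sum to one exactly.

**Stage 2 (co-cultures).** Each row of the interaction databank draws both
clones' rates from the stage-1 truncated-normal fits — propagating phenotype
uncertainty instead of collapsing it to a point estimate — and the
interaction strength received by the focal clone from a uniform prior
(default −30 to 30 x/day). The row simulates the focal mono-culture plus one
co-culture per seeding ratio and records the AUC. ABC on the single AUC
summary yields the interaction posterior, reported as a 95% highest-density
interval (the shortest sample interval holding 95% of the mass) and a modal
interval (the fullest zero-anchored histogram bin; width 0.5 for rates, 1.0
for interaction strengths).

Interactions are inferred **one clone at a time**: while inferring the
strength received by the focal clone, the non-focal clone's received
interaction is fixed at zero. Joint two-dimensional inference would need a
much larger databank for the same acceptance density; the one-at-a-time
design matches how the posteriors are reported and interpreted.

A clone's **sign call** is positive/negative when its HDI excludes zero and
neutral otherwise (no point-null testing). The pair label is a pure function
of the two sign calls: mutualism (+,+), commensalism (+,0), exploitation
(+,−), competition (−,−), amensalism (−,0), neutral (0,0). The **maximal
effect** view pairs motility draws `m` with interaction draws `I` and
compares `m` against `max(0, m + I)` — the effective motility if the other
clone's proportion were 1 — to show the largest shift the interaction could
produce.

# The synthetic-experiment generator

`generate_synthetic_experiment()` emulates the assay design with known
ground truth: mono-cultures of both clones and co-cultures at the configured
seeding ratios (defaults 75:25 and 50:50), imaged at 24 h intervals over
four days, several replicates per condition. Masks are written as plain-text
portable bitmaps with a manifest CSV and a ground-truth JSON. Per-condition
seeds are derived from the master seed by stable string hashing, so a
specification regenerates byte-identical datasets.

Optional segmentation-like noise drops occupied pixels (false negatives) and
sets empty pixels inside the mask's convex hull (false positives —
segmentation errors happen around the spheroid, not in empty matrix). The
real segmentation pipeline's error rates are not quantified anywhere, so the
noise rates are robustness-testing knobs, not calibrated quantities; the
default in the generator is zero noise.

What the generator deliberately does **not** emulate: fluorescence rendering
and image registration, microscope optics, uneven illumination, or
real-pixel calibration (1 lattice unit = 1 pixel; inference is
unit-relative). A green recovery test on synthetic data therefore
establishes that the inference machinery is self-consistent — that the
pipeline recovers what the simulator put in — not that the CA model is an
adequate description of any particular cell line.

# Numerical choices and degenerate inputs

* Wave fits run three starts over the diffusion scale (0.5, 2, 8) because
  the RSS surface can be shallow in `a`; profiles with fewer than 4 bins or
  constant occupancy are rejected.
* Convex hulls with fewer than 3 non-collinear points have area 0; densities
  over zero area are errors (or 0 inside forward models).
* `abc_reject` raises the threshold to meet the accepted-row floor and
  errors only when the databank itself is smaller than the floor.
* Zero-variance summary columns are left unstandardized (divider 1).
* Modal-interval ties break toward the lowest bin.
* Empty lattices fast-forward the clock (total rate 0); full lattices abort.
* Seeds derived internally (databank rows, synthetic conditions) stay below
  2³¹.

# Known limitations

* The death rate is pinned at 10% of division and not inferred; if death
  could be measured the pinning should be revisited.
* Inference is noise-ignorant by default: databank simulations contain no
  segmentation noise. At the default acceptance rule this is robust to mild
  (5%) pixel dropout, but at much tighter acceptance thresholds the dropout
  bias in diffusion and density summaries becomes visible as a coverage
  loss. If the observation process is known to be noisy, the remedy is to
  apply the same noise model inside the databank forward simulations.
* Strong spatial competition can mask interactions (a fast clone engulfing a
  slow one restricts its invasion regardless of signalling); the model
  quantifies the net effect and cannot separate mechanism.
* No quiescence/"go-or-grow" switching, no nutrient fields, no off-lattice
  mechanics, and no PDE-level estimation of true diffusion constants — the
  travelling-wave coefficients are descriptive statistics only.
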