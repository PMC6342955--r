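---
title: "Methods: tracer diffusion and pore-scale rates in crowded 2D media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracer diffusion and pore-scale rates in crowded 2D media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crowdperc)
```

## The model

crowdperc simulates a hard disc (the tracer) performing a random walk
through a quenched matrix of non-overlapping hard discs in a periodic
square box — the excluded-volume 2D Lorentz model used to reason about,
for example, protein diffusion in crowded membranes. All lengths are in
units of the disc diameter $\sigma$ (obstacles and tracer share it), and
one Monte Carlo time unit is one sweep, $t = \mathrm{MCS}/N_\mathrm{tracer}$.

The control parameters are the obstacle area fraction
$\varphi = \pi N \sigma^2 / 4L^2$ and the maximum per-axis step size
$\Delta$: each attempt displaces one randomly chosen tracer by
independent shifts uniform on $[-\Delta, \Delta]$. A move is accepted iff

1. the trial position overlaps no obstacle (centre distance $\ge \sigma$),
   and
2. the move segment crosses no *impassable channel*: a Delaunay edge of
   the obstacle centres whose gap $g = l - 2\sigma \le 0$, where $l$ is
   the edge length ($2\sigma$ = obstacle diameter + tracer diameter).

Rule 2 removes geometrically impossible pore-to-pore jumps that a large
$\Delta$ would otherwise allow (a finite step can land beyond a
bottleneck narrower than the tracer), and makes the percolation threshold
of the dynamics independent of $\Delta$. Small $\Delta$ corresponds to a
viscous solvent (many tiny steps per pore), large $\Delta$ to rapid,
poorly equilibrated motion.

Near the void-percolation threshold $\varphi_c$ the long-time diffusion
coefficient vanishes as $D \sim (\varphi_c - \varphi)^\mu$. The lattice
value $\mu^{latt.} = 1.31$ in 2D is often assumed universal. The package
measures $\mu(\Delta)$ directly, and independently explains its
$\Delta$-dependence at the pore level: channel transition rates
$W$ develop a power-law singularity $\rho(W) \sim W^{-\alpha}$ when the
local equilibrium approximation behind transition-state theory (TST)
fails, and renormalisation-group theory then predicts
$\mu = \max(\mu^{latt.}, 1/(1-\alpha))$ in 2D.

## The generator and what it emulates

`generate_matrix()` is random sequential adsorption (RSA): discs are
inserted at uniform random positions and rejected on overlap, then
quenched. This is the disordered-medium ensemble whose structure
(`radial_distribution()`, `gap_distribution()`) is *independent of*
$\Delta$ by construction — the central control of the study: any
$\Delta$-dependence of dynamics cannot be structural.

The generator does *not* emulate: equilibrated (Metropolis) hard-disc
liquids (RSA has slightly different short-range correlations),
overlapping-obstacle "Swiss cheese" media, polydispersity, soft
interactions, or mobile crowders. Conclusions from passing tests
therefore concern the quenched-RSA ensemble only; real membranes add
obstacle mobility and softness that the model deliberately excludes.

Placement uses a periodic cell list ($O(1)$ overlap checks), a per-disc
attempt cap of $10^6$ (exceeding it raises a saturation error — RSA jams
near $\varphi \approx 0.547$), and one named seeded generator
(xoshiro256++) per run; identical seeds give bit-identical media. Tracers
are placed without overlap against obstacles *and* each other at $t = 0$;
afterwards tracer–tracer interactions are off, so they may overlap during
the run (they are independent walkers sharing one medium).

## Pore network

`tessellate()` builds the periodic Delaunay triangulation of the obstacle
centres: triangles are pores, edges are channels. Implementation: the
point set is tiled with periodic images inside an adaptive margin,
triangulated with a Bowyer–Watson kernel, and the torus tessellation is
the set of triangles whose circumcentre falls in the central cell (each
periodic triangle has exactly one such image). The result is verified
structurally on every call — $T = 2N$, $E = 3T/2$ (torus Euler
characteristic), every periodic edge shared by exactly two triangles, and
every kept circumdisc inside the tiled domain — and the margin is
enlarged on failure. Co-circular degeneracies (e.g. lattice
configurations) are broken by a deterministic jitter of
$10^{-10}\sigma$ keyed on the matrix seed. Geometry tolerances are bare
double precision; grazing contacts in segment tests are counted as
crossings (conservative, measure zero).

The accessible area $A$ of a pore (the region its centre of mass can
occupy) is the triangle minus the three vertex exclusion discs of radius
$\sigma$, computed exactly by Green's theorem over the clipped boundary
(`accessible_area()`); when the discs only cut corner sectors this
reduces to $A_{tri} - \pi\sigma^2/2$. Overlapping discs and discs
reaching past the opposite edge are handled by the same boundary
decomposition, validated against rejection sampling in the tests.

Percolation (`has_wrapping_cluster()`) is torus wrapping: union–find over
pores joined by passable channels with integer displacement bookkeeping;
a cluster that closes on itself with non-zero net boundary crossing wraps
that axis. A configuration percolates when some cluster wraps at least
one axis. Wrapping is boundary-free and scales cleanly with $L$; an
independent grid flood-fill oracle (0.015–0.02$\sigma$ resolution) agrees
with it on $\ge 95\%$ of near-threshold configurations in the tests.

The threshold pipeline (`estimate_phi_c()`) fits
$P(\varphi, L) = \tfrac12[1 + \tanh((\varphi_c(L) - \varphi)/\Delta\varphi)]$
per size and extrapolates $\varphi_c(L)$ against $L^{-1/\nu}$,
$\nu = 4/3$. The default $\varphi$ grids track the finite-size transition
at $0.2125 + 0.09\,L^{-3/4}$ with half-width $0.6\,L^{-3/4}$ (about
2.6 tanh half-widths), calibrated once from pilot wrapping curves so the
data bracket $P$ from $\approx 0.99$ to $\approx 0.01$ — a precondition
of the fit, not a tuned outcome. At $L \in \{50, 100, 150\}$ with 200
configurations per point the extrapolation reproduces
$\varphi_c = 0.2125$ to within $\pm 0.005$.

## Dynamics and diffusion estimation

`run_simulation()` evolves tracers with the two acceptance rules; edge
crossing queries use a halo grid of periodically shifted edge images, so
move segments never need unwrapping logic. Positions accumulate
unwrapped for the MSD. Determinism: a fixed seed reproduces trajectories
bit-for-bit, and the channel rule is provably inert when
$\Delta$ is below the smallest positive gap (the tests exploit this as a
small-step equivalence check), while cluster confinement (a consequence
of rule 2) is asserted by point location along trajectories.

`msd()` supports two estimators. The default is the fixed-origin
ensemble average $\langle |r(t) - r(0)|^2\rangle$, matching an
ensemble-of-configurations protocol. For desk-scale ensembles its noise
makes long-time slopes unstable, so `multi_origin = TRUE` computes the
sliding-origin (time-averaged) MSD on an arithmetic sampling grid — the
two agree in expectation for these stationary dynamics, and the
time-averaged curve is used by the exponent sweep.

`diffusion_coefficient()` implements two gates. The `"plateau"`
estimator applies the Einstein relation over the final window whose
log-slope lies in $[0.95, 1.05]$ for at least half a decade, raising a
typed "no diffusive window" error otherwise (this is the sub-diffusion
detector). The `"linear"` estimator fits $\mathrm{msd} = C + 4Dt$ over
the trailing 70% of the curve: the constant $C$ absorbs the short-time
crossover offset that depresses the raw log-slope long after $D$ has
converged, and the gate instead requires the two halves of the window to
agree on $D$ within 20%. The exponent sweep uses the linear estimator;
its small residual bias is shared across step sizes.

## The exponent sweep and its window

`mu_sweep()` measures $D(\varphi)$ at fixed $\varphi_c = 0.2125$ (the
threshold is determined by its own pipeline and held fixed — co-fitting
$\mu$ and $\varphi_c$ is badly conditioned) over
$\varphi \in [0.10, 0.175]$, extended to $0.185$ for
$\Delta \ge 0.3$ whose faster clock makes the diffusive regime reachable
there; run lengths scale as $1/\Delta^2$ and grow towards the threshold.
Matrices and tracer starts are shared across step sizes, so
$\mu$ differences are a paired comparison in which quenched-disorder
noise largely cancels.

Problem sizes are $L = 100$, 10 tracers, and 10–12 configurations per
point, with runs up to $2\times10^6$ sweeps — chosen so the whole sweep
completes in minutes on one CPU. At these sizes the window sits further
from the threshold than an asymptotic critical fit requires, so the
fitted values are *effective* exponents: their ordering and growth with
$\Delta$ is the meaningful statement, while absolute values are biased
low relative to the asymptotic exponents (which at full scale reach
$\approx 2.06$ at $\Delta = 2$ versus $1.31$ at $\Delta \le 0.1$).
Equation-of-motion consistency is checked instead through the scaling
collapse: $\langle\Delta r^2\rangle / t^{2/z}$ against
$t(\varphi_c - \varphi)^{2\nu + \mu - \beta}$ with
$z = (2\nu - \beta + \mu)/(\nu - \beta/2)$, $\beta = 5/36$. The sign
convention on $\beta$ in the collapse exponent is exposed as a flag
(`beta_sign`), with the minus sign — the scaling form consistent with
$z$ — as the default; the collapse quality score (mean squared log-spread
over the common support) is this package's scalar stand-in for a visual
collapse judgement.

## Pore-level rates

`first_passage()` starts tracers uniformly over the accessible region of
a pore (rejection sampling against all obstacle exclusion discs — the
equilibrium measure TST presupposes) and evolves them under the same MC
rules until the first accepted move whose endpoint leaves the starting
triangle; the exit side is the first starting-triangle edge crossed along
that segment (a large-$\Delta$ jump can traverse several pores, so
attribution must be parametric and deterministic). Escape times are
$\tau_\mathrm{MFPT}$ in sweeps; non-escapes within the step cap are
censored and reported. Closed pores (no passable side) are excluded — a
trial there would never end.

`rate_table()` assembles, per channel, the TST side
$W_\mathrm{TST} = \max(g, 0)/A$ and
$P_\mathrm{TST} = g_i / \sum_i g_i$ (negative gaps clamped), and the
numerical side $P_\mathrm{num} = N_i/N_\mathrm{trial}$ and
$W_\mathrm{num} = P_\mathrm{num}/(2\tau_\mathrm{MFPT})$. Comparisons use
the free-space diffusivity $D_0 = \Delta^2/6$ as the TST prefactor.

Two desk-scale caveats are built into the estimators and matter for
interpretation:

* **The $D_0$ prefactor is approximate.** Measured first-exit rates at
  small $\Delta$ sit a systematic factor $\approx 2$ above
  $D_0 g/A$ — consistent with diffusion-limited escape theory, where the
  rate through an aperture $g$ in a pore of area $A$ carries a
  $\pi/(g \ln(\cdot))$ correction, and confirmed by an independent
  brute-force simulation of a clean three-obstacle fixture. The exact
  prefactor for stochastic dynamics is not known in closed form; only
  the *shape* comparison of the distributions is parameter-free.
* **Finite trial counts Poisson-thin the small-rate tail.** A channel
  whose expected escape count is of order one appears in only a fraction
  of tables. `fit_alpha_rates()` therefore weights detected channels by
  the inverse detection probability $1/(1 - e^{-N_i})$, excludes rates
  below the scale where a typical pore expects fewer than one escape,
  and `fit_alpha()` caps its window below the distribution mode, since
  $\alpha$ describes the $W \to 0$ limit and fitting across the bulk
  peak would measure the bulk's flank. A negative fitted exponent means
  the density *decreases* towards small rates — no singularity — and the
  singularity strength is $\max(0, \alpha)$. With these corrections,
  500 trials per pore on a $\varphi = 0.21$ medium resolve the
  singularity growth with $\Delta$; at $\Delta = 0.01$ no singularity is
  detectable (the TST expectation), and at large $\Delta$ the RG value
  $\max(1.31, 1/(1-\alpha))$ lands in the non-universal range measured
  independently from $D(\varphi)$.

The log-binned density itself (`rate_distribution()`) bins exactly on
the log scale (10 bins/decade by default); R's histogram fuzzing is
unreliable when bin widths span many decades.

## Other design choices

* Multiple passable-edge crossings in one jump are allowed; only
  sub-$\sigma$-gap crossings reject (the literal acceptance rules).
* Moves grazing a tessellation vertex count as crossing all incident
  edges (conservative; measure zero).
* Tracer starting positions are not filtered to the percolating cluster;
  below $\varphi_c$ a small fraction of walkers are confined and lower
  the MSD plateau accordingly. A cluster-restricted average would raise
  $D$ slightly; the default mirrors unconditioned placement.
* `p_ratio` distributions (`ratio_distribution()`) use linear bins
  covering at least $[0, 3]$; the mass outside $[0.4, 1.6]$ is the
  scalar used to quantify TST breakdown growth with $\Delta$.

## Known limitations

* Effective exponents, not asymptotic ones: the desk windows stop at
  $\varphi \le 0.185$ where correlation lengths still fit in $L = 100$.
* The singularity exponent at very small $\Delta$ is bounded, not
  resolved: showing a clean plateau over decades of $W$ needs
  $\gtrsim 10^4$ trials per pore and $\sim 10^5$ pores.
* Rule 2 checks segment crossings against channel edges; it is exact for
  the pore-network dynamics defined here, which is itself an
  approximation to continuum hard-disc motion only in the small-$\Delta$
  limit.
* One CPU, no parallelism: thread counts never affect results because
  there are none.
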