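---
title: "Pathway activation scoring: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway activation scoring: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pascore)
```

# The scoring model

`pascore` scores the activation state of signaling pathways one case
sample at a time. The method deliberately collapses pathway topology to
a single signed coefficient per member: each gene product either
promotes the pathway's output (activator, role +1), inhibits it
(repressor, −1), acts in a partial or ambiguous way (±0.5), or is
neutral (0). Under the simplifying assumption that activator and
repressor branches act as sequential chains, the pathway's multiplicative
readout is the signal outcome

$$SO = \frac{\prod_i [\mathrm{AGEL}]_i}{\prod_j [\mathrm{RGEL}]_j},$$

the product of activator expression levels over the product of
repressor levels. Taking logarithms gives the additive pathway
activation strength for pathway $p$ in one case sample,

$$\mathrm{PAS}_p = \sum_n \mathrm{ARR}_{np}\,\cdot\,\mathrm{BTIF}_n
  \,\cdot\, w_n \,\cdot\, \lg \mathrm{CNR}_n,$$

where $\mathrm{CNR}_n$ is the case-to-norm ratio (case expression over
the arithmetic mean of the reference group), $\mathrm{BTIF}_n$ gates
genes whose deviation from the reference group is not convincing, and
$w_n$ is an optional importance factor. `compute_pas()` asserts the
log-linkage $\mathrm{PAS} = \lg SO$ (uniform weights, filter off, unit
roles) to 1e−12 in the test suite; it is the structural identity tying
the two formulations together.

Assumptions worth stating explicitly:

- expression values are linear-scale and strictly positive (log
  fold-changes must be defined); log-transformed input must be
  de-transformed upstream;
- the reference ("norm") group represents the unperturbed condition and
  has at least two samples, so a sample standard deviation exists;
- roles are per-(pathway, gene): the same gene may activate one pathway
  and repress another;
- a pathway gene missing from the platform contributes zero and is
  counted in `n_missing` rather than raising an error — no microarray
  or RNA-seq annotation covers every catalog member.

# The tolerance filter

The BTIF flag is 1 only when two criteria hold simultaneously:

1. **fold-change**: CNR outside $[1 - c,\ 1 + c]$ with $c$ =
   `fold_cutoff` = 0.5 by default, i.e. outside $[0.5, 1.5]$;
2. **dispersion**: $|x_\mathrm{case} - \bar{x}_\mathrm{norm}| >
   k \cdot s_\mathrm{norm}$ with $k$ = `sd_multiplier` = 2 and
   $s_\mathrm{norm}$ the *sample* SD ($n-1$ denominator).

Two readings of a "50% cut-off" exist: symmetric on the linear CNR axis
(outside $[0.5, 1.5]$, our default) or symmetric in log space (outside
$[2/3, 1.5]$). We chose the linear reading because it treats a 50%
drop and a 50% rise as the same fraction of the reference level; the
cutoff is a parameter, so the log-symmetric alternative is one argument
away. Similarly, "standard deviation" is taken as the sample SD — with
reference groups of 3–10 arrays the difference from the population SD
is material, and the sample SD is the unbiased default everywhere else
in R. The filter is **on** by default for every scoring path; the
unfiltered "simplified" score is exposed via `apply_btif = FALSE`
because the log-linkage identity and the robustness analysis are
naturally stated on it.

# Kinetic models and importance factors

Where a mass-action kinetic model of a pathway exists, the relative
importance of its proteins can be computed instead of assumed.

**Representation.** A model is a list of named molecular *forms* (state
variables) with initial concentrations, mass-action reactions
(rate = $k \cdot \prod$ reactant concentrations $\cdot \prod$ modifier
concentrations; modifiers catalyse without being consumed), one
designated effector form, and conservation groups — sets of
interconverting forms of one protein whose concentrations sum to a
fixed total $C^{tot}$. We deliberately model at the form level rather
than auto-expanding each protein into implicit active/inactive forms:
the file states exactly the states that exist, group totals are the sum
of member initials, and perturbing a total scales all member initials
by one factor so the initial active fraction is preserved. Species
outside every declared group form implicit singleton groups, giving
every protein an addressable total.

**Integration.** `simulate_network()` uses a stiff-capable solver
(`deSolve::lsoda`) — signaling cascades routinely mix fast binding with
slow accumulation — on a log-spaced output grid of 200 points spanning
six decades up to the horizon (default 1e4 time units), which resolves
both the early transient and the approach to steady state. Only
structurally conserved groups (zero net stoichiometry in every
reaction) are checked against their totals at output time; open
systems, used e.g. to test non-settling dynamics, are legal.

**Steady state.** The steady-state time $T$ is the first output time at
which the scaled derivative norm $\max_j |\dot C_j| / (atol + |C_j|)$
falls below `tol` (default 1e−6) *and stays below it* for the rest of
the horizon; a system that never satisfies this reports "not reached"
(`NA`) and the sensitivity integral refuses to run rather than
silently truncating.

**Sensitivity importance** $w^{(1)}_j = \frac{1}{T}\int_0^T
\left|\frac{\partial \ln \mathrm{EFF}(t)}{\partial \ln C^{tot}_j}\right|
dt$ is estimated by multiplicative central differences: the model is
re-simulated with the total scaled by $(1 \pm h)$, $h$ = `rel_step` =
1e−3, on the *same* time grid over $[0, T]$ as the base run — mixing
per-run steady-state times would compare the integrand at different
times and bias the integral. The integral uses the trapezoid rule on
that grid; points where the base effector has not yet risen above the
integrator's `atol` are excluded, because the log-derivative at
$\mathrm{EFF}=0$ is an artifact of the initial condition. Totals with
no structural reaction path to the effector return 0 exactly, without
simulation. The function accepts an explicit `t_end` because the *time
average* converges to the steady-state log-sensitivity only once the
settled phase dominates the window; on the one-step cascade the
transient contributes $\pi^2/24 \approx 0.41$ to the running integral,
so probing the large-$T$ limit needs a window several times longer
than the detected settling time.

**Stiffness importance.** The Hessian of the fit objective
$S(C^{tot}) = \sum_k (\mathrm{EFF}(C^{tot}, t_k) -
\mathrm{EFF}^{exp}_k)^2/\sigma_k^2$ is computed by central second
differences with per-coordinate step `rel_step` $\cdot\, C^{tot}_i$
(default 0.01 — second differences sit closer to integrator noise than
first differences, so the step is an order larger) and symmetrized as
$(H + H^\top)/2$. `stiffness_importance()` returns $w^{(2)}_j =
|\xi_{sj}|$, the absolute components of the unit eigenvector whose
eigenvalue has the largest *absolute* value: finite-difference Hessians
of noisy objectives can have negative eigenvalues, and magnitude is
what "stiff" means. Exact ties on $|\lambda|$ are broken toward the
eigenvector whose first nonzero component has the smallest species
index, making the output deterministic.

**Mapping to genes.** Kinetic models cover a handful of proteins;
pathways list dozens of genes. `map_importance_to_weights()` gives
mapped genes their species' factor and unmapped genes the *mean* of the
mapped factors — a neutral fallback that neither inflates nor erases
the unmapped members — then rescales the vector to mean 1 so weighted
and unweighted PAS live on the same scale (the natural scale on which
their ratio is examined). Perturbation weights in the robustness
analysis are deliberately *not* rescaled: the analysis measures the raw
moment of the weight distribution.

# Robustness analysis

For pathways without kinetic models the package quantifies how unknown
importance factors could move the score. Each of `n_trials` = 98 trials
draws one weight per gene, $w_n = 2^{x_n}$ with $x_n \sim N(0, 0.5^2)$
(log-normal, $E[w] = e^{(\sigma \ln 2)^2/2} \approx 1.0619$), shared
across pathways within the trial (one transcript, one weight), and
rescored every (pathway, sample) pair. Because PAS is linear in the
weights, $E[\mathrm{APAS}] = E[w]\cdot\mathrm{PAS}$; the acceptance
suite checks the regression slope of mean APAS on PAS against this
moment, and the per-pathway SD bars are the robustness statement
itself. Trials use a counter-based seeding scheme (a fixed integer mix
of seed and trial index keys R's generator), so trial $t$ is
reproducible without generating trials $1..t-1$ and the caller's RNG
state is never disturbed.

# The synthetic-data generator

`synthesis_spec()` describes everything the test and acceptance runs
need: a catalog of 68 pathways (the scale of the analysis the method
was built for) of 10–30 members drawn from a shared pool of 500 genes
(sharing exercises the one-weight-per-gene rule), roles from
{−1, −0.5, 0.5, 1} with a 60% activator fraction; a cohort of 10 norm
and 3 case samples with per-gene baselines log-uniform over 10–1000
intensity units and multiplicative log-normal noise (`sdlog` 0.25,
microarray-like); and optional planted activation — a fold $f$ applied
to a pathway's activators and $1/f$ to its repressors in case samples,
which is exactly the displacement the score is designed to detect.

What the generator does *not* emulate: probe-level artifacts,
normalization residue, batch effects, correlated co-expression within
pathways, heavy-tailed outliers, or realistic pathway size/role
distributions from curated databases. Passing tests therefore
demonstrate the algebraic and statistical correctness of the method
under its own noise model, not performance on any real platform.

Toy kinetic cascades (`generate_cascade()`) are linear activation
chains with per-tier conservation; the one-step cascade has the closed
form $E^*(t) = \frac{k_f S E_{tot}}{k_f S + k_b}(1 - e^{-(k_f S +
k_b)t})$ used as the integration oracle, and multi-tier steady states
follow tier-by-tier fixed-point recursion. Synthetic effector
"experiments" sample the simulated trajectory and add Gaussian noise
clipped at zero, mirroring how previously validated models stand in
for measured Western-blot series.

# Numerical choices and degenerate inputs

- Integrator tolerances default to `rtol` 1e−8, `atol` 1e−10;
  trajectories are clipped of sub-`atol` negative undershoot and
  conservation is verified at every output time.
- `sensitivity_importance` refuses an effector that never rises above
  `atol` (log-sensitivity undefined) and a model that does not settle
  (no principled $T$ exists).
- `objective_hessian` rejects $\sigma_k = 0$ and non-finite objective
  values at displaced points rather than returning NaN entries.
- Zero-valued expression is rejected unless a pseudocount is supplied
  explicitly — silent flooring would fabricate fold-changes.
- `sigma = 0` in the perturbation config is accepted as the degenerate
  point-mass case (all weights 1), which also anchors the
  `n_trials = 1` convention `apas_sd = 0`.
- With the BTIF gate on, a pathway with no flagged genes scores exactly
  0 (`n_btif_pass = 0` implies `pas = 0`); with the gate off the score
  may be nonzero by construction.

Problem sizes in the shipped tests and acceptance script — 68-pathway
catalogs, 98-trial robustness runs, 1e5 weight draws, 20-seed recovery
sweeps, 100 random 5×5 eigenproblems — were chosen as the smallest
sizes at which the statistical checks have comfortable margins; the
whole suite runs in well under a minute.

# Known limitations

- Topology is collapsed to signed roles: feedback loops, crosstalk and
  saturation are invisible to PAS by design.
- No significance calibration is attached to PAS; it is an effect-size
  style score, and comparing it across catalogs with very different
  pathway sizes requires care (the sum grows with membership).
- The kinetic machinery is mass-action only — no Michaelis–Menten or
  Hill kinetics, no parameter fitting; it targets small hand-built
  cascades, not genome-scale models.
- Probe-to-gene collapsing, normalization and symbol mapping are
  documented preprocessing obligations of the caller, not silent
  behaviors of the loader.
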