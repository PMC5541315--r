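---
title: "Endogenous network dynamics, gene-age enrichment and age-filtered prognostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endogenous network dynamics, gene-age enrichment and age-filtered prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endonet)
```

# The model

An endogenous molecular network is a small, manually curated signed digraph
whose nodes are proteins or protein complexes from cancer-hallmark functional
modules and whose edges are activating or inhibiting regulations. `endonet`
quantifies such a network as a deterministic dynamical system: each node
carries an activity $x_k \in [0,1]$ obeying

$$\frac{dx_k}{dt} = f_k(x) - \frac{x_k}{\tau_k},$$

where $\tau_k$ is a degradation constant (simplified to 1 for every node, as
protein-specific degradation rates are not measurable at this scale) and
$f_k$ is the integrated production rate built from sigmoid Hill terms,

$$f_{\mathrm{act}}(x) = \frac{a x^n}{1 + a x^n}, \qquad
  f_{\mathrm{inh}}(x) = \frac{1}{1 + a x^n}.$$

Multiple regulators of the same sign are pooled inside a single Hill
denominator: with activator set $A_k$ and inhibitor set $I_k$,

$$f_k = \frac{\sum_{i \in A_k} a x_i^n}{1 + \sum_{i \in A_k} a x_i^n}
        \cdot \frac{1}{1 + \sum_{j \in I_k} a x_j^n}.$$

This is the natural generalisation of the worked four-regulator example (a
node activated by two factors and inhibited by two others), and it is the only
multi-regulator combination rule the source dynamics define; per-edge Hill
factors multiplied together would saturate much faster and are not used.

**Parameters.** The system behaves as a switch only for Hill coefficients
roughly between 3 and 10, with $a \approx 2^n$; within that regime the
attractor sets are substantially equivalent across $(n, a)$ choices (the test
suite checks $(3, 8)$ against $(4, 16)$ on the toy networks). The defaults are
$n = 3$, $a = 8$, enforced to $3 \le n \le 10$ by `dynamics_params()`.

**Unregulated inputs.** The multiplicative form degenerates gracefully: a node
with no inhibitors gets inhibition factor 1, and by default a node with no
activators gets activation factor 1 ("constitutive" mode), so a node with no
in-edges relaxes to $x = \tau$. The alternative `"zero"` mode sets the missing
activation factor to 0, forcing unactivated nodes to decay to 0. The choice
matters for source nodes of motifs such as the four-regulator apoptosis motif,
where the regulators themselves are network inputs.

# Attractor enumeration

Attractors are found by explicit-Euler fixed-point iteration
$v_{l+1} = v_l + \Delta t \cdot f(v_l)$ from `n_starts` uniform-random initial
vectors. A run converges when both $\max_k |v_{l+1,k} - v_{l,k}| < \varepsilon$
and $\max_k |f_k(v_l)| < \delta$, with $\delta = 10^{-4}$ (the documented
convergence tolerance of the original analyses) and $\varepsilon = 10^{-4}$
chosen symmetric and conservative since only $\delta$ is documented. The
iteration cap is 40,000 steps; $\Delta t = 0.01$ (not documented in the source
analyses) spans 400 time units at the cap, ample for networks of a dozen
nodes, and guarantees forward invariance: with $\tau = 1$,
$x_{l+1} = x_l(1 - \Delta t) + \Delta t\, f$ is a convex combination of
quantities in $[0, 1]$, so trajectories can never leave the unit box. Runs
that hit the cap without meeting both criteria (e.g. on limit cycles produced
by negative feedback loops) are reported as non-convergent, not forced into
attractors.

Converged states closer than `merge_tol = 0.01` in max-norm are merged into
one attractor whose basin count is the number of merged starts. The
representative state of a merged cluster is the member with the smallest
residual rather than the cluster mean: every reported attractor must satisfy
$\max|dx/dt| < \delta$ when re-evaluated, and a mean of distinct converged
states cannot guarantee that.

Steady states are bounded above by the Hill ceiling $a/(1+a) \approx 0.889$;
`attractor_table(..., rescale = TRUE)` optionally rescales by $(1+a)/a$ for
display on an exact 0–1 scale, since published attractor heatmaps span 0 to 1
and it is not documented whether those values are raw steady states or
rescaled. All computations use the raw states.

On the single self-activating node the fixed points are the roots of
$x(8x^3 - 8x^2 + 1) = 0$: stable at $0$ and $(1+\sqrt 5)/4 \approx 0.8090$,
unstable at $1/2$. The test suite checks the enumeration against an
independent grid-plus-bisection oracle on such 1–2 node systems.

# Cell-status classification

Attractors map to cell statuses in two ways.

**Module rules.** Each annotated node promotes or inhibits its functional
module. A module is active when its nodes behave as under full function
(promoting nodes above an activity threshold, inhibiting nodes at or below
it); each node casts one vote and a strict majority wins, with ties resolved
to inactive. The threshold defaults to 0.5 of the activity range — no high/low
cutoff is documented, and 0.5 is the natural midpoint for switch-like states
that settle near the extremes. The status rules are applied in fixed
precedence:

1. proliferation (cancer-like): cell cycle, glycolysis, immune response and
   angiogenesis active; apoptosis and cell adhesion inactive;
2. cell-cycle arrest (normal-like): cell adhesion active, everything else
   inactive;
3. apoptosis: apoptosis active, everything else inactive;
4. stress response: immune response active;
5. otherwise unclassified.

The stress-response definition overlaps the proliferation pattern, so the
precedence is what makes the map single-valued; the test suite evaluates all
$2^6$ module assignments and checks totality and the three exact rules.
Modules absent from a partial map are skipped in rule evaluation, which means
rules can fire vacuously on very sparse maps — callers classifying attractors
of subnetworks missing whole modules (e.g. an immune-less subnetwork) should
prefer reference matching.

**Reference matching.** Published attractors of the complete networks serve as
references (a TSV input, not hard-coded, since they come from supplementary
tables). An attractor inherits the label of the nearest reference by mean
absolute per-node difference over shared nodes, if within `max_dist = 0.3`;
ties and larger distances give unclassified. The original comparison was
visual; 0.3 mean absolute difference is this package's numeric surrogate
(configurable) — on a 0–1 activity scale it tolerates disagreement on a
minority of nodes but rejects pattern-level mismatches.

**Accuracy.** Simulated cancer-vs-normal changes use a band of
`tol = 0.1` around zero difference for "unchanged" (the unchanged band for
simulated values is not documented; 0.1 separates genuine switch transitions,
which move activities by ~0.5 or more, from numerical wobble). Accuracy is
the fraction of annotated nodes whose simulated direction matches the
annotation, computed over nodes present in the (sub)network only;
unchanged/unchanged agreements count by default (`count_unchanged = FALSE`
drops them from both numerator and denominator).

# Gene-age enrichment

Human genes fall into eight consensus evolutionary strata: cellular organisms,
euk_archaea, euk+bac (horizontal transfer from bacteria), eukaryota,
opisthokonta, eumetazoa, vertebrata, mammalia. The euk+bac stratum has no
position on the species tree; for the youngest-component rule (a protein
complex inherits the age of its youngest component) it is ordered between
euk_archaea and eukaryota, as its genes are ancient in origin. Driver-set
enrichment per stratum uses the hypergeometric upper tail with the age-map
universe as background, corrected by Benjamini–Hochberg across the eight
strata of one driver set (the correction family is per driver dataset, the
one unambiguous reading of a per-dataset results table). Significance stars
(`*` < 0.05, `**` < 0.01, `***` < 0.001) are applied to the adjusted
q-values; whether published stars reflect raw or adjusted values is ambiguous,
and adjusted is the conservative choice.

# Prognostic signatures

Given a training cohort, `cox_screen()` fits one univariate Cox
proportional-hazards model per gene and keeps genes with Wald $p < 0.001$
(strict) as candidates. `select_signature()` then keeps the candidates
originating from eukaryota, opisthokonta or eumetazoa as the gene-age-based
signature, and the same number of most-significant candidates (any stratum)
as the control signature. Each signature gene carries the sign of its training
coefficient, and the per-patient risk score is the unweighted sum of
expression over positive-sign genes minus the sum over negative-sign genes.

Decisions the source procedure leaves open, surfaced as arguments:

- **Standardisation.** Expression is z-scored per gene within each dataset
  before screening and scoring (`standardize = TRUE`). The unweighted score is
  scale-sensitive and multi-platform microarray data are not otherwise
  comparable; raw mode is available.
- **Cutpoint.** Patients split at the within-dataset median risk score, ties
  to the low group. The median is the only cutpoint that guarantees balanced
  groups without a tuning step.
- **Hazard ratio.** Estimated from a Cox fit on the binary high/low indicator
  with Efron tie handling; the log-rank test supplies the separation p-value.

# Synthetic data

The generators exist so that every stage has inputs with known truth:

- `make_toy_network()`: the self-activator and toggle (closed-form or
  oracle-checkable fixed points), the four-regulator apoptosis motif, an
  edgeless network, and seed-deterministic random signed digraphs.
- `make_annotations()`: per node, the annotation equals the simulated
  direction with probability `p_agree`, else a different label uniformly —
  observed accuracy estimates `p_agree`.
- `make_age_universe()`: strata sampled by weight; drivers drawn with a
  `fold`-times weight on a planted stratum (`fold = 1` is an exact null).
- `make_survival_cohorts()`: standard-normal expression; exponential event
  times with hazard $\lambda_0 \exp(\sum_g \beta_g x_g)$ over planted signal
  genes whose strata lie in the allowed set; independent exponential censoring
  with its rate solved numerically so the expected censored fraction matches
  the request. Optional decoy genes model passenger associations: they carry a
  hazard effect in the training cohort only, and their strata lie outside the
  allowed set. This is the mechanism by which purely statistical selection
  fails on independent data — a decoy passes the screen as convincingly as a
  true signal gene, but its association does not reproduce.

What the generators do **not** emulate: microarray platform and batch effects,
probe-to-gene mapping noise, correlated expression blocks, non-proportional
hazards, and informative censoring. Passing tests on these fixtures
demonstrate that the machinery is correct under the stated model, not that the
biological conclusions transfer to any particular cohort.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: 1000 random starts for the
bistable toy (closed-form check to $10^{-3}$), 100 random 10-node networks at
15 starts each for the invariance bounds, exact enumeration of every
hypergeometric configuration with a universe up to 12 genes, 1000 replicates
of a 1000-gene/200-driver null for the false-flag rate, and 50 replicates each
for hazard-ratio recovery ($n = 400$) and for the age-based vs control
signature comparison ($n = 250$ train/test, 120 genes, 8 signal + 8 decoy).
These sizes give stable Monte-Carlo estimates for the properties tested while
keeping a full run in the order of a minute.

Degenerate inputs are rejected early: activities outside $[0,1]$, dangling
edges, duplicate (source, target, sign) triples, inconsistent hypergeometric
counts, non-positive follow-up times, screens with fewer than two events, and
empty risk groups all raise informative errors; constant-expression genes and
non-convergent Cox fits are skipped with warnings, and candidates with an
exactly zero coefficient are excluded from signatures since their sign is
undefined.

# Known limitations

- Dynamics are deterministic; stochastic (noise-driven) exploration of the
  attractor landscape, basin depth and bifurcation structure are out of scope.
- Oscillatory (limit-cycle) behaviour is detected only as non-convergence.
- The module-rule classifier assumes annotated promoting/inhibiting roles;
  without them every node defaults to promoting its module.
- Network curation itself — selecting nodes and wiring from the literature —
  is an input to this package, not a feature of it.
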