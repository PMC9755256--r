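---
title: "Cultural repertoire patterns without copying: the model behind exclusim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cultural repertoire patterns without copying: the model behind exclusim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exclusim)
```

## The scientific question

Field studies of ape culture typically rely on the *method of exclusion*
(the distributional approach): a behaviour observed at some sites but not
at others, where the difference is unlikely to be genetic or ecological, is
classified as cultural. A recurring — and logically unwarranted — further
step is to read such distributions as evidence for *copying*: social
learning that transmits the specifics of behavioural forms. `exclusim`
implements an individual-based model in which copying is impossible by
construction: agents can only innovate behaviours from a fixed latent
repertoire, and social influence merely biases *which* latent behaviour an
individual is likely to re-innovate (socially mediated re-innovation, or
"triggering"). If the census of such a world still shows the classic
cultural patterns, those patterns cannot be used to infer copying.

## The world

Six populations sit at fixed planar positions approximating the
west-to-east arrangement of six well-known ape field sites, with fixed
sizes 20, 42, 49, 76, 50 and 95 (`site_map()`). Coordinates are arbitrary
planar units; only relative distances matter. The latent repertoire
(`behaviour_space()`) holds 64 behaviours: 32 social, in four
sub-categories ("play", "display", "groom", "courtship") of eight
behaviours each, and 32 food-related, in ten sub-categories of sizes
8, 5, 4, 4, 3, 2, 2, 2, 1, 1, alternately providing nutrient Y or Z (five
sub-categories each). The food structure is a documented default — only the
category totals and the two-nutrient scheme are fixed by the design — and
is fully configurable through `behaviour_space(food_structure = ...)` or a
YAML file (`read_world_config()`).

### Genetic propensity and ecological availability

Each behaviour has, at every site, a genetic propensity $p_g \in [0, 1]$,
and each food behaviour additionally an ecological availability
$p_e \in [0, 1]$ (social behaviours have $p_e = 1$). Independently per
behaviour, with probability $\alpha_g$ (resp. $\alpha_e$) the values differ
across sites: a point is drawn uniformly from the sites' bounding box and
the site distances $d_i$ to it are rescaled linearly,

$$p_i = \frac{d_{\max} - d_i}{d_{\max} - d_{\min}},$$

so the nearest site gets exactly 1 and the farthest exactly 0 — at that
site the behaviour can never be expressed. Otherwise a single uniform draw
is shared by all six sites: $\alpha = 0$ means no *differences* between
populations, not no genetic or ecological influence. Two choices here were
genuinely open. The random point comes from the bounding box of the sites,
which keeps every site reachable as "nearest". And the rescaling is the
min–max map: it is the affine transformation onto $[0, 1]$ that attains
both endpoints exactly, which the zero-availability census level (below)
and the gradient semantics require; the degenerate all-equidistant point
(measure zero) returns 0.5 everywhere.

## Demography

A time step is one month. Ages are initialised uniformly over
$[0, 300)$ months (0–25 years); from age 300 months on, each agent dies
with probability 0.01 per month, and exceeding 720 months (60 years) is
lethal with certainty. The death check runs after the monthly age
increment, and each dead agent is replaced in place by a newborn with an
empty repertoire, so population sizes are exactly constant. Initial
repertoires are empty even for initialised adults: with the default
$t_{\max} = 6000$ (500 years) the census is taken long past the transient,
so the initial condition is irrelevant at census time.

## Innovation dynamics

An agent's *state* summarises how well its repertoire fulfils its
functions:

* social state: the fraction of the four social sub-categories with at
  least one expressed behaviour (0, 0.25, ..., 1);
* food state: $(F - |F_Y - F_Z|)/C$, where $F$ of the $C$ food
  sub-categories are fulfilled, $F_Y$ providing nutrient Y and $F_Z$
  nutrient Z — coverage rewarded, nutrient imbalance penalised.

Each month, for each category, an agent attempts an acquisition with
probability drawn from $\mathcal{N}(1 - \text{state}, \sigma)$ clamped to
$[0, 1]$: the less fulfilled the agent, the more likely it innovates. The
spread $\sigma$ (default 0.05) keeps the relation between state and
innovation probability stochastic rather than deterministic.

Which behaviour is attempted depends on the parameter $S$. With
probability $S$ the acquisition is *socially mediated*: the behaviour is
drawn with weights given by the agent's noisy perception of the expresser
counts in its own population, $w_j = \max(0,\,\mathcal{N}(c_j,
\texttt{peer\_noise}))$, computed from a snapshot of counts taken at the
start of the step so that within-step order cannot bias the weighting.
Otherwise the draw is uniform over the 32 behaviours of the category.
Nothing about the *form* of a behaviour is ever transmitted — frequency
only catalyses individual re-innovation.

The perceptual noise (default standard deviation 1, i.e. on the order of
one observed individual) is a deliberate and consequential design choice.
With exact proportional weights, a behaviour whose expresser count reaches
zero can never be selected again under $S = 1$; whole repertoires then
freeze on the behaviours seeded in the first months, the trait distribution
never equilibrates, and the cultural count is driven by founder drift
rather than by the ecological and genetic variability parameters. With
perceptual noise, rare and unexpressed behaviours retain a small selection
probability, repertoires converge to the set favoured by the local
propensities, and the cultural count responds to $\alpha_e$ and $\alpha_g$
— which is the regime the model is meant to explore. Setting
`peer_noise = 0` recovers the exact proportional semantics (with a uniform
fallback while a whole category is unexpressed), and the unit tests
exercise both regimes.

The drawn behaviour is then gated: it enters the repertoire with
probability $p_g$ (social) or $p_g \cdot p_e$ (food) at the agent's site —
the two gates are independent conditions, so their product is the natural
combination. The two categories are processed in random order and the
first successful addition of a *new* behaviour ends the agent's turn, so
at most one behaviour per agent per month; drawing an already-owned
behaviour or failing a gate consumes the attempt without granting a retry.
Repertoires never shrink during an agent's life.

Populations are fully independent — there is no migration and no cross-site
observation. Each site runs on its own RNG stream seeded from the master
seed, which the test suite exploits: perturbing one site leaves every other
site's trajectory bit-identical.

### Engines

The site loop exists twice: a reference R implementation whose steps are
the exported `demographic_step()` and `innovation_step()` (and which
replays them draw for draw), and a compiled C++ engine (the default) that
implements the same model substantially faster with per-agent rather than
per-vector RNG consumption. The engines are cross-validated in the test
suite: the R engine against the step functions exactly, the two engines
against each other statistically.

## The census: method of exclusion

After $t_{\max}$ steps each behaviour is classified at each site
(`census_table()`):

* **customary** — expressed by strictly more than 50% of the members of at
  least one non-empty age class (default classes: 0–16, 16–40, 40–60
  years; boundaries are configurable, and the headline results use
  population-level criteria insensitive to this choice);
* **habitual** — at least two expressers in the population;
* **present** — exactly one;
* **ecological explanation** — unexpressed with local $p_e = 0$ (only then
  is the absence attributable to ecology alone);
* **absent** — unexpressed otherwise.

The observational "unknown" category of field studies cannot occur: the
simulation output is completely known. Patterns are then assigned per
behaviour (`assign_patterns()`), evaluated in precedence order: **A**
(absent at no site), **B** (not reaching habitual frequencies at any
site), **C** (every absence ecologically explained), else **D** — habitual
or customary somewhere yet absent elsewhere without ecological
explanation, the "cultural" pattern. The precedence order makes the four
verbally overlapping definitions exhaustive and mutually exclusive, which
the tests verify against a brute-force truth-table oracle on all $5^6$
level vectors. `locally_restricted()` additionally reports behaviours
expressed at exactly one site, the focus of the method of local
restriction.

## Parameters at a glance

| parameter | meaning | default |
|---|---|---|
| `S` | probability an acquisition is socially mediated | 1 |
| `alpha_g` | probability a behaviour's genetic propensity differs across sites | 0 |
| `alpha_e` | probability a food behaviour's ecological availability differs across sites | 0 |
| `t_max` | months simulated | 6000 |
| `sigma` | sd of the innovation-probability draw | 0.05 |
| `peer_noise` | sd of perceived expresser counts | 1 |
| `death_onset` | first at-risk month | 300 |
| `death_hazard` | monthly death probability from onset | 0.01 |
| `max_age` | hard age cap (months) | 720 |
| `init_max_age` | exclusive bound on initial ages (months) | 300 |
| `age_breaks` | census age-class cut points (months) | 192, 480 |

## Experiments

`sweep_grid()` runs the factorial experiment over ecological and genetic
variability (defaults: $\alpha_e \in \{0.5, 0.625, 0.75, 0.875, 1\}$,
$\alpha_g \in \{0, 0.1, ..., 0.5\}$, 20 replicates — 600 runs), recording
the cultural count and the number of locally restricted behaviours per
run, with every row reconstructible from its recorded seed.
`correlation_experiment()` pools, over replicate runs, one (population
size, expressed cultural behaviours) pair per site and reports their
Spearman rank correlation; the symbol $\rho$ with tied integer counts
points to the rank version, and Pearson plus a permutation p-value are
available for sensitivity. `s_effect_experiment()` sweeps $S$ at fixed
variability. A run near the benchmark condition ($S = 1$, $\alpha_e =
0.8$, $\alpha_g = 0.2$) yields a few dozen cultural behaviours; lowering
$S$ lowers the count, and some cultural traits persist even at
$\alpha_e = \alpha_g = 0$.

```{r example, eval = FALSE}
sim <- run_simulation(sim_params(S = 1, alpha_e = 0.8, alpha_g = 0.2, seed = 42))
glance(sim)
autoplot(sim, cultural_only = TRUE)
```

## What the simulated world does and does not emulate

The generator reproduces the *structure* of the field setting — six
censused communities of realistic sizes, an age-structured demography, a
bounded latent repertoire with functional sub-categories, spatially
autocorrelated genetic and ecological variation — under complete knowledge
of every propensity and every repertoire, which no field study has. It
deliberately omits sex structure, fertility schedules, migration,
cumulative modification of forms, and any transmission of behavioural
specifics. Passing censuses here therefore show what distributional
patterns do *not* imply about mechanism; they say nothing about how often
copying actually occurs in real apes.

## Numerical and testing choices

Tolerances in the statistical tests are classical significance bands
(e.g. chi-square goodness of fit at $\alpha = 0.01$ for the geometric
survival law); exact assertions (propensity gates, pattern logic, state
formulas, determinism under a seed) are tested without tolerance. Unit
tests run the dynamics on shortened horizons (60–800 months), while the
headline checks use the full $t_{\max} = 6000$ at 20 replicates per
condition and a 30-run scaled variant of the 100-run correlation
experiment — sizes chosen so the whole suite completes comfortably on a
single core while keeping the Monte Carlo bands tight enough to be
meaningful.

## Known limitations

* The food sub-category structure, site coordinates and age-class
  boundaries are documented defaults, not field-calibrated quantities;
  qualitative conclusions should be (and in the tests, are) robust to
  perturbing them.
* The cultural count at a given parameter combination depends on
  implementation details of the innovation rule (notably `peer_noise` and
  `sigma`); comparisons across parameter settings are more meaningful than
  absolute counts.
* With `peer_noise = 0` and `S = 1` the dynamics are non-ergodic by
  design; results under that setting describe founder-dominated drift, not
  the equilibrium regime.
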