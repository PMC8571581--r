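---
title: "Models and methods: random versus coordinated division of labor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: random versus coordinated division of labor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labordiv)
```

`labordiv` implements two linked models of reproductive division of labor in
social microbes: a tractable evolutionary game comparing *fully random* with
*fully coordinated* specialization, and an individual-based simulation in
which the degree of coordination is itself an evolving, continuous trait.
This vignette is the package's own account of the science: the assumptions,
the parameters, the numerical conventions, and what the built-in experiments
do and do not demonstrate.

## The life cycle and the game

A social group is founded by `l` cells. Each founder grows a clonal lineage
of `m` cells, so the mature group has `n = lm` cells and the whole-group
relatedness — the chance that two members drawn with replacement share a
founder — is `1/l`. At maturity each cell becomes either a sterile helper or
a pure reproductive. Helpers produce a public good shared by the whole group:
a reproductive's fecundity is `1 − ε + εP`, where `P` is the group's realized
helper proportion and `ε ∈ [0, 1]` (the *essentiality of cooperation*)
weights how much fecundity depends on help. Generations do not overlap;
offspring disperse globally and compete to found the next round of groups, so
there is no between-group population structure beyond the founding step.

Each founder carries a heritable *target* helper proportion `q`. The
mechanism that turns the target into phenotypes is what the two models vary:

* **Random specialization**: every cell independently becomes a helper with
  probability `q`. The realized lineage proportion fluctuates binomially
  around the target.
* **Coordinated specialization**: the lineage signals internally and realizes
  exactly a proportion `q` of helpers, paying a relative fecundity cost `θ`.

Expected founder fitness, with the rest of the group at resident target `Q`:

$$w_{FR}(q,Q) = (1-q)\Bigl(1-\varepsilon+\tfrac{\varepsilon q}{l}
  +\tfrac{\varepsilon(l-1)Q}{l}-\tfrac{\varepsilon q}{lm}\Bigr),\qquad
w_{FC}(q,Q) = (1-\theta)(1-q)\Bigl(1-\varepsilon+\tfrac{\varepsilon q}{l}
  +\tfrac{\varepsilon(l-1)Q}{l}\Bigr).$$

The `εq/(lm)` term is the expected opportunity cost of binomial noise: in a
finite lineage the helper fraction covaries with the reproductive fraction.
`fitness_random()` is validated in the test suite against
`fitness_random_exact()`, an independent oracle that enumerates the focal
lineage's helper count over `Binomial(m, q)` (other lineages enter at their
expectation, which is exact because fitness is linear in their helper
counts); agreement is required to `1e-12` across the full parameter grid.

Both expressions are concave quadratics in `q`, so the best response is a
clipped vertex and the symmetric equilibrium is the unique fixed point of the
best-response map. We solve it two ways and require agreement to `1e-8`:

* `ess_numeric()`: root-finding (`stats::uniroot`, tolerance `1e-12`) on
  `best_response(q) − q`. Plain fixed-point iteration is *not* used: the
  best-response map has slope `−(l−1)m/(2(m−1))` for the random mechanism and
  diverges when `m(l−1) > 2(m−1)`.
* the closed forms: `q*_FR = (m−1−lm(1−ε)/ε)/(lm+m−2)` above the threshold
  `ε = lm/(lm+m−1)`, else 0; `q*_FC = (1−l(1−ε)/ε)/(l+1)` above `l/(l+1)`,
  else 0. At the threshold the interior formula is exactly 0, so the boundary
  is assigned to the no-helper branch by continuity. The degenerate case
  `l = m = 1` (a lone cell) is caught by the threshold, which equals 1 when
  `m = 1`.

`q*_FC` is independent of `m` and `θ`, never smaller than `q*_FR`, and both
equilibria rise with essentiality and fall with the number of lineages.

## Invasion analysis and its boundary convention

With the resident at its ESS, whether a rare mutant using the *other*
mechanism (same target `q`) can invade reduces to the sign of
`D(q) = θlm − ε(θlm(1−q) + q)`, because
`w_{FR}(q,q) − w_{FC}(q,q) = (1−q)D(q)/(lm)`. `labordiv` evaluates the
closed inequality and the direct fitness comparison on every call and errors
if they disagree (a dual-route consistency guard).

Two conventions needed a decision:

* **Residents without helpers.** If a mechanism's ESS is 0 it supports no
  division of labor, so it is reported as uninvadable and uninvading rather
  than plugging `q* = 0` into the invasion conditions (which presuppose a
  resident that actually divides labor). When both ESS are 0 the region is
  `no_division_of_labor`.
* **Exact fitness ties.** On the curve `D(q*) = 0` — for instance the product
  `θlm = 1` evaluated at `ε = 1` — the two mechanisms have *identical*
  fitness. We resolve ties toward random specialization: a tied random mutant
  counts as able to invade, a tied coordinated mutant does not (tolerance
  `1e-9` on `D`). The rationale is mechanistic: at exact neutrality selection
  cannot maintain the costly coordination machinery, and the simpler default
  of independent stochastic switching prevails. With this convention the
  statement "`θlm ≥ 1` makes random specialization universally dominant"
  holds with the boundary included, which is exactly what the sweep in
  `scripts/acceptance.R` measures. Ties occur only on a measure-zero boundary,
  so no interior conclusion depends on the convention.

`classify_region()` supports two mutant models: `resident_q` (the mutant
inherits the resident's target, isolating the mechanism difference; mutual
invasion is provably impossible here because `D` is evaluated at two points
ordered the same way as its sign changes) and `mutant_optimal_q` (the mutant
plays its best response to the resident; both directions can succeed at once,
opening a mutual-invasion region that widens as relatedness falls).
`phase_grid()` maps either mode over an essentiality-by-group-size grid;
cells whose `n` is not divisible by `l` are kept but flagged invalid, never
silently rounded.

## The individual-based simulation

The simulator relaxes the all-or-nothing mechanism: each founder also carries
a coordination level `s ∈ [0, 1]`, and both traits coevolve.

* **Network.** Each cell independently links to every other group member
  with probability equal to its *own* `s` (the receiver pays to observe; the
  sender is passive). Links are one-way and there are no self-links. With
  `coordination_scope = "own_lineage"` candidates are restricted to
  clone-mates.
* **Resolution.** All cells start as intended reproductives. Cells are then
  visited exactly once, in a uniformly random order (one full pass by
  default; `resolution_passes` exposes extra sweeps for robustness checks —
  one pass is the simplest reading of sequential sampling and already
  produces the intended behavior). A visited cell with at least one in-link
  compares the current intended-helper fraction among its observed senders
  with its target: below target it plans to help, at or above target
  (including an exact tie) it plans to reproduce. The tie-break keeps `q = 0`
  populations helper-free under full coordination. A cell with no in-links —
  always the case at `s = 0` — falls back to an independent Bernoulli(`q`)
  draw, the continuous limit of the random mechanism.
* **Fitness.** `w = (1 − cost(s))(1 − h)(1 − ε + εP)` with `P` the
  whole-group realized helper fraction (not lineage-local: the public good is
  shared group-wide). The default cost is `θ(1 − e^{−5s})`: concave
  (decelerating), so the machinery is expensive to establish and cheap to
  extend, and it approximately equals the analytical cost `θ` at `s = 1`.
  Linear and accelerating alternatives are anchored to the same endpoints
  `cost(0) = 0`, `cost(1) = θ(1 − e^{−5})`, so the three shapes differ only
  in curvature.
* **Selection and mutation.** The next generation's founders are a
  multinomial sample over *all* cells with weights proportional to fecundity
  (global competition makes parents' group membership irrelevant). Each trait
  mutates independently with probability `p_mut = 0.01`; a mutation adds a
  Normal(0, 0.1) deviation and clamps to `[0, 1]`. The control scenario
  `s_locked_at_zero = TRUE` holds `s = 0` so only the target evolves.

### Parameters and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `l`, `m` | founding lineages; cells per lineage | — | set by the question; relatedness is `1/l` |
| `epsilon` | essentiality of cooperation | — | swept in most experiments |
| `theta` | coordination cost coefficient | 0.025 | the reference cost used in the phase diagrams; free to vary |
| `target_pop_size` | cells per generation | 10^4 | full-scale study condition; realized size is `lm⌊pop/(lm)⌋` |
| `generations` | run length | 10^5 | long enough for trait convergence at full scale |
| `p_mut`, `mut_sd` | mutation rate and step SD | 0.01, 0.1 | study conditions |
| `replicates` | independent runs | 10 | study conditions |
| `record_fraction` | trailing summary window | 0.1 | averages the quasi-stationary tail |
| `init_q`, `init_s` | initial traits | 0.5, 0 | coordination must evolve de novo |

The `"desk"` preset (population 2000, 2×10^4 generations, 5 replicates) is
the package's own reduced scale for routine work, the test suite and the
acceptance script; the `"paper"` preset keeps the full-scale settings. For
relatedness comparisons the package uses group size `n = 24` when contrasting
`l = 1` with `l = 8`, the nearest size divisible by both (a 20-cell group
cannot be split into 8 equal lineages), so both conditions share an identical
group size. Replicate seeds are derived from the master seed by a fixed
counter scheme, so replicate `i` reproduces identically regardless of how many
replicates are requested; the compiled engine draws from R's RNG and is
bit-reproducible from `set.seed()`.

### What the simulator emulates — and what it does not

The generator *is* the study system: haystack groups, public-good sharing,
global competition, and noisy-versus-informed developmental switching. It
deliberately omits features of real microbial groups: space (all group
members are equally observable), population-size feedbacks (fixed group and
population sizes), signal content (links carry a binary intended phenotype,
never deception), within-generation plasticity after resolution, and
non-reproductive forms of labor division. Passing tests therefore show that
the implementation realizes this idealized model faithfully — the
simulator–theory bridge checks that the `s = 0` control evolves to `q*_FR`,
and the mechanics tests check that `s = 1` clonal groups realize `|P − q| ≤
1/n` while `s = 0` lineages produce Binomial(`m`, `q`) helper counts — not
that any particular real species behaves this way.

## Numerical conventions, in one place

* Domain checks reject proportions outside `[0, 1]`; group sizes are
  integers, enforced at construction.
* ESS root-finding tolerance `1e-12`; closed-vs-numeric agreement asserted at
  `1e-8`; oracle agreement for the random-fitness expression at `1e-12`.
* Invasion tie tolerance `1e-9` on the margin `D`, ties to random (above).
* Resolution tie (observed fraction equals target) → reproductive.
* Zero in-links with `s > 0` → Bernoulli(`q`) fallback.
* Zero total fecundity (every cell a helper) is an error advising a
  parameter check, not a silent restart.
* `generations = 0` returns the initial founder means with `P` undefined.

## Known limitations

* The analytical layer compares only the two extreme mechanisms; intermediate
  coordination exists solely in the simulator.
* Desk-scale runs are short: slow-evolving quantities (notably `s` under weak
  selection, since `θ` is small) are farther from their long-run values than
  helper proportions are, and across-run variability of `s` is high. The
  package reports variance ratios (`variability_test()`) rather than
  asserting them at reduced scale.
* The compiled and tidy engines consume randomness in different orders, so
  they agree statistically, not draw-for-draw.
* Whether helpers would pay the coordination cost is unobservable under this
  fitness function (helper fecundity is 0); extensions with partially sterile
  helpers would need to decide it.
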