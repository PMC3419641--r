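---
title: "Stochastic discrete dynamical systems: model, kernel and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic discrete dynamical systems: model, kernel and simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdds)
```

## The model class

A *stochastic discrete dynamical system* (SDDS) describes a regulatory
network of $n$ components $x_1, \dots, x_n$, each taking values in a finite
ordered level set $X_i = \{0, 1, \dots, k_i - 1\}$ (levels are discretised
concentrations; $k_i = 2$ gives the Boolean case).  The system is a
collection of triplets

$$F = \{(f_i,\; p_i^{\uparrow},\; p_i^{\downarrow})\}_{i=1}^{n},$$

where $f_i : X \to X_i$ is the logical update rule of component $i$ over the
product space $X = X_1 \times \cdots \times X_n$, $p_i^{\uparrow} \in [0,1]$
is its **activation propensity** and $p_i^{\downarrow} \in [0,1]$ its
**degradation propensity**.  The modelling assumption is that intrinsic
noise acts at the level of the biological function: even when the levels of
the regulators call for activation (or decay) of a component, the underlying
biochemical process may fail to occur in that time step.  Activation and
degradation are distinct biochemical processes, which is why each direction
carries its own probability — exactly as activation and decay rates are
separate parameters in kinetic models.

At each discrete time step every coordinate is updated independently:

$$
\pi_{i,x}(x_i \to f_i(x)) =
\begin{cases}
p_i^{\uparrow} & x_i < f_i(x)\\
p_i^{\downarrow} & x_i > f_i(x)\\
1 & x_i = f_i(x),
\end{cases}
\qquad
\pi_{i,x}(x_i \to x_i) =
\begin{cases}
1 - p_i^{\uparrow} & x_i < f_i(x)\\
1 - p_i^{\downarrow} & x_i > f_i(x)\\
1 & x_i = f_i(x),
\end{cases}
$$

and $\pi_{i,x}(x_i \to y_i) = 0$ for any other level $y_i$.  The one-step
transition probability between states is the product
$w_{x \to y} = \prod_{i=1}^n \pi_{i,x}(x_i \to y_i)$, which defines a
discrete-time Markov chain on $X$; the package calls its weighted digraph
(zero-weight edges omitted) the *state graph*.  Two limits anchor the
semantics: with all propensities equal to 1 the chain degenerates to the
synchronous deterministic system $G = (f_1, \dots, f_n)$, and with all
propensities 0 every state is frozen.  For any propensities the absorbing
states of the chain are exactly the fixed points of $G$ — the package treats
this identity as a theorem and tests it on every bundled model and on
hundreds of randomly generated ones.

This construction is a special case of a probabilistic Boolean network in
which each node chooses between its rule and the identity function, with the
choice probability depending on the direction of the called move.

## Representation and the rule language

Truth tables are the canonical representation.  A model stores one fully
expanded column per variable over the whole state space, enumerated in
lexicographic order with variable 1 most significant; every analysis
(kernel, graph, fixed points, simulation) reads only these tables, so a
model parsed from an expression file and one parsed from a table file with
the same semantics are indistinguishable.  Expressions
(`min`, `max`, `not`, integer constants, arithmetic `+ - *`, comparisons)
are a readability layer expanded once at construction time.  The expanded
form is practical because the package targets fully enumerable spaces; the
constructor refuses spaces beyond $2^{20}$ states, and symbolic or
decision-diagram representations are deliberately out of scope.

States are written as digit strings (`"0011"`, leftmost digit = variable 1)
whenever every cardinality is at most 10, and as tuples (`"(0,12,1)"`)
otherwise.  Model files come in a JSON dialect (variables, rules, optional
tables, propensities) and a truth-table TSV; both round-trip exactly,
with propensities serialised at full double precision.

## Numerical choices

* **Exact zero pruning.**  Candidate successors are generated per changed
  coordinate from the pair (stay, move) with probabilities
  $(1-p, p)$; entries with probability exactly 0 are dropped *before* any
  multiplication.  "Omit edges of weight zero" therefore holds bit-exactly
  rather than through an epsilon threshold, and a sampler can never step
  outside the support of the exact kernel.
* **Deterministic factor order.**  Both `transition_weight()` and
  `transition_distribution()` multiply coordinate factors in ascending
  coordinate order, rounding after each multiplication, so the two routes
  agree bit for bit (R's `prod()` is avoided because its extended-precision
  accumulation rounds differently).  Probabilities are plain doubles; at the
  target model sizes ($n \le 20$ for enumerated work) no log-space
  representation is needed.
* **Normalisation.**  Out-weights of every state sum to 1 as an algebraic
  identity; tests assert the residual is below $10^{-12}$, and exact
  distribution propagation conserves mass to $10^{-9}$ over 60 steps.
* **Attractors.**  The package defines attractors as the terminal strongly
  connected components of the positive-weight digraph — the recurrent
  classes of the chain.  This is the natural formalisation of the informal
  notion of a steady state or terminal cycle; components are computed with
  igraph and closedness (no positive weight leaving a terminal component) is
  asserted in the tests.
* **Asynchronous schemes.**  `deterministic_trajectory()` implements the
  synchronous scheme and a fixed-order asynchronous scheme (one designated
  permutation per call, each update seeing the partially updated state);
  which asynchronous discipline is meant by the classical inclusion claim is
  ambiguous, so the tests cover both the fixed-order variant and
  single-coordinate steps.  Every synchronous step has positive chain weight
  whenever all propensities are in $(0, 1]$.  For *asynchronous*
  single-variable steps the inclusion holds on the open interval $(0, 1)$:
  at a boundary propensity of exactly 1 a coordinate that wants to move
  cannot stay, so a step that freezes it has weight 0.  The property tests
  therefore draw propensities from the interior for the asynchronous
  variant.

## Sampling and reproducibility

`simulate_cell()` draws each coordinate independently per step (ascending
index order, which is irrelevant to the distribution but fixed for
reproducibility), so the induced successor law is exactly the kernel — this
is asserted by comparing 100,000-cell empirical state frequencies against
`exact_distribution()` at several horizons, within four binomial standard
errors per state.

`simulate_population()` derives the seed of cell $i$ from the master seed by
an affine counter scheme modulo $2^{31}-1$ and reseeds R's generator per
cell.  Populations are therefore bit-reproducible from
`(model, init, n_cells, steps, seed)`, independent of execution order, and
the caller's RNG state is never disturbed.  Summaries report the
across-cell mean and (population) standard deviation of every variable at
every step, plus full per-state occupancy counts for enumerable spaces;
with a single cell the summary degenerates to the trajectory itself with
zero dispersion.

Outcome classification labels each cell by the labelled attractor containing
its final state, with everything else counted as unresolved.  Classification
by the final state (rather than by the set of visited states) was chosen
because trajectories that have entered a terminal component can never leave
it, so at horizons where nearly all mass is absorbed the two conventions
coincide; the unresolved count makes the residual explicit.

## The bundled models

**Worked two-variable example** (`example_2_1_1`): $f_1 = x_2$,
$f_2 = x_1 \wedge \neg x_2$ with propensities $(.1, .2)$ and $(.5, .9)$.
Its state graph has 4 nodes and 11 positive-weight edges; `00` is the unique
fixed point.  All eleven one-step probabilities are asserted bit-exactly as
products of the propensity factors.

**p53–Mdm2 damage response** (`p53_mdm2`): P (p53, levels 0–2), Mc
(cytoplasmic Mdm2), Mn (nuclear Mdm2), dam (DNA damage), in that order.  The
logic follows the published four-variable analysis of this network: nuclear
Mdm2 shuts p53 off; p53 drives cytoplasmic Mdm2, which drives nuclear
import; basal nuclear entry requires both absence of p53 and absence of
damage; and the damage rule has no activator, so repair is a pure decay
governed by $p_{dam}^{\downarrow}$ (default .05, with activation propensity
1 as an inert placeholder).  Because the published description of the rules
is qualitative, the transcription is guarded by structural facts re-checked
at every `load_fixture()`: `0010` is the unique fixed point, and holding
damage on, the remaining coordinates traverse a deterministic 6-cycle
(`0001 → 2001 → 2101 → 2111 → 0111 → 0011`), i.e. p53 oscillates for as long
as damage persists.  At the population level the 100-cell, 60-step summary
from `0011` shows the expected damped mean-p53 oscillation (cells desynchronise
and repair), and raising $p_{dam}^{\downarrow}$ from .05 to .20 shortens the
expected time-to-repair — both asserted in the acceptance tests.

**Phage lambda lysis/lysogeny switch** (`phage_lambda`): CI (0–2), CRO
(0–3), CII, N, following the classical Thieffry–Thomas logical model.  CI is
fully expressed when CRO is absent or CII is present and fully repressed
when CRO is active with CII absent; fully expressed CI silences every other
gene; CRO self-limits at its top level, producing the lysis 2-cycle
`{0200, 0300}`; CII and N require low CRO and absent CI.  Integrity checks
assert the unique fixed point `2000` (lysogeny), the terminal 2-cycle
(lysis), and the three qualitative CI facts directly on the truth table.
Two published propensity sets are bundled: the CI-favouring set
(CI .8/.2, CRO .2/.8) and the CRO-favouring set (CI .3/.7, CRO .7/.3), CII
and N at .9/.9 in both.

A known limitation of the lambda transcription: from the infection state
`0000` at 10 steps the package computes an outcome split of roughly 5%
lysis / 95% lysogeny for the CI-favouring set and 82% / 18% for the
CRO-favouring set.  The qualitative bistability and the direction of the
bias match the published account of this switch, and the CI-favouring
numbers agree with the published 4%/96% frame within two points, but the
published 93%/7% split for the CRO-favouring frame is not reproducible by
*any* truth table satisfying the published structural constraints: if CI
can switch on fully in one step whenever CRO is absent (the literal reading
of the published logic), the lysogeny probability under the CRO-favouring
set is bounded below by
$p_{CI}^{\uparrow}(1 - p_{CRO}^{\uparrow}) = .3 \times .3 = .09 > .07$.
The published percentages were estimated from 100 cells (binomial standard
error around 3 points), which plausibly accounts for part of the gap; the
corresponding acceptance assertion is kept at its stated tolerance and
fails honestly rather than being widened.

**Random models** (`random_model()`) draw uniform truth tables and uniform
propensities under a seed, and are the raw material for the property tests
(kernel versus all-pairs oracle, fixed-point identity, round-trips).  They
emulate arbitrary logic, not biological structure: passing them shows the
*machinery* is exact, while the fixtures carry the biology.

## Problem sizes used by the test suite

The suite checks the fixed-point identity on the three fixtures plus 200
random models of up to 8 Boolean variables; kernel/oracle agreement on 30
random mixed-cardinality models (exhaustively over every state);
Monte-Carlo versus exact-kernel agreement with 100,000 cells per fixture;
the lambda outcome split with 10,000 cells per propensity set; and the p53
population behaviour with the published 100 cells and 60 steps.  These sizes
keep every stochastic check well inside its sampling tolerance while the
whole suite runs in a couple of minutes.

## Command-line interface

`exec/sdds` exposes the workflow as
`sdds statespace|fixedpoints|simulate|population|sweep` with `--model
<path|fixture:NAME>`, `--init`, `--steps`, `--cells`, `--seed`, `--out`,
`--labels name=state,state`, `--set VAR.up=p` overrides and, for sweeps,
`--grid` and `--pair`.  All randomness flows from `--seed` (a missing seed
is drawn and logged so any run can be reproduced after the fact); outputs
carry a configuration-hash header; logs go to stderr and data only to files.
Exit codes: 0 success, 2 input error, 3 fixture-integrity failure.

## Limitations

Beyond the lambda calibration note above: the package has no continuous-time
semantics and no correspondence to reaction-level simulation; propensities
are not fitted to data (no calibration machinery is provided); only fully
enumerable state spaces are analysed exactly; and extrinsic noise (parameter
fluctuation across cells) is not modelled — every cell in a population run
shares one model and differs only through the intrinsic update noise.
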