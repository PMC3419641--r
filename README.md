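# sdds — stochastic discrete dynamical systems for gene regulatory networks

Cell populations that are genetically identical and identically treated
still behave heterogeneously: intrinsic noise — small molecule numbers,
fluctuating reaction timing — makes biological functions fail occasionally
even when their inputs call for them.  `sdds` implements a discrete
modelling framework that captures exactly this, for researchers who work
with logical (Boolean and multi-valued) models of gene regulation and want
stochastic single-cell and cell-population dynamics without kinetic rate
constants.

## The model

A **stochastic discrete dynamical system** over variables
$x_1, \dots, x_n$ with finite ordered level sets
$X_i = \{0, \dots, k_i - 1\}$ is a collection of triplets

$$F = \{(f_i,\ p_i^{\uparrow},\ p_i^{\downarrow})\}_{i=1}^{n}$$

where $f_i : X \to X_i$ is the logical update rule of variable $i$,
$p_i^{\uparrow}$ its activation propensity and $p_i^{\downarrow}$ its
degradation propensity.  Per time step each coordinate independently moves
to its rule target $f_i(x)$ — with probability $p_i^{\uparrow}$ if that is
an increase, $p_i^{\downarrow}$ if a decrease — and otherwise holds its
value.  The one-step probability of $x \to y$ is the product
$w_{x\to y} = \prod_i \pi_{i,x}(x_i \to y_i)$ of the coordinate terms,
defining a Markov chain on the finite state space whose absorbing states
are exactly the fixed points of the deterministic system
$G = (f_1, \dots, f_n)$, and which degenerates to synchronous iteration of
$G$ when all propensities are 1.

The package provides: model construction from expressions or truth tables
(JSON and TSV dialects with exact round-trips), the exact transition
kernel and weighted state graph (DOT/CSV export), fixed points and
attractors (terminal strongly connected components), exact distribution
propagation, seeded single-cell and population simulation with outcome
tallies and propensity sweeps, three bundled regulatory models — a
two-variable worked example, the p53–Mdm2 damage-response network and the
phage lambda lysis/lysogeny switch — plus a random-model generator and a
command-line interface (`exec/sdds`).

## A worked example

```r
library(sdds)

m <- load_fixture("example_2_1_1")
m
#> Stochastic discrete dynamical system: 2 variables, 4 states
#>   x1       levels 0..1  p_up=0.1   p_down=0.2    x2
#>   x2       levels 0..1  p_up=0.5   p_down=0.9    min(x1, not(x2))

transition_distribution(m, "01")
#> Transition distribution from 01:
#>   -> 00  0.81
#>   -> 10  0.09
#>   -> 01  0.09
#>   -> 11  0.01
```

From `01` the rules call for x1 to rise (granted with probability .1) and
x2 to decay (granted with probability .9), so the system most likely falls
to the fixed point `00`: the weight .81 is the product
$(1-.1)\times.9$, and the four weights sum to 1.

The lambda switch shows the population-level use.  Its chain is bistable —
an absorbing lysogenic state and a terminal lytic 2-cycle — and from the
infection state `0000` intrinsic noise alone splits a clonal population
between the two fates:

```r
lam <- load_fixture("phage_lambda")
attractors(build_state_graph(lam))
#> Attractors:
#>   fixed point 2000
#>   terminal component {0200, 0300}

pop <- simulate_population(lam, "0000", n_cells = 10000, steps = 10, seed = 93)
classify_outcomes(pop, list(lysogeny = "2000", lysis = c("0200", "0300")))
#>      outcome count fraction
#> 1   lysogeny  9472   0.9472
#> 2      lysis   528   0.0528
#> 3 unresolved     0   0.0000
```

With the default CI-favouring propensities about 95% of cells integrate the
phage genome (lysogeny, CI fully expressed) and 5% lyse (CRO cycling);
`load_fixture("phage_lambda", propensity_set = "cro")` biases the race the
other way.  `propensity_sweep()` traces the whole lysis/lysogeny curve as a
function of the CI/CRO propensity balance, and for the p53 model
`simulate_population()` reproduces damped population-average oscillations of
p53 while DNA damage is being repaired.

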