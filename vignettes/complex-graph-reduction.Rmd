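---
title: "Reducing enzyme-kinetic reaction networks by deleting complexes"
author: "crnreduce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing enzyme-kinetic reaction networks by deleting complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnreduce)
```

## The model

A kinetic model of a biochemical pathway is a set of coupled rational ODEs
for the metabolite concentrations `x` (mM). `crnreduce` works with the
*complex graph* of such a network: the vertices are the *complexes* — the
distinct left- and right-hand sides of the reactions — and the directed
edges are the reactions. Two integer matrices fix the structure:

* `Z` (m × c), the complex stoichiometric matrix, whose column α gives the
  species composition of complex α;
* `B` (c × r), the incidence matrix, with −1 at a reaction's substrate
  complex and +1 at its product complex.

Each directed reaction rate is stored in the factored form

$$ v_j(x) \;=\; d_j(x)\, k_j \prod_i x_i^{(Z_{S_j})_i}, $$

a proportionality constant `k_j` times the mass-action monomial of the
substrate complex, damped by a rational denominator `d_j` that maps the open
positive orthant to positive reals. Mass action is the degenerate case
`d ≡ 1`; irreversible and reversible Michaelis–Menten laws, competitive,
noncompetitive and uncompetitive modifiers, and Hill kinetics are all of
this form, and the two directions of a reversible Michaelis–Menten reaction
share one binding polynomial (and hence one set of saturation constants).
Collecting the edge weights `k_j d_j(x)` into a weighted adjacency matrix
`A(x)` and setting `L(x) = Δ(x) − A(x)` (with `Δ` the diagonal of column
sums) gives the state-dependent weighted Laplacian of the complex graph, and
the whole network dynamics is

$$ \dot x \;=\; -Z\,L(x)\,\mathrm{Exp}(Z^\top \mathrm{Ln}\,x) \;+\; Z\,v_b(x), $$

where `v_b` holds per-complex boundary (exchange) fluxes and the
exponential-of-log term is evaluated as the monomial product with
`0^0 := 1`, so states on the boundary of the orthant need no special-casing.
The identity `B v(x) = −L(x) Exp(Zᵀ Ln x)` is checked against a direct
per-reaction flux summation in the test suite (to 1e−10, relative).

## Reduction by deleting complexes

Deleting a set `V_o` of complexes imposes *complex balancing* on each of
them — net inflow equals net outflow — which, after partitioning `L` into
retained (1) and deleted (2) blocks, amounts to the Schur complement

$$ \hat L(x) \;=\; L_{11} - L_{12} L_{22}^{-1} L_{21},
   \qquad P = [\,I \;\; -L_{12} L_{22}^{-1}\,], $$

and the reduced dynamics
$\dot x = Z_1\,(P v_b(x) - \hat L(x)\,\mathrm{Exp}(Z_1^\top \mathrm{Ln}\,x))$.
The Schur complement of a weighted Laplacian is again a weighted Laplacian
(positive diagonal, nonpositive off-diagonal, zero column sums), so the
reduced model is again a bona fide enzyme-kinetic reaction network, and the
result does not depend on the order in which complexes are eliminated. Both
facts are exercised as property suites over hundreds of random networks.

Species that appear only in deleted complexes get a structurally zero row of
`Z_1` and drop out of the state; their concentrations are *frozen* at
caller-supplied values (the automated procedure uses the pre-event steady
state of the original network) everywhere they still occur — in particular
inside the denominators `d_j` of retained reactions and inside boundary
fluxes. Elimination is decided on the integer stoichiometry, never by a
floating-point test. Because `L` depends on the state through every `d_j`,
`Lhat(x)` is recomputed at every right-hand-side evaluation; nothing in the
derivation licenses freezing it.

```{r example}
net <- example1_network()      # X1+X2 <=> X3+X4 <=> X5+X6, reversible MM
red <- delete_complexes(net, 2, frozen = c(X3 = 0.5, X4 = 0.5))
red
count_reduced_reactions(red)   # one reversible reaction remains
```

For a chain of two reversible Michaelis–Menten steps the reduction has a
closed form: `collapse_rev_mm_chain()` returns the 8-parameter collapsed law
(4 in the unimolecular case) whose equilibrium constant is the product of
the step equilibrium constants. The closed form is validated against a
substitution oracle that solves the complex-balancing condition for the
intermediate monomial directly. The exact dependence of each reduced
constant on the frozen values follows from expanding the frozen binding
polynomials; the package derives it by that expansion rather than claiming
any other printed form.

```{r collapse}
r <- net$reactions
claw <- collapse_rev_mm_chain(list(fwd = r[[1]]$law, rev = r[[2]]$law),
                              list(fwd = r[[3]]$law, rev = r[[4]]$law),
                              frozen = c(X3 = 0.5, X4 = 0.5))
claw
```

### Structural effects

Deleting a complex restructures its linkage class in a small number of
archetypal ways, reported by `classify_deletion()`: a `type1` interior
complex of a reversible chain shortens the chain; a `type2` complex (one
reversible, one irreversible neighbour) collapses the pair into a single
irreversible reaction; a `type3` hub (more than two reactions) completely
couples its neighbours without reducing the reaction or parameter count; a
complex forming a two-complex linkage class removes the class entirely
(`linkage_removal`). A deletion is `disconnecting` when it splits reactions
that share no species into independent subsystems — detected structurally
from species co-occurrence plus the Kron fill-in of the complex graph —
and such deletions are refused by the automated procedure unless explicitly
allowed, because they change the dynamics drastically. The disconnecting
label takes precedence over `linkage_removal` when both apply.

## The automated procedure

`greedy_reduce()` automates the choice of deletions under a *scenario*: a
dynamic event (a step change of clamped species at t = 0, or an explicit
displaced initial state), an observation horizon `T` (min), a nonempty set
of *significant species* that must be retained, and a cutoff. Each
iteration ranks every deletable complex by the error integral

$$ I \;=\; \sum_{i \in \mathcal M_I} \frac{1}{T\,n(\mathcal M_I)}
   \int_0^T \Bigl|\,1 - \frac{x_i^{r}(t)}{x_i^{f}(t)}\,\Bigr|\,dt, $$

the dimensionless time- and species-averaged relative deviation of the
candidate reduced model from the full model, and deletes the minimizer;
iteration stops when the best candidate exceeds the cutoff (default 0.1) or
no candidates remain. Complexes containing a significant species are never
candidates ("made of" is read as "containing"). Reducing an N-species model
to L species with M protected costs `simulation_count(N, M, L)` =
Σ_{i=L..N}(i − M) candidate simulations.

Numerical choices:

* The integrand uses the absolute value. The bare expression
  `1 − x_r/x_f` could take both signs and cancel over the horizon,
  reporting spurious agreement; the absolute value is the conservative
  reading and the one implemented.
* Quadrature is the trapezoid rule on the union of the two adaptive solver
  grids; with solver tolerances rtol 1e−8 / atol 1e−10 (defaults chosen so
  error-integral differences of 1e−3 are resolvable against a 0.1 cutoff),
  quadrature error is far below the cutoff.
* Frozen values at every greedy step come from the *original* network's
  pre-event steady state, not from the partially reduced model: the steady
  state is computed once, and order-independence of the Schur reduction
  supports a fixed reference.
* The full-model trajectory is simulated once per greedy run and cached;
  ties in `I` break toward the lowest complex index, so runs are
  deterministic (no randomness anywhere in the procedure).
* Steady states are found by stiff integration with horizon doubling,
  polished by a Moore–Penrose Newton step (the Jacobian is singular along
  conservation laws, so a pseudoinverse is used; a step is kept only when
  it lowers the residual) until
  `||rhs||_inf ≤ 1e−9 · max(1, ||x||_inf)`.
* The scenario type accepts an explicit event initial state in addition to
  clamped-species steps: closed benchmark networks have no clamped species
  to step, yet the procedure must be exercisable on them; displacing the
  initial state from the steady state plays the role of the upshift.

```{r greedy}
onet <- example1_network(open = TRUE)
x_ss <- find_steady_state(onet, t_init = 5)
x_event <- x_ss
x_event[c("X1", "X2")] <- 1.5 * x_event[c("X1", "X2")]
scen <- scenario(T = 3, significant = c("X1", "X2", "X5", "X6"),
                 cutoff = 0.1, x0 = x_event)
res <- greedy_reduce(onet, scen)
res$trace
```

`convergence_times()` reports, per species, the first time after which the
trajectory stays within 5% of its concentration change between the two
steady states; it exists because the deletion order chosen by the error
integral need *not* coincide with the order of convergence times, which is
what distinguishes this reduction from time-scale-separation approaches.

## Fixtures: what the generators emulate, and what they do not

All tests run on programmatically generated networks. `example1_network()`
builds the two-step reversible Michaelis–Menten chain (6 species, 3
complexes, 12 parameters). Its default maximum rates (2/1 for the first
step, 20/10 for the second, unit Michaelis constants, mM initial values of
order one) make the intermediate step fast relative to the ends, so complex
balancing on the intermediate complex is a good approximation — the regime
in which the method is designed to operate; with `open = TRUE` a constant
inflow (0.5 mM/min) at the first complex and a first-order drain at the
last give it a hyperbolically stable steady state. `chain_network()`,
`type2_chain()`, `type3_star()` and `disconnecting_triple()` realise the
linkage-class archetypes; `clamped_input_chain()` is the upshift archetype
(a clamped extracellular species stepped at t = 0);
`random_enzymatic_network()` draws connected complex graphs with mixed
mass-action/Michaelis–Menten kinetics and log-uniform parameters for the
property suites, reproducibly by seed.

These fixtures emulate the *structure* of metabolic models — linkage
classes, shared-denominator reversibility, clamped inputs, exchange fluxes
— at desk scale (≤ 10 complexes, horizons of a few minutes). They do not
reproduce the stiffness spectrum, the regulatory cross-dependencies
(allosteric effectors acting across linkage classes), or the parameter
correlations of curated genome-scale or pathway models; passing tests
demonstrate the algebra and the procedure, not predictive accuracy on any
particular organism's pathway. Applying the pipeline to a curated model is
a matter of transcribing it into the native JSON or annotated-SBML format
(the architecture loads either); the kinetic constants belong to those
models' own publications and are deliberately not bundled here.

## Degenerate inputs, tolerances, limitations

* Deleting a set whose `L22` block is singular or has condition number
  above 1e12 raises an error naming the offending complexes; during
  integration the same condition aborts with a state dump.
* Trajectories clamp negative excursions below 1e−12 mM to zero (counted
  in the trajectory metadata) and abort on substantial negativity.
* The error integral is undefined when a full-model significant
  concentration reaches zero; this raises an error rather than returning
  an infinite value.
* Hill kinetics is factored as `k = V/K^n` with
  `d(x) = x^{n−1}/(1+(x/K)^n)`, which keeps `d` positive on the open
  positive orthant for any real exponent `n ≥ 1`.
* SBML support is a Level 3 subset: species, stoichiometry and the
  catalogued rate-law parameterisation carried in a package annotation
  namespace. Arbitrary MathML kinetic laws are rejected with an explicit
  unsupported-law error — automatic factorisation of arbitrary rate
  expressions into `(k, d)` form is out of scope. A numerically reduced
  model exports its reduction block as an annotation, since no standard
  kinetic law expresses a state-dependent Schur complement.
* Quasi-steady-state approximation is *not* a mode of this package: QSSA
  equates inflow and outflow of individual species and generally requires
  solving polynomial equations (and fails outright when a deleted complex
  contains two species); complex balancing solves a linear system instead
  and stays inside enzyme kinetics. The comparison is documented here as a
  non-goal.
* Deficiency theory, weak-reversibility classification, persistence and
  bifurcation analysis are out of scope.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the property suites on 200
random networks of 4–9 complexes, 50 random parameter sets for the
equilibrium-constant composition, and greedy reductions of the open
two-step chain over a 3-minute horizon — sizes chosen so the full check
suite completes in well under a minute on one core while still sampling
the structural variety the proofs quantify over.
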