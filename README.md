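# crnreduce

Kinetic models of metabolic pathways pile up state variables and parameters
faster than they can be analysed or fitted: every enzyme adds a rational
rate law with its own saturation constants, and tools for stability or
bifurcation analysis choke on the dimensionality. `crnreduce` implements a
structural model-order-reduction method for such networks, aimed at
modellers who want a smaller model that (i) remains an enzyme-kinetic
reaction network with a biochemical reading, and (ii) demonstrably tracks
the transient behaviour of the metabolites they care about.

## The method

The package represents a network by its **complex graph**: vertices are the
complexes (distinct left/right-hand sides of reactions, columns of the
complex stoichiometric matrix `Z`), edges are reactions (columns of the
incidence matrix `B`). Every directed rate law is stored in the factored
form

    v_j(x) = d_j(x) · k_j · ∏_i x_i^(Z_Sj)_i,

with `d_j` a positive rational denominator (mass action: `d ≡ 1`;
Michaelis–Menten, modifier and Hill laws all fit). The edge weights
`k_j d_j(x)` assemble a state-dependent weighted Laplacian `L(x)` of the
complex graph, and the dynamics becomes

    ẋ = −Z L(x) Exp(Zᵀ Ln x) + Z v_b(x),

with `v_b` per-complex boundary fluxes. **Reduction deletes complexes**: the
deleted set is forced into complex balance (inflow = outflow), which is
exactly the Schur complement (Kron reduction) `L̂ = L₁₁ − L₁₂L₂₂⁻¹L₂₁` of the
Laplacian — again a Laplacian, so the reduced model is again a reaction
network, with fewer complexes, reactions, state variables and parameters.
Species occurring only in deleted complexes are frozen at reference values.
An automated greedy procedure ranks candidate deletions by the **error
integral**

    I = Σ_{i∈M_I} 1/(T·n(M_I)) ∫₀ᵀ |1 − x_i^r(t)/x_i^f(t)| dt,

the time- and species-averaged relative deviation of the candidate reduced
model from the full model over a user-chosen set of significant species,
and deletes greedily until the best candidate exceeds a cutoff (default
0.1). For a chain of two reversible Michaelis–Menten steps the reduction
also has a closed form (`collapse_rev_mm_chain()`), whose equilibrium
constant composes as the product of the step equilibrium constants.

## Worked example

The two-step reversible Michaelis–Menten chain
`X1+X2 ⇌ X3+X4 ⇌ X5+X6` (12 parameters, 6 state variables), opened with a
constant inflow at the first complex and a drain at the last:

```r
library(crnreduce)
net <- example1_network(open = TRUE)
net
#> Reaction network: 6 species, 3 complexes, 4 directed reactions, 2 boundary fluxes
#> Complexes: X1+X2, X3+X4, X5+X6
#> Linkage classes: 1

x_ss <- find_steady_state(net, t_init = 5)
round(x_ss, 4)
#>     X1     X2     X3     X4     X5     X6
#> 2.0153 2.0153 0.8374 0.8374 1.0000 1.0000

x_event <- x_ss
x_event[c("X1", "X2")] <- 1.5 * x_event[c("X1", "X2")]
scen <- scenario(T = 3, significant = c("X1", "X2", "X5", "X6"),
                 cutoff = 0.1, x0 = x_event)
res <- greedy_reduce(net, scen)
res$trace
#> Reduction trace: 1 deletion(s), stopped because: no_candidates
#>   1. delete X3+X4  (min I = 0.02369)
```

The greedy procedure deletes the intermediate complex `X3+X4` — the only
complex not containing a significant species — and the reduced model's
trajectories deviate from the full model by 2.4% averaged over time and the
four significant species. The closed-form collapsed law shows the parameter
reduction (12 → 8) and the equilibrium-constant composition:

```r
r <- net$reactions
collapse_rev_mm_chain(list(fwd = r[[1]]$law, rev = r[[2]]$law),
                      list(fwd = r[[3]]$law, rev = r[[4]]$law),
                      frozen = x_ss[c("X3", "X4")])
#> Collapsed reversible law X1+X2 <=> X5+X6
#>   kf_red = 0.564187, kr_red = 0.141047, Keq_red = 4
#>   8 parameters: kf_red, kr_red, X1, X2, X1:X2, X5, X6, X5:X6
```

`Keq_red = 4` is exactly `KeqI · KeqII = 2 · 2`.

Networks are read and written as native JSON (`read_network_json()`,
bit-exact round trip) or an SBML Level 3 subset (`read_sbml()`,
`write_sbml()`). A command-line interface is installed as `exec/crnreduce`:

```sh
crnreduce reduce model.json --significant X1,X2,X5,X6 \
    --horizon 3 --cutoff 0.1 --out reduced.json --trace trace.json
```

## Scope

The package reduces models; it does not ship any particular organism's
kinetic model. Curated pathway models can be transcribed into the native
JSON or annotated-SBML format and reduced with the same functions.
Quasi-steady-state approximation, deficiency theory and bifurcation
analysis are out of scope (see the vignette for the comparison with QSSA).
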