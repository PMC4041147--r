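# Programmatic generators for the canonical network archetypes: the two-step
# reversible Michaelis-Menten chain, reversible (mass-action or MM) chains,
# the chain-with-irreversible-step and hub (star) linkage classes, the
# three-reaction disconnecting example, a two-state relaxation network, a
# clamped-input chain for step-perturbation scenarios, and seeded random
# enzymatic networks for property tests.

#' Two-step reversible Michaelis-Menten chain (six species, three complexes)
#'
#' The network \eqn{X_1+X_2 \rightleftharpoons X_3+X_4 \rightleftharpoons
#' X_5+X_6} with both reversible reactions governed by two-site reversible
#' Michaelis-Menten kinetics: 12 parameters, 2 reversible reactions, 6 state
#' variables. The default parameters make the intermediate reaction fast
#' relative to the ends, so that complex balancing on \eqn{X_3+X_4} is a good
#' approximation.
#'
#' @param VfI,VrI,VfII,VrII maximum rates (mM/min) of the two reversible
#'   reactions.
#' @param KmI named Michaelis constants (mM) of reaction I over X1..X4.
#' @param KmII named Michaelis constants (mM) of reaction II over X3..X6.
#' @param x0 named initial concentrations (mM).
#' @param open add a constant inflow at the first complex and a first-order
#'   outflow at the last, making a nontrivial steady state possible
#'   (default `FALSE`: closed network).
#' @param k_in,k_out boundary-flux constants used when `open = TRUE`.
#' @return A `crn` network.
#' @export
example1_network <- function(VfI = 2, VrI = 1, VfII = 20, VrII = 10,
                             KmI = c(X1 = 1, X2 = 1, X3 = 1, X4 = 1),
                             KmII = c(X3 = 1, X4 = 1, X5 = 1, X6 = 1),
                             x0 = c(X1 = 2, X2 = 2, X3 = 0.5, X4 = 0.5,
                                    X5 = 0.2, X6 = 0.2),
                             open = FALSE, k_in = 0.5, k_out = 0.5) {
  lawsI <- rev_mm_laws(VfI, VrI, KmI, substrates = c("X1", "X2"),
                       products = c("X3", "X4"))
  lawsII <- rev_mm_laws(VfII, VrII, KmII, substrates = c("X3", "X4"),
                        products = c("X5", "X6"))
  boundary <- list()
  if (open)
    boundary <- list(boundary_flux(c(X1 = 1, X2 = 1), "constant", k_in),
                     boundary_flux(c(X5 = 1, X6 = 1), "first_order", k_out))
  reaction_network(
    species = data.frame(id = paste0("X", 1:6), x0 = unname(x0[paste0("X", 1:6)])),
    reactions = list(
      reversible_reaction(c(X1 = 1, X2 = 1), c(X3 = 1, X4 = 1), lawsI),
      reversible_reaction(c(X3 = 1, X4 = 1), c(X5 = 1, X6 = 1), lawsII)),
    boundary_fluxes = boundary)
}

#' Four-complex mass-action network with bimolecular complexes
#'
#' A small branched network on four species whose complexes are
#' \eqn{2X_1+X_2}, \eqn{X_3}, \eqn{X_1+2X_2} and \eqn{X_4}:
#' \eqn{2X_1+X_2 \rightleftharpoons X_3 \rightleftharpoons X_1+2X_2} and
#' \eqn{2X_1+X_2 \to X_4}, all mass action with unit rate constants unless
#' overridden.
#'
#' @param k named list of rate constants (`k1f`, `k1r`, `k2f`, `k2r`, `k3`).
#' @param x0 initial concentrations.
#' @return A `crn` network.
#' @export
branched_network <- function(k = list(k1f = 1, k1r = 1, k2f = 1, k2r = 1, k3 = 1),
                           x0 = c(X1 = 1, X2 = 1, X3 = 1, X4 = 0)) {
  reaction_network(
    species = data.frame(id = paste0("X", 1:4), x0 = unname(x0[paste0("X", 1:4)])),
    reactions = list(
      reversible_reaction(c(X1 = 2, X2 = 1), c(X3 = 1),
                          rev_mass_action_laws(k$k1f, k$k1r)),
      reversible_reaction(c(X3 = 1), c(X1 = 1, X2 = 2),
                          rev_mass_action_laws(k$k2f, k$k2r)),
      rxn(c(X1 = 2, X2 = 1), c(X4 = 1), mass_action_law(k$k3))))
}

#' Reversible chain of unimolecular complexes
#'
#' \eqn{C_1 \rightleftharpoons C_2 \rightleftharpoons \cdots
#' \rightleftharpoons C_n} with one species per complex, governed by mass
#' action or single-site reversible Michaelis-Menten kinetics. Deleting an
#' interior complex shortens the chain by one (the type-1 restructuring).
#'
#' @param n number of complexes (>= 3).
#' @param kinetics `"mass_action"` or `"rev_mm"`.
#' @param kf,kr rate-constant vectors (length `n - 1`, recycled).
#' @param Km Michaelis constant used for every species (rev_mm only).
#' @param x0 initial concentration per species (recycled).
#' @param open add constant inflow at `C_1` and first-order outflow at
#'   `C_n`.
#' @param k_in,k_out boundary constants when `open = TRUE`.
#' @param seed optional seed: when given, rate constants are drawn
#'   log-uniformly from [0.1, 10] instead of `kf`/`kr`.
#' @return A `crn` network with species `S1..Sn`.
#' @export
chain_network <- function(n, kinetics = c("mass_action", "rev_mm"),
                          kf = 1, kr = 1, Km = 1, x0 = 1,
                          open = FALSE, k_in = 0.3, k_out = 0.3,
                          seed = NULL) {
  kinetics <- match.arg(kinetics)
  stopifnot(n >= 3)
  kf <- rep_len(kf, n - 1)
  kr <- rep_len(kr, n - 1)
  if (!is.null(seed)) {
    set.seed(seed)
    kf <- 10^stats::runif(n - 1, -1, 1)
    kr <- 10^stats::runif(n - 1, -1, 1)
  }
  ids <- paste0("S", seq_len(n))
  rxns <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    sub <- stats::setNames(1L, ids[i])
    prod <- stats::setNames(1L, ids[i + 1])
    laws <- if (kinetics == "mass_action")
      rev_mass_action_laws(kf[i], kr[i])
    else
      rev_mm_laws(kf[i] * Km, kr[i] * Km,
                  stats::setNames(c(Km, Km), c(ids[i], ids[i + 1])),
                  substrates = ids[i], products = ids[i + 1])
    rxns[[i]] <- reversible_reaction(sub, prod, laws)
  }
  boundary <- list()
  if (open)
    boundary <- list(boundary_flux(stats::setNames(1L, ids[1]), "constant", k_in),
                     boundary_flux(stats::setNames(1L, ids[n]), "first_order", k_out))
  reaction_network(
    species = data.frame(id = ids, x0 = rep_len(x0, n)),
    reactions = rxns, boundary_fluxes = boundary)
}

#' Two-state relaxation network A <=> B
#'
#' Mass action with `kf = 2`, `kr = 1` from `x0 = (3, 0)`; the closed system
#' relaxes to the equilibrium `(1, 2)` (detailed balance with total 3).
#'
#' @param kf,kr rate constants.
#' @param x0 initial concentrations `c(A, B)`.
#' @return A `crn` network.
#' @export
two_state_network <- function(kf = 2, kr = 1, x0 = c(A = 3, B = 0)) {
  reaction_network(
    species = data.frame(id = c("A", "B"), x0 = unname(x0[c("A", "B")])),
    reactions = list(reversible_reaction(c(A = 1), c(B = 1),
                                         rev_mass_action_laws(kf, kr))))
}

#' Chain with one reversible and one irreversible step (type-2 linkage class)
#'
#' \eqn{C_1 \rightleftharpoons C_2 \to C_3} on unimolecular complexes, mass
#' action; deleting \eqn{C_2} collapses the pair into the single
#' irreversible reaction \eqn{C_1 \to C_3}.
#'
#' @param k1f,k1r,k2 rate constants.
#' @return A `crn` network with species `S1..S3`.
#' @export
type2_chain <- function(k1f = 1, k1r = 0.5, k2 = 1) {
  reaction_network(
    species = data.frame(id = paste0("S", 1:3), x0 = c(1, 0.5, 0.1)),
    reactions = list(
      reversible_reaction(c(S1 = 1), c(S2 = 1),
                          rev_mass_action_laws(k1f, k1r)),
      rxn(c(S2 = 1), c(S3 = 1), mass_action_law(k2))))
}

#' Hub linkage class (type 3): one complex in more than two reactions
#'
#' A star with hub \eqn{C_2} reversibly connected to \eqn{C_1}, \eqn{C_3}
#' and \eqn{C_4}; deleting the hub couples the three leaves completely, so
#' the reaction count (and the parameter count) does not decrease.
#'
#' @param kf,kr rate constants of the three reversible spokes (recycled).
#' @return A `crn` network with species `S1..S4` (hub species `S2`).
#' @export
type3_star <- function(kf = c(1, 0.8, 1.2), kr = c(0.5, 0.4, 0.6)) {
  kf <- rep_len(kf, 3)
  kr <- rep_len(kr, 3)
  leaves <- c("S1", "S3", "S4")
  rxns <- lapply(seq_along(leaves), function(i)
    reversible_reaction(stats::setNames(1L, "S2"),
                        stats::setNames(1L, leaves[i]),
                        rev_mass_action_laws(kf[i], kr[i])))
  reaction_network(
    species = data.frame(id = paste0("S", 1:4), x0 = c(0.5, 1, 0.5, 0.5)),
    reactions = rxns)
}

#' Three-reaction network whose middle complex deletion is disconnecting
#'
#' \eqn{X_1+X_2 \rightleftharpoons X_3+X_4},
#' \eqn{X_4+X_5 \rightleftharpoons X_6+X_7},
#' \eqn{X_7+X_8 \rightleftharpoons X_9+X_{10}} (mass action). The first and
#' third reaction share no species; deleting \eqn{X_4+X_5} removes the
#' middle reaction and leaves them evolving independently, the hazard the
#' automated procedure refuses by default.
#'
#' @param kf,kr rate constants (recycled over the three reactions).
#' @return A `crn` network with species `X1..X10`.
#' @export
disconnecting_triple <- function(kf = 1, kr = 1) {
  kf <- rep_len(kf, 3)
  kr <- rep_len(kr, 3)
  reaction_network(
    species = data.frame(id = paste0("X", 1:10), x0 = rep(1, 10)),
    reactions = list(
      reversible_reaction(c(X1 = 1, X2 = 1), c(X3 = 1, X4 = 1),
                          rev_mass_action_laws(kf[1], kr[1])),
      reversible_reaction(c(X4 = 1, X5 = 1), c(X6 = 1, X7 = 1),
                          rev_mass_action_laws(kf[2], kr[2])),
      reversible_reaction(c(X7 = 1, X8 = 1), c(X9 = 1, X10 = 1),
                          rev_mass_action_laws(kf[3], kr[3]))))
}

#' Clamped-input chain for step-perturbation scenarios
#'
#' An upshift archetype: a clamped extracellular species `Sin` feeds a
#' reversible chain `S1 <=> ... <=> Sn` via `Sin -> S1`, with a first-order
#' drain on the last species. Stepping the clamped value of `Sin` at t = 0
#' (e.g. 0.2 -> 5 mM) displaces the network from its pre-event steady state.
#'
#' @param n chain length (internal species count, >= 3).
#' @param sin0 pre-event clamped concentration of `Sin` (mM).
#' @param k_uptake rate constant of the uptake reaction.
#' @param kf,kr chain rate constants (recycled).
#' @param k_out drain constant on `Sn`.
#' @return A `crn` network.
#' @export
clamped_input_chain <- function(n = 3, sin0 = 0.2, k_uptake = 1,
                                kf = 2, kr = 1, k_out = 1) {
  stopifnot(n >= 3)
  kf <- rep_len(kf, n - 1)
  kr <- rep_len(kr, n - 1)
  ids <- paste0("S", seq_len(n))
  rxns <- list(rxn(c(Sin = 1), stats::setNames(1L, ids[1]),
                   mass_action_law(k_uptake)))
  for (i in seq_len(n - 1))
    rxns[[length(rxns) + 1L]] <-
      reversible_reaction(stats::setNames(1L, ids[i]),
                          stats::setNames(1L, ids[i + 1]),
                          rev_mass_action_laws(kf[i], kr[i]))
  reaction_network(
    species = data.frame(id = c("Sin", ids),
                         x0 = c(sin0, rep(0.1, n)),
                         fixed = c(TRUE, rep(FALSE, n))),
    reactions = rxns,
    boundary_fluxes = list(boundary_flux(stats::setNames(1L, ids[n]),
                                         "first_order", k_out)))
}

#' Seeded random enzymatic network for property testing
#'
#' Generates a connected complex graph (random spanning tree plus extra
#' edges) on randomly composed complexes (one or two species, coefficients 1
#' or 2), every edge reversible, with a random mix of mass-action and
#' shared-denominator reversible Michaelis-Menten kinetics and log-uniform
#' parameters. A fixed seed reproduces the network exactly.
#'
#' @param m number of species.
#' @param c_n number of complexes (`>= 2`).
#' @param density probability of each extra (non-tree) edge.
#' @param mm_fraction fraction of edges with Michaelis-Menten kinetics.
#' @param seed integer seed (required, for reproducibility).
#' @return A `crn` network with species `S1..Sm`.
#' @export
random_enzymatic_network <- function(m = 6, c_n = 5, density = 0.15,
                                     mm_fraction = 0.5, seed) {
  stopifnot(c_n >= 2, m >= 2)
  set.seed(seed)
  ids <- paste0("S", seq_len(m))
  complexes <- list()
  keys <- character()
  guard <- 0
  while (length(complexes) < c_n) {
    guard <- guard + 1
    if (guard > 1000) stop("cannot place ", c_n, " distinct complexes on ",
                           m, " species")
    k <- sample(1:2, 1)
    sp <- sample(ids, k)
    coef <- sample(1:2, k, replace = TRUE)
    st <- stats::setNames(as.integer(coef), sp)
    key <- canonical_complex_key(st)
    if (key %in% keys) next
    keys <- c(keys, key)
    complexes[[length(complexes) + 1L]] <- st
  }
  edges <- matrix(integer(0), ncol = 2)
  for (v in 2:c_n)
    edges <- rbind(edges, c(sample(seq_len(v - 1), 1), v))
  for (a in seq_len(c_n - 1)) for (b in seq((a + 1), c_n)) {
    if (any(edges[, 1] == a & edges[, 2] == b)) next
    if (stats::runif(1) < density) edges <- rbind(edges, c(a, b))
  }
  rxns <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    sub <- complexes[[edges[e, 1]]]
    prod <- complexes[[edges[e, 2]]]
    use_mm <- stats::runif(1) < mm_fraction
    laws <- if (use_mm) {
      members <- unique(c(names(sub), names(prod)))
      Km <- stats::setNames(10^stats::runif(length(members), -1, 1), members)
      rev_mm_laws(10^stats::runif(1, -1, 1), 10^stats::runif(1, -1, 1), Km,
                  substrates = names(sub), products = names(prod),
                  sites = list(members))
    } else
      rev_mass_action_laws(10^stats::runif(1, -1, 1), 10^stats::runif(1, -1, 1))
    rxns[[e]] <- reversible_reaction(sub, prod, laws)
  }
  species <- data.frame(id = ids, x0 = round(10^stats::runif(m, -1, 0.5), 4))
  # species not in any complex would be orphans; give each a unimolecular
  # complex appended to the last tree vertex? no -- simply drop orphans
  used <- unique(unlist(lapply(complexes, names)))
  species <- species[species$id %in% used, , drop = FALSE]
  reaction_network(species = species, reactions = rxns)
}
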