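#' Declare a directed reaction
#'
#' A reaction is a directed edge of the complex graph: it converts its
#' substrate complex into its product complex at a rate given by a rate law
#' in the factored form \eqn{v_j(x) = d_j(x)\, k_j \prod_i x_i^{(Z_{S_j})_i}}.
#' Complexes are written as sparse stoichiometry maps, e.g.
#' `c(X1 = 2, X2 = 1)` for \eqn{2 X_1 + X_2}.
#'
#' @param substrate named integer vector, the substrate complex.
#' @param product named integer vector, the product complex.
#' @param law a rate law built by [mass_action_law()], [mm_law()],
#'   [hill_law()], [custom_law()] or one half of [rev_mm_laws()].
#' @return A reaction specification, to be passed to [reaction_network()].
#' @seealso [reversible_reaction()]
#' @export
rxn <- function(substrate, product, law) {
  stopifnot(inherits(law, "crn_rate_law"))
  check_stoich(substrate, "substrate")
  check_stoich(product, "product")
  structure(list(substrate = substrate, product = product, law = law,
                 reversible = FALSE),
            class = "crn_rxn_spec")
}

#' Declare a reversible reaction as a shared-parameter pair of directed edges
#'
#' Reversibility is an annotation, not a primitive: the pair is stored as two
#' directed edges whose rate laws share one denominator (and hence one set of
#' saturation constants), as in reversible Michaelis-Menten kinetics where the
#' forward and reverse rates divide by the same binding polynomial.
#'
#' @param substrate,product named integer stoichiometry vectors (of the
#'   forward direction).
#' @param laws a list with elements `fwd` and `rev` as returned by
#'   [rev_mm_laws()], or two independently built laws.
#' @return A reversible reaction specification for [reaction_network()].
#' @export
reversible_reaction <- function(substrate, product, laws) {
  stopifnot(is.list(laws), inherits(laws$fwd, "crn_rate_law"),
            inherits(laws$rev, "crn_rate_law"))
  check_stoich(substrate, "substrate")
  check_stoich(product, "product")
  structure(list(substrate = substrate, product = product, laws = laws,
                 reversible = TRUE),
            class = "crn_rxn_spec")
}

check_stoich <- function(s, what) {
  if (length(s) == 0 || is.null(names(s)) || any(!nzchar(names(s))))
    stop(sprintf("%s complex must be a named stoichiometry vector", what))
  if (any(s != round(s)) || any(s < 0))
    stop(sprintf("%s stoichiometric coefficients must be nonnegative integers",
                 what))
  if (all(s == 0))
    stop(sprintf("%s complex has all-zero stoichiometry", what))
}

#' Declare a boundary (exchange) flux on a complex
#'
#' Boundary fluxes model the openness of a biochemical network: inflow to and
#' outflow from complexes, entering the balance laws as
#' \eqn{\dot x = Z B v(x) + Z v_b(x)} with \eqn{v_b \in R^c} indexed by
#' complex. Two parametric forms are supported: `"constant"`, a fixed flux
#' `k` (mM/min, positive = inflow), and `"first_order"`, an outflow
#' \eqn{-k\, w_\alpha(x)} proportional to the complex monomial
#' \eqn{w_\alpha = \prod_i x_i^{Z_{i\alpha}}}.
#'
#' @param complex named integer stoichiometry vector identifying the complex.
#' @param type `"constant"` or `"first_order"`.
#' @param k nonnegative rate constant (sign convention handled by `type`).
#' @return A boundary-flux specification for [reaction_network()].
#' @export
boundary_flux <- function(complex, type = c("constant", "first_order"), k) {
  type <- match.arg(type)
  check_stoich(complex, "boundary")
  stopifnot(is.numeric(k), length(k) == 1, is.finite(k))
  structure(list(complex = complex, type = type, k = k),
            class = "crn_boundary_spec")
}

canonical_complex_key <- function(stoich) {
  s <- stoich[stoich != 0]
  s <- s[order(names(s))]
  paste(names(s), s, sep = ":", collapse = "|")
}

#' Label a complex in chemical notation
#' @param stoich named integer stoichiometry vector.
#' @return Character label such as `"2X1+X2"`.
#' @export
complex_label <- function(stoich) {
  s <- stoich[stoich != 0]
  paste(ifelse(s == 1, names(s), paste0(s, names(s))), collapse = "+")
}

#' Build a kinetic reaction network from reactions and species
#'
#' Assembles the complex-graph representation of a network: the set of
#' complexes is the union of all distinct left- and right-hand sides of the
#' reactions (plus any complex referenced only by a boundary flux), ordered by
#' first appearance (substrate before product, reaction order), so that the
#' complex stoichiometric matrix `Z` and all derived matrices are reproducible
#' run to run.
#'
#' @param species data frame with columns `id` (unique short strings), `x0`
#'   (initial concentrations, mM, nonnegative) and optionally `name` (free
#'   text, defaults to `id`) and `fixed` (logical: externally clamped species,
#'   defaults to `FALSE`).
#' @param reactions list of specifications from [rxn()] and
#'   [reversible_reaction()].
#' @param boundary_fluxes optional list of [boundary_flux()] specifications.
#' @return An object of class `crn`: the network, housing the species table,
#'   the ordered complex list, the directed reaction list (reversible pairs
#'   flattened, sharing a pair id) and the boundary fluxes.
#' @examples
#' laws <- rev_mm_laws(Vf = 2, Vr = 1, Km = c(A = 1, B = 1),
#'                     substrates = "A", products = "B")
#' net <- reaction_network(
#'   species = data.frame(id = c("A", "B"), x0 = c(3, 0)),
#'   reactions = list(reversible_reaction(c(A = 1), c(B = 1), laws)))
#' complex_matrix(net)
#' @export
reaction_network <- function(species, reactions, boundary_fluxes = list()) {
  if (!is.data.frame(species) || !all(c("id", "x0") %in% names(species)))
    stop("species must be a data frame with columns 'id' and 'x0'")
  species$id <- as.character(species$id)
  if (anyDuplicated(species$id))
    stop("species ids must be unique")
  if (any(!is.finite(species$x0)) || any(species$x0 < 0))
    stop("initial concentrations x0 must be finite and nonnegative")
  if (is.null(species$name)) species$name <- species$id
  if (is.null(species$fixed)) species$fixed <- FALSE
  species <- species[, c("id", "name", "x0", "fixed")]

  if (length(reactions) == 0)
    stop("a reaction network needs at least one reaction")

  complexes <- list()
  keys <- character()
  add_complex <- function(stoich) {
    unknown <- setdiff(names(stoich), species$id)
    if (length(unknown) > 0)
      stop("complex ", complex_label(stoich),
           " references undeclared species: ", paste(unknown, collapse = ", "))
    key <- canonical_complex_key(stoich)
    i <- match(key, keys)
    if (is.na(i)) {
      full <- stats::setNames(rep(0L, nrow(species)), species$id)
      full[names(stoich)] <- as.integer(stoich)
      complexes[[length(complexes) + 1L]] <<- full
      keys <<- c(keys, key)
      i <- length(complexes)
    }
    i
  }

  rx_list <- list()
  pair_counter <- 0L
  for (spec in reactions) {
    if (!inherits(spec, "crn_rxn_spec"))
      stop("reactions must be built with rxn() or reversible_reaction()")
    s_idx <- add_complex(spec$substrate)
    p_idx <- add_complex(spec$product)
    if (s_idx == p_idx)
      stop("substrate and product complex of a reaction must differ (",
           complex_label(spec$substrate), ")")
    if (spec$reversible) {
      pair_counter <- pair_counter + 1L
      rx_list[[length(rx_list) + 1L]] <-
        list(substrate = s_idx, product = p_idx, law = spec$laws$fwd,
             pair = pair_counter)
      rx_list[[length(rx_list) + 1L]] <-
        list(substrate = p_idx, product = s_idx, law = spec$laws$rev,
             pair = pair_counter)
    } else {
      rx_list[[length(rx_list) + 1L]] <-
        list(substrate = s_idx, product = p_idx, law = spec$law, pair = NA_integer_)
    }
  }

  bf_list <- list()
  for (bf in boundary_fluxes) {
    if (!inherits(bf, "crn_boundary_spec"))
      stop("boundary_fluxes must be built with boundary_flux()")
    bf_list[[length(bf_list) + 1L]] <-
      list(complex = add_complex(bf$complex), type = bf$type, k = bf$k)
  }

  net <- structure(list(species = species, complexes = complexes,
                        reactions = rx_list, boundary = bf_list),
                   class = "crn")
  net
}

#' @export
print.crn <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d complexes, %d directed reactions",
              nrow(x$species), length(x$complexes), length(x$reactions)))
  if (length(x$boundary) > 0)
    cat(sprintf(", %d boundary fluxes", length(x$boundary)))
  cat("\n")
  labs <- vapply(x$complexes, complex_label, character(1))
  cat("Complexes:", paste(labs, collapse = ", "), "\n")
  lc <- linkage_classes(x)
  cat(sprintf("Linkage classes: %d\n", length(lc)))
  invisible(x)
}

#' Complex stoichiometric matrix
#'
#' The m-by-c matrix `Z` whose column \eqn{\alpha} gives the composition of
#' the \eqn{\alpha}-th complex in the m species; all entries are nonnegative
#' integers. Together with the incidence matrix it determines the balance
#' laws \eqn{\dot x = Z B v(x) + Z v_b(x)}.
#'
#' @param net a `crn` network.
#' @return Integer matrix with species ids as row names and complex labels as
#'   column names.
#' @export
complex_matrix <- function(net) {
  stopifnot(inherits(net, "crn"))
  Z <- vapply(net$complexes, identity, numeric(nrow(net$species)))
  Z <- matrix(as.integer(Z), nrow = nrow(net$species),
              dimnames = list(net$species$id,
                              vapply(net$complexes, complex_label, character(1))))
  Z
}

#' Incidence matrix of the complex graph
#'
#' The c-by-r matrix `B` with, in column j, -1 at the substrate (tail) complex
#' of reaction j and +1 at its product (head) complex. Every column sums to
#' zero.
#'
#' @param net a `crn` network.
#' @return Integer matrix (complexes by directed reactions).
#' @export
incidence_matrix <- function(net) {
  stopifnot(inherits(net, "crn"))
  c_n <- length(net$complexes)
  r_n <- length(net$reactions)
  B <- matrix(0L, c_n, r_n)
  for (j in seq_len(r_n)) {
    B[net$reactions[[j]]$substrate, j] <- -1L
    B[net$reactions[[j]]$product, j] <- 1L
  }
  rownames(B) <- vapply(net$complexes, complex_label, character(1))
  B
}

complex_adjacency_undirected <- function(net) {
  c_n <- length(net$complexes)
  adj <- matrix(FALSE, c_n, c_n)
  for (r in net$reactions) {
    adj[r$substrate, r$product] <- TRUE
    adj[r$product, r$substrate] <- TRUE
  }
  adj
}

#' Linkage classes of a network
#'
#' A linkage class is a maximal set of complexes mutually connected by
#' reactions, i.e. a connected component of the undirected complex graph.
#' Computed by breadth-first search over the adjacency structure.
#'
#' @param net a `crn` network.
#' @return A list of integer vectors partitioning the complex indices; each
#'   complex belongs to exactly one class.
#' @export
linkage_classes <- function(net) {
  stopifnot(inherits(net, "crn"))
  adj <- complex_adjacency_undirected(net)
  c_n <- nrow(adj)
  comp <- integer(c_n)
  nc <- 0L
  for (v in seq_len(c_n)) {
    if (comp[v] != 0L) next
    nc <- nc + 1L
    queue <- v
    comp[v] <- nc
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  lapply(seq_len(nc), function(k) which(comp == k))
}

#' Validate a network and report diagnostics
#'
#' Checks the structural invariants of the complex-graph representation:
#' unique complexes, no all-zero complexes, no self-loop reactions, complex
#' indices in range, nonnegative initial concentrations, and that every
#' species appears in at least one complex (orphans are warnings, the rest are
#' fatal).
#'
#' @param net a `crn` network.
#' @return Invisibly, a list with character vectors `errors` and `warnings`;
#'   fatal issues raise an error unless `stop_on_error = FALSE`.
#' @param stop_on_error raise on fatal issues (default `TRUE`).
#' @export
validate_network <- function(net, stop_on_error = TRUE) {
  stopifnot(inherits(net, "crn"))
  errors <- character()
  warnings <- character()
  c_n <- length(net$complexes)

  keys <- vapply(net$complexes, canonical_complex_key, character(1))
  if (anyDuplicated(keys))
    errors <- c(errors, "duplicate complexes present")
  if (any(vapply(net$complexes, function(s) all(s == 0), logical(1))))
    errors <- c(errors, "complex with all-zero stoichiometry")
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    if (r$substrate < 1 || r$substrate > c_n || r$product < 1 || r$product > c_n)
      errors <- c(errors, sprintf("reaction %d references a complex out of range", j))
    else if (r$substrate == r$product)
      errors <- c(errors, sprintf("reaction %d has identical substrate and product complex", j))
  }
  if (any(net$species$x0 < 0))
    errors <- c(errors, "negative initial concentration")
  Z <- complex_matrix(net)
  orphan <- rownames(Z)[rowSums(Z) == 0]
  if (length(orphan) > 0)
    warnings <- c(warnings,
                  paste("species in no complex (orphans):",
                        paste(orphan, collapse = ", ")))
  used <- unique(c(vapply(net$reactions, `[[`, integer(1), "substrate"),
                   vapply(net$reactions, `[[`, integer(1), "product"),
                   vapply(net$boundary, `[[`, integer(1), "complex")))
  unused <- setdiff(seq_len(c_n), used)
  if (length(unused) > 0)
    errors <- c(errors, paste("complex referenced by no reaction or boundary flux:",
                              paste(colnames(Z)[unused], collapse = ", ")))

  if (length(errors) > 0 && stop_on_error)
    stop("invalid network:\n  ", paste(errors, collapse = "\n  "))
  for (w in warnings) warning(w, call. = FALSE)
  invisible(list(errors = errors, warnings = warnings))
}

#' Evaluate the boundary-flux vector at a state
#'
#' @param net a `crn` network.
#' @param x named nonnegative concentration vector (mM) in species order.
#' @return Numeric c-vector \eqn{v_b(x)} (mM/min per complex).
#' @export
boundary_flux_vector <- function(net, x) {
  x <- species_state(net, x)
  vb <- numeric(length(net$complexes))
  if (length(net$boundary) == 0) return(vb)
  Z <- complex_matrix(net)
  for (bf in net$boundary) {
    vb[bf$complex] <- vb[bf$complex] + switch(bf$type,
      constant = bf$k,
      first_order = -bf$k * monomial(Z[, bf$complex], x),
      stop("unknown boundary flux type: ", bf$type))
  }
  vb
}

# coerce x to a named vector in species order
species_state <- function(net, x) {
  ids <- net$species$id
  if (is.null(names(x))) {
    if (length(x) != length(ids))
      stop("state vector has wrong length")
    names(x) <- ids
  } else {
    missing <- setdiff(ids, names(x))
    if (length(missing) > 0)
      stop("state vector missing species: ", paste(missing, collapse = ", "))
    x <- x[ids]
  }
  if (any(!is.finite(x)))
    stop("non-finite concentration in state vector")
  x
}

#' Count the free parameters of a network's rate laws
#'
#' Directed edges that form a reversible pair share one denominator, so their
#' saturation constants are counted once; the forward and reverse
#' proportionality constants are distinct. For the two-step reversible
#' Michaelis-Menten chain this gives 12 parameters (2 rate constants plus 4
#' Michaelis constants per reversible reaction).
#'
#' @param net a `crn` network.
#' @return Integer parameter count.
#' @export
parameter_count <- function(net) {
  stopifnot(inherits(net, "crn"))
  total <- 0L
  seen_pairs <- character()
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    if (is.na(r$pair)) {
      total <- total + length(r$law$param_names)
    } else {
      key <- as.character(r$pair)
      if (key %in% seen_pairs) next
      seen_pairs <- c(seen_pairs, key)
      partner <- Filter(function(q) !is.na(q$pair) && q$pair == r$pair,
                        net$reactions)
      nm <- unique(unlist(lapply(partner, function(q) q$law$param_names)))
      total <- total + length(nm)
    }
  }
  as.integer(total)
}
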