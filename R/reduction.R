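# Model reduction by deletion of complexes: the Schur complement of the
# weighted Laplacian with respect to the deleted vertex set imposes complex
# balancing (net inflow = net outflow) on each deleted complex and yields the
# reduced dynamics  xdot = Z1 (P v_b(x) - Lhat(x) Exp(Z1^T Ln x)).

#' Schur complement of a Laplacian with respect to deleted vertices
#'
#' Eliminates the rows/columns `delete_idx` of `L` by
#' \eqn{\hat L = L_{11} - L_{12} L_{22}^{-1} L_{21}}. For a weighted Laplacian
#' (zero column sums, nonpositive off-diagonal) the result is again a weighted
#' Laplacian on the retained vertices: positive diagonal, nonpositive
#' off-diagonal, zero column sums (Kron reduction).
#'
#' @param L square numeric matrix (a Laplacian value at some state).
#' @param delete_idx integer indices of the vertices to eliminate; the empty
#'   set returns `L` unchanged.
#' @return The reduced matrix on the retained indices, in their original
#'   relative order.
#' @export
schur_complement <- function(L, delete_idx) {
  stopifnot(is.matrix(L), nrow(L) == ncol(L))
  delete_idx <- as.integer(delete_idx)
  if (length(delete_idx) == 0) return(L)
  if (any(delete_idx < 1 | delete_idx > nrow(L)))
    stop("delete_idx out of range")
  if (anyDuplicated(delete_idx)) stop("duplicated indices in delete_idx")
  if (length(delete_idx) >= nrow(L))
    stop("cannot delete all vertices")
  keep <- setdiff(seq_len(nrow(L)), delete_idx)
  L22 <- L[delete_idx, delete_idx, drop = FALSE]
  kappa <- tryCatch(kappa(L22, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kappa) || kappa > 1e12) {
    labs <- if (!is.null(rownames(L))) rownames(L)[delete_idx] else delete_idx
    stop("block of deleted complexes {", paste(labs, collapse = ", "),
         "} is singular or ill-conditioned (condition number ",
         format(kappa), "); complex balancing cannot be imposed")
  }
  L[keep, keep, drop = FALSE] -
    L[keep, delete_idx, drop = FALSE] %*%
    solve(L22, L[delete_idx, keep, drop = FALSE])
}

#' Species eliminated by deleting a set of complexes
#'
#' Deletion removes the columns of `Z` belonging to `V_o`; species whose
#' remaining row of `Z1` is all zeros have derivative zero in the reduced
#' dynamics and drop out of the state. The decision is structural (integer
#' stoichiometry), never a floating-point test.
#'
#' @param net a `crn` network.
#' @param deleted integer indices of the complexes to delete.
#' @return Character vector of eliminated species ids (possibly empty).
#' @export
eliminated_species <- function(net, deleted) {
  stopifnot(inherits(net, "crn"))
  Z <- complex_matrix(net)
  retained <- setdiff(seq_len(ncol(Z)), deleted)
  Z1 <- Z[, retained, drop = FALSE]
  rownames(Z)[rowSums(Z1 != 0) == 0]
}

#' Delete complexes from a network (complex balancing)
#'
#' Produces the reduced model obtained by imposing the complex-balancing
#' condition on every complex in the deleted set: net inflow equals net
#' outflow, realised as the Schur complement of the state-dependent weighted
#' Laplacian. Species appearing only in deleted complexes are eliminated from
#' the state; their concentrations are frozen at the supplied values
#' everywhere they occur, including inside the denominators of retained rate
#' laws and inside boundary fluxes.
#'
#' @param net a `crn` network.
#' @param deleted integer indices of complexes to delete (nonempty, proper
#'   subset).
#' @param frozen named numeric vector supplying a positive concentration (mM)
#'   for every eliminated species; superfluous entries are ignored. May be
#'   omitted when no species is eliminated.
#' @param protected optional integer indices that must not be deleted (guard
#'   used by the automated procedure).
#' @return Object of class `crn_reduced` with fields `parent`, `retained`,
#'   `deleted`, `frozen`, `Z1`.
#' @export
delete_complexes <- function(net, deleted, frozen = numeric(),
                             protected = integer()) {
  stopifnot(inherits(net, "crn"))
  deleted <- sort(unique(as.integer(deleted)))
  c_n <- length(net$complexes)
  if (length(deleted) == 0) stop("deleted set must be nonempty")
  if (any(deleted < 1 | deleted > c_n)) stop("deleted index out of range")
  if (length(deleted) >= c_n) stop("cannot delete all complexes")
  hit <- intersect(deleted, protected)
  if (length(hit) > 0)
    stop("deletion touches protected complex(es): ",
         paste(vapply(net$complexes[hit], complex_label, character(1)),
               collapse = ", "))
  retained <- setdiff(seq_len(c_n), deleted)
  elim <- eliminated_species(net, deleted)
  missing <- setdiff(elim, names(frozen))
  if (length(missing) > 0)
    stop("missing frozen concentration for eliminated species: ",
         paste(missing, collapse = ", "))
  frozen <- frozen[elim]
  if (length(frozen) > 0 && (any(!is.finite(frozen)) || any(frozen <= 0)))
    stop("frozen concentrations must be positive and finite")
  Z <- complex_matrix(net)
  structure(list(parent = net, retained = retained, deleted = deleted,
                 frozen = frozen, Z1 = Z[, retained, drop = FALSE]),
            class = "crn_reduced")
}

#' @export
print.crn_reduced <- function(x, ...) {
  labs <- vapply(x$parent$complexes, complex_label, character(1))
  cat(sprintf("Reduced network: %d of %d complexes retained\n",
              length(x$retained), length(x$parent$complexes)))
  cat("Deleted:", paste(labs[x$deleted], collapse = ", "), "\n")
  if (length(x$frozen) > 0)
    cat("Eliminated species (frozen):",
        paste(sprintf("%s = %g", names(x$frozen), x$frozen), collapse = ", "),
        "\n")
  invisible(x)
}

# merge a (possibly partial) state with the frozen species values
augment_state <- function(red, x) {
  net <- red$parent
  ids <- net$species$id
  full <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (is.null(names(x))) {
    if (length(x) == length(ids)) full[] <- x
    else stop("unnamed state of wrong length for reduced model")
  } else full[intersect(names(x), ids)] <- x[intersect(names(x), ids)]
  full[names(red$frozen)] <- red$frozen
  if (any(is.na(full)))
    stop("state vector missing species: ",
         paste(ids[is.na(full)], collapse = ", "))
  full
}

#' Right-hand side of the reduced dynamics
#'
#' Evaluates the parent network's weighted Laplacian at the augmented state
#' (retained concentrations merged with frozen values), Schur-complements it
#' with respect to the deleted complexes at that state, and returns
#' \eqn{Z_1 (P v_b(x) - \hat L(x) w_1)} with
#' \eqn{P = [I_{\hat c}\;\; -L_{12} L_{22}^{-1}]} applied to the boundary
#' fluxes and \eqn{w_{1,\alpha} = \prod_i x_i^{Z_{1,i\alpha}}}. Entries for
#' eliminated species are structurally zero; clamped species rows are zeroed.
#'
#' @param red a `crn_reduced` model.
#' @param x named nonnegative concentration vector for the retained species
#'   (entries for eliminated species, if present, are ignored).
#' @return Named m-vector of derivatives (mM/min), zero at eliminated and
#'   clamped species.
#' @export
reduced_rhs <- function(red, x) {
  stopifnot(inherits(red, "crn_reduced"))
  net <- red$parent
  xa <- augment_state(red, x)
  L <- weighted_laplacian(net, xa)$L
  r <- red$retained
  d <- red$deleted
  L22 <- L[d, d, drop = FALSE]
  kappa <- tryCatch(kappa(L22, exact = FALSE), error = function(e) Inf)
  if (!is.finite(kappa) || kappa > 1e12)
    stop("singular L22 block at state [",
         paste(sprintf("%s=%.6g", names(xa), xa), collapse = ", "), "]")
  L12 <- L[r, d, drop = FALSE]
  Lhat <- L[r, r, drop = FALSE] - L12 %*% solve(L22, L[d, r, drop = FALSE])
  vb <- boundary_flux_vector(net, xa)
  Pvb <- vb[r] - L12 %*% solve(L22, vb[d])
  w1 <- complex_monomials(red$Z1, xa)
  dx <- as.numeric(red$Z1 %*% (Pvb - Lhat %*% w1))
  names(dx) <- net$species$id
  dx[net$species$fixed] <- 0
  dx
}

#' Surviving directed reactions of a reduced network
#'
#' The edges of the reduced complex graph are read off the Schur-complemented
#' Laplacian evaluated at a reference state: a directed reaction
#' \eqn{\sigma \to \pi} survives iff \eqn{\hat L[\pi,\sigma] < 0}. Reversible
#' pairs are flagged.
#'
#' @param red a `crn_reduced` model.
#' @param x reference state (default: parent initial concentrations with
#'   frozen values merged, zeros nudged to a small positive value so the
#'   structure is generic).
#' @param tol threshold below which an entry counts as a structural zero.
#' @return Data frame with columns `substrate`, `product` (retained-complex
#'   labels), `weight` and `reversible`.
#' @export
reduced_reactions <- function(red, x = NULL, tol = 1e-12) {
  stopifnot(inherits(red, "crn_reduced"))
  net <- red$parent
  if (is.null(x)) {
    x <- stats::setNames(net$species$x0, net$species$id)
    x[x == 0] <- 1e-3
  }
  xa <- augment_state(red, x)
  L <- weighted_laplacian(net, xa)$L
  Lhat <- schur_complement(L, red$deleted)
  labs <- vapply(net$complexes, complex_label, character(1))[red$retained]
  out <- data.frame(substrate = character(), product = character(),
                    weight = numeric(), reversible = logical(),
                    stringsAsFactors = FALSE)
  n <- nrow(Lhat)
  for (s in seq_len(n)) for (p in seq_len(n)) {
    if (s == p) next
    if (Lhat[p, s] < -tol)
      out[nrow(out) + 1L, ] <- list(labs[s], labs[p], -Lhat[p, s],
                                    Lhat[s, p] < -tol)
  }
  out
}

#' Number of reversible-equivalent reactions in a reduced network
#'
#' Counts undirected edges of the reduced complex graph (a reversible pair
#' counts once, an irreversible edge also once).
#'
#' @inheritParams reduced_reactions
#' @return Integer count.
#' @export
count_reduced_reactions <- function(red, x = NULL) {
  rr <- reduced_reactions(red, x)
  if (nrow(rr) == 0) return(0L)
  key <- apply(rr[, c("substrate", "product")], 1,
               function(e) paste(sort(e), collapse = "|"))
  length(unique(key))
}

# --- structural support of the reduced graph -------------------------------

# undirected complex adjacency after structurally eliminating `deleted`
# one vertex at a time with Kron fill-in (neighbours of an eliminated vertex
# become pairwise adjacent)
reduced_support <- function(adj, deleted) {
  for (v in deleted) {
    nb <- which(adj[v, ])
    nb <- setdiff(nb, v)
    if (length(nb) > 1)
      for (i in nb) for (j in nb) if (i != j) adj[i, j] <- TRUE
    adj[v, ] <- FALSE
    adj[, v] <- FALSE
  }
  adj
}

# number of connected components of the species interaction graph implied by
# a complex adjacency structure: species are linked when they share a complex
# or their complexes are joined by an edge; only `species_keep` and
# `complex_keep` participate
species_components <- function(Z, adj, complex_keep) {
  m <- nrow(Z)
  keep_species <- which(rowSums(Z[, complex_keep, drop = FALSE] != 0) > 0)
  if (length(keep_species) == 0) return(0L)
  sadj <- matrix(FALSE, m, m)
  for (a in complex_keep) {
    members_a <- which(Z[, a] != 0)
    for (i in members_a) for (j in members_a) sadj[i, j] <- TRUE
    for (b in complex_keep) {
      if (b <= a || !adj[a, b]) next
      members_b <- which(Z[, b] != 0)
      for (i in members_a) for (j in members_b) {
        sadj[i, j] <- TRUE
        sadj[j, i] <- TRUE
      }
    }
  }
  comp <- integer(m)
  nc <- 0L
  for (v in keep_species) {
    if (comp[v] != 0L) next
    nc <- nc + 1L
    queue <- v
    comp[v] <- nc
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(sadj[u, ] & comp == 0L)
      nb <- intersect(nb, keep_species)
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  nc
}

#' Would deleting a complex disconnect the species interaction graph?
#'
#' Deleting a complex whose removal (with Kron fill-in on its neighbours)
#' splits the species into groups coupled by no surviving reaction breaks the
#' dynamics into independent parts; such deletions drastically change the
#' behaviour and are refused by default in the automated procedure.
#'
#' @param net a `crn` network.
#' @param idx complex index to test.
#' @param deleted complexes already structurally removed (default none).
#' @return Logical.
#' @export
is_disconnecting <- function(net, idx, deleted = integer()) {
  stopifnot(inherits(net, "crn"))
  Z <- complex_matrix(net)
  adj0 <- reduced_support(complex_adjacency_undirected(net), deleted)
  keep0 <- setdiff(seq_len(ncol(Z)), deleted)
  before <- species_components(Z, adj0, keep0)
  adj1 <- reduced_support(adj0, idx)
  keep1 <- setdiff(keep0, idx)
  after <- species_components(Z, adj1, keep1)
  after > before
}

#' Classify the structural effect of deleting one complex
#'
#' Relates a candidate deletion to the canonical linkage-class archetypes:
#' `type1` (a complex with exactly two reversible neighbours in a chain —
#' deletion shortens the chain), `type2` (one reversible and one irreversible
#' neighbour — the pair collapses to a single irreversible reaction), `type3`
#' (a hub in more than two reactions — deletion completely couples its
#' neighbours without reducing the reaction or parameter count),
#' `linkage_removal` (the complex sits in a two-complex reversible linkage
#' class, so deletion removes the whole class), `disconnecting` (deletion
#' splits reactions sharing no species into independent parts), and `other`.
#' A disconnecting deletion takes precedence over the remaining labels.
#'
#' @param net a `crn` network.
#' @param idx complex index.
#' @return One of `"type1"`, `"type2"`, `"type3"`, `"linkage_removal"`,
#'   `"disconnecting"`, `"other"`.
#' @export
classify_deletion <- function(net, idx) {
  stopifnot(inherits(net, "crn"))
  c_n <- length(net$complexes)
  if (idx < 1 || idx > c_n) stop("complex index out of range")
  if (is_disconnecting(net, idx)) return("disconnecting")
  fwd <- matrix(FALSE, c_n, c_n)
  for (r in net$reactions) fwd[r$substrate, r$product] <- TRUE
  neighbours <- which(fwd[idx, ] | fwd[, idx])
  deg <- length(neighbours)
  if (deg > 2) return("type3")
  lc <- linkage_classes(net)
  own <- lc[[which(vapply(lc, function(s) idx %in% s, logical(1)))]]
  if (length(own) == 2 && deg == 1 && fwd[idx, neighbours] && fwd[neighbours, idx])
    return("linkage_removal")
  if (deg == 2) {
    rev_nb <- vapply(neighbours, function(n) fwd[idx, n] && fwd[n, idx],
                     logical(1))
    if (all(rev_nb)) return("type1")
    if (sum(rev_nb) == 1) return("type2")
  }
  "other"
}
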