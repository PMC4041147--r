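# State-dependent weighted graph matrices of the complex graph and the
# compact network dynamics  xdot = -Z L(x) Exp(Z^T Ln x) + Z v_b(x).

#' Weighted adjacency matrix of the complex graph at a state
#'
#' Entry \eqn{(\pi,\sigma)} sums \eqn{k_j d_j(x)} over all reactions with
#' substrate complex \eqn{\sigma} and product complex \eqn{\pi}; parallel
#' edges accumulate, and absent reactions give zeros. All entries are
#' nonnegative for \eqn{x} in the nonnegative orthant.
#'
#' @param net a `crn` network.
#' @param x named nonnegative concentration vector (mM).
#' @return Nonnegative c-by-c matrix `A(x)`.
#' @export
weighted_adjacency <- function(net, x) {
  stopifnot(inherits(net, "crn"))
  x <- species_state(net, x)
  if (any(x < 0)) stop("negative concentration in state vector")
  c_n <- length(net$complexes)
  A <- matrix(0, c_n, c_n)
  for (r in net$reactions) {
    w <- r$law$k * r$law$d(x)
    if (!is.finite(w))
      stop("non-finite edge weight for reaction ",
           complex_label(net$complexes[[r$substrate]]), " -> ",
           complex_label(net$complexes[[r$product]]))
    A[r$product, r$substrate] <- A[r$product, r$substrate] + w
  }
  labs <- vapply(net$complexes, complex_label, character(1))
  dimnames(A) <- list(labs, labs)
  A
}

#' Weighted Laplacian of the complex graph at a state
#'
#' \eqn{L(x) = \Delta(x) - A(x)} with \eqn{\Delta} the diagonal matrix of
#' column sums of the weighted adjacency. Column sums of `L` are zero to
#' machine precision, its diagonal is nonnegative, and its off-diagonal
#' entries are nonpositive.
#'
#' @inheritParams weighted_adjacency
#' @return Object of class `crn_laplacian`: list with matrices `A`, `Delta`,
#'   `L` and the state `at_state`.
#' @export
weighted_laplacian <- function(net, x) {
  A <- weighted_adjacency(net, x)
  Delta <- diag(colSums(A), nrow = nrow(A))
  dimnames(Delta) <- dimnames(A)
  structure(list(A = A, Delta = Delta, L = Delta - A,
                 at_state = species_state(net, x)),
            class = "crn_laplacian")
}

#' @export
print.crn_laplacian <- function(x, ...) {
  cat("Weighted Laplacian at state:\n")
  print(signif(x$L, 4))
  invisible(x)
}

# w_alpha = prod_i x_i^Z[i,alpha] for every column of Z (0^0 := 1)
complex_monomials <- function(Z, x) {
  vapply(seq_len(ncol(Z)), function(a) monomial(Z[, a], x), numeric(1))
}

#' Right-hand side of the full network dynamics
#'
#' Evaluates \eqn{\dot x = -Z L(x) \mathrm{Exp}(Z^T \mathrm{Ln}\, x)
#' + Z v_b(x)} with the exponential-of-log term computed as the monomial
#' product \eqn{w_\alpha = \prod_i x_i^{Z_{i\alpha}}} (limit-consistent at
#' zero concentrations). Rows of externally clamped (`fixed`) species are
#' zeroed after assembly.
#'
#' @inheritParams weighted_adjacency
#' @return Named m-vector of concentration derivatives (mM/min).
#' @export
network_rhs <- function(net, x) {
  x <- species_state(net, x)
  Z <- complex_matrix(net)
  L <- weighted_laplacian(net, x)$L
  w <- complex_monomials(Z, x)
  vb <- boundary_flux_vector(net, x)
  dx <- as.numeric(-Z %*% (L %*% w) + Z %*% vb)
  if (any(!is.finite(dx))) {
    bad <- which(!is.finite(dx))
    stop("non-finite rate for species ", paste(net$species$id[bad], collapse = ", "))
  }
  names(dx) <- net$species$id
  dx[net$species$fixed] <- 0
  dx
}

#' Check the Laplacian factorisation of the reaction fluxes
#'
#' The flux term of the balance laws satisfies the algebraic identity
#' \eqn{B v(x) = -L(x)\,\mathrm{Exp}(Z^T \mathrm{Ln}\, x)}; this returns the
#' maximum deviation between the two sides relative to the flux magnitude,
#' which should be at the level of rounding error (<= 1e-10) for any network
#' and strictly positive state.
#'
#' @inheritParams weighted_adjacency
#' @return Scalar maximum relative deviation.
#' @export
laplacian_consistency <- function(net, x) {
  x <- species_state(net, x)
  if (any(x <= 0)) stop("consistency check needs a strictly positive state")
  Z <- complex_matrix(net)
  B <- incidence_matrix(net)
  v <- vapply(net$reactions,
              function(r) eval_rate(r$law, Z[, r$substrate], x), numeric(1))
  L <- weighted_laplacian(net, x)$L
  w <- complex_monomials(Z, x)
  max(abs(B %*% v + L %*% w)) / max(1, max(abs(B %*% v)))
}

#' Dump the graph matrices at a state to CSV (debugging aid)
#'
#' @inheritParams weighted_adjacency
#' @param dir directory to write `adjacency.csv`, `degree.csv`,
#'   `laplacian.csv` into.
#' @return Invisibly, the `crn_laplacian` object.
#' @export
dump_laplacian_csv <- function(net, x, dir) {
  lap <- weighted_laplacian(net, x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(lap$A, file.path(dir, "adjacency.csv"))
  utils::write.csv(lap$Delta, file.path(dir, "degree.csv"))
  utils::write.csv(lap$L, file.path(dir, "laplacian.csv"))
  invisible(lap)
}
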