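# Rate laws in the factored form v_j(x) = d_j(x) * k_j * prod_i x_i^(Z_Sj)_i,
# with d_j a rational function mapping the open positive orthant to positive
# reals. Every constructor returns an object carrying the proportionality
# constant `k`, the denominator closure `d` (over the full named species state)
# and enough parameter metadata to serialize and to count free parameters.

new_rate_law <- function(kind, k, d, params, param_names) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0)
    stop("proportionality constant k must be a positive finite scalar")
  structure(list(kind = kind, k = k, d = d, params = params,
                 param_names = param_names),
            class = "crn_rate_law")
}

#' @export
print.crn_rate_law <- function(x, ...) {
  cat(sprintf("rate law <%s>: k = %g, %d parameter(s)\n",
              x$kind, x$k, length(x$param_names)))
  invisible(x)
}

check_pos <- function(v, what) {
  if (any(!is.finite(v)) || any(v <= 0))
    stop(what, " must be positive and finite")
  invisible(v)
}

# resolve a modifier: a species id (concentration read from the state) or a
# fixed numeric value
modifier_value <- function(modifier, x) {
  if (is.character(modifier)) {
    if (!modifier %in% names(x))
      stop("modifier species '", modifier, "' not in state vector")
    unname(x[[modifier]])
  } else modifier
}

#' Mass-action rate law
#'
#' The degenerate factored form with denominator identically one:
#' \eqn{v(x) = k \prod_i x_i^{(Z_S)_i}}.
#'
#' @param k positive rate constant (units depend on the molecularity of the
#'   substrate complex).
#' @param name parameter name used when counting/serialising (`"k"`, or
#'   `"kf"`/`"kr"` for the two directions of a reversible pair).
#' @return A `crn_rate_law`.
#' @export
mass_action_law <- function(k, name = "k") {
  check_pos(k, "k")
  new_rate_law("mass_action", k, function(x) 1,
               params = list(k = k, name = name), param_names = name)
}

#' Reversible mass-action pair
#' @param kf,kr forward and reverse rate constants (positive).
#' @return List with elements `fwd` and `rev` for [reversible_reaction()].
#' @export
rev_mass_action_laws <- function(kf, kr) {
  list(fwd = mass_action_law(kf, name = "kf"),
       rev = mass_action_law(kr, name = "kr"))
}

# shared denominator of a (reversible) Michaelis-Menten law: a product of
# binding-site factors, each 1 + sum_{i in site} x_i/Km_i (+ modifier term)
mm_denominator <- function(Km, sites, inhibitor = NULL, Ki = NULL,
                           mode = "none") {
  force(Km); force(sites); force(inhibitor); force(Ki); force(mode)
  function(x) {
    p <- 1
    first <- TRUE
    for (site in sites) {
      f <- 1 + sum(x[site] / Km[site])
      if (first && mode == "competitive")
        f <- f + modifier_value(inhibitor, x) / Ki
      if (first && mode == "uncompetitive")
        f <- 1 + sum(x[site] / Km[site]) *
          (1 + modifier_value(inhibitor, x) / Ki)
      p <- p * f
      first <- FALSE
    }
    if (mode == "noncompetitive")
      p <- p * (1 + modifier_value(inhibitor, x) / Ki)
    1 / p
  }
}

#' Irreversible Michaelis-Menten law, optionally with a modifier
#'
#' For a single-site law \eqn{v = V (x_1/K_1)/(1 + x_1/K_1)} the factored
#' form has \eqn{k = V/K_1} and \eqn{d(x) = (1 + x_1/K_1)^{-1}}. A
#' competitive modifier adds \eqn{i/K_i} inside the binding factor; a
#' noncompetitive modifier multiplies the denominator by \eqn{(1 + i/K_i)};
#' an uncompetitive modifier scales the substrate term by \eqn{(1 + i/K_i)}.
#' Multi-substrate laws pass several `sites`, each a group of species sharing
#' one binding factor.
#'
#' @param V maximum rate (mM/min).
#' @param Km named vector of Michaelis constants (mM) for every species
#'   appearing in the denominator.
#' @param substrates character vector of substrate species ids; `k` is
#'   \eqn{V / \prod_{s} K_s} over these.
#' @param sites list of character vectors grouping species into binding
#'   factors; default one site per substrate.
#' @param inhibitor species id (resolved from the state) or a fixed numeric
#'   concentration (mM).
#' @param Ki inhibition constant (mM).
#' @param mode `"none"`, `"competitive"`, `"noncompetitive"` or
#'   `"uncompetitive"`.
#' @return A `crn_rate_law`.
#' @export
mm_law <- function(V, Km, substrates, sites = NULL, inhibitor = NULL,
                   Ki = NULL, mode = c("none", "competitive",
                                       "noncompetitive", "uncompetitive")) {
  mode <- match.arg(mode)
  check_pos(V, "V")
  check_pos(Km, "Km")
  if (is.null(names(Km))) stop("Km must be a named vector")
  if (is.null(sites)) sites <- as.list(substrates)
  missing <- setdiff(unlist(sites), names(Km))
  if (length(missing) > 0)
    stop("Km missing for species: ", paste(missing, collapse = ", "))
  if (mode != "none") {
    if (is.null(inhibitor) || is.null(Ki))
      stop("modifier laws need both inhibitor and Ki")
    check_pos(Ki, "Ki")
  }
  k <- V / prod(Km[substrates])
  kind <- switch(mode, none = "mm_irreversible",
                 competitive = "mm_competitive",
                 noncompetitive = "mm_noncompetitive",
                 uncompetitive = "mm_uncompetitive")
  pn <- c("V", paste0("Km.", names(Km)))
  if (mode != "none") pn <- c(pn, "Ki")
  new_rate_law(kind, k,
               mm_denominator(Km, sites, inhibitor, Ki, mode),
               params = list(V = V, Km = Km, substrates = substrates,
                             sites = sites, inhibitor = inhibitor, Ki = Ki,
                             mode = mode),
               param_names = pn)
}

#' Reversible Michaelis-Menten law pair with a shared denominator
#'
#' Builds the two directed halves of a reversible Michaelis-Menten reaction.
#' Both directions divide by the same binding polynomial
#' \eqn{\prod_{\mathrm{sites}} (1 + \sum_{i} x_i/K_i)}, in which substrate
#' and product species of the same binding site appear together; the forward
#' proportionality constant is \eqn{k_f = V_f / \prod_{\mathrm{substrates}} K_s}
#' and the reverse one \eqn{k_r = V_r / \prod_{\mathrm{products}} K_p}. The
#' pair satisfies detailed balance with \eqn{K_{eq} = k_f/k_r}.
#'
#' @param Vf,Vr maximum forward and reverse rates (mM/min).
#' @param Km named vector of Michaelis constants (mM) covering substrates and
#'   products.
#' @param substrates,products character vectors of species ids (of the
#'   forward direction).
#' @param sites list of character vectors grouping species into shared
#'   binding factors; default pairs `substrates[i]` with `products[i]`.
#' @return List with `fwd` and `rev` laws for [reversible_reaction()].
#' @examples
#' rev_mm_laws(Vf = 4, Vr = 2, Km = c(X1 = 1, X2 = 2, X3 = 1, X4 = 2),
#'             substrates = c("X1", "X2"), products = c("X3", "X4"))
#' @export
rev_mm_laws <- function(Vf, Vr, Km, substrates, products, sites = NULL) {
  check_pos(c(Vf, Vr), "Vf, Vr")
  check_pos(Km, "Km")
  if (is.null(sites)) {
    if (length(substrates) == length(products))
      sites <- lapply(seq_along(substrates),
                      function(i) c(substrates[i], products[i]))
    else
      sites <- list(c(substrates, products))
  }
  missing <- setdiff(c(substrates, products), names(Km))
  if (length(missing) > 0)
    stop("Km missing for species: ", paste(missing, collapse = ", "))
  d <- mm_denominator(Km, sites)
  kf <- Vf / prod(Km[substrates])
  kr <- Vr / prod(Km[products])
  pn <- paste0("Km.", names(Km))
  fwd <- new_rate_law("rev_mm_halfreaction", kf, d,
                      params = list(V = Vf, Km = Km, substrates = substrates,
                                    products = products, sites = sites,
                                    role = "forward"),
                      param_names = c("Vf", pn))
  rev <- new_rate_law("rev_mm_halfreaction", kr, d,
                      params = list(V = Vr, Km = Km, substrates = products,
                                    products = substrates, sites = sites,
                                    role = "reverse"),
                      param_names = c("Vr", pn))
  list(fwd = fwd, rev = rev)
}

#' Hill rate law
#'
#' \eqn{v = V (x/K)^n / (1 + (x/K)^n)} on a unimolecular substrate complex,
#' factored as \eqn{k = V/K^n} with
#' \eqn{d(x) = x^{n-1}/(1 + (x/K)^n)} so that, combined with the complex
#' monomial \eqn{x}, the full Hill exponent is recovered. `d` maps the open
#' positive orthant to positive reals for any real exponent \eqn{n \ge 1}.
#'
#' @param V maximum rate (mM/min).
#' @param K half-saturation constant (mM).
#' @param n Hill exponent, real, `n >= 1`.
#' @param species id of the substrate species.
#' @return A `crn_rate_law`.
#' @export
hill_law <- function(V, K, n, species) {
  check_pos(c(V, K), "V, K")
  if (!is.numeric(n) || n < 1) stop("Hill exponent n must be >= 1")
  force(species)
  d <- function(x) {
    xs <- unname(x[[species]])
    xs^(n - 1) / (1 + (xs / K)^n)
  }
  new_rate_law("hill", V / K^n, d,
               params = list(V = V, K = K, n = n, species = species),
               param_names = c("V", "K", "n"))
}

#' Custom-denominator rate law
#'
#' Escape hatch for rate laws outside the built-in catalogue: any
#' user-supplied denominator function, which must map the open positive
#' orthant to positive reals ([check_denominator_positivity()] probes this by
#' sampling before the law is trusted in a simulation).
#'
#' @param k positive proportionality constant.
#' @param d function of the full named species state returning a positive
#'   scalar.
#' @param param_names names of the free parameters the law carries (for
#'   counting); default `"k"`.
#' @return A `crn_rate_law`.
#' @export
custom_law <- function(k, d, param_names = "k") {
  stopifnot(is.function(d))
  new_rate_law("custom_denominator", k, d, params = list(k = k),
               param_names = param_names)
}

#' Build a rate law from a kind keyword and a parameter list
#'
#' Dispatch wrapper over the typed constructors, used by the JSON/SBML
#' readers.
#'
#' @param kind one of `"mass_action"`, `"mm_irreversible"`,
#'   `"mm_competitive"`, `"mm_noncompetitive"`, `"mm_uncompetitive"`,
#'   `"rev_mm_halfreaction"`, `"hill"`, `"custom_denominator"`.
#' @param params named list of parameters as taken by the matching
#'   constructor.
#' @return A `crn_rate_law` (for `rev_mm_halfreaction`, the directed half
#'   described by `params$role`).
#' @export
make_rate_law <- function(kind, params) {
  switch(kind,
    mass_action = mass_action_law(params$k,
                                  name = if (is.null(params$name)) "k" else params$name),
    mm_irreversible = ,
    mm_competitive = ,
    mm_noncompetitive = ,
    mm_uncompetitive = {
      mode <- switch(kind, mm_irreversible = "none",
                     mm_competitive = "competitive",
                     mm_noncompetitive = "noncompetitive",
                     mm_uncompetitive = "uncompetitive")
      mm_law(params$V, unlist(params$Km), unlist(params$substrates),
             sites = params$sites, inhibitor = params$inhibitor,
             Ki = params$Ki, mode = mode)
    },
    rev_mm_halfreaction = {
      Km <- unlist(params$Km)
      subs <- unlist(params$substrates)
      d <- mm_denominator(Km, params$sites)
      pn <- c(if (identical(params$role, "reverse")) "Vr" else "Vf",
              paste0("Km.", names(Km)))
      new_rate_law("rev_mm_halfreaction", params$V / prod(Km[subs]), d,
                   params = params, param_names = pn)
    },
    hill = hill_law(params$V, params$K, params$n, params$species),
    custom_denominator = stop("custom_denominator laws cannot be rebuilt from parameters"),
    stop("unknown rate law kind: ", kind))
}

# complex monomial prod_i x_i^z_i with the 0^0 := 1 limit convention,
# so evaluation is continuous down to the boundary of the orthant
monomial <- function(z, x) {
  nz <- which(z != 0)
  if (length(nz) == 0) return(1)
  prod(x[nz]^z[nz])
}

#' Evaluate a rate law at a state
#'
#' Computes \eqn{v = d(x)\, k \prod_i x_i^{(Z_S)_i}}, taking the monomial
#' product directly (with \eqn{0^0 := 1}) so the limit at states with zero
#' concentrations is used instead of a log-of-zero.
#'
#' @param law a `crn_rate_law`.
#' @param Z_S integer stoichiometry column of the substrate complex (species
#'   order of `x`).
#' @param x named nonnegative concentration vector (mM).
#' @return Flux (mM/min).
#' @export
eval_rate <- function(law, Z_S, x) {
  stopifnot(inherits(law, "crn_rate_law"))
  if (any(x < 0)) stop("negative concentration in state vector")
  mon <- monomial(Z_S, x)
  if (mon == 0) return(0)
  law$d(x) * law$k * mon
}

#' Probe denominator positivity by sampling the positive orthant
#'
#' The reduction method's validity rests on every denominator mapping the
#' open positive orthant to positive reals. This check samples states
#' log-uniformly over several decades and fails with a witness point if any
#' denominator value is nonpositive or non-finite.
#'
#' @param law a `crn_rate_law`.
#' @param species_ids character vector naming the state components to sample.
#' @param n_samples number of sampled states (default 1000).
#' @param seed RNG seed (default 1).
#' @param range log10 sampling range in mM (default `c(-3, 3)`).
#' @return List with `pass` (logical) and, on failure, `witness` (the state)
#'   and `value`.
#' @export
check_denominator_positivity <- function(law, species_ids, n_samples = 1000,
                                         seed = 1, range = c(-3, 3)) {
  stopifnot(inherits(law, "crn_rate_law"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(n_samples)) {
    x <- stats::setNames(10^stats::runif(length(species_ids), range[1], range[2]),
                         species_ids)
    v <- law$d(x)
    if (!is.finite(v) || v <= 0)
      return(list(pass = FALSE, witness = x, value = v))
  }
  list(pass = TRUE)
}
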