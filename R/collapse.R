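# Symbolic collapse of a two-step reversible Michaelis-Menten chain
# S <=> I <=> P into a single reversible reaction S <=> P.  Imposing complex
# balancing on the intermediate complex expresses the product of the
# intermediate concentrations in terms of the end species; freezing the
# intermediates inside the two binding polynomials then yields a closed-form
# enzyme-kinetic law
#
#   v(x) = (kf_red * prod(substrates) - kr_red * prod(products)) / D(x)
#
# whose denominator D is again a positive rational function, and whose
# equilibrium constant composes: Keq_red = KeqI * KeqII.

# decompose one binding site of a frozen-step law: constant part
# a = 1 + sum_{frozen} xf/Km, plus the single retained species with its Km
site_decompose <- function(site, Km, retained, frozen) {
  ret <- intersect(site, retained)
  frz <- intersect(site, names(frozen))
  if (length(ret) != 1)
    stop("chain collapse needs exactly one retained species per binding site")
  list(a = 1 + sum(frozen[frz] / Km[frz]), species = ret, Km = unname(Km[ret]))
}

#' Collapse a reversible Michaelis-Menten chain step pair symbolically
#'
#' Given the two reversible Michaelis-Menten reactions of a chain
#' \eqn{S \rightleftharpoons I \rightleftharpoons P} sharing the intermediate
#' complex \eqn{I}, and frozen concentrations for the intermediate species,
#' returns the closed-form collapsed law of the reduced reaction
#' \eqn{S \rightleftharpoons P}: reduced rate constants `kf_red`, `kr_red`
#' and reduced saturation constants (one per end species plus one per end
#' species pair for bimolecular complexes), 8 parameters in the bimolecular
#' case versus 12 in the original chain, 4 versus 8 in the unimolecular case.
#' The collapsed equilibrium constant is the product of the step equilibrium
#' constants.
#'
#' @param step1,step2 law pairs from [rev_mm_laws()] (lists with `fwd` and
#'   `rev`); the products of `step1` must equal the substrates of `step2`
#'   (the intermediate complex).
#' @param frozen named positive concentrations (mM) for every intermediate
#'   species.
#' @return Object of class `crn_collapsed_law`: reduced constants
#'   (`kf_red`, `kr_red`, `Km_red`), the end species, and `Keq_red`.
#' @export
collapse_rev_mm_chain <- function(step1, step2, frozen) {
  for (st in list(step1, step2))
    if (!is.list(st) || !inherits(st$fwd, "crn_rate_law") ||
        st$fwd$kind != "rev_mm_halfreaction")
      stop("chain collapse applies to reversible Michaelis-Menten steps only")
  p1 <- step1$fwd$params
  p2 <- step2$fwd$params
  inter <- sort(p1$products)
  if (!identical(inter, sort(p2$substrates)))
    stop("steps do not share an intermediate complex")
  if (!all(inter %in% names(frozen)))
    stop("missing frozen concentration for intermediate species: ",
         paste(setdiff(inter, names(frozen)), collapse = ", "))
  frozen <- frozen[inter]
  if (any(!is.finite(frozen)) || any(frozen <= 0))
    stop("frozen concentrations must be positive")

  kfI <- step1$fwd$k
  krI <- step1$rev$k
  kfII <- step2$fwd$k
  krII <- step2$rev$k

  sub_sites <- lapply(p1$sites, site_decompose, Km = p1$Km,
                      retained = p1$substrates, frozen = frozen)
  prod_sites <- lapply(p2$sites, site_decompose, Km = p2$Km,
                       retained = p2$products, frozen = frozen)
  if (length(sub_sites) > 2 || length(prod_sites) > 2)
    stop("chain collapse implemented for one or two binding sites per step")

  c0 <- kfII * prod(vapply(sub_sites, `[[`, numeric(1), "a")) +
        krI * prod(vapply(prod_sites, `[[`, numeric(1), "a"))

  # expand k * prod_i (a_i + x_i/K_i) and normalise the constant term to 1:
  # per-species terms, plus one pairwise term when there are two sites
  side_terms <- function(sites, kconst) {
    terms <- list()
    n <- length(sites)
    for (i in seq_len(n)) {
      other_a <- prod(vapply(sites[-i], `[[`, numeric(1), "a"))
      terms[[sites[[i]]$species]] <-
        c0 * sites[[i]]$Km / (kconst * other_a)
    }
    if (n == 2) {
      pair <- paste(vapply(sites, `[[`, character(1), "species"),
                    collapse = ":")
      terms[[pair]] <- c0 * prod(vapply(sites, `[[`, numeric(1), "Km")) /
        kconst
    }
    terms
  }
  Km_red <- c(side_terms(sub_sites, kfII), side_terms(prod_sites, krI))

  structure(list(
    kf_red = kfI * kfII / c0,
    kr_red = krI * krII / c0,
    Km_red = unlist(Km_red),
    substrates = p1$substrates,
    products = p2$products,
    frozen = frozen,
    Keq_red = (kfI * kfII) / (krI * krII)
  ), class = "crn_collapsed_law")
}

#' @export
print.crn_collapsed_law <- function(x, ...) {
  cat(sprintf("Collapsed reversible law %s <=> %s\n",
              paste(x$substrates, collapse = "+"),
              paste(x$products, collapse = "+")))
  cat(sprintf("  kf_red = %.6g, kr_red = %.6g, Keq_red = %.6g\n",
              x$kf_red, x$kr_red, x$Keq_red))
  cat(sprintf("  %d parameters: %s\n", collapsed_parameter_count(x),
              paste(c("kf_red", "kr_red", names(x$Km_red)), collapse = ", ")))
  invisible(x)
}

#' Number of free parameters of a collapsed law
#' @param claw a `crn_collapsed_law`.
#' @return Integer (8 for a bimolecular chain, 4 for a unimolecular one).
#' @export
collapsed_parameter_count <- function(claw) {
  stopifnot(inherits(claw, "crn_collapsed_law"))
  2L + length(claw$Km_red)
}

# denominator polynomial of the collapsed law at a state
collapsed_denominator <- function(claw, x) {
  D <- 1
  for (nm in names(claw$Km_red)) {
    sp <- strsplit(nm, ":", fixed = TRUE)[[1]]
    D <- D + prod(x[sp]) / claw$Km_red[[nm]]
  }
  D
}

#' Evaluate the net forward rate of a collapsed law
#'
#' @param claw a `crn_collapsed_law`.
#' @param x named nonnegative concentration vector covering the end species.
#' @return Net flux (mM/min) in the forward direction of the collapsed
#'   reaction.
#' @export
eval_collapsed <- function(claw, x) {
  stopifnot(inherits(claw, "crn_collapsed_law"))
  (claw$kf_red * prod(x[claw$substrates]) -
     claw$kr_red * prod(x[claw$products])) / collapsed_denominator(claw, x)
}

#' Turn a collapsed law into a directed law pair
#'
#' The two directions share the collapsed denominator, so the pair carries
#' the collapsed parameter count and satisfies detailed balance at
#' `Keq_red`. Usable with [reversible_reaction()] to build the reduced
#' network explicitly.
#'
#' @param claw a `crn_collapsed_law`.
#' @return List with `fwd` and `rev` `crn_rate_law` objects.
#' @export
collapsed_to_laws <- function(claw) {
  stopifnot(inherits(claw, "crn_collapsed_law"))
  d <- function(x) 1 / collapsed_denominator(claw, x)
  kms <- paste0("Km_red.", names(claw$Km_red))
  list(fwd = new_rate_law("custom_denominator", claw$kf_red, d,
                          params = list(collapsed = claw, role = "forward"),
                          param_names = c("kf_red", kms)),
       rev = new_rate_law("custom_denominator", claw$kr_red, d,
                          params = list(collapsed = claw, role = "reverse"),
                          param_names = c("kr_red", kms)))
}
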