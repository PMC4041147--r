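# Automated choice of complexes to delete: steady state, error integral,
# candidate ranking, and the greedy iterative reduction with a cutoff.

#' Define a reduction scenario
#'
#' A scenario fixes the dynamic event under which reduction error is
#' measured: a step change of externally clamped species at t = 0 (e.g. a
#' glucose upshift of the medium concentration from 0.2 to 5 mM), or an
#' explicit initial state displaced from the steady state for closed
#' networks; the observation horizon; the significant species against which
#' the error integral is computed (complexes containing them are never
#' deleted); and the dimensionless stopping cutoff.
#'
#' @param T horizon (min), positive.
#' @param significant nonempty character vector of significant species ids.
#' @param cutoff dimensionless error bound at which the greedy procedure
#'   stops (default 0.1).
#' @param perturb named numeric vector of step changes applied at t = 0 to
#'   `fixed` species (new clamped values, mM).
#' @param x0 optional explicit event initial state (mM); when omitted the
#'   event starts from the pre-event steady state with `perturb` applied.
#' @return Object of class `crn_scenario`.
#' @export
scenario <- function(T, significant, cutoff = 0.1, perturb = NULL,
                     x0 = NULL) {
  stopifnot(is.numeric(T), length(T) == 1, T > 0)
  if (length(significant) == 0) stop("significant species set must be nonempty")
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff >= 0)
  if (!is.null(perturb) && (is.null(names(perturb)) || any(perturb < 0)))
    stop("perturb must be a named vector of nonnegative clamped values")
  structure(list(T = T, significant = as.character(significant),
                 cutoff = cutoff, perturb = perturb, x0 = x0),
            class = "crn_scenario")
}

apply_perturbation <- function(net, perturb) {
  if (is.null(perturb) || length(perturb) == 0) return(net)
  idx <- match(names(perturb), net$species$id)
  if (any(is.na(idx)))
    stop("perturbed species not in network: ",
         paste(names(perturb)[is.na(idx)], collapse = ", "))
  if (!all(net$species$fixed[idx]))
    stop("perturbation steps are only defined for fixed (clamped) species")
  net$species$x0[idx] <- unname(perturb)
  net
}

#' Find a steady state of a network
#'
#' Long stiff integration with horizon doubling until the right-hand side
#' norm satisfies `||rhs||_inf <= tol * max(1, ||x||_inf)`, followed by a
#' Moore-Penrose Newton refinement (kept only when it lowers the residual;
#' conservation laws make the Jacobian singular, so a pseudoinverse step is
#' used). The network must be asymptotically stable near the sought state;
#' divergence or non-convergence within the budget raises an error carrying
#' the trajectory tail.
#'
#' @param net a `crn` network (or `crn_reduced` model).
#' @param x0 starting concentrations (default: the species table).
#' @param tol residual tolerance (default 1e-9).
#' @param t_init initial integration horizon (min).
#' @param max_doublings budget of horizon doublings (default 30).
#' @return Named steady-state concentration vector.
#' @examples
#' find_steady_state(two_state_network())  # c(A = 1, B = 2)
#' @export
find_steady_state <- function(net, x0 = NULL, tol = 1e-9, t_init = 1,
                              max_doublings = 30) {
  rhs <- model_rhs_fn(net)
  if (is.null(x0)) x0 <- default_x0(net)
  sp <- model_species(net)
  x <- stats::setNames(as.numeric(x0[sp$id]), sp$id)
  resid <- function(x) max(abs(rhs(x)))
  ok <- function(x) resid(x) <= tol * max(1, max(abs(x)))
  horizon <- t_init
  tail_states <- NULL
  for (it in seq_len(max_doublings)) {
    if (ok(x)) break
    traj <- simulate_network(net, x0 = x, T = horizon, n_out = 11,
                             rtol = 1e-10, atol = 1e-12)
    x_new <- traj$states[nrow(traj$states), ]
    tail_states <- utils::tail(traj$states, 3)
    if (any(!is.finite(x_new)) || max(abs(x_new)) > 1e8)
      stop("trajectory diverges while searching for a steady state")
    x <- x_new
    horizon <- horizon * 2
  }
  # pseudoinverse Newton polish (free species only)
  free <- !sp$fixed
  for (it in 1:8) {
    f <- rhs(x)[free]
    if (max(abs(f)) == 0) break
    J <- numeric_jacobian(function(z) {
      xx <- x
      xx[free] <- z
      rhs(xx)[free]
    }, x[free])
    step <- tryCatch(-as.numeric(MASS::ginv(J) %*% f),
                     error = function(e) NULL)
    if (is.null(step)) break
    x_try <- x
    x_try[free] <- pmax(x[free] + step, 0)
    if (max(abs(rhs(x_try))) < max(abs(rhs(x)))) x <- x_try else break
  }
  if (!ok(x))
    stop("no steady-state convergence within budget; residual ",
         format(resid(x)), "; trajectory tail:\n",
         paste(utils::capture.output(print(tail_states)), collapse = "\n"))
  x
}

numeric_jacobian <- function(f, x, eps = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- max(x[i] - h, 0)
    J[, i] <- (f(xp) - f(xm)) / (xp[i] - xm[i])
  }
  J
}

trapezoid <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Error integral between full-model and reduced-model trajectories
#'
#' The dimensionless, time- and species-averaged relative deviation
#' \deqn{I = \sum_{i \in M_I} \frac{1}{T\, n(M_I)} \int_0^T
#'   \left| 1 - \frac{x_i^r(t)}{x_i^f(t)} \right| dt,}
#' computed by the trapezoid rule on the union of the two solver grids
#' restricted to `[0, T]`. The integrand uses the absolute value: a signed
#' integrand could cancel and report spurious agreement.
#'
#' @param full_traj,reduced_traj [crn_trajectory()] objects covering
#'   `[0, T]` for all significant species.
#' @param species character vector of significant species ids.
#' @param T horizon (min).
#' @return Object of class `crn_error`: list with `I` (the mean), the
#'   `per_species` contributions, and `T_used`.
#' @export
error_integral <- function(full_traj, reduced_traj, species, T) {
  stopifnot(inherits(full_traj, "crn_trajectory"),
            inherits(reduced_traj, "crn_trajectory"))
  if (max(full_traj$times) < T || max(reduced_traj$times) < T)
    stop("both trajectories must cover [0, T]")
  missing <- setdiff(species, intersect(colnames(full_traj$states),
                                        colnames(reduced_traj$states)))
  if (length(missing) > 0)
    stop("species missing from a trajectory: ", paste(missing, collapse = ", "))
  tt <- sort(unique(c(full_traj$times, reduced_traj$times, 0, T)))
  tt <- tt[tt >= 0 & tt <= T]
  per <- vapply(species, function(s) {
    xf <- stats::approx(full_traj$times, full_traj$states[, s], xout = tt)$y
    xr <- stats::approx(reduced_traj$times, reduced_traj$states[, s],
                        xout = tt)$y
    if (any(xf <= 0))
      stop("full-model concentration of ", s,
           " reaches zero; relative error undefined")
    trapezoid(tt, abs(1 - xr / xf)) / T
  }, numeric(1))
  structure(list(I = mean(per), per_species = per, T_used = T),
            class = "crn_error")
}

#' @export
print.crn_error <- function(x, ...) {
  cat(sprintf("Error integral I = %.4g over [0, %g] min\n", x$I, x$T_used))
  invisible(x)
}

# event initial state and the (cached) full-model trajectory for a scenario
scenario_event <- function(net, scen, x_ss) {
  net_post <- apply_perturbation(net, scen$perturb)
  x_start <- if (!is.null(scen$x0)) {
    x <- stats::setNames(net$species$x0, net$species$id)
    x[names(scen$x0)] <- scen$x0
    x
  } else x_ss
  if (!is.null(scen$perturb))
    x_start[names(scen$perturb)] <- scen$perturb
  list(net = net_post, x0 = species_state(net, x_start))
}

protected_complexes <- function(net, significant) {
  Z <- complex_matrix(net)
  sig <- intersect(significant, rownames(Z))
  which(colSums(Z[sig, , drop = FALSE] != 0) > 0)
}

#' Rank candidate deletions by error integral
#'
#' For every deletable complex (not containing a significant species, not
#' already deleted, and not disconnecting unless allowed), builds the
#' one-more-complex-deleted reduced model with eliminated species frozen at
#' the original network's pre-event steady state, simulates the scenario for
#' it, and computes the error integral against the (cached) full-model
#' trajectory. Candidates are returned sorted ascending by `I`, ties broken
#' by complex index.
#'
#' @param net a `crn` network (pre-event clamped values).
#' @param scen a [scenario()].
#' @param x_ss pre-event steady state (from [find_steady_state()]).
#' @param deleted complexes already deleted in previous greedy steps.
#' @param allow_disconnecting permit deletions that split the species
#'   interaction graph (default `FALSE`).
#' @param full_traj optional cached full-model trajectory of the event.
#' @return Data frame with columns `complex` (index), `label`, `I`,
#'   `classification`, sorted ascending by `I`.
#' @export
rank_candidates <- function(net, scen, x_ss, deleted = integer(),
                            allow_disconnecting = FALSE, full_traj = NULL) {
  stopifnot(inherits(net, "crn"), inherits(scen, "crn_scenario"))
  ev <- scenario_event(net, scen, x_ss)
  if (is.null(full_traj))
    full_traj <- simulate_network(ev$net, x0 = ev$x0, T = scen$T)
  labs <- vapply(net$complexes, complex_label, character(1))
  prot <- protected_complexes(net, scen$significant)
  candidates <- setdiff(seq_along(net$complexes), union(deleted, prot))
  rows <- list()
  for (cand in candidates) {
    if (!allow_disconnecting && is_disconnecting(net, cand, deleted)) next
    I_val <- tryCatch({
      red <- delete_complexes(ev$net, c(deleted, cand), frozen = x_ss)
      red_traj <- simulate_network(red, x0 = ev$x0, T = scen$T)
      error_integral(full_traj, red_traj, scen$significant, scen$T)$I
    }, error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <-
      data.frame(complex = cand, label = labs[cand], I = I_val,
                 classification = classify_deletion(net, cand),
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(complex = integer(), label = character(),
                      I = numeric(), classification = character(),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, rows)
  tab <- tab[!is.na(tab$I), , drop = FALSE]
  if (nrow(tab) == 0)
    stop("all candidate deletions failed to simulate")
  tab[order(tab$I, tab$complex), , drop = FALSE]
}

#' Greedy stepwise model reduction
#'
#' The automated procedure: find the pre-event steady state, then repeatedly
#' (i) rank the remaining deletable complexes by error integral and
#' (ii) delete the one with the smallest `I`, stopping when the best
#' candidate's `I` exceeds the scenario cutoff (the model from the previous
#' accepted step is returned) or when no candidates remain.
#'
#' @param net a `crn` network.
#' @param scen a [scenario()].
#' @param x0 starting concentrations for the steady-state search.
#' @param allow_disconnecting permit disconnecting deletions.
#' @param verbose log each accepted step.
#' @return List with `reduced` (a `crn_reduced`, or `NULL` when no deletion
#'   was accepted) and `trace` (a `crn_reduction_trace`: ordered steps with
#'   per-step minimum error integrals and ranking tables, and the stopping
#'   reason).
#' @export
greedy_reduce <- function(net, scen, x0 = NULL, allow_disconnecting = FALSE,
                          verbose = FALSE) {
  stopifnot(inherits(net, "crn"), inherits(scen, "crn_scenario"))
  x_ss <- find_steady_state(net, x0 = x0)
  ev <- scenario_event(net, scen, x_ss)
  full_traj <- simulate_network(ev$net, x0 = ev$x0, T = scen$T)
  deleted <- integer()
  steps <- list()
  stopped <- "exhausted"
  repeat {
    tab <- tryCatch(
      rank_candidates(net, scen, x_ss, deleted = deleted,
                      allow_disconnecting = allow_disconnecting,
                      full_traj = full_traj),
      error = function(e) NULL)
    if (is.null(tab) || nrow(tab) == 0) {
      stopped <- "no_candidates"
      break
    }
    best <- tab[1, ]
    if (best$I > scen$cutoff) {
      stopped <- "cutoff"
      break
    }
    deleted <- c(deleted, best$complex)
    steps[[length(steps) + 1L]] <-
      list(complex = best$complex, label = best$label, I = best$I,
           ranking = tab)
    if (verbose)
      message(sprintf("step %d: delete %s (I = %.4g)",
                      length(steps), best$label, best$I))
    if (length(deleted) >= length(net$complexes) - 1L) {
      stopped <- "exhausted"
      break
    }
  }
  trace <- structure(list(steps = steps, stopped_because = stopped),
                     class = "crn_reduction_trace")
  reduced <- if (length(deleted) > 0)
    delete_complexes(ev$net, deleted, frozen = x_ss) else NULL
  list(reduced = reduced, trace = trace)
}

#' @export
print.crn_reduction_trace <- function(x, ...) {
  cat(sprintf("Reduction trace: %d deletion(s), stopped because: %s\n",
              length(x$steps), x$stopped_because))
  for (i in seq_along(x$steps))
    cat(sprintf("  %d. delete %s  (min I = %.4g)\n", i, x$steps[[i]]$label,
                x$steps[[i]]$I))
  invisible(x)
}

#' Export a reduction trace
#'
#' @param trace a `crn_reduction_trace`.
#' @param path output file; `.json` or `.csv` chosen by `format`.
#' @param format `"json"` or `"csv"`.
#' @return Invisibly, the path.
#' @export
write_trace <- function(trace, path, format = c("json", "csv")) {
  format <- match.arg(format)
  tab <- data.frame(step = seq_along(trace$steps),
                    complex = vapply(trace$steps, `[[`, character(1), "label"),
                    I = vapply(trace$steps, `[[`, numeric(1), "I"))
  if (format == "json")
    jsonlite::write_json(list(steps = tab,
                              stopped_because = trace$stopped_because),
                         path, auto_unbox = TRUE, digits = NA)
  else utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Closed-form count of candidate simulations of a full greedy run
#'
#' Reducing an N-species model down to L species while M species are
#' protected (one unimolecular complex per species, no refused deletions)
#' costs \eqn{\sum_{i=L}^{N} (i - M)} error-integral simulations.
#'
#' @param N original species count.
#' @param M protected species count.
#' @param L species count of the final reduced model.
#' @return Integer simulation count.
#' @examples
#' simulation_count(43, 14, 31)  # 299
#' @export
simulation_count <- function(N, M, L) {
  stopifnot(L <= N, M <= L)
  as.integer(sum(seq(L, N) - M))
}

#' 95% convergence times after a perturbation event
#'
#' The time each species needs to achieve 95% of its concentration change
#' between the pre-event and post-event steady states: the first time
#' \eqn{t^*} with \eqn{|x(t) - x_{new}| \le 0.05\, |x_{new} - x_{old}|} for
#' all \eqn{t \ge t^*}, read from a dense simulated trajectory. Species with
#' no concentration change report 0 and are flagged.
#'
#' @param net a `crn` network.
#' @param scen a [scenario()].
#' @param species ids to report (default: all non-clamped species).
#' @param n_out trajectory grid density (default 2001).
#' @return Data frame with columns `species`, `time` (min) and `changed`.
#' @export
convergence_times <- function(net, scen, species = NULL, n_out = 2001) {
  stopifnot(inherits(net, "crn"), inherits(scen, "crn_scenario"))
  if (is.null(species))
    species <- net$species$id[!net$species$fixed]
  x_old <- find_steady_state(net)
  ev <- scenario_event(net, scen, x_old)
  x_new <- find_steady_state(ev$net, x0 = ev$x0)
  traj <- simulate_network(ev$net, x0 = ev$x0, T = scen$T, n_out = n_out)
  out <- data.frame(species = species, time = NA_real_, changed = TRUE)
  for (i in seq_along(species)) {
    s <- species[i]
    delta <- abs(x_new[s] - x_old[s])
    if (delta <= 1e-12 * max(1, abs(x_new[s]))) {
      out$time[i] <- 0
      out$changed[i] <- FALSE
      next
    }
    dev <- abs(traj$states[, s] - x_new[s]) / delta
    inside <- dev <= 0.05
    # first index after which the trajectory stays inside the 5% band
    stay <- rev(cumprod(rev(inside))) == 1
    out$time[i] <- if (any(stay)) traj$times[which(stay)[1]] else NA_real_
  }
  out
}
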