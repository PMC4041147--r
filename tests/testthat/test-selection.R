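test_that("steady state of the two-state network matches detailed balance", {
  # kf a = kr b with a + b = 3 gives (1, 2)
  x_ss <- find_steady_state(two_state_network())
  expect_equal(unname(x_ss), c(1, 2), tolerance = 1e-8)
  # conservation respected: total mass equals the initial total
  expect_equal(sum(x_ss), 3, tolerance = 1e-8)
})

test_that("open-chain steady states satisfy the residual postcondition", {
  net <- example1_network(open = TRUE)
  x_ss <- find_steady_state(net, t_init = 5)
  expect_lt(max(abs(network_rhs(net, x_ss))),
            1e-9 * max(1, max(abs(x_ss))))

  cc <- clamped_input_chain()
  x_ss2 <- find_steady_state(cc)
  expect_lt(max(abs(network_rhs(cc, x_ss2))), 1e-9 * max(1, max(abs(x_ss2))))
  expect_equal(unname(x_ss2[["Sin"]]), 0.2)  # clamped input untouched
})

test_that("conserved moieties are preserved by the steady-state search", {
  net <- example1_network()
  x0 <- stats::setNames(net$species$x0, net$species$id)
  x_ss <- find_steady_state(net, t_init = 5)
  G <- conservation_laws(net)
  expect_equal(as.numeric(t(G) %*% x_ss), as.numeric(t(G) %*% x0),
               tolerance = 1e-6)
})

test_that("error integral closed forms: identical, constant-ratio and averaged cases", {
  tt <- seq(0, 2, length.out = 41)
  xf <- flat_trajectory(tt, c(A = 1, B = 2))

  expect_equal(error_integral(xf, xf, c("A", "B"), T = 2)$I, 0)

  xr <- flat_trajectory(tt, c(A = 0.9, B = 2))
  expect_equal(error_integral(xf, xr, "A", T = 2)$I, 0.1)

  xr2 <- flat_trajectory(tt, c(A = 0.9, B = 2.4))
  rep2 <- error_integral(xf, xr2, c("A", "B"), T = 2)
  expect_equal(rep2$I, 0.15)
  expect_equal(unname(rep2$per_species), c(0.1, 0.2))
  expect_equal(rep2$I, mean(rep2$per_species))

  # zero full-model concentration is an error, not an Inf
  x0f <- flat_trajectory(tt, c(A = 0, B = 2))
  expect_error(error_integral(x0f, xr, "A", T = 2), "zero")
})

test_that("error integral is invariant under rescaling of concentration units", {
  tt <- seq(0, 1.5, length.out = 31)
  set.seed(43)
  f <- matrix(runif(62, 0.5, 2), ncol = 2, dimnames = list(NULL, c("A", "B")))
  r <- f * matrix(runif(62, 0.8, 1.2), ncol = 2)
  tf <- crn_trajectory(tt, f)
  tr <- crn_trajectory(tt, r)
  I1 <- error_integral(tf, tr, c("A", "B"), T = 1.5)$I
  I2 <- error_integral(crn_trajectory(tt, f * 1000),
                       crn_trajectory(tt, r * 1000),
                       c("A", "B"), T = 1.5)$I
  expect_equal(I1, I2, tolerance = 1e-12)
})

test_that("candidate ranking protects significant-species complexes", {
  net <- example1_network(open = TRUE)
  x_ss <- find_steady_state(net, t_init = 5)
  x_event <- x_ss
  x_event[c("X1", "X2")] <- 1.5 * x_event[c("X1", "X2")]
  scen <- scenario(T = 3, significant = c("X1", "X2", "X5", "X6"),
                   cutoff = 0.1, x0 = x_event)
  tab <- rank_candidates(net, scen, x_ss)
  expect_identical(nrow(tab), 1L)            # only the intermediate complex
  expect_identical(tab$label, "X3+X4")
  expect_true(tab$I >= 0)
  # protecting X3 removes the last candidate
  scen2 <- scenario(T = 3, significant = c("X1", "X3", "X5"), x0 = x_event)
  tab2 <- rank_candidates(net, scen2, x_ss)
  expect_identical(nrow(tab2), 0L)
})

test_that("greedy reduction deletes the intermediate complex and stops when exhausted", {
  net <- example1_network(open = TRUE)
  x_event <- find_steady_state(net, t_init = 5)
  x_event[c("X1", "X2")] <- 1.5 * x_event[c("X1", "X2")]
  scen <- scenario(T = 3, significant = c("X1", "X2", "X5", "X6"),
                   cutoff = 0.1, x0 = x_event)
  res <- greedy_reduce(net, scen)
  expect_length(res$trace$steps, 1L)
  expect_identical(res$trace$steps[[1]]$label, "X3+X4")
  expect_identical(res$trace$stopped_because, "no_candidates")
  expect_s3_class(res$reduced, "crn_reduced")
  expect_lte(res$trace$steps[[1]]$I, scen$cutoff)

  # a zero cutoff accepts nothing: the original model is kept
  scen0 <- scenario(T = 3, significant = c("X1", "X2", "X5", "X6"),
                    cutoff = 0, x0 = x_event)
  res0 <- greedy_reduce(net, scen0)
  expect_null(res0$reduced)
  expect_identical(res0$trace$stopped_because, "cutoff")
  expect_length(res0$trace$steps, 0L)
})

test_that("disconnecting deletions are refused unless overridden", {
  net <- disconnecting_triple()
  # make the network open enough to have a steady state: it is closed and
  # already at equilibrium with unit concentrations and kf = kr
  x_ss <- find_steady_state(net)
  x_event <- x_ss
  x_event["X1"] <- 1.3
  scen <- scenario(T = 2, significant = c("X1", "X9"), x0 = x_event)
  tab <- rank_candidates(net, scen, x_ss)
  expect_false("X4+X5" %in% tab$label)
  tab_all <- rank_candidates(net, scen, x_ss, allow_disconnecting = TRUE)
  expect_true("X4+X5" %in% tab_all$label)
})

test_that("the candidate-simulation budget follows the closed-form count", {
  expect_identical(simulation_count(43, 14, 31), 299L)
  # agrees with the equivalent closed form for arbitrary sizes
  for (N in c(10, 20)) for (M in c(2, 5)) for (L in c(M + 1, N - 2)) {
    n_terms <- N - L + 1
    expect_identical(simulation_count(N, M, L),
                     as.integer((L + N) * n_terms / 2 - M * n_terms))
  }
  # and with the per-step candidate counts of an actual unimolecular run:
  # at each step the candidates are the remaining unprotected complexes
  net <- chain_network(5, kf = c(2, 3, 2.5, 2), kr = c(1, 1.5, 1, 1),
                       open = TRUE)
  x_ss <- find_steady_state(net)
  x_event <- x_ss * 1.2
  scen <- scenario(T = 4, significant = c("S1", "S5"), cutoff = Inf,
                   x0 = x_event)
  res <- greedy_reduce(net, scen)
  n_sims <- sum(vapply(res$trace$steps, function(s) nrow(s$ranking),
                       integer(1)))
  N <- 5; M <- 2; L <- 5 - length(res$trace$steps)
  expect_identical(n_sims, simulation_count(N, M, L))
})

test_that("greedy with infinite cutoff exhausts the candidates and each step obeys it", {
  net <- chain_network(4, kf = c(2, 3, 2), kr = c(1, 1, 1), open = TRUE)
  x_ss <- find_steady_state(net)
  scen <- scenario(T = 4, significant = c("S1", "S4"), cutoff = Inf,
                   x0 = x_ss * 1.2)
  res <- greedy_reduce(net, scen)
  expect_length(res$trace$steps, 2L)   # S2 and S3 both deletable
  expect_true(all(vapply(res$trace$steps, `[[`, numeric(1), "I") <= Inf))
  expect_identical(res$trace$stopped_because, "no_candidates")
})

test_that("95% convergence time matches the single-exponential closed form", {
  # clamped inflow Sin -> S1 with first-order drain: x1 relaxes with rate
  # k_out, so the 95% criterion gives t* = ln(20)/k_out
  k_out <- 1.5
  net <- reaction_network(
    species = data.frame(id = c("Sin", "S1"), x0 = c(0.2, 0),
                         fixed = c(TRUE, FALSE)),
    reactions = list(rxn(c(Sin = 1), c(S1 = 1), mass_action_law(1))),
    boundary_fluxes = list(boundary_flux(c(S1 = 1), "first_order", k_out)))
  scen <- scenario(T = 8, significant = "S1", perturb = c(Sin = 5))
  ct <- convergence_times(net, scen, species = "S1", n_out = 8001)
  t_star <- log(20) / k_out
  expect_true(ct$changed)
  expect_equal(ct$time, t_star, tolerance = 5e-3)

  # dense-grid oracle: first time the trajectory stays within the 5% band
  x_old <- find_steady_state(net)
  net5 <- net
  net5$species$x0[1] <- 5
  x_new <- find_steady_state(net5, x0 = c(Sin = 5, S1 = x_old[["S1"]]))
  traj <- simulate_network(net5, x0 = c(Sin = 5, S1 = x_old[["S1"]]), T = 8,
                           n_out = 8001)
  dev <- abs(traj$states[, "S1"] - x_new[["S1"]]) /
    abs(x_new[["S1"]] - x_old[["S1"]])
  oracle_t <- traj$times[which(rev(cumprod(rev(dev <= 0.05))) == 1)[1]]
  expect_equal(ct$time, oracle_t, tolerance = 1e-9)
})

test_that("species with no concentration change are flagged with zero time", {
  net <- two_state_network(x0 = c(A = 1, B = 2))  # starts at equilibrium
  scen <- scenario(T = 2, significant = c("A", "B"))
  ct <- convergence_times(net, scen)
  expect_true(all(!ct$changed))
  expect_true(all(ct$time == 0))
})
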