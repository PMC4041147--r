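test_that("Schur complement of a chain Laplacian matches the closed form", {
  k1f <- 0.7; k1r <- 1.3; k2f <- 2.1; k2r <- 0.4
  L <- matrix(c(k1f, -k1f, 0,            # columns of the chain Laplacian
                -k1r, k1r + k2f, -k2f,
                0, -k2r, k2r), nrow = 3)
  Lhat <- schur_complement(L, 2)
  denom <- k1r + k2f
  want <- matrix(c(k1f * k2f / denom, -k1f * k2f / denom,
                   -k1r * k2r / denom, k1r * k2r / denom),
                 nrow = 2)
  expect_equal(Lhat, want)

  # symmetric unit path graph: series conductance 1/2
  P <- matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), nrow = 3)
  expect_equal(schur_complement(P, 2),
               matrix(c(0.5, -0.5, -0.5, 0.5), nrow = 2))

  expect_identical(schur_complement(L, integer()), L)
  expect_error(schur_complement(L, 1:3), "all vertices")
})

test_that("singular deleted blocks are refused with the complexes named", {
  L <- matrix(0, 3, 3, dimnames = rep(list(c("CA", "CB", "CC")), 2))
  expect_error(schur_complement(L, 2), "CB")
})

test_that("Kron reduction invariants hold on random networks (Laplacian structure)", {
  set.seed(5)
  for (seed in 1:40) {
    net <- random_enzymatic_network(m = 7, c_n = sample(4:8, 1), seed = seed)
    x <- random_state(net)
    L <- weighted_laplacian(net, x)$L
    del <- sample(seq_along(net$complexes), 1)
    Lhat <- schur_complement(L, del)
    expect_true(all(diag(Lhat) > 0))
    offdiag <- Lhat - diag(diag(Lhat))
    expect_true(all(offdiag <= 1e-12))
    expect_lt(max(abs(colSums(Lhat))), 1e-10 * max(1, max(abs(Lhat))))
  }
})

test_that("deletion is independent of the order of elimination", {
  set.seed(9)
  for (seed in 1:20) {
    net <- random_enzymatic_network(m = 7, c_n = 6, seed = seed)
    x <- random_state(net)
    L <- weighted_laplacian(net, x)$L
    pair <- sort(sample(seq_along(net$complexes), 2))
    batch <- schur_complement(L, pair)
    step1 <- schur_complement(L, pair[2])
    # after removing pair[2], pair[1] keeps its index (pair[1] < pair[2])
    seq2 <- schur_complement(step1, pair[1])
    expect_lt(max(abs(batch - seq2)), 1e-10 * max(1, max(abs(batch))))
  }
})

test_that("deleting the intermediate complex eliminates exactly its private species", {
  net <- example1_network()
  expect_identical(eliminated_species(net, 2), c("X3", "X4"))

  chain <- chain_network(4)
  expect_identical(eliminated_species(chain, 2), "S2")

  # a species shared with a retained complex is not eliminated:
  # deleting X3+X4 from the three-reaction triple removes X3 (private to
  # that complex) but keeps X4, which also sits in X4+X5
  tri <- disconnecting_triple()
  expect_identical(eliminated_species(tri, 2), "X3")
})

test_that("delete_complexes enforces frozen values, guards and proper subsets", {
  net <- example1_network()
  expect_error(delete_complexes(net, integer()), "nonempty")
  expect_error(delete_complexes(net, 1:3), "all complexes")
  expect_error(delete_complexes(net, 2), "frozen")
  expect_error(delete_complexes(net, 2, frozen = c(X3 = 1, X4 = -1)),
               "positive")
  expect_error(delete_complexes(net, 2, frozen = c(X3 = 1, X4 = 1),
                                protected = 2), "protected")
  red <- delete_complexes(net, 2, frozen = c(X3 = 0.5, X4 = 0.5))
  expect_s3_class(red, "crn_reduced")
  expect_identical(red$retained, c(1L, 3L))
  expect_identical(dim(red$Z1), c(6L, 2L))
})

test_that("the reduced two-step chain is one reversible reaction on four state variables", {
  net <- example1_network()
  red <- delete_complexes(net, 2, frozen = c(X3 = 0.5, X4 = 0.5))
  rr <- reduced_reactions(red)
  expect_identical(count_reduced_reactions(red), 1L)
  expect_true(all(rr$reversible))
  expect_setequal(unique(c(rr$substrate, rr$product)), c("X1+X2", "X5+X6"))
  n_state <- nrow(net$species) - length(red$frozen)
  expect_identical(n_state, 4L)
})

test_that("type-1 deletion shortens a chain; hub deletion completely couples the leaves", {
  chain <- chain_network(5, kf = c(1, 2, 0.5, 1.5), kr = c(0.5, 1, 1, 0.7))
  red <- delete_complexes(chain, 2, frozen = c(S2 = 1))
  rr <- reduced_reactions(red)
  expect_identical(count_reduced_reactions(red), 3L)  # C1=C3=C4=C5
  expect_true(any(rr$substrate == "S1" & rr$product == "S3"))
  # untouched part of the chain keeps its original edge weights
  x <- stats::setNames(rep(1, 5), paste0("S", 1:5))
  L <- weighted_laplacian(chain, x)$L
  Lhat <- schur_complement(L, 2)
  expect_equal(Lhat[3:4, 3:4], L[4:5, 4:5])

  star <- type3_star()
  redh <- delete_complexes(star, 1, frozen = c(S2 = 1))  # hub complex is S2
  expect_identical(count_reduced_reactions(redh), 3L)    # complete K3
  rrh <- reduced_reactions(redh)
  expect_identical(nrow(rrh), 6L)                        # all directed pairs
})

test_that("reduced dynamics conserve the surviving moieties", {
  net <- example1_network()
  red <- delete_complexes(net, 2, frozen = c(X3 = 0.4, X4 = 0.6))
  set.seed(13)
  for (i in 1:10) {
    x <- random_state(net)
    dx <- reduced_rhs(red, x)
    # eliminated species have structurally zero derivative
    expect_identical(unname(dx[c("X3", "X4")]), c(0, 0))
    # the X1+X5 moiety survives reduction (X3 frozen out of it)
    expect_lt(abs(dx[["X1"]] + dx[["X5"]]), 1e-12)
    expect_lt(abs(dx[["X2"]] + dx[["X6"]]), 1e-12)
  }
})

test_that("complex balancing holds: the implied deleted-complex rates vanish", {
  net <- example1_network(open = TRUE)
  red <- delete_complexes(net, 2, frozen = c(X3 = 0.4, X4 = 0.6))
  set.seed(19)
  for (i in 1:5) {
    x <- random_state(net)
    xa <- x
    xa[c("X3", "X4")] <- c(0.4, 0.6)
    L <- weighted_laplacian(net, xa)$L
    Z <- complex_matrix(net)
    w <- crnreduce:::complex_monomials(Z, xa)
    vb <- boundary_flux_vector(net, xa)
    r <- c(1, 3)
    # the implied intermediate monomial that balances the deleted complex
    w2 <- solve(L[2, 2, drop = FALSE],
                vb[2] - L[2, r, drop = FALSE] %*% w[r])
    y2dot <- vb[2] - L[2, r, drop = FALSE] %*% w[r] - L[2, 2] * w2
    expect_lt(abs(y2dot), 1e-10)
    # and the reduced rhs equals the auxiliary system with w2 substituted
    rhs_aux <- Z[, r] %*% (vb[r] - L[r, r] %*% w[r] -
                             L[r, 2, drop = FALSE] %*% w2)
    expect_equal(unname(reduced_rhs(red, xa)), as.numeric(rhs_aux),
                 tolerance = 1e-10)
  }
})

test_that("at the full steady state the reduced rhs vanishes with steady frozen values", {
  net <- example1_network(open = TRUE)
  x_ss <- find_steady_state(net, t_init = 5)
  red <- delete_complexes(net, 2, frozen = x_ss[c("X3", "X4")])
  dx <- reduced_rhs(red, x_ss)
  expect_lt(max(abs(dx)), 1e-8)
})

test_that("deletions are classified into the linkage-class archetypes", {
  chain <- chain_network(4)
  expect_identical(classify_deletion(chain, 2), "type1")
  expect_identical(classify_deletion(type2_chain(), 2), "type2")
  star <- type3_star()
  expect_identical(classify_deletion(star, 1), "type3")  # hub S2 is complex 1
  tri <- disconnecting_triple()
  expect_identical(classify_deletion(tri, 3), "disconnecting")  # X4+X5

  # a lone reversible pair forming its own linkage class
  lone <- reaction_network(
    species = data.frame(id = c("A", "B", "C", "D"), x0 = rep(1, 4)),
    reactions = list(
      reversible_reaction(c(A = 1), c(B = 1), rev_mass_action_laws(1, 1)),
      reversible_reaction(c(C = 1), c(D = 1), rev_mass_action_laws(1, 1))))
  expect_identical(classify_deletion(lone, 4), "linkage_removal")
})

test_that("the collapsed two-step MM law composes equilibrium constants and has 8 parameters", {
  set.seed(29)
  for (i in 1:50) {
    Vs <- 10^stats::runif(4, -0.5, 0.8)
    KmI <- stats::setNames(10^stats::runif(4, -0.7, 0.7), paste0("X", 1:4))
    KmII <- stats::setNames(10^stats::runif(4, -0.7, 0.7), paste0("X", 3:6))
    frozen <- stats::setNames(10^stats::runif(2, -0.5, 0.5), c("X3", "X4"))
    s1 <- rev_mm_laws(Vs[1], Vs[2], KmI, c("X1", "X2"), c("X3", "X4"))
    s2 <- rev_mm_laws(Vs[3], Vs[4], KmII, c("X3", "X4"), c("X5", "X6"))
    claw <- collapse_rev_mm_chain(s1, s2, frozen)
    KeqI <- s1$fwd$k / s1$rev$k
    KeqII <- s2$fwd$k / s2$rev$k
    expect_equal(claw$Keq_red, KeqI * KeqII, tolerance = 1e-12)
    expect_equal(claw$kf_red / claw$kr_red, KeqI * KeqII, tolerance = 1e-12)
    expect_identical(collapsed_parameter_count(claw), 8L)
    expect_true(all(claw$Km_red > 0))
  }
})

test_that("the collapsed law equals the complex-balancing substitution oracle", {
  set.seed(37)
  for (i in 1:50) {
    Vs <- 10^stats::runif(4, -0.5, 0.8)
    KmI <- stats::setNames(10^stats::runif(4, -0.7, 0.7), paste0("X", 1:4))
    KmII <- stats::setNames(10^stats::runif(4, -0.7, 0.7), paste0("X", 3:6))
    frozen <- stats::setNames(10^stats::runif(2, -0.5, 0.5), c("X3", "X4"))
    s1 <- rev_mm_laws(Vs[1], Vs[2], KmI, c("X1", "X2"), c("X3", "X4"))
    s2 <- rev_mm_laws(Vs[3], Vs[4], KmII, c("X3", "X4"), c("X5", "X6"))
    claw <- collapse_rev_mm_chain(s1, s2, frozen)

    x <- stats::setNames(10^stats::runif(6, -0.7, 0.7), paste0("X", 1:6))
    # oracle: binding polynomials with the intermediates frozen
    xf <- x
    xf[c("X3", "X4")] <- frozen
    p1f <- 1 / s1$fwd$d(xf)
    p2f <- 1 / s2$fwd$d(xf)
    kfI <- s1$fwd$k; krI <- s1$rev$k
    kfII <- s2$fwd$k; krII <- s2$rev$k
    x34 <- (kfI * p2f * x[["X1"]] * x[["X2"]] +
              krII * p1f * x[["X5"]] * x[["X6"]]) /
           (kfII * p1f + krI * p2f)
    v_oracle <- (kfI * x[["X1"]] * x[["X2"]] - krI * x34) / p1f
    expect_equal(eval_collapsed(claw, x), v_oracle, tolerance = 1e-10)
  }
})

test_that("unimolecular chain collapse yields the 4-parameter law", {
  Km1 <- c(A = 0.5, B = 1.2)
  Km2 <- c(B = 0.8, C = 2)
  s1 <- rev_mm_laws(2, 1, Km1, "A", "B")
  s2 <- rev_mm_laws(3, 1.5, Km2, "B", "C")
  claw <- collapse_rev_mm_chain(s1, s2, frozen = c(B = 0.7))
  expect_identical(collapsed_parameter_count(claw), 4L)
  expect_named(claw$Km_red, c("A", "C"))
})

test_that("the collapsed net flux reproduces the chain flux at a balanced state", {
  # full chain at steady state carries one common net flux; the collapsed
  # reaction must carry the same flux when evaluated there
  net <- example1_network(open = TRUE)
  x_ss <- find_steady_state(net, t_init = 5)
  s1 <- rev_mm_laws(2, 1, c(X1 = 1, X2 = 1, X3 = 1, X4 = 1),
                    c("X1", "X2"), c("X3", "X4"))
  s2 <- rev_mm_laws(20, 10, c(X3 = 1, X4 = 1, X5 = 1, X6 = 1),
                    c("X3", "X4"), c("X5", "X6"))
  claw <- collapse_rev_mm_chain(s1, s2, frozen = x_ss[c("X3", "X4")])
  Z <- complex_matrix(net)
  v1f <- eval_rate(net$reactions[[1]]$law, Z[, 1], x_ss)
  v1r <- eval_rate(net$reactions[[2]]$law, Z[, 2], x_ss)
  expect_equal(eval_collapsed(claw, x_ss), v1f - v1r, tolerance = 1e-6)
})
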