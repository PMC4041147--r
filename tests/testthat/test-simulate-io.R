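test_that("the two-state network relaxes to its closed-form equilibrium", {
  traj <- simulate_network(two_state_network(), T = 15)
  final <- traj$states[nrow(traj$states), ]
  expect_equal(unname(final), c(1, 2), tolerance = 1e-6)
})

test_that("closed-network trajectories conserve every moiety", {
  net <- example1_network()
  traj <- simulate_network(net, T = 5)
  G <- conservation_laws(net)
  tot <- traj$states %*% G
  for (k in seq_len(ncol(tot)))
    expect_lt(max(abs(tot[, k] - tot[1, k])), 1e-8 * max(1, abs(tot[1, k])))
})

test_that("simulation at fixed tolerances is reproducible", {
  t1 <- simulate_network(example1_network(), T = 2)
  t2 <- simulate_network(example1_network(), T = 2)
  expect_identical(t1$states, t2$states)
})

test_that("reduced and full trajectories agree when the intermediate equilibrates fast", {
  net <- example1_network()      # fast second step by default
  x_ss <- find_steady_state(net, t_init = 5)
  red <- delete_complexes(net, 2, frozen = x_ss[c("X3", "X4")])
  x0 <- x_ss
  x0[c("X1", "X2")] <- 1.4 * x0[c("X1", "X2")]
  full <- simulate_network(net, x0 = x0, T = 3)
  redt <- simulate_network(red, x0 = x0, T = 3)
  rep <- error_integral(full, redt, c("X1", "X2", "X5", "X6"), T = 3)
  expect_lt(rep$I, 0.1)
})

test_that("trajectory containers validate their grids and clamp tiny negatives", {
  expect_error(crn_trajectory(c(0, 1, 1), matrix(0, 3, 1,
                                                 dimnames = list(NULL, "A"))),
               "increasing")
  tr <- crn_trajectory(c(0, 1), matrix(c(1, -1e-13, 1, 1), 2,
                                       dimnames = list(NULL, c("A", "B"))))
  expect_identical(unname(tr$states[2, "A"]), 0)
  expect_identical(tr$meta$clamped, 1L)
  expect_error(crn_trajectory(c(0, 1), matrix(c(1, -1, 1, 1), 2,
                                              dimnames = list(NULL, c("A", "B")))),
               "negative")
})

test_that("native JSON round-trips bit-exactly", {
  net <- example1_network(open = TRUE)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_network_json(net, f1)
  net2 <- read_network_json(f1)
  write_network_json(net2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(complex_matrix(net2), complex_matrix(net))
  expect_identical(incidence_matrix(net2), incidence_matrix(net))
  expect_identical(parameter_count(net2), parameter_count(net))
  # dynamics identical at a probe state
  x <- c(X1 = 1.3, X2 = 0.6, X3 = 0.8, X4 = 0.2, X5 = 1.1, X6 = 0.4)
  expect_identical(network_rhs(net2, x), network_rhs(net, x))
  unlink(c(f1, f2))
})

test_that("reduced models round-trip through JSON with their reduction block", {
  net <- example1_network()
  red <- delete_complexes(net, 2, frozen = c(X3 = 0.5, X4 = 0.5))
  f <- tempfile(fileext = ".json")
  write_network_json(red, f)
  red2 <- read_network_json(f)
  expect_s3_class(red2, "crn_reduced")
  expect_identical(red2$deleted, red$deleted)
  expect_identical(red2$frozen, red$frozen)
  x <- c(X1 = 1.3, X2 = 0.6, X3 = 0.5, X4 = 0.5, X5 = 1.1, X6 = 0.4)
  expect_equal(reduced_rhs(red2, x), reduced_rhs(red, x))
  unlink(f)
})

test_that("SBML round-trip preserves structure, parameters and dynamics", {
  net <- example1_network(open = TRUE)
  f <- tempfile(fileext = ".xml")
  write_sbml(net, f)
  net2 <- read_sbml(f)
  expect_identical(complex_matrix(net2), complex_matrix(net))
  expect_identical(incidence_matrix(net2), incidence_matrix(net))
  expect_identical(parameter_count(net2), parameter_count(net))
  t1 <- simulate_network(net, T = 2)
  t2 <- simulate_network(net2, T = 2)
  expect_equal(t1$states, t2$states, tolerance = 1e-12)
  unlink(f)
})

test_that("SBML kinetic laws without a catalogued annotation raise an unsupported-law error", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="m">
    <listOfSpecies>
      <species id="A" compartment="cell" initialConcentration="1"
               constant="false" boundaryCondition="false"/>
      <species id="B" compartment="cell" initialConcentration="0"
               constant="false" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="weird" reversible="false">
        <listOfReactants><speciesReference species="A" stoichiometry="1"/></listOfReactants>
        <listOfProducts><speciesReference species="B" stoichiometry="1"/></listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><power/><ci>A</ci><cn>3</cn></apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
  f <- tempfile(fileext = ".xml")
  writeLines(sbml, f)
  expect_error(read_sbml(f), "unsupported kinetic law.*weird")
  unlink(f)
})

test_that("the command-line interface validates, simulates, ranks and reduces", {
  good <- tempfile(fileext = ".json")
  write_network_json(example1_network(open = TRUE), good)

  expect_output(status <- crn_cli(c("validate", good)), "network OK")
  expect_identical(status, 0L)

  out_csv <- tempfile(fileext = ".csv")
  status <- crn_cli(c("simulate", good, "--horizon", "2", "--out", out_csv))
  expect_identical(status, 0L)
  traj <- utils::read.csv(out_csv)
  expect_identical(names(traj), c("time", paste0("X", 1:6)))

  red_json <- tempfile(fileext = ".json")
  trace_json <- tempfile(fileext = ".json")
  suppressMessages(
    status <- crn_cli(c("reduce", good,
                        "--significant", "X1,X2,X5,X6",
                        "--horizon", "3", "--cutoff", "0.1",
                        "--x0", "X1=3", "--x0", "X2=3",
                        "--out", red_json, "--trace", trace_json)))
  expect_identical(status, 0L)
  red <- read_network_json(red_json)
  expect_s3_class(red, "crn_reduced")
  trace <- jsonlite::fromJSON(trace_json)
  expect_identical(trace$steps$complex, "X3+X4")

  # an invalid model exits with status 2
  bad <- tempfile(fileext = ".json")
  writeLines("{\"format\": \"something-else\"}", bad)
  expect_identical(suppressMessages(crn_cli(c("validate", bad))), 2L)
  # unknown command prints usage with status 1
  expect_output(expect_identical(crn_cli(c("frobnicate", good)), 1L),
                "usage")
  unlink(c(good, out_csv, red_json, trace_json, bad))
})
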