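test_that("rate laws evaluate to their defining forms", {
  expect_equal(evaluate_rate(rate_law("mass_action", k = 2), c(A = 3, B = 4)),
               24)
  expect_equal(evaluate_rate(rate_law("michaelis_menten", Vmax = 10, Km = 5),
                             c(S = 5)), 5)
  expect_equal(evaluate_rate(rate_law("constant_flux", k = 0.7), numeric(0)),
               0.7)
  # order overrides: enzymatic step written with stoichiometry 2 but
  # first-order kinetics
  expect_equal(evaluate_rate(rate_law("mass_action", k = 3,
                                      orders = c(A = 1)), c(A = 4)), 12)
  # hill with n = 1 reduces to michaelis_menten on arbitrary inputs
  set.seed(7)
  for (i in 1:20) {
    s <- runif(1, 0, 50); vmax <- runif(1, 1, 20); km <- runif(1, 0.1, 30)
    expect_equal(
      evaluate_rate(rate_law("hill", Vmax = vmax, Km = km, hill_n = 1),
                    c(S = s)),
      evaluate_rate(rate_law("michaelis_menten", Vmax = vmax, Km = km),
                    c(S = s)))
  }
})

test_that("rate-law construction and evaluation reject bad inputs", {
  expect_error(rate_law("mass_action"), "missing parameter")
  expect_error(rate_law("michaelis_menten", Vmax = 1, Km = 0), "Km")
  expect_error(rate_law("hill", Vmax = 1, Km = 1, hill_n = 0.5), "hill_n")
  expect_error(rate_law("mass_action", k = -1), ">= 0")
  expect_error(evaluate_rate(rate_law("mass_action", k = 1), c(A = -2)),
               "negative")
})

test_that("stoichiometry matrix records net production, clamped rows zero", {
  net <- reaction_network(
    list(species("A", 10), species("B", 0)),
    list(reaction("conv", c(A = 1), c(B = 1),
                  rate = rate_law("mass_action", k = 1))),
    name = "ab")
  expect_equal(unname(stoichiometry_matrix(net)[, 1]), c(-1, 1))

  net2 <- reaction_network(
    list(species("A", 10), species("B", 0)),
    list(reaction("dimer", c(A = 2), c(B = 1),
                  rate = rate_law("mass_action", k = 1))),
    name = "dimer")
  expect_equal(unname(stoichiometry_matrix(net2)[, 1]), c(-2, 1))

  # clamped bulk species of the ROS model have identically zero rows
  S <- stoichiometry_matrix(build_ros_network())
  expect_true(all(S["H2O", ] == 0))
  expect_true(all(S["O2", ] == 0))
})

test_that("assembled rhs equals stoichiometry times fluxes and matches a
           finite-difference oracle", {
  net <- reaction_network(
    list(species("A", 2), species("B", 0)),
    list(reaction("conv", c(A = 1), c(B = 1),
                  rate = rate_law("mass_action", k = 1))),
    name = "ab")
  rhs <- assemble_rhs(net)
  expect_equal(unname(rhs(c(A = 2, B = 0))), c(-2, 2))
  expect_equal(unname(rhs(c(A = 0, B = 0))), c(0, 0))

  net5 <- random_network(seed = 11)
  rhs5 <- assemble_rhs(net5)
  S <- stoichiometry_matrix(net5)
  for (i in seq_len(nrow(st <- random_states(net5, 100)))) {
    expect_equal(unname(rhs5(st[i, ])),
                 unname(drop(S %*% network_fluxes(net5, st[i, ]))))
  }

  # central finite differences of an integrated trajectory reproduce the rhs
  h <- 0.05
  res <- integrate_network(net5, simulation_settings(horizon = 2 * h, n_out = 2,
                                                     rtol = 1e-11, atol = 1e-13))
  fd <- (res$conc[3, ] - res$conc[1, ]) / (2 * h)
  an <- rhs5(res$conc[2, ])
  expect_lt(max(abs(fd - an)) / max(abs(an)), 1e-6)
})

test_that("conserved moieties span the left null space", {
  ab <- reaction_network(
    list(species("A", 1), species("B", 2)),
    list(reaction("f", c(A = 1), c(B = 1), rate = rate_law("mass_action", k = 1)),
         reaction("b", c(B = 1), c(A = 1), rate = rate_law("mass_action", k = 1))),
    name = "ab_rev")
  cm <- conserved_moieties(ab)
  expect_length(cm, 1)
  expect_equal(cm[[1]], c(A = 1, B = 1))

  # A + B -> C, C -> A + B: conservations A+C and B+C (2-dim null space,
  # cross-checked against a brute-force orthonormal basis)
  abc <- reaction_network(
    list(species("A", 1), species("B", 1), species("C", 0)),
    list(reaction("bind", c(A = 1, B = 1), c(C = 1),
                  rate = rate_law("mass_action", k = 1)),
         reaction("unbind", c(C = 1), c(A = 1, B = 1),
                  rate = rate_law("mass_action", k = 1))),
    name = "abc")
  cm <- conserved_moieties(abc)
  expect_length(cm, 2)
  S <- stoichiometry_matrix(abc)
  for (v in cm) expect_true(all(t(v) %*% S == 0))
  expect_true(in_span(c(A = 1, B = 0, C = 1), cm))
  expect_true(in_span(c(A = 0, B = 1, C = 1), cm))
  skip_if_not_installed("MASS")
  expect_equal(ncol(MASS::Null(S)), 2)  # independent dimension check

  # no reactions: every unit vector is conserved
  empty <- reaction_network(list(species("A", 1), species("B", 1)), list(),
                            name = "none")
  cm <- conserved_moieties(empty)
  expect_length(cm, 2)
  expect_true(in_span(c(A = 1, B = 0), cm))
})

test_that("validation reports findings without mutating or throwing", {
  ok <- reaction_network(
    list(species("A", 1), species("B", 0)),
    list(reaction("f", c(A = 1), c(B = 1), rate = rate_law("mass_action", k = 1))),
    name = "ok")
  expect_identical(validate_network(ok), character(0))

  bad <- reaction_network(
    list(species("A", 1)),
    list(reaction("f", c(A = 1), c(X = 1), rate = rate_law("mass_action", k = 1))),
    name = "dangling")
  f <- validate_network(bad)
  expect_length(f, 1)
  expect_match(f, "'X'")

  neg <- ok
  neg$species[["A"]]$initial <- -1
  expect_match(validate_network(neg), "negative")

  dup <- reaction_network(
    list(species("A", 1)),
    list(reaction("f", c(A = 1), NULL, rate = rate_law("mass_action", k = 1)),
         reaction("f", c(A = 1), NULL, rate = rate_law("mass_action", k = 2))),
    name = "dup")
  expect_match(paste(validate_network(dup), collapse = ";"),
               "duplicate reaction")

  src <- reaction_network(
    list(species("A", 1)),
    list(reaction("mk", NULL, c(A = 1), rate = rate_law("mass_action", k = 1))),
    name = "src")
  expect_match(validate_network(src), "constant_flux")
})

test_that("constant accessors round-trip through the flat parameter vector", {
  net <- build_ros_network()
  k <- rate_constant(net, "fenton")
  rate_constant(net, "fenton") <- 2 * k
  expect_equal(rate_constant(net, "fenton"), 2 * k)
  pars <- network_constants(net)
  expect_equal(pars[["fenton.k"]], 2 * k)
  net2 <- update_constants(build_ros_network(), pars)
  expect_equal(network_constants(net2), pars)
})
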