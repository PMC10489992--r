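test_that("integrator matches closed forms on elementary systems", {
  # first-order decay: A(t) = A0 exp(-k t)
  net <- make_toy_network("decay", k_decay = 1e-3, A0 = 100)
  res <- integrate_network(net, simulation_settings(horizon = 1000, n_out = 10))
  expect_equal(unname(res$conc[11, "A"]), 100 * exp(-1), tolerance = 1e-6)

  # no reactions: constant trajectories
  const <- reaction_network(list(species("A", 5), species("B", 0.1)), list(),
                            name = "const")
  res <- integrate_network(const, simulation_settings(horizon = 100, n_out = 5))
  expect_true(all(res$conc[, "A"] == 5) && all(res$conc[, "B"] == 0.1))

  # synthesis + decay settles at k_s / k_d
  net <- make_toy_network("synthesis_decay", k_s = 4.2e-4, k_d = 1e-5)
  res <- integrate_network(net, fast_settings(horizon = 3e6))
  expect_equal(unname(res$conc[nrow(res$conc), "E"]), 42, tolerance = 1e-6)
})

test_that("integration failures carry diagnostics instead of silent output", {
  blow <- reaction_network(
    list(species("X", 1)),
    list(reaction("auto", c(X = 1), c(X = 2),
                  rate = rate_law("mass_action", k = 0.5))),
    name = "autocatalytic")
  expect_error(integrate_network(blow, simulation_settings(horizon = 200,
                                                           n_out = 10)),
               "blew up|failed")
  rhs <- assemble_rhs(make_toy_network("decay"))
  expect_error(rhs(c(1, 2)), "length mismatch")
})

test_that("two distinct stiff methods agree on both pathway models", {
  for (net in list(apply_aging_condition(build_ros_network(), 2),
                   build_antioxidant_network())) {
    a <- integrate_network(net, fast_settings(method = "lsoda"))
    b <- integrate_network(net, fast_settings(method = "bdf"))
    fa <- a$conc[nrow(a$conc), ]; fb <- b$conc[nrow(b$conc), ]
    big <- fa > 1e-3  # compare species above solver noise floor
    expect_lt(max(abs(fa[big] - fb[big]) / fa[big]), 0.005)
  }
})

test_that("tightening tolerances tenfold leaves final states essentially
           unchanged (convergence contract)", {
  net <- build_antioxidant_network()
  a <- integrate_network(net, fast_settings())
  b <- integrate_network(net, fast_settings(rtol = 1e-9, atol = 1e-13))
  fa <- a$conc[nrow(a$conc), ]; fb <- b$conc[nrow(b$conc), ]
  expect_lt(max(abs(fa - fb) / (fa + 1e-9)), 1e-3)
})

test_that("steady-state detection accepts settled and rejects oscillating
           trajectories", {
  const <- reaction_network(list(species("A", 5)), list(), name = "const")
  res <- integrate_network(const, simulation_settings(horizon = 100, n_out = 10))
  ss <- detect_steady_state(res)
  expect_true(ss$reached)
  expect_equal(ss$state, c(A = 5))

  # pure decay at 1e-3 1/s is numerically flat long before 7 days
  res <- integrate_network(make_toy_network("decay"), fast_settings())
  expect_true(detect_steady_state(res)$reached)

  # sustained oscillator must fail the test by design
  res <- integrate_network(make_toy_network("oscillator"), fast_settings())
  expect_false(detect_steady_state(res)$reached)
})

test_that("steady-state detection is invariant to uniform resampling", {
  net <- build_antioxidant_network()
  for (n_out in c(120, 480, 1920)) {
    res <- integrate_network(net, fast_settings(n_out = n_out))
    expect_true(detect_steady_state(res)$reached)
  }
  osc <- make_toy_network("oscillator")
  for (n_out in c(240, 960)) {
    res <- integrate_network(osc, fast_settings(n_out = n_out))
    expect_false(detect_steady_state(res)$reached)
  }
})

test_that("percent change follows the signed-percent convention", {
  expect_equal(percent_change(42, 92.4), 120)
  expect_equal(percent_change(3, 3), 0)
  expect_equal(percent_change(7.32, 3.66), -50)
  expect_error(percent_change(0, 1), "> 0")
  expect_error(percent_change(-1, 1), "> 0")
})

test_that("trajectories export as tidy time series", {
  res <- integrate_network(make_toy_network("decay"),
                           simulation_settings(horizon = 10, n_out = 5))
  df <- as.data.frame(res)
  expect_named(df, c("time_s", "species", "concentration_nM"))
  expect_equal(nrow(df), 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(res, path, run_id = "t1")
  back <- utils::read.csv(path)
  expect_equal(back$concentration_nM, df$concentration_nM)
  expect_true(all(back$run_id == "t1"))
})
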