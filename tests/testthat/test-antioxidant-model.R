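test_that("default configuration reproduces the published initial state", {
  net <- build_antioxidant_network()
  init <- species_initials(net)
  expect_identical(unname(init[c("Maf", "Keap1", "Nrf2", "H2O2i")]),
                   c(4000, 2000, 1800, 1500))
  expect_true(all(init[c("CAT", "HO1", "SOD", "GPx")] == 0))
  expect_identical(validate_network(net), character(0))
})

test_that("activated synthesis is silent without nuclear complex", {
  net <- build_antioxidant_network(
    antioxidant_model_config(initial_concentrations = list(Nrf2 = 0)))
  fl <- network_fluxes(net, species_initials(net))
  are <- grep("^are_synthesis_", names(fl), value = TRUE)
  expect_true(all(fl[are] == 0))
})

test_that("Maf and Keap1 totals are conserved moieties", {
  net <- build_antioxidant_network()
  cm <- conserved_moieties(net)
  dyn <- names(cm[[1]])
  maf <- stats::setNames(as.numeric(dyn %in% c("Maf", "Nrf2n_Maf")), dyn)
  keap <- stats::setNames(as.numeric(dyn %in% c("Keap1", "Keap1_Nrf2")), dyn)
  S <- stoichiometry_matrix(net)
  for (v in list(maf, keap)) {
    expect_true(all(t(v) %*% S[dyn, ] == 0))
    expect_true(in_span(v, cm))
  }
  # and they hold along the simulated trajectory
  res <- integrate_network(net, fast_settings())
  for (v in list(maf, keap)) {
    tot <- res$conc[, names(v), drop = FALSE] %*% v
    expect_lt(max(abs(tot - tot[1])) / (tot[1] + 1), 1e-6)
  }
})

test_that("with synthesis off and positive degradation every enzyme decays
           to zero", {
  cfg <- antioxidant_model_config()
  net <- build_antioxidant_network(cfg)
  for (e in c("CAT", "HO1", "SOD", "GPx")) {
    rate_constant(net, paste0("basal_synthesis_", e)) <- 0
    rate_constant(net, paste0("are_synthesis_", e)) <- 0
    net <- set_initial(net, e, 100)
  }
  res <- integrate_network(net, fast_settings())
  final <- res$conc[nrow(res$conc), c("CAT", "HO1", "SOD", "GPx")]
  expect_true(all(final < 100 * exp(-2e-5 * 604800) * 1.001))
  for (e in c("CAT", "HO1", "SOD", "GPx"))
    expect_true(all(diff(res$conc[, e]) <= 1e-9))
})

test_that("independent coupling is a disjoint union, shared coupling merges
           the peroxide pool and enzyme pools", {
  ros <- build_ros_network()
  ax <- build_antioxidant_network()
  ind <- couple_models(ros, ax, "independent")
  expect_length(ind$species, length(ros$species) + length(ax$species))
  expect_identical(validate_network(ind), character(0))
  # the colliding SOD id was prefixed and reported
  expect_true(all(c("ros_SOD", "antiox_SOD") %in% names(ind$species)))
  expect_true("SOD" %in% names(attr(ind, "coupling")$renamed) ||
                any(attr(ind, "coupling")$renamed %in% c("ros_SOD")))

  sh <- couple_models(ros, ax, "shared_h2o2")
  expect_length(sh$species, length(ros$species) + length(ax$species) - 4)
  expect_identical(validate_network(sh), character(0))
  # merged pools take the antioxidant model's basal H2O2 and dynamic enzymes
  expect_equal(sh$species[["H2O2"]]$initial, 1500)
  expect_equal(sh$species[["SOD"]]$initial, 0)

  expect_error(couple_models(make_toy_network("decay"), ax, "shared_h2o2"),
               "H2O2")
})

test_that("in the shared-peroxide model a stronger oxidant source drives
           more enzyme synthesis", {
  ros <- build_ros_network()
  ax <- build_antioxidant_network()
  syn_flux <- function(fold) {
    net <- couple_models(apply_aging_condition(ros, fold), ax, "shared_h2o2")
    st <- detect_steady_state(integrate_network(net, fast_settings()))$state
    network_fluxes(net, st)[["are_synthesis_CAT"]]
  }
  fluxes <- vapply(c(1, 2, 4), syn_flux, numeric(1))
  expect_true(all(diff(fluxes) > 0))
})

test_that("closed-form calibration: synthesis constant equals degradation
           times target", {
  single <- reaction_network(
    list(species("E", 0)),
    list(reaction("basal_synthesis_E", NULL, c(E = 1),
                  rate = rate_law("constant_flux", k = 1)),
         reaction("degradation_E", c(E = 1), NULL,
                  rate = rate_law("mass_action", k = 1e-5))),
    name = "single_enzyme")
  fit <- calibrate_baselines(single, c(E = 42), settings = fast_settings())
  expect_equal(fit$constants[["basal_synthesis_E.k"]], 1e-5 * 42,
               tolerance = 1e-12)
})

test_that("calibrating to the model's own steady state returns the input
           constants", {
  net <- build_antioxidant_network()
  ss <- detect_steady_state(integrate_network(net, fast_settings()))$state
  fit <- calibrate_baselines(net, ss[c("CAT", "HO1", "SOD", "GPx")],
                             settings = fast_settings())
  for (e in c("CAT", "HO1", "SOD", "GPx")) {
    expect_equal(fit$constants[[paste0("basal_synthesis_", e, ".k")]],
                 rate_constant(net, paste0("basal_synthesis_", e)),
                 tolerance = 1e-3)
    expect_equal(fit$constants[[paste0("are_synthesis_", e, ".k")]],
                 rate_constant(net, paste0("are_synthesis_", e)),
                 tolerance = 1e-3)
  }
})

test_that("constants are re-found from a tenfold-perturbed start", {
  net <- build_antioxidant_network()
  truth <- network_constants(net)
  pert <- net
  for (e in c("CAT", "HO1", "SOD", "GPx")) {
    rate_constant(pert, paste0("basal_synthesis_", e)) <-
      10 * rate_constant(net, paste0("basal_synthesis_", e))
    rate_constant(pert, paste0("are_synthesis_", e)) <-
      10 * rate_constant(net, paste0("are_synthesis_", e))
  }
  fit <- calibrate_baselines(pert, c(CAT = 42, HO1 = 11.2, SOD = 2791,
                                     GPx = 15718),
                             settings = fast_settings())
  for (nm in names(fit$constants))
    expect_equal(fit$constants[[nm]], truth[[nm]], tolerance = 0.01)
  expect_true(all(abs(fit$residuals) < 0.01))
})

test_that("a free constant is recovered by root search against a known
           steady state", {
  net <- make_toy_network("scavenger_chain", k_src = 1e-2, k_clear = 1e-3,
                          k_scav = 1e-3, scav = 1)
  # steady state k_src / (k_clear + k_scav * scav) = 5; ask for 8 instead
  fit <- calibrate_baselines(net, c(X = 8), free_constants = "source.k",
                             settings = fast_settings())
  expect_equal(fit$constants[["source.k"]], 8 * 2e-3, tolerance = 1e-5)
})
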