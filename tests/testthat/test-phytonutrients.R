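test_that("the compound fixture satisfies the mechanism constraints", {
  cpds <- default_compounds()
  expect_named(cpds, c("cyanidin", "delphinidin", "ellagic_acid",
                       "kaempferol", "malvidin", "rutin"))
  expect_identical(cpds$cyanidin$targets, "ros_scavenging")
  for (m in cpds) expect_true("ros_scavenging" %in% m$targets)
  nrf2_axis <- vapply(cpds, function(m)
    length(setdiff(m$targets, "ros_scavenging")) > 0, logical(1))
  expect_identical(sum(nrf2_axis), 5L)
  expect_false(nrf2_axis[["cyanidin"]])
  expect_error(compound_mechanism("cyanidin",
                                  c("ros_scavenging", "nrf2_activation"),
                                  c(k_scav = 1)), "exactly")
  expect_error(compound_mechanism("rutin", "ros_scavenging", c(k_scav = 1)),
               "Nrf2-axis")
})

test_that("dose-to-serum mapping is linear through Cmax with optional cap", {
  sp <- function(dose, sat = NULL)
    dose_spec("rutin", dose, cmax = 200, reference_dose = 200, saturation = sat)
  expect_equal(dose_to_serum(sp(0)), 0)
  expect_equal(dose_to_serum(sp(200)), 200)
  expect_equal(dose_to_serum(sp(500)), 500)
  expect_equal(dose_to_serum(sp(500, sat = 300)), 300)
  expect_error(dose_spec("rutin", -1, 200, 200), ">= 0")
})

test_that("zero serum is the identity and scavengers add exactly one
           reaction", {
  ros <- build_ros_network()
  cpds <- default_compounds()
  expect_identical(apply_compound(ros, cpds$delphinidin, 0), ros)

  treated <- apply_compound(ros, cpds$cyanidin, 250)
  expect_length(treated$reactions, length(ros$reactions) + 1)
  expect_length(treated$species, length(ros$species) + 2)
  expect_true(treated$species[["cyanidin"]]$constant)
  expect_equal(treated$species[["cyanidin"]]$initial, 250)
  # untouched elsewhere: all pre-existing fluxes identical
  st <- species_initials(treated)
  expect_identical(network_fluxes(treated, st)[names(ros$reactions)],
                   network_fluxes(ros, st[names(ros$species)])[names(ros$reactions)])

  # cyanidin has no Nrf2-axis action: the antioxidant network is unchanged
  ax <- build_antioxidant_network()
  expect_identical(apply_compound(ax, cpds$cyanidin, 250), ax)
})

test_that("effect factors are saturating: finite at any serum and monotone", {
  ax <- build_antioxidant_network()
  d <- default_compounds()$delphinidin
  k0 <- rate_constant(ax, "nrf2_nuclear_import")
  ks <- vapply(c(0, 10, 100, 1e3, 1e6, 1e12), function(s)
    rate_constant(apply_compound(ax, d, s), "nrf2_nuclear_import"), numeric(1))
  expect_true(all(is.finite(ks)))
  expect_true(all(diff(ks) >= 0))
  a <- d$effect_constants[["a"]]
  expect_lt(ks[length(ks)], k0 * (1 + a) * (1 + 1e-9))
})

test_that("higher serum gives lower steady-state ROS (dose dependence)", {
  cfg <- ros_model_config()
  d <- default_compounds()$delphinidin
  ros_at <- function(serum) {
    net <- apply_compound(apply_aging_condition(build_ros_network(cfg), 2),
                          d, serum)
    ros_biomarker(detect_steady_state(
      integrate_network(net, fast_settings()))$state, cfg)
  }
  r <- vapply(c(0, 150, 600), ros_at, numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("combinations commute, reject duplicates, and empty is identity", {
  ax <- build_antioxidant_network()
  cpds <- default_compounds()
  expect_identical(apply_combination(ax, cpds, numeric()), ax)
  s <- c(delphinidin = 300, rutin = 200)
  n1 <- apply_combination(ax, cpds, s)
  n2 <- apply_combination(ax, cpds, rev(s))
  expect_equal(network_constants(n1), network_constants(n2))
  st <- species_initials(n1)
  expect_equal(network_fluxes(n1, st), network_fluxes(n2, st))
  expect_error(apply_combination(ax, cpds, c(rutin = 1, rutin = 2)),
               "duplicate")
})

test_that("scavenged mass equals the integrated scavenging flux", {
  cfg <- ros_model_config()
  net <- apply_compound(apply_aging_condition(build_ros_network(cfg), 2),
                        default_compounds()$cyanidin, 250)
  res <- integrate_network(net, fast_settings(n_out = 2000))
  k <- rate_constant(net, "scavenge_cyanidin")
  flux <- k * res$conc[, "superoxide"] * res$conc[, "cyanidin"]
  dt <- diff(res$times)
  integral <- sum((flux[-1] + flux[-length(flux)]) / 2 * dt)
  final <- unname(res$conc[nrow(res$conc), "scavenged_cyanidin"])
  expect_equal(final, integral, tolerance = 1e-3)
})

test_that("dropping a compound from a combination never strengthens it", {
  cpds <- default_compounds()
  serum_max <- c(cyanidin = 500, delphinidin = 600, ellagic_acid = 1000,
                 kaempferol = 320, malvidin = 750, rutin = 600)
  cat_at <- function(subset) {
    net <- apply_combination(build_antioxidant_network(), cpds,
                             serum_max[subset])
    detect_steady_state(integrate_network(net, fast_settings()))$state[["CAT"]]
  }
  set.seed(31)
  withnrf2 <- setdiff(names(serum_max), "cyanidin")
  for (i in 1:5) {
    sub <- sample(withnrf2, sample(1:4, 1))
    extra <- sample(setdiff(withnrf2, sub), 1)
    expect_lte(cat_at(sub), cat_at(c(sub, extra)) * (1 + 1e-9))
  }
})
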