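#' Configuration of the antioxidant-enzyme production model
#'
#' Holds the initial concentrations of the Nrf2-axis species (Maf 4000,
#' Keap1 2000, Nrf2 1800, basal intracellular H2O2 1500 nM), the kinetic
#' constants of the Keap1--Nrf2 cycle, and the enzyme baseline panel the
#' calibration targets. Defaults come from
#' `inst/extdata/antioxidant_model.yaml`.
#'
#' @param initial_concentrations Named overrides (`Maf`, `Keap1`, `Nrf2`,
#'   `H2O2i`), nM.
#' @param kinetic_constants Named overrides of kinetic constants (including
#'   the per-enzyme synthesis/degradation constants).
#' @param enzyme_baselines Named target steady-state panel (`CAT`, `HO1`,
#'   `SOD`, `GPx`), nM, used by [calibrate_baselines()].
#' @return An object of class `antioxidant_model_config`.
#' @export
antioxidant_model_config <- function(initial_concentrations = NULL,
                                     kinetic_constants = NULL,
                                     enzyme_baselines = NULL) {
  defaults <- yaml::read_yaml(system.file("extdata", "antioxidant_model.yaml",
                                          package = "redoxsim"))
  init <- unlist(defaults$initial_concentrations)
  if (!is.null(initial_concentrations)) {
    unknown <- setdiff(names(initial_concentrations), names(init))
    if (length(unknown))
      stop("unknown species key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    init[names(initial_concentrations)] <- unlist(initial_concentrations)
  }
  kc <- unlist(defaults$kinetic_constants)
  if (!is.null(kinetic_constants)) {
    unknown <- setdiff(names(kinetic_constants), names(kc))
    if (length(unknown))
      stop("unknown kinetic constant(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    kc[names(kinetic_constants)] <- unlist(kinetic_constants)
  }
  bl <- unlist(defaults$enzyme_baselines)
  if (!is.null(enzyme_baselines)) bl[names(enzyme_baselines)] <- unlist(enzyme_baselines)
  if (any(bl <= 0)) stop("enzyme baselines must be > 0", call. = FALSE)
  syn <- grep("^(k0|k1|k_deg)_", names(kc), value = TRUE)
  if (any(kc[syn] <= 0))
    stop("all enzyme synthesis and degradation constants must be > 0",
         call. = FALSE)
  structure(list(initial_concentrations = init, kinetic_constants = kc,
                 enzyme_baselines = bl),
            class = "antioxidant_model_config")
}

.ANTIOX_ENZYMES <- c("CAT", "HO1", "SOD", "GPx")

#' Build the antioxidant-enzyme production network
#'
#' Constructs the Nrf2/Keap1/ARE axis: reversible Keap1--Nrf2 complex
#' formation in the cytosol; H2O2-stimulated release of Nrf2 from the
#' complex; Keap1-promoted degradation of complexed Nrf2; nuclear import of
#' free Nrf2; reversible dimerisation of nuclear Nrf2 with Maf; and, for
#' each of CAT, HO-1, SOD and GPx, a lumped synthesis flux (zeroth-order
#' basal term plus an ARE-activated term proportional to the nuclear
#' Nrf2-Maf complex) balanced by first-order degradation. Intracellular
#' H2O2 is maintained by a constant source and first-order clearance.
#' Keap1 (free + complexed) and Maf (free + complexed) are conserved
#' moieties of the network.
#'
#' @param config An [antioxidant_model_config()].
#' @return A validated [reaction_network()] named `"antioxidant_production"`.
#' @export
build_antioxidant_network <- function(config = antioxidant_model_config()) {
  stopifnot(inherits(config, "antioxidant_model_config"))
  init <- config$initial_concentrations
  kc <- as.list(config$kinetic_constants)
  core <- c("k_nrf2_syn", "k_bind", "k_unbind", "k_rel", "k_dKN", "k_imp",
            "k_dn", "k_nm", "k_nmu", "k_dNM", "k_h_src", "k_h_clr")
  per_enzyme <- c(outer(c("k0_", "k1_", "k_deg_"), .ANTIOX_ENZYMES, paste0))
  missing <- setdiff(c(core, per_enzyme), names(kc))
  if (length(missing))
    stop("missing kinetic constant(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sp <- c(
    list(species("Maf", init[["Maf"]], "small Maf nuclear protein"),
         species("Keap1", init[["Keap1"]], "Keap1"),
         species("Nrf2", init[["Nrf2"]], "cytosolic Nrf2"),
         species("H2O2i", init[["H2O2i"]], "basal intracellular H2O2"),
         species("Keap1_Nrf2", 0, "Keap1-Nrf2 complex"),
         species("Nrf2n", 0, "nuclear Nrf2"),
         species("Nrf2n_Maf", 0, "nuclear Nrf2-Maf complex")),
    lapply(.ANTIOX_ENZYMES, function(e) species(e, 0, e)))
  ma <- function(k) rate_law("mass_action", k = k)
  rx <- list(
    reaction("nrf2_synthesis", NULL, c(Nrf2 = 1),
             rate = rate_law("constant_flux", k = kc$k_nrf2_syn)),
    reaction("keap1_binding", c(Keap1 = 1, Nrf2 = 1), c(Keap1_Nrf2 = 1),
             rate = ma(kc$k_bind)),
    reaction("keap1_unbinding", c(Keap1_Nrf2 = 1), c(Keap1 = 1, Nrf2 = 1),
             rate = ma(kc$k_unbind)),
    reaction("h2o2_nrf2_release", c(Keap1_Nrf2 = 1), c(Keap1 = 1, Nrf2 = 1),
             modifiers = "H2O2i", rate = ma(kc$k_rel)),
    reaction("keap1_mediated_degradation", c(Keap1_Nrf2 = 1), c(Keap1 = 1),
             rate = ma(kc$k_dKN)),
    reaction("nrf2_nuclear_import", c(Nrf2 = 1), c(Nrf2n = 1),
             rate = ma(kc$k_imp)),
    reaction("nrf2n_degradation", c(Nrf2n = 1), NULL, rate = ma(kc$k_dn)),
    reaction("maf_binding", c(Nrf2n = 1, Maf = 1), c(Nrf2n_Maf = 1),
             rate = ma(kc$k_nm)),
    reaction("maf_unbinding", c(Nrf2n_Maf = 1), c(Nrf2n = 1, Maf = 1),
             rate = ma(kc$k_nmu)),
    reaction("nm_degradation", c(Nrf2n_Maf = 1), c(Maf = 1),
             rate = ma(kc$k_dNM)),
    reaction("h2o2i_source", NULL, c(H2O2i = 1),
             rate = rate_law("constant_flux", k = kc$k_h_src)),
    reaction("h2o2i_clearance", c(H2O2i = 1), NULL, rate = ma(kc$k_h_clr)))
  for (e in .ANTIOX_ENZYMES) {
    rx <- c(rx, list(
      reaction(paste0("basal_synthesis_", e), NULL,
               stats::setNames(1, e),
               rate = rate_law("constant_flux", k = kc[[paste0("k0_", e)]])),
      reaction(paste0("are_synthesis_", e), c(Nrf2n_Maf = 1),
               stats::setNames(c(1, 1), c("Nrf2n_Maf", e)),
               rate = ma(kc[[paste0("k1_", e)]])),
      reaction(paste0("degradation_", e), stats::setNames(1, e), NULL,
               rate = ma(kc[[paste0("k_deg_", e)]]))))
  }
  net <- reaction_network(sp, rx, name = "antioxidant_production")
  .stop_if_invalid(net)
  net
}

#' Couple the ROS and antioxidant networks
#'
#' `mode = "independent"` (the default reading, matching per-pathway
#' biomarker reporting) returns the disjoint union of both networks, with
#' colliding species ids prefixed by their network name. `mode =
#' "shared_h2o2"` merges the two hydrogen-peroxide pools into one `H2O2`
#' species (the antioxidant model's basal level is kept as its initial
#' value) and replaces the fixed enzyme pools of the ROS network (SOD,
#' catalase, glutathione peroxidase) by the dynamically synthesised enzymes
#' of the antioxidant network, closing the feedback loop oxidant -> Nrf2 ->
#' enzymes -> oxidant clearance.
#'
#' @param ros A validated ROS-production network.
#' @param antiox A validated antioxidant-production network.
#' @param mode `"independent"` or `"shared_h2o2"`.
#' @return A validated [reaction_network()] with attribute `"coupling"`
#'   listing merged pools and renamed species.
#' @export
couple_models <- function(ros, antiox, mode = c("independent", "shared_h2o2")) {
  mode <- match.arg(mode)
  .stop_if_invalid(ros); .stop_if_invalid(antiox)
  rename_in_net <- function(net, map) {
    for (old in names(map)) {
      new <- map[[old]]
      i <- match(old, names(net$species))
      if (!is.na(i)) {
        net$species[[i]]$id <- new
        names(net$species)[i] <- new
      }
      net$reactions <- lapply(net$reactions, function(r) {
        names(r$reactants)[names(r$reactants) == old] <- new
        names(r$products)[names(r$products) == old] <- new
        r$modifiers[r$modifiers == old] <- new
        if (!is.null(r$rate$orders))
          names(r$rate$orders)[names(r$rate$orders) == old] <- new
        r
      })
    }
    net
  }
  merged <- character(0); renamed <- character(0)
  if (mode == "shared_h2o2") {
    need <- c("H2O2" %in% names(ros$species), "H2O2i" %in% names(antiox$species))
    if (!all(need))
      stop("shared_h2o2 coupling requires an H2O2 species in the ROS network ",
           "and an H2O2i species in the antioxidant network", call. = FALSE)
    # unify pool/enzyme ids so the union shares them
    ros <- rename_in_net(ros, c(Catalase = "CAT", GPr = "GPx"))
    antiox <- rename_in_net(antiox, c(H2O2i = "H2O2"))
    merged <- c("H2O2", "SOD", "CAT", "GPx")
  }
  collide <- intersect(names(ros$species), names(antiox$species))
  keep_antiox_def <- intersect(collide, merged)
  prefix <- setdiff(collide, merged)
  if (length(prefix)) {
    map1 <- stats::setNames(paste0("ros_", prefix), prefix)
    map2 <- stats::setNames(paste0("antiox_", prefix), prefix)
    ros <- rename_in_net(ros, map1)
    antiox <- rename_in_net(antiox, map2)
    renamed <- c(map1, map2)
  }
  # for merged pools the antioxidant model's species definition wins
  ros_keep <- ros$species[setdiff(names(ros$species), keep_antiox_def)]
  net <- reaction_network(c(ros_keep, antiox$species),
                          c(ros$reactions, antiox$reactions),
                          name = paste0("oxidative_stress_",
                                        sub("_h2o2", "", mode)))
  .stop_if_invalid(net)
  attr(net, "coupling") <- list(mode = mode, merged = merged,
                                renamed = renamed)
  net
}

#' Calibrate kinetic constants to a target steady-state panel
#'
#' For each enzyme target with a `basal_synthesis_<E>` / `are_synthesis_<E>`
#' / `degradation_<E>` reaction triple, the closed form `k_syn = k_deg *
#' target` fixes the total synthesis flux at steady state; it is split
#' between the basal and ARE-activated terms in the proportion already
#' present in the network, using the simulated steady-state nuclear
#' Nrf2-Maf level (enzymes are downstream of the Nrf2 axis, so the closed
#' form is exact). An enzyme with only a basal synthesis reaction gets
#' `k0 = k_deg * target` exactly. A non-enzyme target (e.g. the steady-state
#' superoxide readout of the ROS network) is met by a deterministic 1-D root
#' search over the single free constant named in `free_constants`.
#'
#' @param network A validated [reaction_network()].
#' @param targets Named positive vector: species id -> target steady-state
#'   concentration (nM) at the end of the horizon.
#' @param free_constants For non-enzyme targets, the flat constant names
#'   ([network_constants()] naming) to tune, one per such target, in order.
#' @param tolerance Relative tolerance on the achieved panel.
#' @param settings A [simulation_settings()].
#' @return An object of class `calibration_fit`: list with `constants`
#'   (named vector, the calibrated parameter set), `achieved`, `residuals`
#'   (relative), and `converged`.
#' @export
calibrate_baselines <- function(network, targets, free_constants = NULL,
                                tolerance = 0.02,
                                settings = simulation_settings()) {
  if (any(targets <= 0) || is.null(names(targets)))
    stop("targets must be a named, strictly positive vector", call. = FALSE)
  .stop_if_invalid(network)
  constants <- numeric(0)
  is_enzyme <- vapply(names(targets), function(nm)
    !is.null(network$reactions[[paste0("degradation_", nm)]]) &&
      !is.null(network$reactions[[paste0("basal_synthesis_", nm)]]),
    logical(1))

  nm_ss <- NULL
  if (any(is_enzyme)) {
    needs_are <- any(vapply(names(targets)[is_enzyme], function(nm)
      !is.null(network$reactions[[paste0("are_synthesis_", nm)]]), logical(1)))
    if (needs_are) {
      res <- integrate_network(network, settings)
      nm_ss <- detect_steady_state(res, settings)$state[["Nrf2n_Maf"]]
    }
    for (nm in names(targets)[is_enzyme]) {
      k_deg <- rate_constant(network, paste0("degradation_", nm))
      k_syn_total <- k_deg * targets[[nm]]
      k0 <- rate_constant(network, paste0("basal_synthesis_", nm))
      if (is.null(network$reactions[[paste0("are_synthesis_", nm)]])) {
        constants[[paste0("basal_synthesis_", nm, ".k")]] <- k_syn_total
      } else {
        k1 <- rate_constant(network, paste0("are_synthesis_", nm))
        share_basal <- k0 / (k0 + k1 * nm_ss)
        constants[[paste0("basal_synthesis_", nm, ".k")]] <-
          share_basal * k_syn_total
        constants[[paste0("are_synthesis_", nm, ".k")]] <-
          (1 - share_basal) * k_syn_total / nm_ss
      }
    }
  }

  other <- names(targets)[!is_enzyme]
  if (length(other)) {
    if (length(free_constants) != length(other))
      stop("need exactly one free constant per non-enzyme target ",
           "(got ", length(free_constants), " for ", length(other), ")",
           call. = FALSE)
    net2 <- update_constants(network, constants)
    for (i in seq_along(other)) {
      sp_id <- other[i]
      cname <- free_constants[i]
      base <- network_constants(net2)[[cname]]
      obj <- function(logm) {
        n <- update_constants(net2, stats::setNames(base * 10^logm, cname))
        ss <- detect_steady_state(integrate_network(n, settings))$state
        log(ss[[sp_id]] / targets[[sp_id]])
      }
      root <- stats::uniroot(obj, interval = c(-4, 4), tol = 1e-10)
      constants[[cname]] <- base * 10^root$root
      net2 <- update_constants(net2, constants[cname])
    }
  }

  fitted <- update_constants(network, constants)
  ss <- detect_steady_state(integrate_network(fitted, settings))$state
  achieved <- vapply(names(targets), function(nm) ss[[nm]], numeric(1))
  residuals <- (achieved - targets) / targets
  converged <- all(abs(residuals) <= tolerance)
  if (!converged)
    stop("calibration did not reach tolerance ", tolerance,
         "; best residuals: ",
         paste(sprintf("%s=%+.3g", names(targets), residuals), collapse = ", "),
         call. = FALSE)
  structure(list(constants = constants, achieved = achieved,
                 residuals = residuals, converged = converged),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>", length(x$constants), "constant(s); max |rel residual| =",
      signif(max(abs(x$residuals)), 3), "\n")
  print(signif(x$constants, 6))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) object$constants
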