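#' Define a simulation campaign
#'
#' @param model `"ros"`, `"antioxidant"`, or `"integrated"` (both pathway
#'   models; biomarkers are evaluated per pathway, the default reading).
#' @param compounds Named list of [compound_mechanism()] objects.
#' @param dose_grids Named list of dose grids (same names as `compounds`);
#'   default: a 5-point linear grid from 0 to each compound's `max_dose`.
#' @param aging_fold NADPH-oxidase activity fold for the aging condition
#'   (default 2).
#' @param settings A [simulation_settings()].
#' @param outputs Requested biomarkers, subset of
#'   `c("ros", "cat", "ho1", "sod", "gpx")`.
#' @param ros_config,antiox_config Model configurations.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(model = c("integrated", "ros", "antioxidant"),
                            compounds = default_compounds(),
                            dose_grids = NULL,
                            aging_fold = 2,
                            settings = simulation_settings(),
                            outputs = c("ros", "cat", "ho1", "sod", "gpx"),
                            ros_config = ros_model_config(),
                            antiox_config = antioxidant_model_config()) {
  model <- match.arg(model)
  outputs <- match.arg(outputs, several.ok = TRUE)
  .assert_scalar_num(aging_fold, "aging_fold", positive = TRUE)
  if (is.null(dose_grids))
    dose_grids <- lapply(compounds, function(m)
      make_dose_grid(m$max_dose, n_points = 5, spacing = "linear"))
  stopifnot(all(names(dose_grids) %in% names(compounds)))
  for (g in dose_grids)
    if (any(g < 0) || is.unsorted(g))
      stop("dose grids must be non-negative and sorted", call. = FALSE)
  structure(list(model = model, compounds = compounds,
                 dose_grids = dose_grids, aging_fold = aging_fold,
                 settings = settings, outputs = outputs,
                 ros_config = ros_config, antiox_config = antiox_config),
            class = "experiment_plan")
}

.BIOMARKER_SPECIES <- c(cat = "CAT", ho1 = "HO1", sod = "SOD", gpx = "GPx")

# integrate + steady state; cumulative scavenging sinks are integrals by
# construction, so they are excluded from the steadiness flag
.steady_state <- function(network, settings) {
  res <- integrate_network(network, settings)
  ss <- detect_steady_state(res, settings)
  keep <- !grepl("^scavenged_", names(ss$relative_drift))
  list(state = ss$state,
       reached = all(ss$relative_drift[keep] < settings$steady_threshold))
}

.wants_ros <- function(plan) plan$model %in% c("ros", "integrated") &&
  "ros" %in% plan$outputs
.wants_enzymes <- function(plan) plan$model %in% c("antioxidant", "integrated") &&
  any(names(.BIOMARKER_SPECIES) %in% plan$outputs)

.ros_net <- function(plan) apply_aging_condition(build_ros_network(plan$ros_config),
                                                 plan$aging_fold)
.antiox_net <- function(plan) build_antioxidant_network(plan$antiox_config)

# biomarker vector for one (possibly compound-perturbed) condition
.measure <- function(plan, ros_net = NULL, antiox_net = NULL) {
  out <- list(values = numeric(0), steady = logical(0))
  if (!is.null(ros_net)) {
    s <- .steady_state(ros_net, plan$settings)
    out$values[["ros"]] <- ros_biomarker(s$state, plan$ros_config)
    out$steady[["ros"]] <- s$reached
  }
  if (!is.null(antiox_net)) {
    s <- .steady_state(antiox_net, plan$settings)
    for (b in intersect(names(.BIOMARKER_SPECIES), plan$outputs)) {
      out$values[[b]] <- s$state[[.BIOMARKER_SPECIES[[b]]]]
      out$steady[[b]] <- s$reached
    }
  }
  out
}

#' Run the control condition
#'
#' Simulates the plan's model(s) with zero compound dose and the aging fold
#' applied to the NADPH-oxidase source, and returns the biomarker panel at
#' steady state (the trailing-window mean at the end of the horizon).
#'
#' @param plan An [experiment_plan()].
#' @return An object of class `biomarker_panel`: named numeric vector of
#'   biomarker levels (nM) with a `steady` attribute of per-pathway
#'   steadiness flags.
#' @export
run_control <- function(plan = experiment_plan()) {
  m <- .measure(plan,
                ros_net = if (.wants_ros(plan)) .ros_net(plan),
                antiox_net = if (.wants_enzymes(plan)) .antiox_net(plan))
  structure(m$values, steady = m$steady, class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("<biomarker_panel> (nM)\n")
  print(signif(unclass(x), 5))
  st <- attr(x, "steady")
  if (!all(st)) cat("warning: steady state not reached for:",
                    paste(names(st)[!st], collapse = ", "), "\n")
  invisible(x)
}

.result_row <- function(plan, label, dose, serum, biomarker, control, treated,
                        steady) {
  data.frame(model = plan$model, compound = label, dose = dose,
             serum_nM = serum, biomarker = biomarker,
             control_value = control, treated_value = treated,
             percent_change = if (isTRUE(dose == 0)) 0
                              else percent_change(control, treated),
             steady_reached = steady, stringsAsFactors = FALSE)
}

.treated_measure <- function(plan, mech, serum) {
  ros_net <- if (.wants_ros(plan))
    apply_compound(.ros_net(plan), mech, serum)
  antiox_net <- if (.wants_enzymes(plan))
    apply_compound(.antiox_net(plan), mech, serum)
  .measure(plan, ros_net, antiox_net)
}

#' Run a dose-response sweep for one compound
#'
#' One simulation per grid dose (including the dose-0 control row); serum
#' levels follow the compound's Cmax mapping. Monotonicity of each
#' biomarker's response in dose is checked and annotated in the
#' `"monotone"` attribute.
#'
#' @param plan An [experiment_plan()].
#' @param compound Compound name present in the plan.
#' @return A `result_table` data frame with one row per (dose, biomarker):
#'   columns model, compound, dose, serum_nM, biomarker, control_value,
#'   treated_value, percent_change, steady_reached.
#' @export
run_dose_response <- function(plan, compound) {
  mech <- plan$compounds[[compound]]
  if (is.null(mech)) stop("compound '", compound, "' not in plan", call. = FALSE)
  grid <- plan$dose_grids[[compound]]
  control <- run_control(plan)
  rows <- list()
  for (dose in grid) {
    serum <- dose_to_serum(dose_spec(compound, dose, mech$cmax,
                                     mech$reference_dose,
                                     dose_unit = mech$dose_unit))
    m <- if (dose == 0) list(values = unclass(control),
                             steady = attr(control, "steady"))
         else .treated_measure(plan, mech, serum)
    for (b in names(m$values))
      rows[[length(rows) + 1L]] <-
        .result_row(plan, compound, dose, serum, b,
                    unclass(control)[[b]], m$values[[b]], m$steady[[b]])
  }
  tab <- do.call(rbind, rows)
  mono <- vapply(split(tab, tab$biomarker), function(d) {
    d <- d[order(d$dose), ]
    all(diff(d$treated_value) <= 1e-6 * abs(d$treated_value[-1]) + 1e-9) ||
      all(diff(d$treated_value) >= -1e-6 * abs(d$treated_value[-1]) - 1e-9)
  }, logical(1))
  attr(tab, "monotone") <- mono
  class(tab) <- c("result_table", "data.frame")
  tab
}

.max_serum <- function(plan, cpd) {
  mech <- plan$compounds[[cpd]]
  dose_to_serum(dose_spec(cpd, max(plan$dose_grids[[cpd]]), mech$cmax,
                          mech$reference_dose, dose_unit = mech$dose_unit))
}

#' Run the combination condition
#'
#' Applies every compound in the plan simultaneously, each at the maximum
#' dose of its grid, and also runs each compound individually at its maximum
#' dose for comparison.
#'
#' @param plan An [experiment_plan()] with at least two compounds.
#' @return A `result_table`; the combination rows carry
#'   `compound = "combination"`.
#' @export
run_combination <- function(plan) {
  cpds <- names(plan$compounds)
  if (!length(cpds))
    stop("combination needs at least one compound", call. = FALSE)
  control <- run_control(plan)
  serum <- vapply(cpds, function(cpd) .max_serum(plan, cpd), numeric(1))
  ros_net <- if (.wants_ros(plan))
    apply_combination(.ros_net(plan), plan$compounds, serum)
  antiox_net <- if (.wants_enzymes(plan))
    apply_combination(.antiox_net(plan), plan$compounds, serum)
  m <- .measure(plan, ros_net, antiox_net)
  rows <- list()
  for (b in names(m$values))
    rows[[length(rows) + 1L]] <-
      .result_row(plan, "combination", NA_real_, NA_real_, b,
                  unclass(control)[[b]], m$values[[b]], m$steady[[b]])
  # per-compound best (max-dose) singles for comparison
  for (cpd in cpds) {
    ms <- .treated_measure(plan, plan$compounds[[cpd]], serum[[cpd]])
    for (b in names(ms$values))
      rows[[length(rows) + 1L]] <-
        .result_row(plan, cpd, max(plan$dose_grids[[cpd]]), serum[[cpd]], b,
                    unclass(control)[[b]], ms$values[[b]], ms$steady[[b]])
  }
  tab <- do.call(rbind, rows)
  tab$percent_change <- percent_change(tab$control_value, tab$treated_value)
  class(tab) <- c("result_table", "data.frame")
  tab
}

#' Fit compound effect constants to target percent responses
#'
#' Inverse problem closing the parameterisation gap: given one enzyme-panel
#' percent-increase target per compound (the activated-synthesis factor is
#' shared across the four enzymes, so one scalar per compound suffices),
#' finds the compound's saturating-effect amplitude (`a` for nuclear-import
#' activation, `emax` for Keap1 downregulation or degradation inhibition) by
#' a deterministic 1-D root search on the forward-simulated max-dose
#' response. EC50-type constants (`b`) are fixed by the compound fixture
#' (for ellagic acid, located by its reported dose plateau). A target above
#' the saturating law's ceiling raises an error naming the compound.
#'
#' @param targets Named numeric vector: compound -> target percent increase
#'   of the enzyme panel at the compound's maximum dose.
#' @param plan An [experiment_plan()].
#' @return An object of class `effect_fit`: list with `constants` (named
#'   list compound -> named constant vector), `achieved`, `residuals`
#'   (percentage points), and `mechanisms` (the plan's mechanisms with
#'   fitted constants merged, ready for use).
#' @export
fit_effect_constants <- function(targets, plan = experiment_plan()) {
  if (is.null(names(targets)) || !all(names(targets) %in% names(plan$compounds)))
    stop("targets must be named by compounds present in the plan", call. = FALSE)
  base_net <- .antiox_net(plan)
  control_cat <- .steady_state(base_net, plan$settings)$state[["CAT"]]
  mechs <- plan$compounds
  constants <- list(); achieved <- numeric(0)
  for (cpd in names(targets)) {
    mech <- mechs[[cpd]]
    axis <- setdiff(mech$targets, "ros_scavenging")
    if (!length(axis))
      stop("compound '", cpd, "' has no Nrf2-axis target to fit", call. = FALSE)
    param <- if (axis[1L] %in% c("nrf2_activation", "p21_upregulation")) "a"
             else "emax"
    serum <- .max_serum(plan, cpd)
    forward <- function(value) {
      m2 <- mech
      m2$effect_constants[[param]] <- value
      net <- apply_compound(base_net, m2, serum)
      treated <- .steady_state(net, plan$settings)$state[["CAT"]]
      percent_change(control_cat, treated)
    }
    upper <- if (param == "emax") 0.999999 else {
      u <- 1
      while (forward(u) < targets[[cpd]] && u < 1e6) u <- u * 4
      u
    }
    if (forward(upper) < targets[[cpd]])
      stop("target ", targets[[cpd]], "% for '", cpd,
           "' is unachievable under the saturating effect law", call. = FALSE)
    root <- stats::uniroot(function(v) forward(v) - targets[[cpd]],
                           interval = c(0, upper), tol = 1e-7 * max(upper, 1))
    constants[[cpd]] <- stats::setNames(root$root, param)
    achieved[[cpd]] <- targets[[cpd]] + root$f.root
    mechs[[cpd]]$effect_constants[[param]] <- root$root
  }
  structure(list(constants = constants, achieved = achieved,
                 residuals = achieved - targets, mechanisms = mechs),
            class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  cat("<effect_fit>\n")
  for (cpd in names(x$constants))
    cat(sprintf("  %-14s %s = %.6g  (achieved %+.2f%%, residual %+.3f pp)\n",
                cpd, names(x$constants[[cpd]]), x$constants[[cpd]],
                x$achieved[[cpd]], x$residuals[[cpd]]))
  invisible(x)
}

#' @export
coef.effect_fit <- function(object, ...) {
  unlist(lapply(names(object$constants), function(cpd)
    stats::setNames(object$constants[[cpd]],
                    paste(cpd, names(object$constants[[cpd]]), sep = "."))))
}
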