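#' Compound definitions: mechanisms, potencies and dosing
#'
#' Loads the shipped compound fixture
#' (`inst/extdata/compounds_synthetic.yaml`) describing the six
#' phytonutrients (cyanidin, delphinidin, ellagic acid, kaempferol,
#' malvidin, rutin): their pathway targets, effect constants, and the
#' Cmax-based dose-to-serum mapping. All six scavenge ROS; all but cyanidin
#' additionally act on the Nrf2 axis (delphinidin/malvidin: upregulation of
#' nuclear translocation; ellagic acid: Keap1 downregulation; kaempferol:
#' inhibition of Nrf2 degradation; rutin: p21-mediated activation, lumped
#' into the nuclear-import factor since p21 is not a state variable).
#' Dose/Cmax values and ROS-scavenging potencies in the fixture are
#' synthetic, literature-scale stand-ins (see the fixture header);
#' Nrf2-axis effect constants are the frozen output of
#' [fit_effect_constants()].
#'
#' @param path Optional alternative fixture path.
#' @return Named list of `compound_mechanism` objects.
#' @export
default_compounds <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "compounds_synthetic.yaml",
                        package = "redoxsim")
  raw <- yaml::read_yaml(path)$compounds
  out <- lapply(names(raw), function(nm) {
    rec <- raw[[nm]]
    compound_mechanism(compound = nm,
                       targets = unlist(rec$targets),
                       effect_constants = unlist(rec$effect_constants),
                       cmax = rec$cmax_nM,
                       reference_dose = rec$reference_dose,
                       dose_unit = rec$dose_unit,
                       max_dose = rec$max_dose,
                       enzyme_target_percent = rec$enzyme_target_percent %||% NA_real_)
  })
  names(out) <- names(raw)
  out
}

.COMPOUNDS <- c("cyanidin", "delphinidin", "ellagic_acid", "kaempferol",
                "malvidin", "rutin")
.TARGETS <- c("ros_scavenging", "nrf2_activation", "keap1_downregulation",
              "nrf2_degradation_inhibition", "p21_upregulation")

#' Define a compound mechanism
#'
#' @param compound One of the six supported compound names.
#' @param targets Subset of `"ros_scavenging"`, `"nrf2_activation"`,
#'   `"keap1_downregulation"`, `"nrf2_degradation_inhibition"`,
#'   `"p21_upregulation"`.
#' @param effect_constants Named vector of potencies: `k_scav`
#'   (second-order scavenging constant, 1/nM/s), `a` and `b` (saturating
#'   activation amplitude and EC50 in nM) or `emax` and `b` (saturating
#'   down-scaling amplitude, 0 <= emax < 1, and EC50 in nM).
#' @param cmax Peak serum concentration (nM) at `reference_dose`.
#' @param reference_dose Dose at which `cmax` was measured.
#' @param dose_unit Unit label of the dietary dose axis.
#' @param max_dose Top of the compound's dose grid.
#' @param enzyme_target_percent Reported enzyme-panel percent increase at
#'   max dose (fitting target; `NA` for compounds without an Nrf2 effect).
#' @return An object of class `compound_mechanism`.
#' @export
compound_mechanism <- function(compound, targets, effect_constants,
                               cmax = NA_real_, reference_dose = NA_real_,
                               dose_unit = "mg/day", max_dose = NA_real_,
                               enzyme_target_percent = NA_real_) {
  compound <- match.arg(compound, .COMPOUNDS)
  unknown <- setdiff(targets, .TARGETS)
  if (length(unknown))
    stop("unknown target(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!"ros_scavenging" %in% targets)
    stop("every compound scavenges ROS ('ros_scavenging' missing for ",
         compound, ")", call. = FALSE)
  nrf2_axis <- setdiff(targets, "ros_scavenging")
  if (compound == "cyanidin" && length(nrf2_axis))
    stop("cyanidin targets exactly {ros_scavenging}", call. = FALSE)
  if (compound != "cyanidin" && !length(nrf2_axis))
    stop(compound, " must carry an Nrf2-axis target", call. = FALSE)
  structure(list(compound = compound, targets = targets,
                 effect_constants = effect_constants, cmax = cmax,
                 reference_dose = reference_dose, dose_unit = dose_unit,
                 max_dose = max_dose,
                 enzyme_target_percent = enzyme_target_percent),
            class = "compound_mechanism")
}

#' @export
print.compound_mechanism <- function(x, ...) {
  cat(sprintf("<compound_mechanism> %s: %s\n", x$compound,
              paste(x$targets, collapse = ", ")))
  cat(sprintf("  Cmax %g nM at %g %s; dose grid up to %g %s\n", x$cmax,
              x$reference_dose, x$dose_unit, x$max_dose, x$dose_unit))
  invisible(x)
}

#' Dose specification
#'
#' @param compound Compound name.
#' @param dietary_dose Administered dose (units as in the compound fixture).
#' @param cmax Peak serum concentration (nM) at `reference_dose`.
#' @param reference_dose Dose at which `cmax` applies (> 0).
#' @param saturation Optional serum cap (nM).
#' @param dose_unit Unit label.
#' @return An object of class `dose_spec`.
#' @export
dose_spec <- function(compound, dietary_dose, cmax, reference_dose,
                      saturation = NULL, dose_unit = "mg/day") {
  .assert_scalar_num(dietary_dose, "dietary_dose", nonneg = TRUE)
  .assert_scalar_num(cmax, "cmax", positive = TRUE)
  .assert_scalar_num(reference_dose, "reference_dose", positive = TRUE)
  structure(list(compound = compound, dietary_dose = dietary_dose,
                 cmax = cmax, reference_dose = reference_dose,
                 saturation = saturation, dose_unit = dose_unit),
            class = "dose_spec")
}

#' Map a dietary dose to a serum concentration
#'
#' Serum level at the cell surface scales linearly with dose through the
#' compound's Cmax at its reference dose, optionally capped at a saturation
#' level: `serum = min(dose / reference_dose * cmax, saturation)`.
#'
#' @param spec A [dose_spec()].
#' @return Serum concentration in nM.
#' @export
#' @examples
#' dose_to_serum(dose_spec("rutin", 200, cmax = 200, reference_dose = 200)) # 200
dose_to_serum <- function(spec) {
  stopifnot(inherits(spec, "dose_spec"))
  s <- spec$dietary_dose / spec$reference_dose * spec$cmax
  if (!is.null(spec$saturation)) s <- min(s, spec$saturation)
  s
}

.saturating <- function(serum, b) serum / (b + serum)

#' Apply a compound's mechanisms to a network
#'
#' Per target (only targets resolvable in the given network are applied;
#' e.g. ROS scavenging needs the superoxide pool, Nrf2-axis effects need the
#' Nrf2 cycle):
#' \describe{
#'   \item{ros_scavenging}{adds the compound as a clamped species at its
#'     serum level (constant administration over the whole horizon) plus the
#'     second-order scavenging reaction `superoxide + compound ->
#'     scavenged_<compound>` with rate `k_scav * [superoxide] * [compound]`;
#'     the inert sink accumulates the scavenged mass.}
#'   \item{nrf2_activation / p21_upregulation}{scales the Nrf2 nuclear-import
#'     rate by the saturating factor `1 + a * serum / (b + serum)`.}
#'   \item{keap1_downregulation}{scales the Keap1 pool down by
#'     `1 - emax * serum / (b + serum)`.}
#'   \item{nrf2_degradation_inhibition}{scales the Keap1-mediated Nrf2
#'     degradation rate down by the same form.}
#' }
#' All factors are continuous, monotone in serum and bounded (Emax-type), so
#' no rate becomes singular at high dose. At `serum = 0` the input network
#' is returned unchanged.
#'
#' @param network A validated [reaction_network()].
#' @param mechanism A [compound_mechanism()].
#' @param serum Serum concentration at the cell surface (nM, >= 0).
#' @return A modified copy of the network.
#' @export
apply_compound <- function(network, mechanism, serum) {
  stopifnot(inherits(mechanism, "compound_mechanism"))
  .assert_scalar_num(serum, "serum", nonneg = TRUE)
  if (serum == 0) return(network)
  ec <- as.list(mechanism$effect_constants)
  cpd <- mechanism$compound
  for (target in mechanism$targets) {
    resolvable <- switch(target,
      ros_scavenging = "superoxide" %in% names(network$species),
      nrf2_activation = ,
      p21_upregulation = !is.null(network$reactions[["nrf2_nuclear_import"]]),
      keap1_downregulation = "Keap1" %in% names(network$species),
      nrf2_degradation_inhibition =
        !is.null(network$reactions[["keap1_mediated_degradation"]]),
      stop("unknown target '", target, "'", call. = FALSE))
    if (!resolvable) next
    if (target == "ros_scavenging") {
      if (is.null(ec$k_scav)) stop("missing k_scav for ", cpd, call. = FALSE)
      sink <- paste0("scavenged_", cpd)
      if (cpd %in% names(network$species))
        stop("compound '", cpd, "' already applied", call. = FALSE)
      network$species <- c(network$species, stats::setNames(list(
        species(cpd, serum, cpd, constant = TRUE),
        species(sink, 0, paste("scavenged", cpd, "adduct"))),
        c(cpd, sink)))
      network$reactions[[paste0("scavenge_", cpd)]] <-
        reaction(paste0("scavenge_", cpd),
                 stats::setNames(c(1, 1), c("superoxide", cpd)),
                 stats::setNames(1, sink),
                 rate = rate_law("mass_action", k = ec$k_scav))
    } else if (target %in% c("nrf2_activation", "p21_upregulation")) {
      fac <- 1 + ec$a * .saturating(serum, ec$b)
      rate_constant(network, "nrf2_nuclear_import") <-
        rate_constant(network, "nrf2_nuclear_import") * fac
    } else if (target == "keap1_downregulation") {
      fac <- 1 - ec$emax * .saturating(serum, ec$b)
      network <- set_initial(network, "Keap1",
                             network$species[["Keap1"]]$initial * fac)
    } else if (target == "nrf2_degradation_inhibition") {
      fac <- 1 - ec$emax * .saturating(serum, ec$b)
      rate_constant(network, "keap1_mediated_degradation") <-
        rate_constant(network, "keap1_mediated_degradation") * fac
    }
  }
  .stop_if_invalid(network)
  network
}

#' Apply a combination of compounds
#'
#' Sequential application of [apply_compound()]. Scaling factors commute and
#' scavenging reactions are disjoint per compound, so the resulting fluxes
#' are independent of application order.
#'
#' @param network A validated [reaction_network()].
#' @param mechanisms List of [compound_mechanism()] objects.
#' @param serum Named numeric vector, compound -> serum level (nM); names
#'   must match `mechanisms`. Duplicate compounds are rejected.
#' @return A modified copy of the network.
#' @export
apply_combination <- function(network, mechanisms = default_compounds(),
                              serum = numeric()) {
  if (!length(serum)) return(network)
  if (anyDuplicated(names(serum)))
    stop("duplicate compound in combination", call. = FALSE)
  mnames <- vapply(mechanisms, `[[`, character(1), "compound")
  for (cpd in names(serum)) {
    i <- match(cpd, mnames)
    if (is.na(i)) stop("no mechanism for compound '", cpd, "'", call. = FALSE)
    network <- apply_compound(network, mechanisms[[i]], serum[[cpd]])
  }
  network
}
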