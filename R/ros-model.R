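#' Configuration of the ROS-production model
#'
#' Holds the initial concentrations of the eleven species of the
#' ROS-production pathway (lipid substrate, oxygen, water, ferrous/ferric
#' iron, SOD, hydrogen peroxide, catalase, glutathione, glutathione
#' peroxidase and NADPH oxidase), the kinetic constants, the aging
#' perturbation, and the declaration of which species constitutes the "ROS"
#' biomarker readout. Defaults are read from the shipped config file
#' `inst/extdata/ros_model.yaml`, whose concentration keys follow the source
#' nomenclature verbatim (`"Fe2+"`, `"NADPH Oxidase"`, ...).
#'
#' @param initial_concentrations Named overrides (verbatim keys), nM.
#' @param kinetic_constants Named overrides of kinetic constants.
#' @param aging_fold Positive scalar multiplying NADPH-oxidase activity under
#'   the aging condition (default 2: aged cells show roughly doubled NOX
#'   activity). Applied by [apply_aging_condition()], not at build time.
#' @param ros_readout Named weight vector over network species defining the
#'   ROS biomarker; default is the superoxide pool (the direct NOX product).
#' @return An object of class `ros_model_config`.
#' @export
ros_model_config <- function(initial_concentrations = NULL,
                             kinetic_constants = NULL,
                             aging_fold = 2,
                             ros_readout = c(superoxide = 1)) {
  defaults <- yaml::read_yaml(system.file("extdata", "ros_model.yaml",
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
  .assert_scalar_num(aging_fold, "aging_fold", positive = TRUE)
  if (any(init < 0)) stop("initial concentrations must be >= 0", call. = FALSE)
  structure(list(initial_concentrations = init, kinetic_constants = kc,
                 aging_fold = aging_fold, ros_readout = ros_readout),
            class = "ros_model_config")
}

# verbatim table key -> species id
.ROS_KEY_MAP <- c("LH" = "LH", "O2" = "O2", "H2O" = "H2O",
                  "Fe2+" = "Fe2", "Fe3+" = "Fe3", "SOD" = "SOD",
                  "H2O2" = "H2O2", "Catalase" = "Catalase", "GSH" = "GSH",
                  "GPr" = "GPr", "NADPH Oxidase" = "NOX")

#' Build the ROS-production reaction network
#'
#' Constructs the pro-oxidant pathway: an NADPH-oxidase-catalysed superoxide
#' source, SOD-catalysed and spontaneous dismutation of superoxide to
#' hydrogen peroxide, catalase- and glutathione-peroxidase-catalysed H2O2
#' clearance (with GSSG recycling closing the glutathione pool), Fenton
#' generation of hydroxyl radical from ferrous iron, first-order reductive
#' recycling of ferric iron (so total iron is conserved), and a lipid
#' peroxidation chain (initiation by hydroxyl radical, oxygenation,
#' propagation, radical-radical termination and hydroperoxide repair closing
#' the lipid pool). Water and oxygen are clamped bulk species. The network
#' is built unperturbed; apply the aging condition with
#' [apply_aging_condition()].
#'
#' @param config A [ros_model_config()].
#' @return A validated [reaction_network()] named `"ros_production"`.
#' @export
build_ros_network <- function(config = ros_model_config()) {
  stopifnot(inherits(config, "ros_model_config"))
  init <- config$initial_concentrations
  kc <- as.list(config$kinetic_constants)
  needed <- c("k_nox", "k_sod", "k_sp", "k_cat", "k_gpx", "k_gr", "k_fenton",
              "k_fered", "k_init", "k_ohsink", "k_oxy", "k_prop", "k_term",
              "k_repair")
  missing <- setdiff(needed, names(kc))
  if (length(missing))
    stop("missing kinetic constant(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sp <- c(
    lapply(names(.ROS_KEY_MAP), function(key)
      species(.ROS_KEY_MAP[[key]], initial = init[[key]], display_name = key,
              constant = key %in% c("H2O", "O2"))),
    list(species("superoxide", 0, "superoxide anion"),
         species("OH", 0, "hydroxyl radical"),
         species("GSSG", 0, "glutathione disulfide"),
         species("L", 0, "lipid radical"),
         species("LOO", 0, "lipid peroxyl radical"),
         species("LOOH", 0, "lipid hydroperoxide")))
  ma <- function(k) rate_law("mass_action", k = k)
  rx <- list(
    reaction("nox_superoxide", c(O2 = 1), c(superoxide = 1),
             modifiers = "NOX", rate = ma(kc$k_nox)),
    reaction("sod_dismutation", c(superoxide = 2), c(H2O2 = 1, O2 = 1),
             modifiers = "SOD",
             rate = rate_law("mass_action", k = kc$k_sod,
                             orders = c(superoxide = 1))),
    reaction("spontaneous_dismutation", c(superoxide = 2), c(H2O2 = 1, O2 = 1),
             rate = ma(kc$k_sp)),
    reaction("catalase_clearance", c(H2O2 = 2), c(H2O = 2, O2 = 1),
             modifiers = "Catalase",
             rate = rate_law("mass_action", k = kc$k_cat,
                             orders = c(H2O2 = 1))),
    reaction("gpx_clearance", c(H2O2 = 1, GSH = 2), c(H2O = 2, GSSG = 1),
             modifiers = "GPr",
             rate = rate_law("mass_action", k = kc$k_gpx,
                             orders = c(H2O2 = 1, GSH = 1))),
    reaction("gsh_regeneration", c(GSSG = 1), c(GSH = 2), rate = ma(kc$k_gr)),
    reaction("fenton", c(Fe2 = 1, H2O2 = 1), c(Fe3 = 1, OH = 1),
             rate = ma(kc$k_fenton)),
    reaction("iron_reduction", c(Fe3 = 1), c(Fe2 = 1), rate = ma(kc$k_fered)),
    reaction("lipid_initiation", c(LH = 1, OH = 1), c(L = 1, H2O = 1),
             rate = ma(kc$k_init)),
    reaction("hydroxyl_scavenging", c(OH = 1), c(H2O = 1),
             rate = ma(kc$k_ohsink)),
    reaction("lipid_oxygenation", c(L = 1, O2 = 1), c(LOO = 1),
             rate = ma(kc$k_oxy)),
    reaction("lipid_propagation", c(LOO = 1, LH = 1), c(LOOH = 1, L = 1),
             rate = ma(kc$k_prop)),
    reaction("lipid_termination", c(LOO = 2), c(LOOH = 2), rate = ma(kc$k_term)),
    reaction("lipid_repair", c(LOOH = 1), c(LH = 1), rate = ma(kc$k_repair)))
  net <- reaction_network(sp, rx, name = "ros_production")
  .stop_if_invalid(net)
  net
}

#' Apply the aging condition
#'
#' Aged cells show an approximately two-fold increase in NADPH-oxidase
#' activity. The perturbation scales the catalytic rate constant of the NOX
#' superoxide source (equivalent to scaling the clamped enzyme level, since
#' the source is linear in the enzyme); all other reactions are untouched.
#'
#' @param network A network containing the `nox_superoxide` reaction.
#' @param fold Positive scalar (1 = young control, 2 = aged default).
#' @return A modified copy of the network.
#' @export
apply_aging_condition <- function(network, fold = 2) {
  .assert_scalar_num(fold, "fold", nonneg = TRUE)
  if (is.null(network$reactions[["nox_superoxide"]]))
    stop("network has no NADPH-oxidase source reaction ('nox_superoxide')",
         call. = FALSE)
  rate_constant(network, "nox_superoxide") <-
    rate_constant(network, "nox_superoxide") * fold
  network
}

#' ROS biomarker readout
#'
#' @param state Named concentration vector (nM) covering the readout species.
#' @param config A [ros_model_config()] (its `ros_readout` weights are used).
#' @return ROS level in nM (weighted sum of the readout species).
#' @export
ros_biomarker <- function(state, config = ros_model_config()) {
  w <- config$ros_readout
  missing <- setdiff(names(w), names(state))
  if (length(missing))
    stop("readout species absent from state: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sum(w * state[names(w)])
}
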