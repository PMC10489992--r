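#' Define a chemical species
#'
#' Species are the state variables of a reaction network. Concentrations are
#' expressed in nM throughout the package; time is in seconds.
#'
#' @param id Short unique identifier (used in reactions and as the SBML id,
#'   so it must start with a letter and contain only letters, digits and
#'   underscores).
#' @param initial Initial concentration in nM (non-negative).
#' @param display_name Human-readable name; defaults to `id`.
#' @param constant If `TRUE` the species is clamped: its concentration never
#'   changes during simulation (bulk pools such as water, or a compound held
#'   at a fixed serum level).
#' @return An object of class `rx_species`.
#' @export
#' @examples
#' species("H2O2", initial = 0.38)
species <- function(id, initial = 0, display_name = id, constant = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", id))
    stop("species id must match ^[A-Za-z][A-Za-z0-9_]*$: ", id, call. = FALSE)
  .assert_scalar_num(initial, "initial", nonneg = TRUE)
  structure(list(id = id, display_name = display_name,
                 initial = as.numeric(initial), constant = isTRUE(constant)),
            class = "rx_species")
}

#' Define a kinetic rate law
#'
#' Four forms cover every reaction in the shipped pathway models:
#' \describe{
#'   \item{mass_action}{`k * prod(conc^order)` over the reaction's reactants
#'     (order defaults to the stoichiometric coefficient) and modifiers
#'     (order 1). Orders can be overridden per species via `orders`, e.g.
#'     for an enzymatic step written with stoichiometry 2 but first-order
#'     kinetics in the substrate.}
#'   \item{michaelis_menten}{`Vmax * S / (Km + S)`, `S` being the first
#'     reactant (or, when called directly, the first concentration); any
#'     further concentrations (e.g. an enzyme modifier) multiply linearly.}
#'   \item{hill}{`Vmax * S^n / (Km^n + S^n)` with `hill_n = n >= 1`;
#'     reduces to michaelis_menten at `n = 1`.}
#'   \item{constant_flux}{the constant `k` in nM/s (a zeroth-order source).}
#' }
#'
#' @param form One of `"mass_action"`, `"michaelis_menten"`, `"hill"`,
#'   `"constant_flux"`.
#' @param ... Named non-negative parameters (`k`, or `Vmax`/`Km`/`hill_n`).
#' @param orders Optional named numeric vector of kinetic orders overriding
#'   the stoichiometric default for mass-action laws.
#' @return An object of class `rate_law`.
#' @export
#' @examples
#' rate_law("mass_action", k = 2)
#' rate_law("michaelis_menten", Vmax = 10, Km = 5)
rate_law <- function(form = c("mass_action", "michaelis_menten", "hill",
                              "constant_flux"),
                     ..., orders = NULL) {
  form <- match.arg(form)
  params <- c(...)
  if (length(params) && (is.null(names(params)) || any(!nzchar(names(params)))))
    stop("rate-law parameters must be named", call. = FALSE)
  params <- vapply(params, as.numeric, numeric(1))
  need <- switch(form,
                 mass_action = "k", constant_flux = "k",
                 michaelis_menten = c("Vmax", "Km"),
                 hill = c("Vmax", "Km", "hill_n"))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop(sprintf("rate law '%s' is missing parameter(s): %s", form,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (any(params < 0))
    stop("rate-law parameters must be >= 0", call. = FALSE)
  if (form %in% c("michaelis_menten", "hill") && params[["Km"]] <= 0)
    stop("Km must be > 0", call. = FALSE)
  if (form == "hill" && params[["hill_n"]] < 1)
    stop("hill_n must be >= 1", call. = FALSE)
  if (!is.null(orders)) {
    if (is.null(names(orders)) || any(!nzchar(names(orders))))
      stop("'orders' must be a named numeric vector", call. = FALSE)
    orders <- vapply(orders, as.numeric, numeric(1))
  }
  structure(list(form = form, params = params, orders = orders),
            class = "rate_law")
}

#' Evaluate a rate law at given concentrations
#'
#' @param law A [rate_law()].
#' @param conc Named numeric vector of concentrations (nM) of the species the
#'   law acts on. For mass-action laws every entry enters the product (with
#'   its order); for saturating laws the first entry is the substrate and any
#'   further entries multiply linearly.
#' @return Flux in nM/s (finite, non-negative).
#' @export
#' @examples
#' evaluate_rate(rate_law("mass_action", k = 2), c(A = 3, B = 4)) # 24
evaluate_rate <- function(law, conc) {
  stopifnot(inherits(law, "rate_law"))
  conc <- unlist(conc)
  if (any(!is.finite(conc)))
    stop("non-finite concentration passed to evaluate_rate", call. = FALSE)
  if (any(conc < 0))
    stop("negative concentration passed to evaluate_rate", call. = FALSE)
  p <- law$params
  flux <- switch(law$form,
    constant_flux = p[["k"]],
    mass_action = {
      ord <- rep(1, length(conc))
      if (!is.null(law$orders) && !is.null(names(conc))) {
        hit <- match(names(conc), names(law$orders))
        ord[!is.na(hit)] <- law$orders[hit[!is.na(hit)]]
      }
      p[["k"]] * prod(conc^ord)
    },
    michaelis_menten = {
      if (!length(conc)) stop("michaelis_menten needs a substrate", call. = FALSE)
      s <- conc[[1L]]
      p[["Vmax"]] * s / (p[["Km"]] + s) * prod(conc[-1L])
    },
    hill = {
      if (!length(conc)) stop("hill needs a substrate", call. = FALSE)
      s <- conc[[1L]]
      n <- p[["hill_n"]]
      p[["Vmax"]] * s^n / (p[["Km"]]^n + s^n) * prod(conc[-1L])
    })
  unname(flux)
}

.norm_side <- function(x) {
  if (is.null(x) || !length(x)) return(stats::setNames(numeric(0), character(0)))
  if (is.character(x)) x <- stats::setNames(rep(1, length(x)), x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("reactants/products must be named (species id -> coefficient) or a character vector", call. = FALSE)
  agg <- tapply(as.numeric(x), factor(names(x), levels = unique(names(x))), sum)
  stats::setNames(as.numeric(agg), names(agg))
}

#' Define a reaction
#'
#' @param id Unique reaction identifier.
#' @param reactants,products Named numeric vectors mapping species id to a
#'   stoichiometric coefficient (>= 1), or plain character vectors for unit
#'   coefficients. Either side may be empty (a source must then carry a
#'   `constant_flux` law).
#' @param modifiers Character vector of species that affect the rate without
#'   being consumed (enzymes, activating complexes).
#' @param rate A [rate_law()].
#' @return An object of class `rx_reaction`.
#' @export
#' @examples
#' reaction("dimerise", c(A = 2), c(B = 1), rate = rate_law("mass_action", k = 1e-3))
reaction <- function(id, reactants = NULL, products = NULL,
                     modifiers = character(), rate) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            inherits(rate, "rate_law"))
  structure(list(id = id,
                 reactants = .norm_side(reactants),
                 products = .norm_side(products),
                 modifiers = as.character(modifiers),
                 rate = rate),
            class = "rx_reaction")
}

#' Assemble a reaction network
#'
#' The executable form of a pathway model: an ordered species list, an
#' ordered reaction list, and a name. Use [validate_network()] before
#' simulating; [build_ros_network()] and [build_antioxidant_network()]
#' return validated networks.
#'
#' @param species List of [species()] objects.
#' @param reactions List of [reaction()] objects.
#' @param name Network name (also the SBML model id on export).
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(species = list(), reactions = list(),
                             name = "network") {
  stopifnot(all(vapply(species, inherits, logical(1), "rx_species")),
            all(vapply(reactions, inherits, logical(1), "rx_reaction")))
  net <- structure(list(species = species, reactions = reactions, name = name),
                   class = "reaction_network")
  names(net$species) <- vapply(species, `[[`, character(1), "id")
  names(net$reactions) <- vapply(reactions, `[[`, character(1), "id")
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %s: %d species, %d reactions (%d clamped)\n",
              x$name, length(x$species), length(x$reactions),
              sum(vapply(x$species, `[[`, logical(1), "constant"))))
  invisible(x)
}

#' @export
summary.reaction_network <- function(object, ...) {
  print(object)
  init <- species_initials(object)
  cat("initial state (nM):\n")
  print(init)
  cm <- conserved_moieties(object)
  if (length(cm)) {
    cat("conserved moieties:\n")
    for (v in cm) cat(" ", paste(sprintf("%g*%s", v[v != 0], names(v)[v != 0]),
                                 collapse = " + "), "\n")
  }
  invisible(object)
}

#' Initial state of a network
#' @param network A [reaction_network()].
#' @return Named numeric vector of initial concentrations (nM).
#' @export
species_initials <- function(network) {
  vapply(network$species, `[[`, numeric(1), "initial")
}

#' Validate a reaction network
#'
#' Performs structural checks and returns findings as a character vector
#' (empty when the network is valid). Never throws and never mutates.
#'
#' @param network A [reaction_network()].
#' @return Character vector of findings; `character(0)` if valid.
#' @export
validate_network <- function(network) {
  findings <- character(0)
  sp_ids <- vapply(network$species, `[[`, character(1), "id")
  dup <- unique(sp_ids[duplicated(sp_ids)])
  if (length(dup))
    findings <- c(findings, sprintf("duplicate species id '%s'", dup))
  for (s in network$species) {
    if (!is.finite(s$initial) || s$initial < 0)
      findings <- c(findings,
                    sprintf("species '%s' has negative or non-finite initial concentration", s$id))
  }
  rx_ids <- vapply(network$reactions, `[[`, character(1), "id")
  dupr <- unique(rx_ids[duplicated(rx_ids)])
  if (length(dupr))
    findings <- c(findings, sprintf("duplicate reaction id '%s'", dupr))
  for (r in network$reactions) {
    refs <- c(names(r$reactants), names(r$products), r$modifiers)
    unknown <- setdiff(refs, sp_ids)
    if (length(unknown))
      findings <- c(findings,
                    sprintf("reaction '%s' references unknown species '%s'",
                            r$id, unknown))
    if (!length(r$reactants) && r$rate$form != "constant_flux")
      findings <- c(findings,
                    sprintf("reaction '%s' has no reactants and is not a constant_flux source", r$id))
    coefs <- c(r$reactants, r$products)
    if (length(coefs) && (any(coefs < 1) || any(coefs != round(coefs))))
      findings <- c(findings,
                    sprintf("reaction '%s' has a non-integer or < 1 stoichiometric coefficient", r$id))
    if (any(!is.finite(r$rate$params)) || any(r$rate$params < 0))
      findings <- c(findings,
                    sprintf("reaction '%s' has a negative or non-finite rate parameter", r$id))
  }
  findings
}

.stop_if_invalid <- function(network) {
  f <- validate_network(network)
  if (length(f))
    stop("invalid network '", network$name, "':\n  ",
         paste(f, collapse = "\n  "), call. = FALSE)
  invisible(network)
}

#' Stoichiometry matrix
#'
#' @param network A validated [reaction_network()].
#' @return Integer matrix (species x reactions); entry (i, j) is the net
#'   production coefficient of species i in reaction j. Rows of clamped
#'   (constant) species are identically zero.
#' @export
stoichiometry_matrix <- function(network) {
  .stop_if_invalid(network)
  sp_ids <- names(network$species)
  S <- matrix(0, nrow = length(sp_ids), ncol = length(network$reactions),
              dimnames = list(sp_ids, names(network$reactions)))
  for (j in seq_along(network$reactions)) {
    r <- network$reactions[[j]]
    for (id in names(r$reactants)) S[id, j] <- S[id, j] - r$reactants[[id]]
    for (id in names(r$products))  S[id, j] <- S[id, j] + r$products[[id]]
  }
  const <- vapply(network$species, `[[`, logical(1), "constant")
  S[const, ] <- 0
  S
}

# concentrations relevant to reaction r, in rate-law order
.law_conc <- function(r, state) {
  ids <- c(names(r$reactants), r$modifiers)
  stats::setNames(state[ids], ids)
}

#' Reaction fluxes at a state
#'
#' @param network A validated [reaction_network()].
#' @param state Named numeric vector of concentrations (nM) covering every
#'   species.
#' @return Named numeric vector of fluxes (nM/s), one per reaction.
#' @export
network_fluxes <- function(network, state) {
  vapply(network$reactions, function(r) {
    conc <- .law_conc(r, state)
    law <- r$rate
    if (law$form == "mass_action" && is.null(law$orders) && length(r$reactants)) {
      law$orders <- r$reactants
    }
    evaluate_rate(law, conc)
  }, numeric(1))
}

#' Assemble the ODE right-hand side
#'
#' Builds a deterministic, side-effect-free function computing the time
#' derivative of the concentration vector: the stoichiometry matrix applied
#' to the flux vector, with rows of clamped species forced to zero.
#'
#' @param network A validated [reaction_network()].
#' @return `function(state, t = 0)` returning the derivative vector (nM/s)
#'   in species order.
#' @export
assemble_rhs <- function(network) {
  .stop_if_invalid(network)
  S <- stoichiometry_matrix(network)
  sp_ids <- rownames(S)
  n_sp <- length(sp_ids)
  # precompile index-based rate evaluators (names lookups are slow in the
  # inner solver loop)
  compiled <- lapply(network$reactions, function(r) {
    ri <- match(names(r$reactants), sp_ids)
    mi <- match(r$modifiers, sp_ids)
    law <- r$rate
    if (law$form == "mass_action") {
      ord <- as.numeric(r$reactants)
      if (!is.null(law$orders)) {
        hit <- match(names(r$reactants), names(law$orders))
        ord[!is.na(hit)] <- law$orders[hit[!is.na(hit)]]
      }
      list(type = "ma", k = law$params[["k"]], ri = ri, ord = ord, mi = mi)
    } else if (law$form == "constant_flux") {
      list(type = "cf", k = law$params[["k"]])
    } else {
      si <- if (length(ri)) ri[1L] else mi[1L]
      rest <- c(if (length(ri) > 1L) ri[-1L], if (length(ri)) mi else mi[-1L])
      n <- if (law$form == "hill") law$params[["hill_n"]] else 1
      list(type = "sat", Vmax = law$params[["Vmax"]], Km = law$params[["Km"]],
           n = n, si = si, rest = rest)
    }
  })
  n_rx <- length(compiled)
  function(state, t = 0) {
    if (length(state) != n_sp)
      stop("state vector length mismatch: expected ", n_sp, call. = FALSE)
    cs <- pmax(state, 0)  # solver may probe marginally negative values
    flux <- numeric(n_rx)
    for (j in seq_len(n_rx)) {
      cp <- compiled[[j]]
      flux[j] <- switch(cp$type,
        cf = cp$k,
        ma = {
          f <- cp$k
          if (length(cp$ri)) f <- f * prod(cs[cp$ri]^cp$ord)
          if (length(cp$mi)) f <- f * prod(cs[cp$mi])
          f
        },
        sat = {
          s <- cs[cp$si]
          f <- cp$Vmax * s^cp$n / (cp$Km^cp$n + s^cp$n)
          if (length(cp$rest)) f <- f * prod(cs[cp$rest])
          f
        })
    }
    drop(S %*% flux)
  }
}

#' Conserved moieties of a network
#'
#' Computes an integer basis of the left null space of the stoichiometry
#' matrix restricted to dynamic (non-clamped) species. For every returned
#' vector `v`, the weighted total `sum(v * conc)` is constant along any exact
#' trajectory of the network (e.g. total iron across its redox states, or
#' total Maf across free and complexed forms).
#'
#' @param network A validated [reaction_network()].
#' @return List of named integer vectors over the dynamic species (possibly
#'   empty).
#' @export
conserved_moieties <- function(network) {
  S <- stoichiometry_matrix(network)
  const <- vapply(network$species, `[[`, logical(1), "constant")
  S <- S[!const, , drop = FALSE]
  if (!nrow(S)) return(list())
  basis <- .integer_nullspace(t(S))  # solves t(S) v = 0, i.e. v' S = 0
  if (!ncol(basis)) return(list())
  lapply(seq_len(ncol(basis)), function(k)
    stats::setNames(basis[, k], rownames(S)))
}

# ---- small network-editing accessors -------------------------------------

#' Get or set a rate-law parameter
#'
#' Constants are addressed as `"<reaction id>.<parameter>"` in the flat
#' [network_constants()] vector; these accessors address one at a time.
#'
#' @param network A [reaction_network()].
#' @param reaction_id Reaction identifier.
#' @param param Parameter name; defaults to the law's first parameter.
#' @return The parameter value (nM, s and combinations thereof).
#' @export
rate_constant <- function(network, reaction_id, param = NULL) {
  r <- network$reactions[[reaction_id]]
  if (is.null(r)) stop("no reaction '", reaction_id, "'", call. = FALSE)
  if (is.null(param)) param <- names(r$rate$params)[1L]
  r$rate$params[[param]]
}

#' @rdname rate_constant
#' @param value New non-negative value.
#' @export
`rate_constant<-` <- function(network, reaction_id, param = NULL, value) {
  r <- network$reactions[[reaction_id]]
  if (is.null(r)) stop("no reaction '", reaction_id, "'", call. = FALSE)
  if (is.null(param)) param <- names(r$rate$params)[1L]
  .assert_scalar_num(value, param, nonneg = TRUE)
  network$reactions[[reaction_id]]$rate$params[[param]] <- value
  network
}

#' Set a species' initial concentration
#' @inheritParams rate_constant
#' @param species_id Species identifier.
#' @param value New non-negative initial concentration (nM).
#' @return The modified network.
#' @export
set_initial <- function(network, species_id, value) {
  if (is.null(network$species[[species_id]]))
    stop("no species '", species_id, "'", call. = FALSE)
  .assert_scalar_num(value, "initial", nonneg = TRUE)
  network$species[[species_id]]$initial <- value
  network
}

#' Flat vector of all kinetic constants
#'
#' @param network A [reaction_network()].
#' @return Named numeric vector, names of the form
#'   `"<reaction id>.<parameter>"`.
#' @export
network_constants <- function(network) {
  out <- numeric(0)
  for (r in network$reactions) {
    p <- r$rate$params
    names(p) <- paste(r$id, names(p), sep = ".")
    out <- c(out, p)
  }
  out
}

#' Overwrite kinetic constants from a flat vector
#'
#' @param network A [reaction_network()].
#' @param params Named numeric vector in [network_constants()] naming.
#' @return The modified network.
#' @export
update_constants <- function(network, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    pid <- paste(parts[-length(parts)], collapse = ".")
    rate_constant(network, pid, parts[length(parts)]) <- params[[nm]]
  }
  network
}
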