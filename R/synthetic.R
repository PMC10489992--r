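#' Toy networks with closed-form behaviour
#'
#' Small generated networks used to test every pipeline stage against known
#' analytical solutions:
#' \describe{
#'   \item{decay}{`A -> 0` at rate `k`; `A(t) = A0 * exp(-k t)`.}
#'   \item{synthesis_decay}{constant synthesis `k_s` and first-order decay
#'     `k_d`; steady state `k_s / k_d`.}
#'   \item{oscillator}{a two-species predator-prey (Lotka) mass-action
#'     scheme with a clamped substrate; it sustains oscillations around its
#'     neutral fixed point and by design never passes the steady-state
#'     test.}
#'   \item{scavenger_chain}{constant source `k_src`, first-order clearance
#'     `k_clear`, and second-order scavenging by a clamped scavenger;
#'     steady state `k_src / (k_clear + k_scav * scav)`.}
#' }
#'
#' @param kind One of `"decay"`, `"synthesis_decay"`, `"oscillator"`,
#'   `"scavenger_chain"`.
#' @param ... Overrides of the kind's parameters: decay `(k_decay, A0)`;
#'   synthesis_decay `(k_s, k_d, E0)`; oscillator `(k1, k2, k3, X0, Y0)`;
#'   scavenger_chain `(k_src, k_clear, k_scav, scav)`.
#' @return A validated [reaction_network()].
#' @export
#' @examples
#' make_toy_network("synthesis_decay", k_s = 4.2e-4, k_d = 1e-5) # steady 42 nM
make_toy_network <- function(kind = c("decay", "synthesis_decay",
                                      "oscillator", "scavenger_chain"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  g <- function(nm, default) p[[nm]] %||% default
  ma <- function(k) rate_law("mass_action", k = k)
  net <- switch(kind,
    decay = reaction_network(
      list(species("A", g("A0", 100))),
      list(reaction("decay", c(A = 1), NULL, rate = ma(g("k_decay", 1e-3)))),
      name = "toy_decay"),
    synthesis_decay = reaction_network(
      list(species("E", g("E0", 0))),
      list(reaction("synthesis", NULL, c(E = 1),
                    rate = rate_law("constant_flux", k = g("k_s", 4.2e-4))),
           reaction("decay", c(E = 1), NULL, rate = ma(g("k_d", 1e-5)))),
      name = "toy_synthesis_decay"),
    oscillator = reaction_network(
      list(species("A", 1, constant = TRUE),
           species("X", g("X0", 10)), species("Y", g("Y0", 5))),
      list(reaction("prey_growth", c(X = 1), c(X = 2), modifiers = "A",
                    rate = ma(g("k1", 5e-4))),
           reaction("predation", c(X = 1, Y = 1), c(Y = 2),
                    rate = ma(g("k2", 1e-4))),
           reaction("predator_death", c(Y = 1), NULL, rate = ma(g("k3", 5e-4)))),
      name = "toy_oscillator"),
    scavenger_chain = reaction_network(
      list(species("X", 0), species("SCAV", g("scav", 1), constant = TRUE),
           species("X_scavenged", 0)),
      list(reaction("source", NULL, c(X = 1),
                    rate = rate_law("constant_flux", k = g("k_src", 1e-2))),
           reaction("clearance", c(X = 1), NULL, rate = ma(g("k_clear", 1e-3))),
           reaction("scavenging", c(X = 1, SCAV = 1), c(X_scavenged = 1),
                    rate = ma(g("k_scav", 1e-3)))),
      name = "toy_scavenger_chain"))
  .stop_if_invalid(net)
  net
}

#' Specification of a parameter perturbation
#'
#' @param coefficient_of_variation Positive coefficient of variation of the
#'   multiplicative lognormal factors (default 0.2, a typical spread of
#'   reported kinetic constants across experimental conditions).
#' @param distribution Only `"lognormal"` (positivity-preserving;
#'   parameterised with median 1 so perturbations are unbiased on the log
#'   scale).
#' @param seed Integer seed; identical seeds reproduce identical draws.
#' @param constants_subset Optional regular expression selecting which
#'   constants to perturb.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(coefficient_of_variation = 0.2,
                              distribution = "lognormal", seed = 1L,
                              constants_subset = NULL) {
  .assert_scalar_num(coefficient_of_variation, "coefficient_of_variation",
                     positive = TRUE)
  distribution <- match.arg(distribution)
  structure(list(cv = coefficient_of_variation, distribution = distribution,
                 seed = as.integer(seed), constants_subset = constants_subset),
            class = "perturbation_spec")
}

#' Perturb a parameter set
#'
#' Multiplies each selected constant by an independent lognormal factor with
#' median 1 and the specified coefficient of variation
#' (`sdlog = sqrt(log(1 + cv^2))`, `meanlog = 0`). Reproducible under the
#' spec's seed; the caller's RNG state is left untouched.
#'
#' @param params Named positive numeric vector (e.g. [network_constants()]).
#' @param spec A [perturbation_spec()].
#' @return Perturbed named numeric vector of the same shape.
#' @export
perturb_parameters <- function(params, spec = perturbation_spec()) {
  if (any(params <= 0)) stop("params must be positive", call. = FALSE)
  sel <- if (is.null(spec$constants_subset)) seq_along(params)
         else grep(spec$constants_subset, names(params))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$cv^2))
  factors <- stats::rlnorm(length(sel), meanlog = 0, sdlog = sdlog)
  params[sel] <- params[sel] * factors
  params
}

#' Build a dose grid
#'
#' @param max_dose Top dose (> 0).
#' @param n_points Number of grid points including 0 (>= 2).
#' @param spacing `"linear"` or `"log"` (log grids span `decades` decades
#'   below `max_dose`, plus the 0 point).
#' @param decades Span of a log grid in decades.
#' @return Sorted numeric vector starting at 0 and ending at `max_dose`.
#' @export
#' @examples
#' make_dose_grid(100, 5) # 0 25 50 75 100
make_dose_grid <- function(max_dose, n_points = 5L,
                           spacing = c("linear", "log"), decades = 2) {
  .assert_scalar_num(max_dose, "max_dose", positive = TRUE)
  spacing <- match.arg(spacing)
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  if (spacing == "linear") {
    seq(0, max_dose, length.out = n_points)
  } else {
    c(0, max_dose * 10^seq(-decades, 0, length.out = n_points - 1L))
  }
}
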