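# shared fixtures, all built in code

# reporting grid can be coarse in tests; solver accuracy is set by rtol/atol
fast_settings <- function(n_out = 240, ...) simulation_settings(n_out = n_out, ...)

# random connected mass-action network over `n` species, reproducible
random_network <- function(seed = 1L, n = 5L, n_rx = 7L) {
  set.seed(seed)
  ids <- paste0("S", seq_len(n))
  sp <- lapply(ids, function(id) species(id, initial = runif(1, 1, 10)))
  rx <- lapply(seq_len(n_rx), function(j) {
    from <- sample(ids, sample(1:2, 1))
    to <- sample(setdiff(ids, from), 1)
    reaction(paste0("r", j), stats::setNames(rep(1, length(from)), from),
             stats::setNames(1, to),
             rate = rate_law("mass_action", k = 10^runif(1, -4, -2)))
  })
  reaction_network(sp, rx, name = paste0("random_", seed))
}

random_states <- function(network, n = 100L, seed = 42L) {
  set.seed(seed)
  ids <- names(network$species)
  m <- matrix(runif(n * length(ids), 0, 100), nrow = n,
              dimnames = list(NULL, ids))
  m
}

# is `v` in the span of the list of basis vectors?
in_span <- function(v, basis) {
  if (!length(basis)) return(all(v == 0))
  B <- do.call(cbind, basis)
  fit <- qr.coef(qr(B), v)
  fit[is.na(fit)] <- 0
  max(abs(B %*% fit - v)) < 1e-8
}
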