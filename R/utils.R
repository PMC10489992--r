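# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  a
}

.gcd <- function(x) {
  x <- x[x != 0]
  if (!length(x)) return(1)
  Reduce(.gcd2, abs(x))
}

# Integer basis of the null space of an integer matrix A (solutions of
# A %*% v = 0), by fraction-free Gaussian elimination.  Entries stay exact
# as long as intermediate values are below 2^53, which holds comfortably
# for stoichiometry matrices.  Returns a matrix with one basis vector per
# column (ncol 0 when the null space is trivial).
.integer_nullspace <- function(A) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m <- nrow(A); n <- ncol(A)
  if (n == 0L) return(matrix(numeric(0), nrow = 0, ncol = 0))
  if (m == 0L) return(diag(1, n))
  R <- A
  pivot_col <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    sel <- which(abs(R[row:m, col]) > 0.5)
    if (!length(sel)) next
    p <- row + sel[1L] - 1L
    if (p != row) R[c(row, p), ] <- R[c(p, row), ]
    for (i in seq_len(m)[-row]) {
      if (abs(R[i, col]) > 0.5) {
        R[i, ] <- R[i, ] * R[row, col] - R[row, ] * R[i, col]
        g <- .gcd(R[i, ])
        if (g > 1) R[i, ] <- R[i, ] / g
      }
    }
    g <- .gcd(R[row, ])
    if (g > 1) R[row, ] <- R[row, ] / g
    pivot_col <- c(pivot_col, col)
    row <- row + 1L
  }
  free_col <- setdiff(seq_len(n), pivot_col)
  if (!length(free_col)) return(matrix(numeric(0), nrow = n, ncol = 0))
  basis <- matrix(0, nrow = n, ncol = length(free_col))
  for (k in seq_along(free_col)) {
    f <- free_col[k]
    v <- numeric(n)
    v[f] <- 1
    # back-substitute pivot rows bottom-up, rescaling to stay integral
    for (i in rev(seq_along(pivot_col))) {
      pc <- pivot_col[i]
      s <- sum(R[i, -pc] * v[-pc])
      if (abs(s) < 0.5) next
      piv <- R[i, pc]
      g <- .gcd2(s, piv)
      v <- v * (abs(piv) / g)
      v[pc] <- -sign(piv) * s / g
    }
    g <- .gcd(v)
    if (g > 1) v <- v / g
    nz <- which(v != 0)
    if (length(nz) && v[nz[1L]] < 0) v <- -v
    basis[, k] <- v
  }
  basis
}

# Shortest decimal string that reads back to the identical double.
.num_to_str <- function(x) {
  vapply(x, function(v) {
    s <- as.character(v)
    if (identical(as.numeric(s), v)) s else sprintf("%.17g", v)
  }, character(1))
}

.assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
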