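#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_angle <- function(x) {
  y <- x %% (2 * pi)
  y[y > pi] <- y[y > pi] - 2 * pi
  y
}

# trapezoidal rule; x must be sorted increasing
trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# row-wise normalisation of a matrix of log-weights into probabilities,
# numerically stable for N <= a handful of columns. Rows whose weights all
# underflow to -Inf (zero density under every state) fall back to uniform:
# the conditional 0/0 is undefined and the tie is broken symmetrically.
softmax_rows <- function(lw) {
  m <- lw[, 1]
  n <- ncol(lw)
  if (n > 1) for (j in 2:n) m <- pmax(m, lw[, j])
  dead <- !is.finite(m)
  if (any(dead)) lw[dead, ] <- 0
  s <- exp(lw - ifelse(dead, 0, m))
  s / rowSums(s)
}

# all permutations of 1..n as rows (n <= 3 in practice, kept generic)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic derived seed that stays inside 32-bit integer range
derive_seed <- function(seed, mult, offset) {
  as.integer((as.numeric(seed) * mult + offset) %% 2147483647)
}
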