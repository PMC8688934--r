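# Independent oracles used across the kinetics tests. These deliberately do
# NOT share code with the package internals they check.

# King-Altman / matrix-tree steady state of a cyclic transporter: occupancy
# of state i is proportional to the sum over spanning trees rooted at i of
# the product of edge rates directed towards i. For a single N-cycle the
# spanning trees are the N-1 edge paths obtained by deleting one edge.
ka_occupancy <- function(fw, bw) {
  n <- length(fw)           # fw[i]: i -> i+1 (mod n), bw[i]: i+1 -> i
  w <- numeric(n)
  for (root in seq_len(n)) {
    tot <- 0
    for (cut in seq_len(n)) {       # delete edge (cut, cut+1)
      prod <- 1
      # forward arc: nodes cut+1, ..., root-1 use their edge j -> j+1
      i <- cut %% n + 1
      while (i != root) { prod <- prod * fw[i]; i <- i %% n + 1 }
      # backward arc: nodes cut, cut-1, ..., root+1 use their edge j -> j-1,
      # whose rate is bw[j-1] (bw[i] is the rate of (i+1) -> i)
      i <- cut
      while (i != root) {
        ib <- if (i == 1) n else i - 1
        prod <- prod * bw[ib]
        i <- ib
      }
      tot <- tot + prod
    }
    w[root] <- tot
  }
  w / sum(w)
}

# Long-time limit of the master equations dp/dt = A p from uniform occupancy,
# by implicit (backward) Euler, which is unconditionally stable and preserves
# the occupancy sum exactly (column sums of A are zero).
relax_occupancy <- function(fw, bw, dt = 0.5, n_steps = 2000L) {
  n <- length(fw)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    A[i, i] <- A[i, i] - fw[i]; A[j, i] <- A[j, i] + fw[i]
    A[j, j] <- A[j, j] - bw[i]; A[i, j] <- A[i, j] + bw[i]
  }
  p <- rep(1 / n, n)
  M <- solve(diag(n) - dt * A)
  for (s in seq_len(n_steps)) p <- M %*% p
  as.numeric(p)
}

# Directed rate vectors (fw, bw) of the SGLT1 cycle for given conditions,
# recomputed here from the parameter object's public fields.
sglt1_rate_vectors <- function(p, na_out, glc_out, na_in, glc_in, v_mv) {
  k <- p$rates; q <- p$charges
  u2 <- (v_mv * 1e-3) / (2 * 8.314462618 * 310.15 / 96485.33212)
  f <- function(qq) exp(-qq * u2)
  fw <- c(k[["k12"]] * na_out^2 * f(q[["q12"]]),
          k[["k23"]] * glc_out,
          k[["k34"]] * f(q[["q34"]]),
          k[["k45"]],
          k[["k56"]],
          k[["k61"]] * f(q[["q61"]]))
  bw <- c(k[["k21"]] / f(q[["q12"]]),
          k[["k32"]],
          k[["k43"]] / f(q[["q34"]]),
          k[["k54"]] * glc_in,
          k[["k65"]] * na_in^2,
          k[["k16"]] / f(q[["q61"]]))
  list(fw = fw, bw = bw)
}

# Deterministic random parameter draw for property tests.
random_sglt1 <- function() {
  r <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  sglt1_params(k12 = r(1e-3, 1), k21 = r(10, 1e3), k23 = r(0.1, 100),
               k32 = r(1, 1e3), k34 = r(1, 1e3), k43 = r(1, 1e3),
               k45 = r(10, 1e5), k54 = r(0.1, 1e3), k56 = r(1, 1e3),
               k65 = r(1e-6, 1e-3), k61 = r(0.5, 100), n_copies = 1e7)
}

random_carrier <- function(symmetric = FALSE) {
  r <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  if (symmetric) {
    on <- r(1, 100); off <- r(10, 1e4); tl <- r(1, 1e3); mt <- r(1, 1e3)
    carrier_params(on, off, on, off, tl, tl, mt, n_copies = 1e8)
  } else {
    carrier_params(r(1, 1e3), r(10, 1e4), r(1, 1e3), r(10, 1e4),
                   r(1, 1e3), r(1, 1e3), r(1, 1e3), n_copies = 1e8)
  }
}

make_state <- function(na, k, cl, hco3 = 0, glucose = 0, volume = 1e-15,
                       role = "cell", ph = 7.2) {
  compartment_state(na, k, cl, hco3, glucose, ph = ph, volume = volume,
                    role = role)
}
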