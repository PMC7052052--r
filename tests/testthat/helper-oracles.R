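# Independent oracles used across the suite. These never call the code
# paths they check.

# adaptive-quadrature merger-rate oracle: int x^(k-2) (1-x)^(b-k) dP(x)
quad_moment <- function(measure, b, k) {
  if (measure$family == "point_mass") {
    x <- measure$psi
    e1 <- k - 2
    e2 <- b - k
    (if (e1 == 0) 1 else x^e1) * (if (e2 == 0) 1 else (1 - x)^e2)
  } else {
    stats::integrate(function(x)
      x^(k - 2) * (1 - x)^(b - k) * stats::dbeta(x, measure$a, measure$b),
      0, 1, rel.tol = 1e-12, abs.tol = 1e-12, subdivisions = 2000L)$value
  }
}

# brute-force total rate by quadrature term sum
quad_total_rate <- function(measure, b) {
  sum(vapply(2:b, function(k)
    choose(b, k) * quad_moment(measure, b, k), numeric(1))) *
    measure$rate_multiplier
}

# exact subset-enumeration oracle for decline subsampling: offspring of a
# fixed-size step are U brood slots (parent 0) and N - U singles; returns
# E((U_eff)_a) over all C(N, target) retained subsets
enum_decline_moment <- function(N, U, target, a) {
  slots <- c(rep(0L, U), seq_len(N - U))   # parent label per offspring slot
  subs <- utils::combn(N, target)
  vals <- apply(subs, 2, function(s) {
    ueff <- sum(slots[s] == 0L)
    prod(ueff - seq_len(a) + 1)
  })
  mean(vals)
}

# falling factorial helper for expected values in tests
ff <- function(x, k) {
  out <- rep(1, length(x))
  for (i in seq_len(k)) out <- out * (x - i + 1)
  out
}

# exact pmf of realized parent multiplicities when `target` offspring are
# drawn uniformly without replacement from a pool with the given counts:
# enumerates all subsets of pool members (pools <= ~12)
enum_pool_multiplicities <- function(counts, target) {
  owner <- rep.int(seq_along(counts), counts)
  S <- length(owner)
  subs <- utils::combn(S, target)
  keys <- apply(subs, 2, function(s)
    paste(tabulate(owner[s], length(counts)), collapse = ","))
  tab <- table(keys) / ncol(subs)
  tab
}
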