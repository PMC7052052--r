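#' Heavy-tailed offspring law
#'
#' The per-parent potential offspring number X has the exact power-law tail
#' \deqn{P(X \ge k) = k^{-\alpha}, \quad k = 1, 2, \dots}
#' so that \eqn{X \ge 1} a.s. and the tail constant is 1. For
#' \eqn{\alpha \in (1,2)} the mean is \eqn{\mu = \zeta(\alpha) > 1} and the
#' variance infinite, the regime whose rescaled Cannings genealogies
#' converge to the Beta\eqn{(2-\alpha, \alpha)}-coalescent; \eqn{\alpha = 1}
#' (Bolthausen-Sznitman regime, logarithmic time scale) is supported by the
#' sampler but has infinite mean, so the shortfall bound and exponent
#' regression refuse it.
#'
#' @param alpha Tail exponent in `[1, 2)`.
#' @return An object of class `heavy_tail_law` with fields `alpha` and
#'   `mu` (`Inf` at `alpha = 1`).
#' @examples
#' law <- heavy_tail_law(1.5)
#' mean(sample_offspring_counts(100, law)$counts)   # near zeta(1.5) = 2.612
#' @export
heavy_tail_law <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 1 || alpha >= 2)
    stop("'alpha' must lie in [1, 2)", call. = FALSE)
  mu <- if (alpha > 1) sum((1:1e6)^(-alpha)) +
    (1e6)^(1 - alpha) / (alpha - 1) else Inf   # zeta via Euler-Maclaurin tail
  structure(list(alpha = alpha, mu = mu), class = "heavy_tail_law")
}

#' @export
print.heavy_tail_law <- function(x, ...) {
  cat(sprintf("Heavy-tailed offspring law: P(X >= k) = k^-%g, mean %.4f\n",
              x$alpha, x$mu))
  invisible(x)
}

# pmf P(X = k) = k^-alpha - (k+1)^-alpha
.ht_pmf <- function(law, k) k^(-law$alpha) - (k + 1)^(-law$alpha)

#' Draw a generation's potential offspring pool
#'
#' i.i.d. draws of X by exact inverse-CDF: `X = floor(U^(-1/alpha))` for
#' U uniform on (0,1) reproduces `P(X >= k) = k^-alpha` exactly. A hard cap
#' of 1e9 on a single draw guards pathological tails (error, never
#' truncation).
#'
#' @param N_r Number of parents.
#' @param law A [heavy_tail_law()].
#' @return A list with `counts` (length `N_r`) and the pool total `S`.
#' @export
sample_offspring_counts <- function(N_r, law) {
  stopifnot(inherits(law, "heavy_tail_law"), N_r >= 1)
  x <- floor(stats::runif(N_r)^(-1 / law$alpha))
  if (any(x > 1e9))
    stop("offspring draw exceeded 1e9; tail too heavy for this engine",
         call. = FALSE)
  list(counts = x, S = sum(x))
}

#' Assemble the next generation from a potential-offspring pool
#'
#' If the pool holds at least `target` offspring, a uniform
#' without-replacement sample of `target` of them survives, so the realized
#' per-parent multiplicities are multivariate hypergeometric given the
#' counts (drawn sequentially, one hypergeometric per parent). On a
#' shortfall every potential offspring survives and each missing individual
#' is attached to an independently uniformly chosen parent, which preserves
#' exchangeability.
#'
#' @param counts Integer vector of potential offspring per parent.
#' @param target Size of the next generation, `>= 1`.
#' @return A `parent_assignment` with the realized multiplicities in
#'   `counts` (`multiplier`/`U_eff` fields are `NA`: this engine has no
#'   distinguished parent).
#' @export
assemble_generation <- function(counts, target) {
  target <- as.integer(target)
  if (target < 1L) stop("'target' must be >= 1", call. = FALSE)
  S <- sum(counts)
  Np <- length(counts)
  if (S >= target) {
    kept <- numeric(Np)
    rem_tot <- S
    rem_keep <- target
    for (i in seq_len(Np)) {
      if (rem_keep == 0) break
      ci <- counts[i]
      kept[i] <- stats::rhyper(1L, ci, rem_tot - ci, rem_keep)
      rem_tot <- rem_tot - ci
      rem_keep <- rem_keep - kept[i]
    }
  } else {
    kept <- counts + tabulate(sample.int(Np, target - S, replace = TRUE), Np)
  }
  structure(list(N_parents = Np, N_offspring = target, counts = kept,
                 multiplier = NA_integer_, U_eff = NA_integer_,
                 nonreproducers = which(kept == 0L)),
            class = "parent_assignment")
}

#' Heavy-tailed Cannings model with variable population size
#'
#' Each generation every parent draws an i.i.d. potential offspring count
#' from the [heavy_tail_law()]; the next generation is assembled from the
#' pool by [assemble_generation()]. Simultaneous multiple mergers of
#' several sibships in one generation are possible and recorded as separate
#' events at the same generation.
#'
#' @param N Reference population size.
#' @param alpha Tail exponent in `[1, 2)`.
#' @param profile A [size_profile()].
#' @param horizon_t Coalescent-time horizon for non-constant profiles.
#' @param c_ref Optional pairwise coalescence probability at the reference
#'   size used as the time scaling; when `NULL` it is estimated once by
#'   Monte Carlo with `c_ref_reps` replicates.
#' @param c_ref_reps Replicates for the `c_ref` estimate.
#' @return An object of class `schweinsberg_model`.
#' @export
schweinsberg_model <- function(N, alpha, profile = size_profile("constant"),
                               horizon_t = 10, c_ref = NULL,
                               c_ref_reps = 20000L) {
  N <- as.integer(N)
  law <- heavy_tail_law(alpha)
  obj <- list(N = N, alpha = alpha, law = law, profile = profile,
              horizon_t = horizon_t)
  class(obj) <- "schweinsberg_model"
  if (is.null(c_ref)) {
    obj$trajectory <- NULL
    c_ref <- .schweinsberg_cN_mc(law, N, N, c_ref_reps)$estimate
    if (c_ref <= 0)
      stop("could not estimate c_N; increase c_ref_reps", call. = FALSE)
  }
  obj$c_ref <- c_ref
  obj$trajectory <- discretize_profile(profile, N, c_ref, horizon_t, n = 2L)
  # convergence regime: per-generation relative increments must be small
  if (profile$kind != "constant") {
    r_all <- 0:min(obj$trajectory$R, 10000L)
    sz <- trajectory_sizes(obj$trajectory, r_all)
    if (length(sz) > 1L) {
      rel <- abs(diff(sz)) / sz[-1]
      if (max(rel) > 0.5)
        warning("per-generation relative size increments exceed 0.5; ",
                "the sampling construction may be strained", call. = FALSE)
    }
  }
  obj
}

#' @export
print.schweinsberg_model <- function(x, ...) {
  cat(sprintf(
    "Heavy-tailed Cannings model: N = %d, alpha = %g, profile = %s\n",
    x$N, x$alpha, x$profile$kind))
  cat(sprintf("  c_N (reference, MC) = %.6g\n", x$c_ref))
  invisible(x)
}

# vectorized Bernoulli MC of the pairwise coalescence probability at one
# generation step Nr -> Nprev: conditional on the realized pool, two
# uniformly chosen distinct surviving offspring share a parent with
# probability sum (X_i)_2 / (S)_2 (no shortfall; survivors of a uniform
# subsample of the pool are themselves a uniform choice from the pool),
# or the explicit multiplicity computation on a shortfall.
.schweinsberg_cN_mc <- function(law, Nr, Nprev, reps, chunk = 5000L) {
  hits <- 0L
  done <- 0L
  inv <- -1 / law$alpha
  while (done < reps) {
    m <- min(chunk, reps - done)
    X <- matrix(floor(stats::runif(m * Nr)^inv), m, Nr)
    S <- rowSums(X)
    p <- (rowSums(X * X) - S) / (S * (S - 1))
    short <- which(S < Nprev)
    for (i in short) {
      Y <- X[i, ] + tabulate(sample.int(Nr, Nprev - S[i], replace = TRUE), Nr)
      p[i] <- sum(Y * (Y - 1)) / (Nprev * (Nprev - 1))
    }
    hits <- hits + sum(stats::runif(m) < p)
    done <- done + m
  }
  est <- hits / reps
  list(estimate = est, se = sqrt(est * (1 - est) / reps), reps = reps)
}

#' @export
pairwise_coalescence_mc.schweinsberg_model <- function(model, r = 1L,
                                                       reps = 10000L) {
  Nr <- trajectory_sizes(model$trajectory, r)
  Nprev <- trajectory_sizes(model$trajectory, r - 1L)
  out <- .schweinsberg_cN_mc(model$law, Nr, Nprev, reps)
  out$N_r <- Nr
  out$N_prev <- Nprev
  out
}

# parents of b uniformly chosen distinct surviving offspring of one
# generation step Nr -> Nprev; returns integer parent labels
.schweinsberg_sample_parents <- function(law, Nr, Nprev, b) {
  x <- sample_offspring_counts(Nr, law)
  w <- x$counts
  if (x$S < Nprev)  # shortfall: survivors = pool + uniformly attached extras
    w <- w + tabulate(sample.int(Nr, Nprev - x$S, replace = TRUE), Nr)
  parents <- integer(b)
  for (j in seq_len(b)) {
    i <- sample.int(Nr, 1L, prob = w)
    parents[j] <- i
    w[i] <- w[i] - 1
  }
  parents
}

#' @rdname simulate_genealogy
#' @export
simulate_genealogy.schweinsberg_model <- function(model, n, ...,
                                                  max_generations = Inf) {
  n <- as.integer(n)
  traj <- model$trajectory
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (n > model$N || (traj$kind != "constant" &&
                      n > min(trajectory_sizes(traj, 0:traj$R))))
    stop("sample size exceeds a population size on the horizon",
         call. = FALSE)
  events <- list()
  reps <- seq_len(n)
  b <- n
  r <- 0
  while (b > 1L && r < max_generations) {
    r <- r + 1
    Nr <- trajectory_sizes(traj, r)
    Nprev <- trajectory_sizes(traj, r - 1L)
    parents <- .schweinsberg_sample_parents(model$law, Nr, Nprev, b)
    if (anyDuplicated(parents)) {
      groups <- split(seq_len(b), parents)
      groups <- groups[lengths(groups) >= 2L]
      drop <- integer()
      for (g in groups) {
        events[[length(events) + 1L]] <-
          list(time = as.numeric(r), generation = r, members = reps[g])
        keepone <- g[which.min(reps[g])]
        reps[keepone] <- min(reps[g])
        drop <- c(drop, setdiff(g, keepone))
      }
      if (length(drop)) reps <- reps[-drop]
      b <- length(reps)
    }
  }
  lab <- sprintf("alpha = %g, %s profile, N = %d", model$alpha,
                 model$profile$kind, model$N)
  .new_genealogy(n, events, engine = "schweinsberg", unit = "generations",
                 c_ref = model$c_ref, open = b > 1L, model_label = lab)
}

#' Chernoff-type bound on the shortfall probability
#'
#' Bounds the probability that a generation's potential offspring pool
#' falls short of the next generation's size when per-generation growth is
#' at most a fraction `epsilon`: with f the probability generating function
#' of X, \eqn{P(S_N < N(1+\epsilon)) \le A_1^N} where
#' \eqn{A_1 = \min_{u \in (0,1)} u^{-(1+\epsilon)} f(u) < 1} whenever the
#' mean \eqn{\mu} exceeds \eqn{1 + \epsilon}. The pgf is evaluated by a
#' truncated series with an explicit tail bound.
#'
#' @param law A [heavy_tail_law()] with `alpha > 1`.
#' @param epsilon Maximal relative per-generation increment, `< mu - 1`.
#' @param N Population size at which to report the bound.
#' @return A list with the bound `A1^N`, the optimizer `u0`, and `A1`.
#' @export
shortfall_bound <- function(law, epsilon, N) {
  stopifnot(inherits(law, "heavy_tail_law"))
  if (law$alpha <= 1)
    stop("shortfall bound requires alpha > 1 (finite mean)", call. = FALSE)
  if (epsilon < 0 || epsilon >= law$mu - 1)
    stop("'epsilon' must lie in [0, mu - 1)", call. = FALSE)
  K <- 2000L
  ks <- seq_len(K)
  pk <- .ht_pmf(law, ks)
  f <- function(u) sum(pk * u^ks) + u^(K + 1) * (K + 1)^(-law$alpha)
  g <- function(u) u^(-(1 + epsilon)) * f(u)
  opt <- stats::optimize(g, c(1e-6, 1 - 1e-9))
  if (opt$objective >= 1)
    stop("no u in (0,1) achieves u^-(1+eps) f(u) < 1; bound unavailable ",
         "(alpha too close to 1 or epsilon too large)", call. = FALSE)
  A1 <- opt$objective
  list(bound = A1^N, A1 = A1, u0 = opt$minimum)
}

#' Empirical scaling exponent of the coalescence probability
#'
#' Estimates \eqn{c_N} by Monte Carlo on a grid of population sizes and
#' regresses \eqn{\log \hat c_N} on \eqn{\log N} (weighted least squares,
#' weights from the propagated binomial standard errors). For the
#' heavy-tailed model with \eqn{\alpha \in (1,2)} the asymptotic slope is
#' \eqn{1 - \alpha}, since
#' \eqn{c_N \sim C\alpha B(2-\alpha,\alpha) E(X)^{-\alpha} N^{1-\alpha}}.
#'
#' @param law A [heavy_tail_law()] with `alpha > 1`, or `NULL` when a
#'   custom `estimator` is supplied.
#' @param N_grid At least 3 population sizes.
#' @param reps Monte-Carlo replicates per grid point.
#' @param level Confidence level for the slope interval.
#' @param estimator Optional `function(N, reps)` returning a list with
#'   `estimate` and `se`, substituted for the heavy-tailed Monte-Carlo
#'   estimator (e.g. to regress another model's coalescence probability on
#'   the same grid).
#' @return A list with `slope`, `ci`, and the per-size `table`
#'   (`N`, `c_hat`, `se`).
#' @export
empirical_cN_exponent <- function(law, N_grid, reps = 200000L, level = 0.95,
                                  estimator = NULL) {
  if (is.null(estimator)) {
    stopifnot(inherits(law, "heavy_tail_law"))
    if (law$alpha <= 1)
      stop("exponent regression requires alpha > 1", call. = FALSE)
    estimator <- function(N, reps) .schweinsberg_cN_mc(law, N, N, reps)
  }
  if (length(N_grid) < 3L) stop("need at least 3 sizes", call. = FALSE)
  est <- vapply(N_grid, function(N)
    unlist(estimator(N, reps)[c("estimate", "se")]),
    numeric(2))
  c_hat <- est[1, ]
  se <- est[2, ]
  if (any(c_hat == 0))
    stop("a c_N estimate is 0; increase reps", call. = FALSE)
  lse <- pmax(se / c_hat, 1e-12)
  fit <- stats::lm(log(c_hat) ~ log(N_grid), weights = 1 / lse^2)
  slope <- unname(stats::coef(fit)[2])
  sse <- sqrt(stats::vcov(fit)[2, 2])
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(slope = slope, ci = c(slope - z * sse, slope + z * sse),
       table = data.frame(N = N_grid, c_hat = c_hat, se = se))
}
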