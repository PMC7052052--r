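#' Offspring laws of fixed-size modified Moran models
#'
#' In a modified Moran model of constant size N, each generation one randomly
#' chosen parent (the "multiplier") has \eqn{U_N \ge 2} offspring,
#' \eqn{U_N - 1} parents have none, and every other parent has exactly one.
#' These constructors build the law of \eqn{U_N}:
#'
#' * `uprime_law()` gives the skewed-offspring law \eqn{U'_N} induced by a
#'   Lambda measure, distributed like the size of the first merger of the
#'   Lambda-N-coalescent:
#'   \deqn{P(U'_N = j) = \lambda_N^{-1}\binom{N}{j} E(X^{j-2}(1-X)^{N-j}),
#'   \quad j = 2,\dots,N,}
#'   with \eqn{\lambda_N} the total rate of the Lambda-N-coalescent and
#'   \eqn{X \sim \Lambda}.
#' * `standard_law()` is the classical Moran model, \eqn{U_N \equiv 2}.
#' * `custom_law()` accepts any pmf on \eqn{\{2,\dots,N\}} (e.g. the
#'   Eldon-Wakeley two-point sweepstake law).
#'
#' The pmf is computed in log space and normalized at the end, which keeps
#' it accurate for N in the thousands.
#'
#' @param measure A [lambda_measure()].
#' @param N Population size, integer `>= 2`.
#' @param pmf For `custom_law()`: numeric vector of probabilities over
#'   `support` (normalized internally if it sums to 1 within 1e-8).
#' @param support For `custom_law()`: integer support, a subset of `2:N`.
#' @return An object of class `moran_law` with fields `N`, `support`, `pmf`,
#'   `provenance` and (for `uprime_law`) `measure` and `lambda_N`.
#' @examples
#' law <- uprime_law(lambda_measure("beta", a = 1, b = 1), N = 20)
#' coalescence_prob(law)          # = 1 / total_rate(measure, 20)
#' factorial_moment(law, 3)
#' @export
uprime_law <- function(measure, N) {
  stopifnot(inherits(measure, "lambda_measure"))
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 2)
    stop("'N' must be a single integer >= 2", call. = FALSE)
  j <- 2:N
  lw <- lchoose(N, j) + .log_integrand_moment(measure, N, j)
  keep <- is.finite(lw)
  lw <- lw[keep]
  j <- j[keep]
  M <- max(lw)
  p <- exp(lw - M)
  p <- p / sum(p)
  structure(list(N = N, support = j, pmf = p, provenance = "uprime",
                 measure = measure, lambda_N = total_rate(measure, N)),
            class = "moran_law")
}

#' @rdname uprime_law
#' @export
standard_law <- function(N) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 2)
    stop("'N' must be a single integer >= 2", call. = FALSE)
  structure(list(N = N, support = 2L, pmf = 1, provenance = "standard"),
            class = "moran_law")
}

#' @rdname uprime_law
#' @export
custom_law <- function(N, support, pmf) {
  N <- as.integer(N)
  support <- as.integer(support)
  if (any(support < 2L) || any(support > N))
    stop("support must lie in {2, ..., N}", call. = FALSE)
  if (length(pmf) != length(support) || any(pmf < 0))
    stop("'pmf' must be nonnegative and match 'support'", call. = FALSE)
  s <- sum(pmf)
  if (abs(s - 1) > 1e-8)
    stop("'pmf' must sum to 1", call. = FALSE)
  o <- order(support)
  structure(list(N = N, support = support[o], pmf = pmf[o] / s,
                 provenance = "custom"),
            class = "moran_law")
}

#' @export
print.moran_law <- function(x, ...) {
  cat(sprintf("Modified Moran offspring law (%s), N = %d, support {%d..%d}\n",
              x$provenance, x$N, min(x$support), max(x$support)))
  cat(sprintf("  E(U) = %.4f, c_N = %.6g\n",
              sum(x$support * x$pmf), coalescence_prob(x)))
  invisible(x)
}

# falling factorial (x)_k = x(x-1)...(x-k+1); vectorized over x
.falling <- function(x, k) {
  if (k == 0) return(rep(1, length(x)))
  out <- as.numeric(x)
  if (k > 1) for (i in 1:(k - 1)) out <- out * (x - i)
  out
}

#' Rarefied sweepstake offspring law
#'
#' Dilutes a skewed offspring law so that large reproduction events occur
#' only on an "activation" event \eqn{A_N}: the effective offspring count is
#' \deqn{U_N = U'_N 1_{A_N} + 2(1 - 1_{A_N}),}
#' with \eqn{P(A_N)} chosen so that the pairwise coalescence probability is
#' calibrated to \eqn{N^{-\gamma}}, i.e.
#' \eqn{E((U'_N)_2) P(A_N) / (N)_2 = N^{-\gamma}}, which gives
#' \eqn{P(A_N) = N^{-\gamma}\lambda_N} (the multiplier clock runs at Kingman
#' pace between activations). This is the discrete construction whose
#' rescaled genealogies converge to the time-changed Lambda-n-coalescent
#' with time-change exponent \eqn{\gamma \in (1, 2)}.
#'
#' @param measure A [lambda_measure()].
#' @param N Population size.
#' @param gamma Rarefaction exponent, in `(1, 2)`.
#' @return An object of class `rarefied_law` with fields `base` (the
#'   [uprime_law()]), `gamma` and `p_activation`.
#' @examples
#' rl <- rarefy(lambda_measure("point_mass", psi = 1), N = 100, gamma = 1.5)
#' rl$p_activation                   # 100^-1.5 = 1e-3 (lambda_N = 1 here)
#' coalescence_prob(rl)
#' @export
rarefy <- function(measure, N, gamma) {
  stopifnot(inherits(measure, "lambda_measure"))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 1 || gamma >= 2)
    stop("'gamma' must lie in (1, 2)", call. = FALSE)
  N <- as.integer(N)
  base <- uprime_law(measure, N)
  # calibration uses the probability-measure total rate so that
  # p_activation * c'_N = N^-gamma holds exactly for any rate_multiplier
  lamP <- base$lambda_N / measure$rate_multiplier
  p_act <- N^(-gamma) * lamP
  if (p_act > 1) {
    feasible <- function(Ni) Ni^(-gamma) *
      total_rate(measure, as.integer(Ni)) / measure$rate_multiplier <= 1
    Ntry <- N
    Nok <- NA_integer_
    while (Ntry < 2e5) {
      Ntry <- as.integer(max(Ntry + 1L, ceiling(Ntry * 1.1)))
      if (feasible(Ntry)) {
        Nok <- Ntry
        break
      }
    }
    if (is.na(Nok))
      stop(sprintf(paste0("infeasible rarefaction: N^-gamma * lambda_N = ",
                          "%.3g > 1 and no admissible size exists up to 2e5 ",
                          "(the measure violates the rarefaction regime)"),
                   p_act), call. = FALSE)
    lo <- N
    hi <- Nok
    while (hi - lo > 1L) {          # refine to the minimal admissible size
      mid <- as.integer((lo + hi) %/% 2L)
      if (feasible(mid)) hi <- mid else lo <- mid
    }
    stop(sprintf(paste0("infeasible rarefaction: N^-gamma * lambda_N = %.3g ",
                        "> 1; smallest admissible N is %d"), p_act, hi),
         call. = FALSE)
  }
  # The construction targets measures whose E((U'_N)_2)/(N-1) stays bounded
  # away from 0 as N grows; asymptotic, so probed heuristically on a
  # quadrupled size and flagged by a warning only.
  r_here <- factorial_moment(base, 2L) / (N - 1)
  Nbig <- as.integer(min(4L * N, 5000L))
  r_big <- factorial_moment(uprime_law(measure, Nbig), 2L) / (Nbig - 1)
  if (Nbig > N && r_big < 0.75 * r_here)
    warning(paste("E((U'_N)_2)/(N-1) appears to vanish as N grows;",
                  "the rarefied construction targets measures for which",
                  "it stays bounded away from 0"), call. = FALSE)
  structure(list(base = base, N = N, gamma = gamma, p_activation = p_act,
                 measure = measure),
            class = "rarefied_law")
}

#' @export
print.rarefied_law <- function(x, ...) {
  cat(sprintf(
    "Rarefied modified Moran law, N = %d, gamma = %g, P(activation) = %.4g\n",
    x$N, x$gamma, x$p_activation))
  cat(sprintf("  c_N = %.6g (calibrated N^-gamma = %.6g)\n",
              coalescence_prob(x), x$N^(-x$gamma)))
  invisible(x)
}

#' Factorial moments of an offspring law
#'
#' \eqn{E((U_N)_k)} with \eqn{(x)_k} the falling factorial. For `uprime`
#' laws the closed form \eqn{E((U'_N)_k) = (N)_k \lambda_N^{-1} E(X^{k-2})}
#' is available and is the default; `method = "direct"` sums over the pmf
#' instead (the two agree to numerical precision, which the test suite
#' asserts). Rarefied laws mix the base law with the constant 2.
#'
#' @param law A `moran_law` or `rarefied_law`.
#' @param k Moment order, integer `>= 1`.
#' @param method `"auto"` (closed form where available), `"closed_form"`,
#'   or `"direct"`.
#' @return \eqn{E((U_N)_k)}; 0 when `k > N`.
#' @export
factorial_moment <- function(law, k, method = c("auto", "closed_form", "direct")) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (k < 1) stop("'k' must be >= 1", call. = FALSE)
  if (inherits(law, "rarefied_law")) {
    return(law$p_activation * factorial_moment(law$base, k, method) +
             (1 - law$p_activation) * .falling(2, k))
  }
  stopifnot(inherits(law, "moran_law"))
  if (k > law$N) return(0)
  use_closed <- law$provenance == "uprime" && k >= 2 && method != "direct"
  if (method == "closed_form" && !use_closed)
    stop("closed form requires an uprime law and k >= 2", call. = FALSE)
  if (use_closed) {
    .falling(law$N, k) / law$lambda_N *
      measure_moment(law$measure, k - 2L) * law$measure$rate_multiplier
  } else {
    sum(.falling(law$support, k) * law$pmf)
  }
}

#' Pairwise coalescence probability of a modified Moran model
#'
#' \eqn{c_N = E((U_N)_2)/(N)_2}: the probability that two uniformly chosen
#' distinct individuals of one generation share a parent in the previous
#' one. It defines the model's time scale (one coalescent unit =
#' \eqn{c_N^{-1}} generations). For a `uprime` law this is exactly
#' \eqn{1/\lambda_N}; for a rarefied law it is exactly
#' \eqn{N^{-\gamma} + (1 - P(A_N))\,2/(N)_2}.
#'
#' @param law A `moran_law` or `rarefied_law`.
#' @return A probability in `(0, 1]`.
#' @export
coalescence_prob <- function(law) {
  if (inherits(law, "rarefied_law")) {
    N <- law$N
    return(N^(-law$gamma) + (1 - law$p_activation) * 2 / (N * (N - 1)))
  }
  stopifnot(inherits(law, "moran_law"))
  factorial_moment(law, 2L) / (law$N * (law$N - 1))
}

#' Draw offspring counts of the multiplying parent
#'
#' Samples from the law of \eqn{U_N}; for rarefied laws this is the
#' Bernoulli(`p_activation`) mixture of the base law and the constant 2.
#' Reproducible under `set.seed()`.
#'
#' @param law A `moran_law` or `rarefied_law`.
#' @param n Number of draws.
#' @return Integer vector in `{2, ..., N}`.
#' @export
sample_U <- function(law, n = 1L) {
  if (inherits(law, "rarefied_law")) {
    act <- stats::runif(n) < law$p_activation
    out <- rep(2L, n)
    if (any(act)) out[act] <- sample_U(law$base, sum(act))
    return(out)
  }
  stopifnot(inherits(law, "moran_law"))
  if (length(law$support) == 1L) return(rep(law$support, n))
  law$support[sample.int(length(law$support), n, replace = TRUE,
                         prob = law$pmf)]
}

# effective U pmf of any law as (support, pmf) -- rarefied laws expanded to
# their Bernoulli mixture. Internal; used by the gap-skipping simulator and
# the exact diagnostics.
.effective_pmf <- function(law) {
  if (inherits(law, "rarefied_law")) {
    b <- law$base
    p <- b$pmf * law$p_activation
    sup <- b$support
    i2 <- match(2L, sup)
    if (is.na(i2)) {
      sup <- c(2L, sup)
      p <- c(1 - law$p_activation, p)
    } else {
      p[i2] <- p[i2] + (1 - law$p_activation)
    }
    o <- order(sup)
    list(support = sup[o], pmf = p[o], N = law$N)
  } else {
    list(support = law$support, pmf = law$pmf, N = law$N)
  }
}

# population size a law was built for
.law_N <- function(law) if (inherits(law, "rarefied_law")) law$N else law$N
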