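#' Lambda measures parameterizing multiple-merger coalescents
#'
#' A Lambda-n-coalescent is a partition-valued Markov process in which any
#' k of b ancestral lineages merge at rate
#' \deqn{\lambda_{b,k} = \int_0^1 x^{k-2}(1-x)^{b-k}\,\Lambda(dx),}
#' where \eqn{\Lambda} is a finite measure on \eqn{[0,1]}. `lambda_measure()`
#' represents the two families used throughout this package: a point mass at
#' \eqn{\psi} (Dirac coalescents; \eqn{\psi = 0} is Kingman's coalescent,
#' \eqn{\psi = 1} the star-like coalescent) and the Beta\eqn{(a,b)} family
#' (Beta coalescents; Beta(1,1) is the Bolthausen-Sznitman coalescent).
#'
#' The underlying measure is always a probability measure; `rate_multiplier`
#' rescales all merger rates uniformly, i.e. the effective measure is
#' `rate_multiplier` times the probability measure. This corresponds to a
#' linear change of the coalescent's time unit and nothing else.
#'
#' @param family `"point_mass"` or `"beta"`.
#' @param psi Location of the point mass, in `[0,1]` (point_mass family only).
#'   The convention `0^0 = 1` is used when evaluating the merger-rate
#'   integrand at the endpoints.
#' @param a,b Shape parameters of the Beta family, both `> 0`.
#' @param rate_multiplier Positive scalar multiplying every merger rate.
#' @return An object of class `lambda_measure`.
#' @examples
#' kingman <- lambda_measure("point_mass", psi = 0)
#' bs <- lambda_measure("beta", a = 1, b = 1)   # Bolthausen-Sznitman
#' merger_rate(bs, b = 4, k = 2)
#' total_rate(bs, b = 10)                        # equals 9
#' @export
lambda_measure <- function(family = c("point_mass", "beta"),
                           psi = NULL, a = NULL, b = NULL,
                           rate_multiplier = 1) {
  family <- match.arg(family)
  stopifnot(is.numeric(rate_multiplier), length(rate_multiplier) == 1L,
            rate_multiplier > 0)
  if (family == "point_mass") {
    if (is.null(psi) || !is.numeric(psi) || length(psi) != 1L ||
        psi < 0 || psi > 1)
      stop("point_mass family requires 'psi' in [0,1]", call. = FALSE)
    obj <- list(family = "point_mass", psi = as.numeric(psi),
                rate_multiplier = rate_multiplier)
  } else {
    if (is.null(a) || is.null(b) || a <= 0 || b <= 0)
      stop("beta family requires shape parameters a > 0 and b > 0",
           call. = FALSE)
    obj <- list(family = "beta", a = as.numeric(a), b = as.numeric(b),
                rate_multiplier = rate_multiplier)
  }
  class(obj) <- "lambda_measure"
  obj
}

#' @export
print.lambda_measure <- function(x, ...) {
  if (x$family == "point_mass") {
    lab <- if (x$psi == 0) "point mass at 0 (Kingman)"
           else sprintf("point mass at %g (Dirac)", x$psi)
  } else {
    lab <- sprintf("Beta(%g, %g)", x$a, x$b)
  }
  cat("Lambda measure:", lab)
  if (x$rate_multiplier != 1)
    cat(sprintf(", rate multiplier %g", x$rate_multiplier))
  cat("\n")
  invisible(x)
}

# x^p with the 0^0 = 1 convention used for merger-rate integrands
.pow00 <- function(x, p) ifelse(p == 0, 1, x^p)

# log E[X^{k-2}(1-X)^{b-k}] of the *probability* measure; -Inf when the
# expectation is 0. Vectorized over k. Log-Beta differences for the Beta
# family avoid overflow at large b.
.log_integrand_moment <- function(measure, b, k) {
  if (measure$family == "point_mass") {
    # fully in log space (0 * log(0) := 0 via the 0^0 = 1 convention)
    e1 <- k - 2
    e2 <- b - k
    ifelse(e1 == 0, 0, e1 * log(measure$psi)) +
      ifelse(e2 == 0, 0, e2 * log(1 - measure$psi))
  } else {
    a1 <- measure$a + k - 2
    b1 <- measure$b + b - k
    if (any(a1 <= 0) || any(b1 <= 0))
      stop("non-integrable Beta merger rate: a + k - 2 <= 0", call. = FALSE)
    lbeta(a1, b1) - lbeta(measure$a, measure$b)
  }
}

#' Merger rate of a Lambda coalescent
#'
#' Computes \eqn{\lambda_{b,k} = \int_0^1 x^{k-2}(1-x)^{b-k}\Lambda(dx)},
#' the rate at which a fixed set of k of b lineages merges. The Beta family
#' uses the closed form \eqn{B(a+k-2, b+b'-k)/B(a,b')} evaluated through
#' log-Beta differences; the point mass evaluates the integrand at \eqn{\psi}
#' with the \eqn{0^0 = 1} convention.
#'
#' @param measure A [lambda_measure()].
#' @param b Number of lineages present (integer, `>= 2`).
#' @param k Merger size(s), integer(s) in `[2, b]`; vectorized.
#' @return Nonnegative rate(s), including the `rate_multiplier`.
#' @export
merger_rate <- function(measure, b, k) {
  stopifnot(inherits(measure, "lambda_measure"))
  b <- as.integer(b)
  if (length(b) != 1L || is.na(b) || b < 2)
    stop("'b' must be a single integer >= 2", call. = FALSE)
  if (any(k < 2) || any(k > b))
    stop("'k' must satisfy 2 <= k <= b", call. = FALSE)
  measure$rate_multiplier * exp(.log_integrand_moment(measure, b, k))
}

#' Total transition rate of a Lambda b-coalescent
#'
#' \eqn{\lambda_b = \sum_{k=2}^b \binom{b}{k}\lambda_{b,k}}, the rate at
#' which the first merger among b lineages occurs.
#'
#' @inheritParams merger_rate
#' @return A positive scalar.
#' @export
total_rate <- function(measure, b) {
  stopifnot(inherits(measure, "lambda_measure"))
  b <- as.integer(b)
  if (length(b) != 1L || is.na(b) || b < 2)
    stop("'b' must be a single integer >= 2", call. = FALSE)
  k <- 2:b
  lv <- lchoose(b, k) + .log_integrand_moment(measure, b, k)
  measure$rate_multiplier * sum(exp(lv))
}

#' Moments of the underlying probability measure
#'
#' Returns \eqn{E(X^m)} for \eqn{X \sim \Lambda} (the probability measure
#' before `rate_multiplier`): \eqn{\psi^m} for a point mass (with
#' \eqn{0^0 = 1}), \eqn{B(a+m,b)/B(a,b)} for the Beta family.
#'
#' @param measure A [lambda_measure()].
#' @param m Nonnegative integer moment order(s); vectorized.
#' @return Value(s) in `[0, 1]`.
#' @export
measure_moment <- function(measure, m) {
  stopifnot(inherits(measure, "lambda_measure"))
  if (any(m < 0)) stop("'m' must be >= 0", call. = FALSE)
  if (measure$family == "point_mass") {
    .pow00(measure$psi, m)
  } else {
    exp(lbeta(measure$a + m, measure$b) - lbeta(measure$a, measure$b))
  }
}

#' Merger-rate table for b lineages
#'
#' All rates \eqn{\lambda_{b,k}}, k = 2..b, together with the total rate
#' \eqn{\lambda_b} and the jump-chain probabilities
#' \eqn{\binom{b}{k}\lambda_{b,k}/\lambda_b} of the next merger's size.
#'
#' @inheritParams merger_rate
#' @return A list of class `merger_rate_table` with components `b`, `k`,
#'   `rates`, `total` and `size_probs`.
#' @export
merger_rate_table <- function(measure, b) {
  stopifnot(inherits(measure, "lambda_measure"))
  b <- as.integer(b)
  if (length(b) != 1L || is.na(b) || b < 2)
    stop("'b' must be a single integer >= 2", call. = FALSE)
  k <- 2:b
  lograte <- log(measure$rate_multiplier) + .log_integrand_moment(measure, b, k)
  lw <- lchoose(b, k) + lograte
  M <- max(lw)
  logtot <- M + log(sum(exp(lw - M)))
  structure(list(b = b, k = k, rates = exp(lograte), total = exp(logtot),
                 size_probs = exp(lw - logtot)),
            class = "merger_rate_table")
}

#' @export
print.merger_rate_table <- function(x, ...) {
  cat(sprintf("Merger rates for b = %d lineages (total rate %.6g)\n",
              x$b, x$total))
  df <- data.frame(k = x$k, rate = x$rates, size_prob = x$size_probs)
  print(utils::head(df, 10), row.names = FALSE)
  if (x$b > 11) cat(sprintf("  ... %d more rows\n", x$b - 11L))
  invisible(x)
}

# jump-chain pmf of the next merger size, as a bare vector over k = 2..b
.merger_size_probs <- function(measure, b) merger_rate_table(measure, b)$size_probs
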