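#' Deterministic time change induced by a size profile
#'
#' Population-size change enters the limiting Lambda-n-coalescent only
#' through the deterministic clock
#' \deqn{\mathcal{G}(t) = \int_0^t \nu(s)^{-\gamma}\, ds,}
#' where \eqn{\gamma > 0} is the scaling exponent of the discrete model's
#' coalescence probability (\eqn{c_N \asymp N^{-\gamma}}); \eqn{\gamma = 0}
#' encodes the logarithmic-\eqn{c_N} case, for which \eqn{\mathcal{G}} is
#' the identity. Exponential profiles \eqn{\nu(t) = e^{-\rho t}} admit the
#' closed form \eqn{\mathcal{G}(t) = (\rho\gamma)^{-1}(e^{\rho\gamma t}-1)};
#' other profiles are integrated adaptively.
#'
#' @param profile A [size_profile()].
#' @param gamma Nonnegative time-change exponent.
#' @return An object of class `time_change` with functions `G` and `Ginv`.
#' @examples
#' tc <- time_change(size_profile("exponential", rho = 1), gamma = 2)
#' time_change_G(tc, 1)        # (e^2 - 1)/2
#' @export
time_change <- function(profile, gamma) {
  stopifnot(inherits(profile, "size_profile"))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("'gamma' must be >= 0", call. = FALSE)
  structure(list(profile = profile, gamma = gamma), class = "time_change")
}

#' @export
print.time_change <- function(x, ...) {
  cat(sprintf("Time change G(t) = int_0^t nu(s)^-%g ds, profile = %s\n",
              x$gamma, x$profile$kind))
  invisible(x)
}

#' Evaluate the time change and its inverse
#'
#' `time_change_G` computes \eqn{\mathcal{G}(t)}; `time_change_Ginv` solves
#' \eqn{\mathcal{G}(t) = g} for t (closed form for exponential profiles,
#' monotone bracketing plus `uniroot` to absolute tolerance 1e-10
#' otherwise).
#'
#' @param tc A [time_change()].
#' @param t Nonnegative time(s).
#' @param g Nonnegative internal time(s).
#' @return Nonnegative value(s).
#' @export
time_change_G <- function(tc, t) {
  stopifnot(inherits(tc, "time_change"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  g <- tc$gamma
  p <- tc$profile
  if (g == 0 || p$kind == "constant") return(t)
  if (p$kind == "exponential") {
    rg <- p$rho * g
    if (rg == 0) return(t)
    return((exp(rg * t) - 1) / rg)
  }
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    stats::integrate(function(s) profile_value(p, s,
                                               warn_extrapolate = FALSE)^(-g),
                     0, ti, rel.tol = 1e-12, abs.tol = 1e-12,
                     subdivisions = 2000L)$value
  }, numeric(1))
}

#' @rdname time_change_G
#' @export
time_change_Ginv <- function(tc, g) {
  stopifnot(inherits(tc, "time_change"))
  if (any(g < 0)) stop("'g' must be >= 0", call. = FALSE)
  ga <- tc$gamma
  p <- tc$profile
  if (ga == 0 || p$kind == "constant") return(g)
  if (p$kind == "exponential") {
    rg <- p$rho * ga
    if (rg == 0) return(g)
    arg <- rg * g + 1
    if (any(arg <= 0))
      stop("time change saturates before reaching the requested internal ",
           "time (declining-size horizon)", call. = FALSE)
    return(log(arg) / rg)
  }
  vapply(g, function(gi) {
    if (gi == 0) return(0)
    hi <- 1
    while (time_change_G(tc, hi) < gi) {
      hi <- hi * 2
      if (hi > 1e12)
        stop("cannot bracket the time-change inverse on this profile",
             call. = FALSE)
    }
    stats::uniroot(function(t) time_change_G(tc, t) - gi, c(0, hi),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Simulate a (time-changed) Lambda-n-coalescent exactly
#'
#' From b blocks the process waits an Exp(\eqn{\lambda_b}) internal time,
#' merges k blocks with probability
#' \eqn{\binom{b}{k}\lambda_{b,k}/\lambda_b} (the k blocks uniform among
#' all \eqn{\binom{b}{k}} subsets), and repeats until one block remains.
#' With a [time_change()] the internal waiting time W after the last event
#' at external time \eqn{t_0} is mapped to the external wait t solving
#' \eqn{\mathcal{G}(t_0+t) - \mathcal{G}(t_0) = W}; the jump chain (the
#' sequence of merger sizes and merging blocks) is unaffected, so matched
#' seeds give identical jump chains with and without time change.
#'
#' @param measure A [lambda_measure()].
#' @param n Sample size, `>= 1`.
#' @param tc Optional [time_change()]; `NULL` means the standard coalescent.
#' @return A [genealogy] in coalescent units.
#' @examples
#' tr <- simulate_lambda_coalescent(lambda_measure("point_mass", psi = 0.5), 6)
#' events_table(tr)
#' @export
simulate_lambda_coalescent <- function(measure, n, tc = NULL) {
  stopifnot(inherits(measure, "lambda_measure"))
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  if (!is.null(tc)) stopifnot(inherits(tc, "time_change"))
  events <- list()
  reps <- seq_len(n)
  b <- n
  t_ext <- 0
  g_int <- 0   # G(t_ext), tracked to avoid re-evaluating G
  size_cache <- new.env(parent = emptyenv())
  while (b > 1L) {
    key <- as.character(b)
    if (is.null(size_cache[[key]])) {
      tab <- merger_rate_table(measure, b)
      size_cache[[key]] <- list(total = tab$total, probs = tab$size_probs)
    }
    sc <- size_cache[[key]]
    W <- stats::rexp(1L, sc$total)
    k <- if (b == 2L) 2L else
      1L + sample.int(b - 1L, 1L, prob = sc$probs)
    if (is.null(tc)) {
      t_ext <- t_ext + W
    } else {
      g_int <- g_int + W
      t_ext <- time_change_Ginv(tc, g_int)
    }
    sel <- sample.int(b, k)
    events[[length(events) + 1L]] <-
      list(time = t_ext, generation = NULL, members = reps[sel])
    reps <- c(reps[-sel], min(reps[sel]))
    b <- b - (k - 1L)
  }
  lab <- if (is.null(tc)) "standard" else
    sprintf("time-changed (%s profile, gamma = %g)", tc$profile$kind, tc$gamma)
  .new_genealogy(n, events, engine = "limit", unit = "coalescent",
                 c_ref = 1, open = FALSE,
                 model_label = paste(lab, "limit coalescent"))
}

#' Gompertz waiting-time distribution under exponential growth
#'
#' Under exponential growth (\eqn{\nu(t) = e^{-\rho t}}, time-change
#' exponent \eqn{\gamma}), the external waiting time T to the next merger,
#' given the last merger at \eqn{t_0} left b blocks, is Gompertz with
#' parameters \eqn{a = \lambda_b e^{\rho\gamma t_0}} and \eqn{b = \rho\gamma}:
#' \deqn{P(T \le t) = 1 - \exp\left(-\frac{\lambda_b}{\rho\gamma}
#'   e^{\rho\gamma t_0}(e^{\rho\gamma t}-1)\right),}
#' which is exactly \eqn{1 - e^{-\lambda_b(\mathcal{G}(t_0+t)-\mathcal{G}(t_0))}}.
#'
#' @param b Block count, `>= 2`.
#' @param t0 External time of the last merger.
#' @param rho Growth rate, `> 0`.
#' @param gamma Time-change exponent, `> 0`.
#' @param measure A [lambda_measure()] (supplies \eqn{\lambda_b}).
#' @param t Nonnegative waiting time(s).
#' @return Probability(ies) \eqn{P(T \le t)}.
#' @export
gompertz_waiting_cdf <- function(b, t0, rho, gamma, measure, t) {
  stopifnot(rho > 0, gamma > 0, t0 >= 0)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  lam <- total_rate(measure, b)
  rg <- rho * gamma
  1 - exp(-lam / rg * exp(rg * t0) * (exp(rg * t) - 1))
}
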