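#' Population-size profiles in coalescent time
#'
#' A size profile \eqn{\nu(t)} gives the population size \eqn{t} coalescent
#' time units into the past as a fraction of the reference (present) size N:
#' the discrete model has \eqn{N_{\lfloor t c_N^{-1}\rfloor} \approx N\nu(t)}.
#' By convention \eqn{\nu(0) = 1}, and on every bounded horizon \eqn{\nu}
#' must stay bounded away from 0 and \eqn{\infty} (sizes of order N).
#'
#' Supported kinds:
#' * `"constant"`: \eqn{\nu \equiv 1}.
#' * `"exponential"`: \eqn{\nu(t) = e^{-\rho t}}; \eqn{\rho > 0} is growth
#'   (forward in time), so the population shrinks going into the past.
#' * `"piecewise"`: piecewise-constant levels between breakpoints
#'   (bottlenecks); the first level must be 1.
#' * `"tabulated"`: linear interpolation of `(times, values)` with
#'   `times[1] = 0`, `values[1] = 1`; constant extrapolation beyond the last
#'   time (with a warning on use).
#'
#' @param kind One of `"constant"`, `"exponential"`, `"piecewise"`,
#'   `"tabulated"`.
#' @param rho Exponential growth rate (may be negative for decline).
#' @param breakpoints Increasing positive times delimiting the piecewise
#'   levels; level `i` applies on `[breakpoints[i-1], breakpoints[i])`.
#' @param levels Positive sizes relative to N, one more than `breakpoints`;
#'   `levels[1]` must equal 1.
#' @param times,values Tabulated profile nodes.
#' @return An object of class `size_profile`.
#' @examples
#' bott <- size_profile("piecewise", breakpoints = c(1, 2), levels = c(1, 0.1, 1))
#' profile_value(bott, c(0.5, 1.5, 3))
#' @export
size_profile <- function(kind = c("constant", "exponential", "piecewise",
                                  "tabulated"),
                         rho = NULL, breakpoints = NULL, levels = NULL,
                         times = NULL, values = NULL) {
  kind <- match.arg(kind)
  obj <- list(kind = kind)
  if (kind == "exponential") {
    if (is.null(rho) || !is.numeric(rho) || length(rho) != 1L)
      stop("exponential profile requires a scalar 'rho'", call. = FALSE)
    obj$rho <- rho
  } else if (kind == "piecewise") {
    if (is.null(breakpoints) || is.null(levels) ||
        length(levels) != length(breakpoints) + 1L)
      stop("piecewise profile requires levels = breakpoints + 1 values",
           call. = FALSE)
    if (is.unsorted(breakpoints, strictly = TRUE) || any(breakpoints <= 0))
      stop("'breakpoints' must be strictly increasing and positive",
           call. = FALSE)
    if (any(levels <= 0)) stop("'levels' must be positive", call. = FALSE)
    if (levels[1] != 1)
      stop("levels[1] must be 1 (nu(0) = 1 convention)", call. = FALSE)
    obj$breakpoints <- breakpoints
    obj$levels <- levels
  } else if (kind == "tabulated") {
    if (is.null(times) || is.null(values) || length(times) != length(values))
      stop("tabulated profile requires matching 'times' and 'values'",
           call. = FALSE)
    if (times[1] != 0 || values[1] != 1)
      stop("tabulated profile must start at (0, 1)", call. = FALSE)
    if (is.unsorted(times, strictly = TRUE))
      stop("'times' must be strictly increasing", call. = FALSE)
    if (any(values <= 0)) stop("'values' must be positive", call. = FALSE)
    obj$times <- times
    obj$values <- values
  }
  class(obj) <- "size_profile"
  obj
}

#' @export
print.size_profile <- function(x, ...) {
  lab <- switch(x$kind,
    constant = "constant",
    exponential = sprintf("exponential, rho = %g", x$rho),
    piecewise = sprintf("piecewise constant, %d pieces", length(x$levels)),
    tabulated = sprintf("tabulated, %d nodes on [0, %g]", length(x$times),
                        max(x$times)))
  cat("Population-size profile:", lab, "\n")
  invisible(x)
}

#' Evaluate a size profile
#'
#' Returns \eqn{\nu(t)}; vectorized over `t`.
#'
#' @param profile A [size_profile()].
#' @param t Nonnegative coalescent time(s).
#' @param warn_extrapolate Warn when a tabulated profile is evaluated beyond
#'   its last node (constant extrapolation is used).
#' @return Positive value(s) of \eqn{\nu(t)}.
#' @export
profile_value <- function(profile, t, warn_extrapolate = TRUE) {
  stopifnot(inherits(profile, "size_profile"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  switch(profile$kind,
    constant = rep(1, length(t)),
    exponential = exp(-profile$rho * t),
    piecewise = profile$levels[findInterval(t, profile$breakpoints) + 1L],
    tabulated = {
      if (warn_extrapolate && any(t > max(profile$times)))
        warning("evaluating tabulated profile beyond its range; ",
                "constant extrapolation used", call. = FALSE)
      stats::approx(profile$times, profile$values, xout = pmin(t, max(profile$times)),
                    rule = 2)$y
    })
}

#' Discretize a size profile into a backward generation-size trajectory
#'
#' Builds the sequence \eqn{N_r} of population sizes r generations into the
#' past (r = 0 is the sampling generation), matching the profile through the
#' time map \eqn{t = r c_N}. Exponential profiles use the geometric
#' recursion \eqn{N_r = \lfloor N(1-\rho c_N)^r\rfloor} (evaluated in closed
#' form on demand, so long horizons cost nothing); other profiles use
#' \eqn{N_r = \mathrm{round}(N\nu(r c_N))}, clamped below at
#' \eqn{\max(2, n)} with a warning. The forward per-generation increments
#' \eqn{d_{N,r} = N_{r-1} - N_r} are available via [trajectory_sizes()].
#'
#' @param profile A [size_profile()].
#' @param N Reference population size (present day), integer `>= 2`.
#' @param cN Pairwise coalescence probability of the reference-size model,
#'   in `(0, 1)`; one coalescent time unit spans `1/cN` generations.
#' @param horizon_t Coalescent-time horizon to cover.
#' @param n Sample size the trajectory must support (sizes never drop below
#'   `max(2, n)`).
#' @return An object of class `size_trajectory`.
#' @export
discretize_profile <- function(profile, N, cN, horizon_t, n = 2L) {
  stopifnot(inherits(profile, "size_profile"))
  N <- as.integer(N)
  if (!is.numeric(cN) || length(cN) != 1L || cN <= 0 || cN > 1)
    stop("'cN' must lie in (0, 1]", call. = FALSE)
  if (horizon_t <= 0) stop("'horizon_t' must be positive", call. = FALSE)
  floorN <- max(2L, as.integer(n))
  R <- ceiling(horizon_t / cN)
  obj <- list(profile = profile, N0 = N, cN = cN, horizon_t = horizon_t,
              R = R, floorN = floorN)
  if (profile$kind == "constant") {
    if (N < floorN) stop("N below max(2, n)", call. = FALSE)
    obj$kind <- "constant"
  } else if (profile$kind == "exponential") {
    obj$kind <- "exponential"
    obj$rho <- profile$rho
    nu_end <- (1 - profile$rho * cN)^R
    if (N * min(1, nu_end) < floorN)
      stop("profile dips below max(2, n)/N on the horizon", call. = FALSE)
  } else {
    tgrid <- (0:R) * cN
    nu <- profile_value(profile, tgrid, warn_extrapolate = FALSE)
    if (any(N * nu < floorN))
      stop("profile dips below max(2, n)/N on the horizon", call. = FALSE)
    sizes <- round(N * nu)
    if (any(sizes < floorN)) {
      warning("trajectory clamped at max(2, n)", call. = FALSE)
      sizes <- pmax(sizes, floorN)
    }
    obj$kind <- "materialized"
    obj$sizes <- as.integer(sizes)
  }
  class(obj) <- "size_trajectory"
  obj
}

#' Generation sizes of a trajectory
#'
#' Returns \eqn{N_r} for backward generation indices `r` (vectorized).
#' Indices beyond the built horizon extend the profile by its own rule
#' (constant extrapolation for tabulated profiles, with a warning).
#'
#' @param trajectory A [discretize_profile()] result.
#' @param r Nonnegative integer generation indices.
#' @return Integer sizes.
#' @export
trajectory_sizes <- function(trajectory, r) {
  stopifnot(inherits(trajectory, "size_trajectory"))
  if (any(r < 0)) stop("'r' must be >= 0", call. = FALSE)
  N <- trajectory$N0
  switch(trajectory$kind,
    constant = rep(N, length(r)),
    exponential = {
      s <- floor(N * (1 - trajectory$rho * trajectory$cN)^r)
      pmax(as.integer(s), trajectory$floorN)
    },
    materialized = {
      if (any(r > trajectory$R)) {
        warning("extending trajectory beyond its horizon", call. = FALSE)
        nu <- profile_value(trajectory$profile, r * trajectory$cN,
                            warn_extrapolate = FALSE)
        pmax(as.integer(round(N * nu)), trajectory$floorN)
      } else {
        trajectory$sizes[r + 1L]
      }
    })
}

#' @export
print.size_trajectory <- function(x, ...) {
  cat(sprintf(
    "Size trajectory: N0 = %d, cN = %.4g, horizon %.3g coalescent units (%d generations)\n",
    x$N0, x$cN, x$horizon_t, x$R))
  r_show <- unique(pmin(c(0, 1, floor(x$R / 2), x$R), x$R))
  cat("  N_r at r =", paste(r_show, collapse = ", "), ":",
      paste(trajectory_sizes(x, r_show), collapse = ", "), "\n")
  invisible(x)
}

#' Spread an instantaneous size jump over many generations
#'
#' An instantaneous size change of magnitude \eqn{mN} on the coalescent
#' scale can be realized in the discrete model by changing the size by
#' roughly \eqn{mN\sqrt{c_N}} per generation for \eqn{1/\sqrt{c_N}}
#' generations, so per-generation relative increments vanish as N grows.
#' This takes a trajectory and superimposes such a ramp: sizes further in
#' the past than the ramp differ by exactly \eqn{\lfloor mN\rfloor}
#' (`m > 0` means the population *gained* that many individuals, forward in
#' time, around `at_t`, so it is smaller further in the past).
#'
#' @param trajectory A [discretize_profile()] result.
#' @param m Signed jump fraction of the reference size N.
#' @param at_t Coalescent time (into the past) at which the change is
#'   centered.
#' @return A materialized `size_trajectory` with the ramp applied.
#' @export
spread_jump <- function(trajectory, m, at_t) {
  stopifnot(inherits(trajectory, "size_trajectory"))
  if (m == 0) return(trajectory)
  N <- trajectory$N0
  cN <- trajectory$cN
  J <- floor(abs(m) * N) * sign(m)
  g <- ceiling(1 / sqrt(cN))
  r0 <- as.integer(round(at_t / cN))
  if (r0 + g > trajectory$R)
    stop("jump ramp does not fit within the trajectory horizon",
         call. = FALSE)
  r_all <- 0:trajectory$R
  sizes <- trajectory_sizes(trajectory, r_all)
  # cumulative integer ramp: after the ramp the offset is exactly -J
  ramp <- -round(J * (seq_len(g) / g))
  offset <- integer(trajectory$R + 1L)
  offset[(r0 + 1L):(r0 + g)] <- ramp
  if (r0 + g < trajectory$R) offset[(r0 + g + 1L):(trajectory$R + 1L)] <- -J
  sizes <- sizes + offset
  if (any(sizes < trajectory$floorN))
    stop("spread jump pushes sizes below max(2, n)", call. = FALSE)
  out <- trajectory
  out$kind <- "materialized"
  out$sizes <- as.integer(sizes)
  out
}
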