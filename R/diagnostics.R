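#' Monte-Carlo estimate of merger-pattern probabilities
#'
#' \eqn{\Phi^{(N)}_l(r; a_1,\dots,a_l)} is the probability that, among
#' \eqn{\sum a_i} individuals sampled without replacement in generation
#' r-1 and split into disjoint sets of sizes \eqn{a_1,\dots,a_l}, each set
#' finds a single common parent in generation r, with the parents distinct
#' across sets. For l = 1, a = 2 this is the pairwise coalescence
#' probability \eqn{c_{N,r}}. Estimated by replaying single generations.
#'
#' @param model A [moran_model()] or [schweinsberg_model()].
#' @param r Parent-generation index, `>= 1`.
#' @param pattern Integer vector \eqn{(a_1,\dots,a_l)}, each `>= 1`.
#' @param reps Monte-Carlo replicates.
#' @return A list of class `phi_estimate`: `estimate`, `se`, `reps`,
#'   `pattern`, `r`.
#' @export
estimate_phi <- function(model, r = 1L, pattern, reps = 10000L) {
  pattern <- as.integer(pattern)
  if (any(pattern < 1L)) stop("'pattern' entries must be >= 1", call. = FALSE)
  m <- sum(pattern)
  traj <- model$trajectory
  Nr <- trajectory_sizes(traj, r)
  Nprev <- trajectory_sizes(traj, r - 1L)
  if (m > Nprev)
    stop("pattern exceeds the offspring generation size", call. = FALSE)
  set_id <- rep.int(seq_along(pattern), pattern)
  hits <- 0L
  if (inherits(model, "moran_model")) {
    law <- model$law_at(Nr)
    for (i in seq_len(reps)) {
      U_eff <- .draw_U_eff(model, law, Nr, Nprev)
      pos <- sample.int(Nprev, m)
      lab <- ifelse(pos <= U_eff, 0L, pos)   # 0 = the multiplier
      hits <- hits + .phi_event(lab, set_id, pattern)
    }
  } else {
    for (i in seq_len(reps)) {
      lab <- .schweinsberg_sample_parents(model$law, Nr, Nprev, m)
      hits <- hits + .phi_event(lab, set_id, pattern)
    }
  }
  est <- hits / reps
  structure(list(estimate = est, se = sqrt(est * (1 - est) / reps),
                 reps = reps, pattern = pattern, r = r),
            class = "phi_estimate")
}

#' @export
print.phi_estimate <- function(x, ...) {
  cat(sprintf("Phi(%s) at generation %s: %.5g (SE %.2g, %d reps)\n",
              paste(x$pattern, collapse = ","), format(x$r), x$estimate,
              x$se, x$reps))
  invisible(x)
}

# success indicator: each set shares one parent; parents distinct across sets
.phi_event <- function(lab, set_id, pattern) {
  parents <- integer(length(pattern))
  for (s in seq_along(pattern)) {
    ls <- lab[set_id == s]
    if (length(unique(ls)) != 1L) return(0L)
    parents[s] <- ls[1]
  }
  as.integer(!anyDuplicated(parents))
}

#' Check the Moehle-Sagitov convergence ratios
#'
#' The discrete genealogies converge to the Lambda-n-coalescent iff
#' \eqn{c_N^{-1}\Phi^{(N)}_l(a_1,\dots,a_l) \to \phi_l(a_1,\dots,a_l)},
#' where the limit is \eqn{\lambda_{\sum a_i, a_1}} for a single merging
#' set and 0 for any simultaneous pattern. For modified Moran models with
#' l = 1 the ratio is computed exactly:
#' \eqn{\Phi_1(a) = E((U_N)_a)/(N)_a}, and for skewed (`uprime`) laws
#' it equals \eqn{E(X^{a-2})} for every N, not just in the limit.
#' Other cases are estimated by [estimate_phi()].
#'
#' @param model_for A `function(N)` returning the model at reference size N
#'   (constant-size profiles expected).
#' @param N_grid Population sizes to evaluate.
#' @param patterns List of integer vectors \eqn{(a_1,\dots,a_l)} with
#'   \eqn{a_1 \ge \dots \ge a_l \ge 2}.
#' @param measure The limiting [lambda_measure()] (supplies \eqn{\phi_l}).
#' @param reps Monte-Carlo replicates for non-exact cases.
#' @return A `data.frame` with one row per (N, pattern): the ratio, its SE
#'   (0 for exact entries), and the limit value `phi`.
#' @export
moehle_sagitov_check <- function(model_for, N_grid, patterns, measure,
                                 reps = 20000L) {
  stopifnot(is.function(model_for), inherits(measure, "lambda_measure"))
  rows <- list()
  for (N in N_grid) {
    model <- model_for(N)
    for (pat in patterns) {
      pat <- as.integer(sort(pat, decreasing = TRUE))
      if (any(pat < 2L))
        stop("patterns must have all a_i >= 2", call. = FALSE)
      btot <- sum(pat)
      phi <- if (length(pat) == 1L) merger_rate(measure, btot, pat[1]) else 0
      exact <- inherits(model, "moran_model") &&
        model$profile$kind == "constant"
      if (exact && length(pat) == 1L) {
        law <- model$law_at(N)
        ratio <- factorial_moment(law, pat[1]) / .falling(N, pat[1]) /
          coalescence_prob(law)
        se <- 0
      } else if (exact && length(pat) > 1L) {
        ratio <- 0   # a single multiplying parent: simultaneous mergers impossible
        se <- 0
      } else {
        ph <- estimate_phi(model, 1L, pat, reps)
        cN <- pairwise_coalescence_mc(model, 1L, reps)
        ratio <- ph$estimate / cN$estimate
        se <- ratio * sqrt((ph$se / max(ph$estimate, 1e-300))^2 +
                             (cN$se / cN$estimate)^2)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(N = N, pattern = paste(pat, collapse = ","),
                   ratio = ratio, se = se, phi = phi)
    }
  }
  do.call(rbind, rows)
}

#' Discrete time-scale table and its shifted pseudo-inverse
#'
#' Builds \eqn{F_N(s) = \sum_{r=1}^{[s]} c_{N,r}} over the trajectory and
#' the shifted pseudo-inverse
#' \eqn{\mathcal{G}_N^{-1}(t) = \inf\{s > 0 : F_N(s) > t\} - 1}, the
#' generation at which accumulated coalescence probability first exceeds
#' t. In `"exact"` mode the per-generation \eqn{c_{N,r}} of a modified
#' Moran model is computed from the offspring law: decline generations
#' preserve \eqn{E((U)_2)/(N_r)_2} exactly (hypergeometric subsampling is
#' neutral), growth generations use the scheme's conditional law of the
#' multiplier share A. `"mc"` mode estimates each \eqn{c_{N,r}} by
#' [pairwise_coalescence_mc()].
#'
#' @param model A [moran_model()] (exact or mc) or [schweinsberg_model()]
#'   (mc only).
#' @param horizon_t Coalescent-time horizon (defaults to the model's).
#' @param mode `"exact"` or `"mc"`.
#' @param reps Replicates per generation for `"mc"`.
#' @return An object of class `time_scale_table`: data.frame `table` with
#'   `r`, `N_r`, `c_Nr`, `F`, plus function `Ginv(t)` returning the shifted
#'   pseudo-inverse in generations.
#' @export
empirical_time_scale <- function(model, horizon_t = NULL,
                                 mode = c("exact", "mc"), reps = 5000L) {
  mode <- match.arg(mode)
  traj <- model$trajectory
  if (is.null(horizon_t)) horizon_t <- traj$horizon_t
  R <- min(ceiling(horizon_t / traj$cN), traj$R)
  r_all <- seq_len(R)
  sizes <- trajectory_sizes(traj, 0:R)
  if (mode == "exact") {
    if (!inherits(model, "moran_model"))
      stop("exact mode requires a modified Moran model", call. = FALSE)
    cNr <- vapply(r_all, function(r)
      .moran_cNr_exact(model, sizes[r + 1L], sizes[r]), numeric(1))
  } else {
    cNr <- vapply(r_all, function(r)
      pairwise_coalescence_mc(model, r, reps)$estimate, numeric(1))
  }
  FN <- cumsum(cNr)
  tab <- data.frame(r = r_all, N_r = sizes[-1L], c_Nr = cNr, F = FN)
  Ginv <- function(t) {
    if (any(t >= FN[R]))
      warning("t beyond accumulated coalescence probability; ",
              "pseudo-inverse capped at the horizon", call. = FALSE)
    pmin(findInterval(t, FN), R)
  }
  structure(list(table = tab, Ginv = Ginv, cN = traj$cN, N0 = traj$N0,
                 mode = mode),
            class = "time_scale_table")
}

#' @export
print.time_scale_table <- function(x, ...) {
  cat(sprintf("Time-scale table (%s), N0 = %d, %d generations, F_N(end) = %.4g\n",
              x$mode, x$N0, nrow(x$table), max(x$table$F)))
  invisible(x)
}

# exact per-generation pairwise coalescence probability of one modified
# Moran step Nr -> Nprev
.moran_cNr_exact <- function(model, Nr, Nprev) {
  law <- model$law_at(Nr)
  d <- Nprev - Nr
  if (d <= 0L) return(factorial_moment(law, 2L) / (Nr * (Nr - 1)))
  pe <- .effective_pmf(law)
  u <- pe$support
  EU2 <- switch(model$scheme,
    to_multiplier = sum(pe$pmf * (u + d) * (u + d - 1)),
    to_nonreproducers = {
      if (any(d > u - 1L))
        stop("infeasible to_nonreproducers allocation", call. = FALSE)
      sum(pe$pmf * u * (u - 1))
    },
    proportional = {
      tot <- 0
      for (i in seq_along(u)) {
        a <- 0:d
        pa <- stats::dbinom(a, d, u[i] / Nr)
        amin <- max(0L, d - (u[i] - 1L))          # overflow pushed up
        a_eff <- pmax(a, amin)
        tot <- tot + pe$pmf[i] *
          sum(pa * (u[i] + a_eff) * (u[i] + a_eff - 1))
      }
      tot
    })
  EU2 / (Nprev * (Nprev - 1))
}

#' Distributional test of a discrete model against its coalescent limit
#'
#' Simulates `reps` genealogies from the discrete model (times rescaled by
#' its reference coalescence probability) and from the (optionally
#' time-changed) Lambda-n-coalescent, and compares: the pairwise
#' coalescence time by two-sample Kolmogorov-Smirnov when n = 2; the
#' first-merger-size distribution by a chi-squared test against the limit
#' jump-chain pmf \eqn{\binom{n}{k}\lambda_{n,k}/\lambda_n} when n >= 3
#' (categories with expected count below 5 pooled with the largest-size
#' bin); and the TMRCA distribution by two-sample KS. Run under a fixed
#' seed for a reproducible report.
#'
#' @param model A [moran_model()] or [schweinsberg_model()].
#' @param measure The limiting [lambda_measure()].
#' @param n Sample size.
#' @param reps Replicates per side.
#' @param tc Optional [time_change()] applied to the limit.
#' @return A list of class `convergence_report` with components
#'   `pairwise_ks`, `first_merger_chisq`, `tmrca_ks` (each with `statistic`
#'   and `p_value`; `NULL` where not applicable) and the raw draws.
#' @export
genealogy_convergence_test <- function(model, measure, n, reps = 500L,
                                       tc = NULL) {
  stopifnot(inherits(measure, "lambda_measure"))
  n <- as.integer(n)
  disc_t <- numeric(reps)
  disc_first <- integer(reps)
  lim_t <- numeric(reps)
  lim_first <- integer(reps)
  for (i in seq_len(reps)) {
    gd <- simulate_genealogy(model, n)
    disc_t[i] <- if (gd$open) NA_real_ else gd$tmrca * model$c_ref
    disc_first[i] <- gd$first_merger_size
    gl <- simulate_lambda_coalescent(measure, n, tc)
    lim_t[i] <- gl$tmrca
    lim_first[i] <- gl$first_merger_size
  }
  out <- list(n = n, reps = reps)
  if (n == 2L) {
    # discrete generation times can tie; the approximate KS p-value is fine
    ks <- suppressWarnings(stats::ks.test(disc_t[!is.na(disc_t)], lim_t))
    out$pairwise_ks <- list(statistic = unname(ks$statistic),
                            p_value = ks$p.value)
  }
  if (n >= 3L) {
    probs <- .merger_size_probs(measure, n)
    obs <- tabulate(disc_first, n)[2:n]
    out$first_merger_chisq <- .chisq_pooled(obs, probs)
  }
  ks2 <- suppressWarnings(stats::ks.test(disc_t[!is.na(disc_t)], lim_t))
  out$tmrca_ks <- list(statistic = unname(ks2$statistic),
                       p_value = ks2$p.value)
  out$draws <- list(discrete_tmrca = disc_t, limit_tmrca = lim_t,
                    discrete_first = disc_first, limit_first = lim_first)
  class(out) <- "convergence_report"
  out
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence report (n = %d, %d reps per side)\n", x$n, x$reps))
  if (!is.null(x$pairwise_ks))
    cat(sprintf("  pairwise-time KS: D = %.4f, p = %.4g\n",
                x$pairwise_ks$statistic, x$pairwise_ks$p_value))
  if (!is.null(x$first_merger_chisq))
    cat(sprintf("  first-merger-size chi^2: X2 = %.3f (df %d), p = %.4g\n",
                x$first_merger_chisq$statistic, x$first_merger_chisq$df,
                x$first_merger_chisq$p_value))
  cat(sprintf("  TMRCA KS: D = %.4f, p = %.4g\n",
              x$tmrca_ks$statistic, x$tmrca_ks$p_value))
  invisible(x)
}

# goodness-of-fit chi^2 with expected-count pooling (< 5 pooled together
# with the largest-size bin). Degenerate expected categories that received
# observations force p = 0 (analytically impossible under H0).
.chisq_pooled <- function(obs, probs) {
  reps <- sum(obs)
  expd <- reps * probs
  impossible <- probs < 1e-14 & obs > 0
  if (any(impossible))
    return(list(statistic = Inf, df = NA_integer_, p_value = 0))
  pool <- expd < 5
  if (any(pool)) pool[length(pool)] <- TRUE
  if (sum(!pool) < 1 || sum(pool) == length(pool)) {
    # everything pooled: no resolution left
    pool <- rep(FALSE, length(obs))
    pool[length(obs)] <- TRUE
  }
  o <- c(obs[!pool], sum(obs[pool]))
  e <- c(expd[!pool], sum(expd[pool]))
  keep <- e > 0
  o <- o[keep]
  e <- e[keep]
  stat <- sum((o - e)^2 / e)
  df <- length(o) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Non-vanishing coalescence under an abrupt expansion
#'
#' A single-generation population jump of size \eqn{\lfloor mN \rfloor}
#' allocated entirely to the multiplying parent makes the pairwise
#' coalescence probability of that generation order 1 instead of
#' vanishing: it is bounded below by \eqn{(mN-1)^2/(N_{r-1})_2} with
#' \eqn{N_{r-1} = N + \lfloor mN \rfloor}. Returns the analytic bound next
#' to a Monte-Carlo estimate of the actual probability; this is why abrupt
#' size changes must be spread over many generations (see [spread_jump()])
#' for a coalescent limit to exist.
#'
#' @param N Population size before the jump.
#' @param m Jump fraction in `(0, 1]` with `N*m >= 2`.
#' @param reps Monte-Carlo replicates.
#' @param law Offspring law of the base model (defaults to the standard
#'   Moran law, U = 2).
#' @return A list with `bound`, `estimate`, `se`, `d`.
#' @export
abrupt_expansion_demo <- function(N, m, reps = 100000L, law = NULL) {
  if (m < 0 || m > 1) stop("'m' must lie in (0, 1]", call. = FALSE)
  if (is.null(law)) law <- standard_law(N)
  d <- floor(N * m)
  if (m > 0 && d < 2) stop("'N*m' must be >= 2", call. = FALSE)
  U <- sample_U(law, reps)
  U_eff <- U + d
  Nprev <- N + d
  p <- U_eff * (U_eff - 1) / (Nprev * (Nprev - 1))
  hits <- stats::runif(reps) < p
  est <- mean(hits)
  bound <- if (d > 0) (N * m - 1)^2 / (Nprev * (Nprev - 1)) else 0
  list(bound = bound, estimate = est,
       se = sqrt(est * (1 - est) / reps), d = d)
}
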