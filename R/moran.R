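#' Modified Moran model with variable population size
#'
#' Bundles everything one generation step needs: the offspring-law family
#' (evaluated at each generation's size), the backward size trajectory
#' derived from a [size_profile()], and the growth-allocation scheme.
#' One generation, backwards in time, from parents (generation r, size
#' \eqn{N_r}) to offspring (generation r-1, size \eqn{N_{r-1}}):
#'
#' 1. a fixed-size modified Moran step at \eqn{N_r} (one multiplier with
#'    \eqn{U_{N_r}} offspring, \eqn{U_{N_r}-1} childless parents, all
#'    others one offspring);
#' 2. if \eqn{N_{r-1} < N_r}, a uniform without-replacement subsample of
#'    \eqn{N_{r-1}} offspring (the multiplier's surviving brood is then
#'    hypergeometric);
#' 3. if \eqn{N_{r-1} > N_r}, the \eqn{d_{N,r}} extra individuals are
#'    allocated according to `scheme`: all to the multiplier
#'    (`"to_multiplier"`), all to previously childless parents
#'    (`"to_nonreproducers"`, feasible only when \eqn{d \le U-1}), or
#'    binomially with probability \eqn{U_{N_r}/N_r} to the multiplier
#'    (`"proportional"`), overflow beyond the available childless slots
#'    being pushed to the multiplier.
#'
#' @param N Reference (present-day) population size.
#' @param offspring `"standard"` (U = 2), `"uprime"` (skewed law from
#'   `measure`), or `"rarefied"` (skewed law activated with probability
#'   \eqn{N^{-\gamma}\lambda_N}).
#' @param measure A [lambda_measure()]; required for `"uprime"` and
#'   `"rarefied"`.
#' @param gamma Rarefaction exponent in `(1,2)` (rarefied only).
#' @param profile A [size_profile()]; defaults to constant size.
#' @param scheme Growth-allocation scheme (see above).
#' @param horizon_t Coalescent-time horizon used to pre-build the size
#'   trajectory for non-constant profiles.
#' @param law_factory Optional `function(N)` returning a `moran_law`; overrides
#'   `offspring` (for custom laws such as Eldon-Wakeley two-point models).
#' @return An object of class `moran_model`.
#' @examples
#' m <- moran_model(N = 100, offspring = "standard")
#' g <- simulate_genealogy(m, n = 4)
#' summary(g)
#' @export
moran_model <- function(N, offspring = c("standard", "uprime", "rarefied"),
                        measure = NULL, gamma = NULL,
                        profile = size_profile("constant"),
                        scheme = c("proportional", "to_multiplier",
                                   "to_nonreproducers"),
                        horizon_t = 10, law_factory = NULL) {
  scheme <- match.arg(scheme)
  N <- as.integer(N)
  if (is.null(law_factory)) {
    offspring <- match.arg(offspring)
    if (offspring %in% c("uprime", "rarefied") &&
        !inherits(measure, "lambda_measure"))
      stop(sprintf("offspring = \"%s\" requires a lambda_measure", offspring),
           call. = FALSE)
    if (offspring == "rarefied" && is.null(gamma))
      stop("offspring = \"rarefied\" requires gamma", call. = FALSE)
    law_factory <- switch(offspring,
      standard = function(N) standard_law(N),
      uprime = function(N) uprime_law(measure, N),
      rarefied = function(N) rarefy(measure, N, gamma))
    label <- offspring
  } else {
    stopifnot(is.function(law_factory))
    label <- "custom"
  }
  cache <- new.env(parent = emptyenv())
  law_at <- function(Nr) {
    key <- as.character(Nr)
    if (is.null(cache[[key]])) cache[[key]] <- law_factory(as.integer(Nr))
    cache[[key]]
  }
  c_ref <- coalescence_prob(law_at(N))
  trajectory <- discretize_profile(profile, N, c_ref, horizon_t, n = 2L)
  structure(list(N = N, offspring = label, measure = measure, gamma = gamma,
                 profile = profile, scheme = scheme, horizon_t = horizon_t,
                 law_at = law_at, c_ref = c_ref, trajectory = trajectory),
            class = "moran_model")
}

#' @export
print.moran_model <- function(x, ...) {
  cat(sprintf(
    "Modified Moran model: N = %d, offspring = %s, profile = %s, scheme = %s\n",
    x$N, x$offspring, x$profile$kind, x$scheme))
  cat(sprintf("  c_N (reference) = %.6g  (1 coalescent unit = %.4g generations)\n",
              x$c_ref, 1 / x$c_ref))
  invisible(x)
}

#' One fixed-size modified Moran generation
#'
#' Draws the multiplier's offspring count U from `law`, chooses the
#' multiplier uniformly among the N parents and U - 1 distinct
#' non-reproducers; all other parents get one offspring. The offspring
#' order is exchangeable (lineage placement uses uniformly random slots).
#'
#' @param N Population size.
#' @param law A `moran_law` or `rarefied_law` for this N.
#' @return A `parent_assignment`: fields `N_parents`, `N_offspring`,
#'   `counts` (offspring per parent), `multiplier`, `U_eff`,
#'   `nonreproducers`.
#' @export
moran_fixed_step <- function(N, law) {
  N <- as.integer(N)
  stopifnot(N >= 2, .law_N(law) == N)
  U <- sample_U(law, 1L)
  multiplier <- sample.int(N, 1L)
  pool <- seq_len(N)[-multiplier]
  others <- pool[sample.int(length(pool), U - 1L)]
  counts <- rep(1L, N)
  counts[multiplier] <- U
  counts[others] <- 0L
  structure(list(N_parents = N, N_offspring = N, counts = counts,
                 multiplier = multiplier, U_eff = as.integer(U),
                 nonreproducers = sort(others)),
            class = "parent_assignment")
}

#' @export
print.parent_assignment <- function(x, ...) {
  cat(sprintf(
    "Parent assignment: %d parents -> %d offspring; multiplier #%d with %d offspring\n",
    x$N_parents, x$N_offspring, x$multiplier, x$U_eff))
  invisible(x)
}

#' Population decline by hypergeometric subsampling
#'
#' Retains a uniform without-replacement subset of `target` of the
#' assignment's offspring: each parent's retained brood is (multivariate)
#' hypergeometric given its offspring count, which preserves all merger
#' functionals exactly (the retained multiplier brood `U_eff` given
#' \eqn{U_{N_r}} is hypergeometric).
#'
#' @param assignment A `parent_assignment`.
#' @param target New offspring count, `2 <= target < N_offspring`.
#' @return The subsampled `parent_assignment` (`U_eff` may degenerate to
#'   0 or 1, in which case no multi-merger is possible that generation).
#' @export
moran_resize_decline <- function(assignment, target) {
  stopifnot(inherits(assignment, "parent_assignment"))
  target <- as.integer(target)
  if (target < 2L) stop("'target' must be >= 2", call. = FALSE)
  if (target > assignment$N_offspring)
    stop("'target' must be < current offspring count", call. = FALSE)
  if (target == assignment$N_offspring) return(assignment)
  counts <- assignment$counts
  kept <- integer(length(counts))
  remaining_total <- sum(counts)
  remaining_keep <- target
  for (i in seq_along(counts)) {
    if (remaining_keep == 0L) break
    ci <- counts[i]
    kept[i] <- stats::rhyper(1L, ci, remaining_total - ci, remaining_keep)
    remaining_total <- remaining_total - ci
    remaining_keep <- remaining_keep - kept[i]
  }
  assignment$counts <- kept
  assignment$N_offspring <- target
  assignment$U_eff <- kept[assignment$multiplier]
  assignment
}

#' Population growth by offspring allocation
#'
#' Adds `d` offspring to the assignment. `A` of them go to the multiplier
#' (so its brood becomes \eqn{U_{N,r} = U_{N_r} + A}); the remaining
#' `d - A` become single offspring of previously non-reproducing parents
#' (each at most once, which requires \eqn{d - A \le U_{N_r} - 1}).
#' The scheme determines A: `"to_multiplier"` sets A = d,
#' `"to_nonreproducers"` sets A = 0, `"proportional"` draws
#' A ~ Binomial(d, \eqn{U_{N_r}/N_r}) and pushes any overflow beyond the
#' available non-reproducer slots to the multiplier. `A` may also be given
#' explicitly.
#'
#' @param assignment A `parent_assignment` (from [moran_fixed_step()]).
#' @param d Number of added individuals, `> 0`.
#' @param scheme Allocation scheme.
#' @param A Optional explicit multiplier share, overriding the scheme.
#' @return The grown `parent_assignment`.
#' @export
moran_resize_growth <- function(assignment, d,
                                scheme = c("proportional", "to_multiplier",
                                           "to_nonreproducers"),
                                A = NULL) {
  stopifnot(inherits(assignment, "parent_assignment"))
  scheme <- match.arg(scheme)
  d <- as.integer(d)
  if (d < 0L) stop("'d' must be >= 0", call. = FALSE)
  if (d == 0L) return(assignment)
  U <- assignment$U_eff
  free_slots <- length(assignment$nonreproducers)
  if (is.null(A)) {
    A <- switch(scheme,
      to_multiplier = d,
      to_nonreproducers = {
        if (d > U - 1L)
          stop(sprintf(paste0(
            "infeasible allocation: d = %d exceeds the U - 1 = %d ",
            "non-reproducer slots (d - A must not exceed the smallest ",
            "possible offspring count minus 1)"), d, U - 1L), call. = FALSE)
        0L
      },
      proportional = {
        a <- stats::rbinom(1L, d, U / assignment$N_parents)
        max(a, d - free_slots)        # overflow forced to the multiplier
      })
  } else {
    A <- as.integer(A)
    if (A > d || d - A > free_slots)
      stop("explicit 'A' incompatible with d and available slots",
           call. = FALSE)
  }
  extra <- d - A
  if (extra > 0L) {
    nr <- assignment$nonreproducers
    who <- nr[sample.int(length(nr), extra)]
    assignment$counts[who] <- 1L
    assignment$nonreproducers <- setdiff(assignment$nonreproducers, who)
  }
  assignment$counts[assignment$multiplier] <-
    assignment$counts[assignment$multiplier] + A
  assignment$U_eff <- assignment$U_eff + as.integer(A)
  assignment$N_offspring <- assignment$N_offspring + d
  assignment
}

#' Follow sample lineages through one generation
#'
#' Given the current partition (blocks of the n sampled leaves), the
#' offspring-slot each block occupies, and a parent assignment, routes each
#' block to its parent and merges blocks with a common parent. Offspring
#' slots are numbered parent-by-parent; exchangeability is realized by the
#' uniformly random slot placement of the lineages themselves.
#'
#' @param blocks List of integer vectors: the current partition blocks.
#' @param assignment A `parent_assignment`.
#' @param placement Integer vector, one offspring slot per block (distinct).
#' @return A list with the coarsened `blocks`, the `parents` each new block
#'   occupies in the parent generation, and `merged` (list of representative
#'   vectors, one entry per merger that happened).
#' @export
ancestry_update <- function(blocks, assignment, placement) {
  stopifnot(inherits(assignment, "parent_assignment"),
            length(blocks) == length(placement))
  if (anyDuplicated(placement))
    stop("internal invariant violation: placement not injective",
         call. = FALSE)
  parent_of_slot <- rep.int(seq_along(assignment$counts), assignment$counts)
  parents <- parent_of_slot[placement]
  merged <- list()
  if (anyDuplicated(parents)) {
    for (p in unique(parents[duplicated(parents)])) {
      idx <- which(parents == p)
      merged <- c(merged, list(vapply(blocks[idx], min, 1L)))
    }
    newblocks <- lapply(split(seq_along(parents), parents),
                        function(i) sort(unlist(blocks[i])))
    newparents <- as.integer(names(newblocks))
    o <- order(vapply(newblocks, min, 1L))
    blocks <- unname(newblocks[o])
    parents <- newparents[o]
  }
  list(blocks = blocks, parents = parents, merged = merged)
}

# per-generation effective-U draw for the simulate loop; returns U_eff
.draw_U_eff <- function(model, law, Nr, Nprev) {
  U <- sample_U(law, 1L)
  d <- Nprev - Nr
  if (d < 0L) {
    stats::rhyper(1L, U, Nr - U, Nprev)
  } else if (d > 0L) {
    A <- switch(model$scheme,
      to_multiplier = d,
      to_nonreproducers = {
        if (d > U - 1L)
          stop(sprintf(paste0("infeasible allocation at size %d: d = %d > ",
                              "U - 1 = %d"), Nr, d, U - 1L), call. = FALSE)
        0L
      },
      proportional = max(stats::rbinom(1L, d, U / Nr), d - (U - 1L)))
    U + A
  } else U
}

#' Simulate the genealogy of an n-sample
#'
#' Runs the model backwards generation by generation until one ancestral
#' block remains (or the horizon is exhausted, in which case the genealogy
#' is flagged open). Only the at most n sample lineages are tracked: by
#' exchangeability each generation's lineages form a uniform subset of the
#' offspring, so the number that fall into the multiplier's brood is
#' hypergeometric and those (if at least two) merge. Across stretches of
#' constant population size the waiting time to the next merger generation
#' is drawn geometrically in one step, which is exact and makes long
#' Kingman-scale horizons cheap.
#'
#' @param model A [moran_model()] or [schweinsberg_model()].
#' @param n Sample size (`n <=` every population size on the horizon).
#' @param ... Passed to methods.
#' @return A [genealogy] with times in generations and the model's
#'   reference `c_ref` attached for conversion to coalescent units.
#' @export
simulate_genealogy <- function(model, n, ...) UseMethod("simulate_genealogy")

#' @rdname simulate_genealogy
#' @param max_generations Safety cap on simulated generations.
#' @export
simulate_genealogy.moran_model <- function(model, n, ...,
                                           max_generations = Inf) {
  n <- as.integer(n)
  traj <- model$trajectory
  if (n > model$N || (traj$kind != "constant" &&
                      n > min(trajectory_sizes(traj, 0:traj$R))))
    stop("sample size exceeds a population size on the horizon",
         call. = FALSE)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  events <- list()
  reps <- seq_len(n)              # representatives of active blocks
  b <- n
  r <- 0L
  constant <- traj$kind == "constant"
  gap_cache <- new.env(parent = emptyenv())
  law0 <- model$law_at(model$N)
  while (b > 1L && r < max_generations) {
    if (constant) {
      gd <- .gap_dist(gap_cache, law0, model$N, b)
      if (gd$p <= 0) break                        # no merger possible
      gap <- floor(log(stats::runif(1L)) / log1p(-gd$p)) + 1
      if (!is.finite(gap) || r + gap > max_generations) {
        r <- max_generations
        break
      }
      r <- r + gap
      u <- gd$support[sample.int(length(gd$support), 1L, prob = gd$cond)]
      K <- .rhyper_trunc2(u, model$N - u, b)
    } else {
      r <- r + 1L
      Nr <- trajectory_sizes(traj, r)
      Nprev <- trajectory_sizes(traj, r - 1L)
      law <- model$law_at(Nr)
      U_eff <- .draw_U_eff(model, law, Nr, Nprev)
      if (U_eff < 2L) next
      K <- stats::rhyper(1L, U_eff, Nprev - U_eff, b)
      if (K < 2L) next
    }
    sel <- sample.int(b, K)
    events[[length(events) + 1L]] <-
      list(time = as.numeric(r), generation = as.numeric(r),
           members = reps[sel])
    reps <- c(reps[-sel], min(reps[sel]))
    b <- b - (K - 1L)
  }
  lab <- sprintf("%s offspring, %s profile, N = %d", model$offspring,
                 model$profile$kind, model$N)
  .new_genealogy(n, events, engine = "moran", unit = "generations",
                 c_ref = model$c_ref, open = b > 1L, model_label = lab)
}

# per-(law, N, b) distribution of the merger generation under constant size:
# p = P(some merger), cond = conditional pmf of U_eff given a merger
.gap_dist <- function(cache, law, N, b) {
  key <- as.character(b)
  if (!is.null(cache[[key]])) return(cache[[key]])
  pe <- .effective_pmf(law)
  u <- pe$support
  lcNb <- lchoose(N, b)
  h0 <- exp(lchoose(N - u, b) - lcNb)
  h1 <- exp(log(u) + lchoose(N - u, b - 1L) - lcNb)
  q <- pmax(0, 1 - h0 - h1)
  p <- sum(pe$pmf * q)
  keep <- q > 0 & pe$pmf > 0
  out <- list(p = p, support = u[keep],
              cond = (pe$pmf[keep] * q[keep]) / p)
  cache[[key]] <- out
  out
}

# hypergeometric K (successes among b draws from u + rest) truncated to K >= 2
.rhyper_trunc2 <- function(u, rest, b) {
  kmax <- min(u, b)
  ks <- 2:kmax
  pk <- stats::dhyper(ks, u, rest, b)
  ks[sample.int(length(ks), 1L, prob = pk)]
}

#' Monte-Carlo pairwise coalescence probability
#'
#' Estimates \eqn{c_{N,r}}: the probability that two uniformly chosen
#' distinct individuals of generation r-1 share a parent in generation r.
#' Each replicate draws one generation of the model and one Bernoulli trial
#' whose success probability, given the realized multiplier brood (or
#' realized parent multiplicities for the heavy-tailed engine), is the
#' exact conditional pairing probability.
#'
#' @param model A [moran_model()] or [schweinsberg_model()].
#' @param r Backward generation index of the parent generation.
#' @param reps Number of Monte-Carlo replicates.
#' @return A list with `estimate`, `se` (binomial), `reps`, and the exact
#'   `N_r`, `N_prev` used.
#' @export
pairwise_coalescence_mc <- function(model, r = 1L, reps = 10000L) {
  UseMethod("pairwise_coalescence_mc")
}

#' @export
pairwise_coalescence_mc.moran_model <- function(model, r = 1L, reps = 10000L) {
  traj <- model$trajectory
  Nr <- trajectory_sizes(traj, r)
  Nprev <- trajectory_sizes(traj, r - 1L)
  law <- model$law_at(Nr)
  U <- sample_U(law, reps)
  d <- Nprev - Nr
  U_eff <- if (d < 0L) {
    stats::rhyper(reps, U, Nr - U, Nprev)
  } else if (d > 0L) {
    A <- switch(model$scheme,
      to_multiplier = rep(d, reps),
      to_nonreproducers = {
        if (any(d > U - 1L))
          stop("infeasible to_nonreproducers allocation", call. = FALSE)
        rep(0L, reps)
      },
      proportional = pmax(stats::rbinom(reps, d, U / Nr), d - (U - 1L)))
    U + A
  } else U
  p <- U_eff * (U_eff - 1) / (Nprev * (Nprev - 1))
  hits <- stats::runif(reps) < p
  est <- mean(hits)
  list(estimate = est, se = sqrt(est * (1 - est) / reps), reps = reps,
       N_r = Nr, N_prev = Nprev)
}
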