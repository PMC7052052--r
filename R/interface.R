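#' Validate a run configuration
#'
#' A run configuration is a plain list (or a path to a JSON file with the
#' same structure) with components:
#' * `family`: `"moran"`, `"schweinsberg"` or `"limit"`;
#' * `measure`: list, e.g. `list(family = "beta", a = 1, b = 1)` or
#'   `list(family = "point_mass", psi = 0.5)` (+ optional
#'   `rate_multiplier`); required for moran (uprime/rarefied) and limit;
#' * `profile`: list, e.g. `list(kind = "exponential", rho = 1)`
#'   (default constant);
#' * `N`, `n`, `seed`; `offspring` + optional `gamma` and `scheme` (moran);
#'   `alpha` (schweinsberg); `gamma` (limit, the time-change exponent);
#'   optional `theta` (mutation overlay) and `horizon_t`.
#'
#' All cross-field constraints are checked before any simulation; a
#' violated constraint is reported by name.
#'
#' @param config A list or a JSON file path.
#' @return The validated config (class `run_config`), with defaults filled.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or JSON path",
                             call. = FALSE)
  req <- function(field, ok, what) {
    if (is.null(config[[field]]) || !ok(config[[field]]))
      stop(sprintf("invalid config: %s (%s)", field, what), call. = FALSE)
  }
  req("family", function(x) x %in% c("moran", "schweinsberg", "limit"),
      "one of moran/schweinsberg/limit")
  req("n", function(x) is.numeric(x) && x >= 1, "sample size >= 1")
  req("seed", function(x) is.numeric(x), "integer seed")
  if (is.null(config$profile)) config$profile <- list(kind = "constant")
  if (is.null(config$theta)) config$theta <- 0
  if (is.null(config$horizon_t)) config$horizon_t <- 10
  fam <- config$family
  if (fam %in% c("moran", "schweinsberg"))
    req("N", function(x) is.numeric(x) && x >= 2, "population size >= 2")
  if (fam == "moran") {
    if (is.null(config$offspring)) config$offspring <- "standard"
    if (config$offspring %in% c("uprime", "rarefied"))
      req("measure", is.list, "Lambda measure spec")
    if (config$offspring == "rarefied")
      req("gamma", function(x) is.numeric(x) && x > 1 && x < 2,
          "gamma in (1,2) for rarefied offspring")
    if (is.null(config$scheme)) config$scheme <- "proportional"
  } else if (fam == "schweinsberg") {
    req("alpha", function(x) is.numeric(x) && x >= 1 && x < 2,
        "alpha in [1,2)")
  } else {
    req("measure", is.list, "Lambda measure spec")
    if (config$profile$kind != "constant")
      req("gamma", function(x) is.numeric(x) && x >= 0,
          "gamma (time-change exponent) required for non-constant profiles")
    if (is.null(config$gamma)) config$gamma <- 0
  }
  class(config) <- c("run_config", "list")
  config
}

.measure_from_spec <- function(spec) {
  do.call(lambda_measure, spec)
}

.profile_from_spec <- function(spec) {
  do.call(size_profile, spec)
}

#' Run a configured simulation and write its artifacts
#'
#' Deterministic given the seed: the same config and seed produce
#' byte-identical Newick and event-table output. Writes
#' `<out_prefix>.nwk` (Newick, coalescent units), `<out_prefix>_events.tsv`
#' (columns `generation`, `coal_time`, `merged_blocks`,
#' `block_count_after`), `<out_prefix>_mutations.tsv` when `theta > 0`, and
#' `<out_prefix>_provenance.json` (config, seed, package version, the
#' effective reference coalescence probability and event count).
#'
#' @param config A [run_config()] (or list/path coercible to one).
#' @param out_prefix Output path prefix; `NULL` runs without writing.
#' @return The simulated [genealogy], invisibly; artifacts on disk.
#' @export
run_simulation <- function(config, out_prefix = NULL) {
  config <- run_config(config)
  set.seed(as.integer(config$seed))
  profile <- .profile_from_spec(config$profile)
  fam <- config$family
  if (fam == "moran") {
    measure <- if (!is.null(config$measure))
      .measure_from_spec(config$measure) else NULL
    model <- moran_model(N = config$N, offspring = config$offspring,
                         measure = measure, gamma = config$gamma,
                         profile = profile, scheme = config$scheme,
                         horizon_t = config$horizon_t)
    g <- simulate_genealogy(model, config$n)
    c_ref <- model$c_ref
  } else if (fam == "schweinsberg") {
    model <- schweinsberg_model(N = config$N, alpha = config$alpha,
                                profile = profile,
                                horizon_t = config$horizon_t)
    g <- simulate_genealogy(model, config$n)
    c_ref <- model$c_ref
  } else {
    measure <- .measure_from_spec(config$measure)
    tc <- if (profile$kind == "constant" && config$gamma == 0) NULL
          else time_change(profile, config$gamma)
    g <- simulate_lambda_coalescent(measure, config$n, tc)
    c_ref <- 1
  }
  muts <- if (config$theta > 0) scatter_mutations(g, config$theta) else NULL
  if (!is.null(out_prefix)) {
    write_newick(g, units = "coalescent",
                 file = paste0(out_prefix, ".nwk"))
    utils::write.table(events_table(g),
                       paste0(out_prefix, "_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(muts))
      utils::write.table(muts, paste0(out_prefix, "_mutations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    prov <- list(config = unclass(config), seed = config$seed,
                 package = "mmcsim",
                 version = as.character(utils::packageVersion("mmcsim")),
                 c_ref = c_ref, n_events = length(g$events),
                 open = g$open)
    jsonlite::write_json(prov, paste0(out_prefix, "_provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(g)
}

#' Tabulate merger rates for a measure
#'
#' Convenience dump of \eqn{\lambda_{b,k}} tables for a range of block
#' counts, as written by the command-line `rates` verb.
#'
#' @param measure A [lambda_measure()].
#' @param b_max Largest block count.
#' @return A `data.frame` with columns `b`, `k`, `rate`, `size_prob`.
#' @export
rates_table <- function(measure, b_max = 10L) {
  rows <- lapply(2:b_max, function(b) {
    tab <- merger_rate_table(measure, b)
    data.frame(b = b, k = tab$k, rate = tab$rates, size_prob = tab$size_probs)
  })
  do.call(rbind, rows)
}
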