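#' @title Genealogy objects
#' @description Both discrete engines and the limit-coalescent simulator
#'   return a `genealogy`: the sample size n, the ordered list of merger
#'   events (each with its time, the representatives of the blocks merged,
#'   and the block count afterwards), and derived quantities (TMRCA, total
#'   branch length, Newick text). Discrete genealogies carry times in
#'   generations together with the reference scaling `c_ref` (= pairwise
#'   coalescence probability at the reference size), so that
#'   `generation * c_ref` is coalescent time; limit genealogies are in
#'   coalescent units natively. Blocks are labelled by their smallest leaf.
#' @name genealogy
NULL

# events: list of list(time, generation, members); `members` is the integer
# vector of the merged blocks' representatives (smallest leaf per block)
.new_genealogy <- function(n, events, engine, unit, c_ref = NA_real_,
                           open = FALSE, model_label = "") {
  asm <- .assemble_tree(n, events, open)
  structure(list(n = n, engine = engine, unit = unit, c_ref = c_ref,
                 events = events, open = open,
                 newick = asm$newick, tmrca = asm$tmrca,
                 total_length = asm$total_length, branches = asm$branches,
                 first_merger_size = if (length(events))
                   length(events[[1]]$members) else NA_integer_,
                 model_label = model_label),
            class = "genealogy")
}

# Replays merger events into Newick text, branch table and totals.
# Branch lengths are in the genealogy's native unit.
.assemble_tree <- function(n, events, open) {
  rep_id <- seq_len(n)
  height <- numeric(n)
  nwk <- as.character(seq_len(n))
  alive <- rep(TRUE, n)
  idx_of <- seq_len(n)           # representative -> slot
  branches <- vector("list", length(events) + 1L)
  bi <- 0L
  for (ev in events) {
    slots <- idx_of[ev$members]
    slots <- slots[!is.na(slots) & alive[slots]]
    reps <- rep_id[slots]
    lens <- ev$time - height[slots]
    bi <- bi + 1L
    branches[[bi]] <- data.frame(block = reps, start = height[slots],
                                 end = ev$time)
    piece <- paste0("(", paste0(nwk[slots], ":", format(lens, digits = 12,
                                                        trim = TRUE),
                                collapse = ","), ")")
    keep <- slots[1]
    newrep <- min(reps)
    rep_id[keep] <- newrep
    height[keep] <- ev$time
    nwk[keep] <- piece
    drop <- slots[-1]
    alive[drop] <- FALSE
    idx_of[reps] <- keep
  }
  roots <- which(alive)
  tm <- if (length(events)) events[[length(events)]]$time else 0
  br <- do.call(rbind, branches[seq_len(bi)])
  total <- if (is.null(br)) 0 else sum(br$end - br$start)
  if (n == 1L && !length(events)) {
    newick <- "1:0.0;"
  } else if (!open && length(roots) == 1L) {
    newick <- paste0(nwk[roots], ";")
  } else {
    # open genealogy: forest of the surviving blocks, padded to the horizon
    newick <- paste0(vapply(roots, function(s) paste0(nwk[s], ";"), ""),
                     collapse = "\n")
  }
  list(newick = newick, tmrca = if (open) NA_real_ else tm,
       total_length = total,
       branches = if (is.null(br)) data.frame(block = integer(),
                                              start = numeric(),
                                              end = numeric()) else br)
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("%s genealogy of n = %d (%s)\n",
              switch(x$engine, moran = "Modified-Moran",
                     schweinsberg = "Heavy-tailed Cannings",
                     limit = "Lambda-coalescent"),
              x$n, x$model_label))
  if (x$open) {
    cat("  open genealogy: MRCA not reached within the horizon\n")
  } else {
    cat(sprintf("  %d merger events, TMRCA %.4g %s, total length %.4g\n",
                length(x$events), x$tmrca, x$unit, x$total_length))
  }
  invisible(x)
}

#' @export
summary.genealogy <- function(object, ...) {
  sizes <- vapply(object$events, function(e) length(e$members), 1L)
  out <- list(n = object$n, engine = object$engine, unit = object$unit,
              n_events = length(object$events), merger_sizes = sizes,
              tmrca = object$tmrca, total_length = object$total_length,
              open = object$open, c_ref = object$c_ref)
  class(out) <- "summary.genealogy"
  out
}

#' @export
print.summary.genealogy <- function(x, ...) {
  cat(sprintf("Genealogy summary (n = %d, %s engine)\n", x$n, x$engine))
  cat(sprintf("  events: %d; merger sizes: %s\n", x$n_events,
              paste(x$merger_sizes, collapse = ", ")))
  cat(sprintf("  TMRCA: %.5g %s; total branch length: %.5g\n",
              x$tmrca, x$unit, x$total_length))
  invisible(x)
}

#' Event table of a genealogy
#'
#' One row per merger event: backward generation index (NA for limit
#' genealogies), coalescent time, the representatives (smallest leaves) of
#' the merged blocks, and the block count after the event.
#'
#' @param genealogy A `genealogy`.
#' @return A `data.frame` with columns `generation`, `coal_time`,
#'   `merged_blocks`, `block_count_after`.
#' @export
events_table <- function(genealogy) {
  stopifnot(inherits(genealogy, "genealogy"))
  evs <- genealogy$events
  bc <- genealogy$n
  rows <- lapply(evs, function(e) {
    k <- length(e$members)
    bc <<- bc - (k - 1L)
    data.frame(
      generation = if (is.null(e$generation)) NA_integer_ else e$generation,
      coal_time = if (genealogy$unit == "generations")
        e$time * genealogy$c_ref else e$time,
      merged_blocks = paste(sort(e$members), collapse = ","),
      block_count_after = bc)
  })
  if (!length(rows))
    return(data.frame(generation = integer(), coal_time = numeric(),
                      merged_blocks = character(),
                      block_count_after = integer()))
  do.call(rbind, rows)
}

#' Write a genealogy as Newick text
#'
#' Multifurcations are written natively (no artificial binary resolution).
#' Discrete genealogies can be written in generations or converted to
#' coalescent units via their reference scaling `c_ref`. Open genealogies
#' (MRCA not reached) are exported as a forest, one tree per line, with a
#' warning, unless `allow_forest = FALSE`.
#'
#' @param genealogy A `genealogy`.
#' @param units `"coalescent"` or `"generations"` (the latter only for
#'   discrete genealogies).
#' @param file Optional path; when `NULL` the text is returned.
#' @param allow_forest Permit forest export of open genealogies.
#' @return Newick text, invisibly when written to `file`.
#' @examples
#' tr <- simulate_lambda_coalescent(lambda_measure("beta", a = 1, b = 1), n = 5)
#' write_newick(tr)
#' @export
write_newick <- function(genealogy, units = c("coalescent", "generations"),
                         file = NULL, allow_forest = TRUE) {
  stopifnot(inherits(genealogy, "genealogy"))
  units <- match.arg(units)
  if (genealogy$open) {
    if (!allow_forest)
      stop("open genealogy: MRCA not reached and forest export disabled",
           call. = FALSE)
    warning("open genealogy exported as a forest", call. = FALSE)
  }
  txt <- genealogy$newick
  if (genealogy$unit == "generations" && units == "coalescent") {
    scaled <- .rescale_events(genealogy, genealogy$c_ref)
    txt <- scaled$newick
  } else if (genealogy$unit == "coalescent" && units == "generations") {
    stop("limit genealogies have no generation scale", call. = FALSE)
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

.rescale_events <- function(genealogy, factor) {
  evs <- lapply(genealogy$events, function(e) {
    e$time <- e$time * factor
    e
  })
  .assemble_tree(genealogy$n, evs, genealogy$open)
}

#' Convert a genealogy to an ape "phylo" tree
#'
#' Parses the genealogy's Newick text with \pkg{ape}; requires a completed
#' genealogy (single root).
#'
#' @inheritParams write_newick
#' @return An object of class `phylo`.
#' @export
as_phylo <- function(genealogy, units = c("coalescent", "generations")) {
  stopifnot(inherits(genealogy, "genealogy"))
  if (genealogy$open)
    stop("open genealogy cannot be converted to a single tree", call. = FALSE)
  if (genealogy$n < 2L)
    stop("ape requires at least 2 leaves", call. = FALSE)
  ape::read.tree(text = write_newick(genealogy, units))
}

#' Overlay neutral mutations on a genealogy
#'
#' For limit genealogies, mutations fall as a Poisson point process with
#' intensity `theta` per unit branch length: the total count is
#' Poisson(`theta * L`) with L the total branch length, positions uniform
#' on the branch-length measure. For discrete genealogies the counterpart
#' is a per-generation mutation probability `mu_N = theta * c_ref` on every
#' lineage (so the expected count per coalescent unit matches `theta`),
#' realized as Binomial(branch generations, `mu_N`) per branch.
#'
#' @param genealogy A `genealogy`.
#' @param theta Nonnegative mutation intensity on the coalescent scale.
#' @return A `data.frame` with columns `block` (the branch's block
#'   representative) and `time` (native units), one row per mutation.
#' @export
scatter_mutations <- function(genealogy, theta) {
  stopifnot(inherits(genealogy, "genealogy"), theta >= 0)
  br <- genealogy$branches
  if (theta == 0 || nrow(br) == 0L)
    return(data.frame(block = integer(), time = numeric()))
  len <- br$end - br$start
  if (genealogy$unit == "coalescent") {
    total <- stats::rpois(1L, theta * sum(len))
    if (total == 0L) return(data.frame(block = integer(), time = numeric()))
    which_br <- sample.int(nrow(br), total, replace = TRUE, prob = len)
    data.frame(block = br$block[which_br],
               time = br$start[which_br] + stats::runif(total) * len[which_br])
  } else {
    mu <- theta * genealogy$c_ref
    counts <- stats::rbinom(nrow(br), pmax(0L, as.integer(len)), mu)
    idx <- rep.int(seq_len(nrow(br)), counts)
    if (!length(idx)) return(data.frame(block = integer(), time = numeric()))
    gens <- unlist(lapply(seq_len(nrow(br)), function(i) {
      if (counts[i] == 0L) return(integer())
      br$start[i] + sample.int(as.integer(len[i]), counts[i])
    }))
    data.frame(block = br$block[idx], time = gens)
  }
}
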