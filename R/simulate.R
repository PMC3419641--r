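# Stochastic simulation: single-cell trajectories, cell-population summaries,
# outcome classification and propensity sweeps.
#
# Reproducibility contract: every sampled trajectory is driven by R's RNG
# seeded per cell with a seed derived deterministically from the master seed
# and the cell index (an affine counter scheme modulo 2^31 - 1).  Populations
# are therefore reproducible bit-exactly and cells are independent of the
# order in which they are run.  The caller's RNG state is left untouched.

cell_seed <- function(master_seed, cell_index) {
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(cell_index) * 10007) %%
               2147483647)
}

with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  force(code)
}

# inner sampling loop over ranks; assumes RNG already seeded
sample_trajectory_ranks <- function(model, x, steps) {
  n <- model$n
  pv <- state_place_values(model$cardinalities)
  pup <- model$propensities[, "up"]
  pdown <- model$propensities[, "down"]
  tab <- model$table
  r <- as.integer(sum(x * pv) + 1)
  ranks <- integer(steps + 1L)
  ranks[1L] <- r
  for (t in seq_len(steps)) {
    fx <- tab[r, ]
    d <- fx != x
    if (any(d)) {
      p <- numeric(n)
      up <- fx > x
      p[up] <- pup[up]
      p[!up] <- pdown[!up]
      mv <- d & (stats::runif(n) < p)
      if (any(mv)) {
        x[mv] <- fx[mv]
        r <- as.integer(sum(x * pv) + 1)
      }
    }
    ranks[t + 1L] <- r
  }
  ranks
}

#' Draw one stochastic update step
#'
#' Each coordinate is updated independently: coordinate `i` moves to its rule
#' target `f_i(x)` with the activation propensity (if the target is larger)
#' or the degradation propensity (if smaller), and otherwise keeps its value.
#' The induced successor distribution equals [transition_distribution()].
#' Coordinates are sampled in ascending index order for reproducibility; the
#' order does not affect the distribution.
#'
#' @param model an `sdds_model`.
#' @param x current state (levels vector or state string).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (and advanced).
#' @return the successor state as an integer levels vector.
#' @export
sample_step <- function(model, x, seed = NULL) {
  x <- as_state_matrix(model, x)[1L, ]
  draw <- function() {
    r <- sample_trajectory_ranks(model, x, 1L)[2L]
    model$states[r, ]
  }
  if (is.null(seed)) draw()
  else with_preserved_rng({ set.seed(seed); draw() })
}

#' Simulate a single cell
#'
#' Repeated application of [sample_step()] for `steps` time steps.  The same
#' `(model, init, steps, seed)` always yields the same trajectory.
#'
#' @param model an `sdds_model`.
#' @param init initial state (string or levels vector).
#' @param steps number of time steps (>= 0).
#' @param seed integer seed for the trajectory.
#' @return an object of class `sdds_trajectory`: list with `states`
#'   (character vector of length `steps + 1`), `levels` (integer matrix,
#'   one row per time point), `ranks`, `steps` and `seed`.
#' @examples
#' p53 <- load_fixture("p53_mdm2")
#' tr <- simulate_cell(p53, "0011", steps = 60, seed = 1)
#' head(as.data.frame(tr))
#' @export
simulate_cell <- function(model, init, steps, seed) {
  if (steps < 0) sdds_stop("sdds_validation_error", "steps must be >= 0")
  x <- as_state_matrix(model, init)[1L, ]
  ranks <- with_preserved_rng({
    set.seed(seed)
    sample_trajectory_ranks(model, x, steps)
  })
  structure(list(states = state_labels(model)[ranks],
                 levels = model$states[ranks, , drop = FALSE],
                 ranks = ranks, steps = steps, seed = seed,
                 variable_names = model$variables$name),
            class = "sdds_trajectory")
}

#' @export
as.data.frame.sdds_trajectory <- function(x, ...) {
  d <- data.frame(step = seq_along(x$states) - 1L, x$levels)
  names(d) <- c("step", x$variable_names)
  d
}

#' @export
print.sdds_trajectory <- function(x, ...) {
  cat(sprintf("SDDS trajectory: %d steps, seed %d\n", x$steps, x$seed))
  cat("  ", paste(utils::head(x$states, 15L), collapse = " "),
      if (length(x$states) > 15L) "..." else "", "\n")
  invisible(x)
}

#' Simulate a cell population
#'
#' Runs `n_cells` independent single-cell trajectories (cell `i` is seeded
#' with a counter-derived seed from the master seed, so runs are reproducible
#' bit-exactly and order-independent) and aggregates, per time step: the
#' per-variable mean and standard deviation across cells and, for enumerable
#' spaces, the full per-state occupancy counts.
#'
#' @param model an `sdds_model`.
#' @param init initial state shared by every cell.
#' @param n_cells number of cells (>= 1).
#' @param steps time steps per cell.
#' @param seed master seed.
#' @return an object of class `sdds_population`: list with `mean` and `sd`
#'   (`(steps + 1) x n` matrices), `state_counts` (`(steps + 1) x
#'   total_states` integer matrix of per-step occupancies), `final_states`
#'   (character vector of length `n_cells`), `n_cells`, `steps`, `seed`.
#' @examples
#' p53 <- load_fixture("p53_mdm2")
#' pop <- simulate_population(p53, "0011", n_cells = 100, steps = 60, seed = 1)
#' pop$mean[1:5, ]
#' @export
simulate_population <- function(model, init, n_cells, steps, seed) {
  if (n_cells < 1) sdds_stop("sdds_validation_error", "n_cells must be >= 1")
  x0 <- as_state_matrix(model, init)[1L, ]
  total <- model$total_states
  counts <- matrix(0L, nrow = steps + 1L, ncol = total)
  final <- integer(n_cells)
  with_preserved_rng({
    for (i in seq_len(n_cells)) {
      set.seed(cell_seed(seed, i))
      ranks <- sample_trajectory_ranks(model, x0, steps)
      idx <- (ranks - 1L) * (steps + 1L) + seq_len(steps + 1L)
      counts[idx] <- counts[idx] + 1L
      final[i] <- ranks[steps + 1L]
    }
  })
  freq <- counts / n_cells
  mean_levels <- freq %*% model$states
  second_moment <- freq %*% (model$states^2)
  sd_levels <- sqrt(pmax(second_moment - mean_levels^2, 0))
  dimnames(mean_levels) <- dimnames(sd_levels) <-
    list(NULL, model$variables$name)
  colnames(counts) <- state_labels(model)
  structure(list(mean = mean_levels, sd = sd_levels, state_counts = counts,
                 final_states = state_labels(model)[final],
                 n_cells = n_cells, steps = steps, seed = seed,
                 variable_names = model$variables$name),
            class = "sdds_population")
}

#' @export
print.sdds_population <- function(x, ...) {
  cat(sprintf("SDDS population: %d cells, %d steps, seed %d\n",
              x$n_cells, x$steps, x$seed))
  invisible(x)
}

#' @export
as.data.frame.sdds_population <- function(x, ...) {
  d <- data.frame(step = seq_len(nrow(x$mean)) - 1L, x$mean, x$sd)
  names(d) <- c("step", paste0("mean_", x$variable_names),
                paste0("sd_", x$variable_names))
  d
}

#' Plot population mean traces
#'
#' One line per variable: the across-cell mean expression level against time.
#'
#' @param x an `sdds_population`.
#' @param vars variables to draw (names); default all.
#' @param ... further arguments passed to [graphics::matplot()].
#' @export
plot.sdds_population <- function(x, vars = x$variable_names, ...) {
  j <- match(vars, x$variable_names)
  graphics::matplot(seq_len(nrow(x$mean)) - 1L, x$mean[, j, drop = FALSE],
                    type = "l", lty = 1, xlab = "time step",
                    ylab = "mean expression level", ...)
  graphics::legend("topright", legend = vars, lty = 1,
                   col = seq_along(j), bty = "n")
  invisible(x)
}

#' Classify trajectory outcomes by attractor
#'
#' Labels each cell by the labelled attractor containing its final state;
#' cells whose final state is in no labelled set are counted as unresolved.
#'
#' @param x an `sdds_population`, or a character vector of final states.
#' @param labels named list of state-string vectors, one entry per outcome
#'   (e.g. `list(lysogeny = "2000", lysis = c("0200", "0300"))`).  Labels
#'   must not overlap.
#' @return an object of class `sdds_tally`: data frame with `outcome`,
#'   `count` and `fraction` (fractions over all cells, including an
#'   `unresolved` row).
#' @export
classify_outcomes <- function(x, labels) {
  final <- if (inherits(x, "sdds_population")) x$final_states else as.character(x)
  all_labelled <- unlist(labels, use.names = FALSE)
  if (anyDuplicated(all_labelled))
    sdds_stop("sdds_validation_error",
              "attractor labels overlap: state %s appears in more than one outcome",
              all_labelled[duplicated(all_labelled)][1L])
  n <- length(final)
  counts <- vapply(labels, function(s) sum(final %in% s), integer(1))
  counts <- c(counts, unresolved = n - sum(counts))
  out <- data.frame(outcome = names(counts), count = as.integer(counts),
                    fraction = as.numeric(counts) / n,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("sdds_tally", "data.frame")
  attr(out, "n_cells") <- n
  out
}

#' Sweep symmetric propensities of an antagonistic variable pair
#'
#' For each grid value `a`, sets the activation propensity of `var_a` and the
#' degradation propensity of `var_b` to `a`, and the degradation propensity
#' of `var_a` and activation propensity of `var_b` to `1 - a` (the symmetric
#' design used to probe a bistable switch), runs a population simulation and
#' tallies outcomes.
#'
#' @param model an `sdds_model`.
#' @param init initial state.
#' @param n_cells cells per grid point.
#' @param steps time steps per cell.
#' @param a numeric vector of grid values in `[0, 1]`.
#' @param var_a,var_b the antagonistic pair (e.g. `"CI"`, `"CRO"`).
#' @param labels outcome labels as in [classify_outcomes()].
#' @param seed master seed; each grid point derives its own sub-seed.
#' @return data frame with one row per grid value: `a`, a count column per
#'   outcome (`n_<outcome>`), `n_unresolved` and the matching fractions.
#' @export
propensity_sweep <- function(model, init, n_cells, steps, a,
                             var_a, var_b, labels, seed) {
  rows <- lapply(seq_along(a), function(j) {
    av <- a[j]
    m <- set_propensity(model, var_a, up = av, down = 1 - av)
    m <- set_propensity(m, var_b, up = 1 - av, down = av)
    pop <- simulate_population(m, init, n_cells, steps,
                               seed = cell_seed(seed, 1000003 * j))
    tl <- classify_outcomes(pop, labels)
    stats <- c(setNames(tl$count, paste0("n_", tl$outcome)),
               setNames(tl$fraction, paste0("fraction_", tl$outcome)))
    c(a = av, stats)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out
}
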