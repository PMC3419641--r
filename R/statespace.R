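# State-space analysis: the full weighted transition digraph, fixed points,
# attractors (terminal strongly connected components), exact distribution
# propagation and deterministic reference trajectories.

#' Build the full weighted state-transition graph
#'
#' Enumerates `transition_distribution()` for every state of the space and
#' collects the positive-weight edges.  The dynamics of the system is exactly
#' this weighted digraph: nodes are the states of X, and `x -> y` carries the
#' product of coordinate propensities.
#'
#' @param model an `sdds_model`.
#' @param max_states refuse to enumerate spaces larger than this (default
#'   `1e6`); for larger models use the sampling workflow
#'   ([simulate_population()]).
#' @return an object of class `sdds_graph`: list with `model`, `n_nodes`,
#'   `edges` (data frame with `source`, `target` state strings, `from`, `to`
#'   ranks and `weight`).
#' @export
build_state_graph <- function(model, max_states = 1e6) {
  if (model$total_states > max_states)
    sdds_stop("sdds_validation_error",
              "state space has %d states (cap %g); use the simulation workflow instead",
              model$total_states, max_states)
  parts <- lapply(seq_len(model$total_states), function(r) {
    td <- transition_distribution(model, model$states[r, ])
    data.frame(from = r, to = td$ranks, weight = td$prob)
  })
  edges <- do.call(rbind, parts)
  labels <- state_labels(model)
  edges <- data.frame(source = labels[edges$from], target = labels[edges$to],
                      from = edges$from, to = edges$to, weight = edges$weight,
                      stringsAsFactors = FALSE)
  structure(list(model = model, n_nodes = model$total_states, edges = edges),
            class = "sdds_graph")
}

#' @export
print.sdds_graph <- function(x, ...) {
  cat(sprintf("SDDS state graph: %d nodes, %d positive-weight edges\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Sparse one-step transition matrix
#'
#' Row-stochastic matrix indexed by lexicographic state rank (variable 1 most
#' significant).
#'
#' @param model an `sdds_model`.
#' @param max_states cap on the enumerable space, as in [build_state_graph()].
#' @return a `dgCMatrix` of dimension `total_states x total_states`.
#' @export
transition_matrix <- function(model, max_states = 1e6) {
  g <- build_state_graph(model, max_states)
  Matrix::sparseMatrix(i = g$edges$from, j = g$edges$to, x = g$edges$weight,
                       dims = c(model$total_states, model$total_states))
}

#' Fixed points (steady states)
#'
#' A state is a fixed point when the deterministic map leaves it unchanged,
#' `G(x) = x`; these are exactly the absorbing states of the stochastic
#' system, for any propensity values.
#'
#' @param model an `sdds_model`.
#' @return character vector of fixed-point state strings; the level matrix is
#'   attached as attribute `states`.
#' @export
fixed_points <- function(model) {
  idx <- which(rowSums(model$table != model$states) == 0)
  out <- state_labels(model)[idx]
  attr(out, "states") <- model$states[idx, , drop = FALSE]
  out
}

#' Attractors of the stochastic system
#'
#' Attractors are the terminal strongly connected components of the
#' positive-weight transition digraph -- the recurrent classes of the Markov
#' chain.  Singleton components are reported as fixed points, larger ones as
#' cycles.
#'
#' @param graph an `sdds_graph` from [build_state_graph()], or an
#'   `sdds_model` (the graph is then built internally).
#' @return an object of class `sdds_attractors`: list with `fixed_points`
#'   (character vector) and `cycles` (list of character vectors).
#' @export
attractors <- function(graph) {
  if (inherits(graph, "sdds_model")) graph <- build_state_graph(graph)
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = seq_len(graph$n_nodes)))
  comp <- igraph::components(g, mode = "strong")
  member <- comp$membership
  # a component is terminal iff no positive-weight edge leaves it
  leaving <- member[graph$edges$from] != member[graph$edges$to]
  open_comps <- unique(member[graph$edges$from[leaving]])
  terminal <- setdiff(seq_len(comp$no), open_comps)
  labels <- state_labels(graph$model)
  fps <- character(0)
  cycles <- list()
  for (cid in terminal) {
    states <- labels[which(member == cid)]
    if (length(states) == 1L) fps <- c(fps, states)
    else cycles[[length(cycles) + 1L]] <- sort(states)
  }
  structure(list(fixed_points = sort(fps), cycles = cycles),
            class = "sdds_attractors")
}

#' @export
print.sdds_attractors <- function(x, ...) {
  cat("Attractors:\n")
  for (s in x$fixed_points) cat(sprintf("  fixed point %s\n", s))
  for (cy in x$cycles)
    cat(sprintf("  terminal component {%s}\n", paste(cy, collapse = ", ")))
  if (length(x$fixed_points) + length(x$cycles) == 0L) cat("  none\n")
  invisible(x)
}

#' Propagate an exact state distribution
#'
#' Iterates the transition kernel `steps` times starting from a point mass or
#' an arbitrary initial distribution.  This is the exact counterpart of the
#' Monte-Carlo population averages: the expected level of each variable at
#' any time is computable from the returned vector.
#'
#' @param model an `sdds_model`.
#' @param init a state (string or levels vector) for a point mass, or a
#'   numeric vector of length `total_states` summing to 1 (indexed by state
#'   rank).
#' @param steps number of steps (>= 0).
#' @return numeric vector of length `total_states`, named by state strings.
#' @export
exact_distribution <- function(model, init, steps) {
  if (is.numeric(init) && length(init) == model$total_states && model$n != model$total_states) {
    v <- as.numeric(init)
    if (abs(sum(v) - 1) > 1e-9 || any(v < 0))
      sdds_stop("sdds_validation_error", "init must be a probability vector summing to 1")
  } else {
    v <- numeric(model$total_states)
    v[state_rank(model, init)] <- 1
  }
  P <- transition_matrix(model)
  for (t in seq_len(steps)) v <- as.numeric(v %*% P)
  names(v) <- state_labels(model)
  v
}

#' Expected variable levels under a state distribution
#'
#' @param model an `sdds_model`.
#' @param dist numeric vector over state ranks (e.g. from
#'   [exact_distribution()]).
#' @return named numeric vector of per-variable expected levels.
#' @export
expected_levels <- function(model, dist) {
  setNames(as.numeric(dist %*% model$states), model$variables$name)
}

#' Deterministic reference trajectories
#'
#' Iterates the deterministic system under the classical update schemes: the
#' synchronous scheme applies `G` to all coordinates at once; the
#' asynchronous scheme updates one variable at a time in a fixed order within
#' each step, each update seeing the partially updated state.  Whenever all
#' propensities are positive, every consecutive pair of the synchronous
#' trajectory is a positive-weight edge of the stochastic graph.
#'
#' @param model an `sdds_model`.
#' @param init initial state (string or levels vector).
#' @param steps number of steps.
#' @param scheme `"synchronous"` or `"asynchronous"`.
#' @param order for the asynchronous scheme, a permutation of `1..n` giving
#'   the within-step update order (default ascending).
#' @return character vector of `steps + 1` state strings.
#' @export
deterministic_trajectory <- function(model, init, steps,
                                     scheme = c("synchronous", "asynchronous"),
                                     order = seq_len(model$n)) {
  scheme <- match.arg(scheme)
  x <- as_state_matrix(model, init)[1L, ]
  out <- character(steps + 1L)
  out[1L] <- state_to_string(model, x)
  if (scheme == "asynchronous" &&
      !identical(sort(as.integer(order)), seq_len(model$n)))
    sdds_stop("sdds_validation_error", "order must be a permutation of 1..n")
  for (t in seq_len(steps)) {
    if (scheme == "synchronous") {
      x <- model$table[state_rank(model, x), ]
    } else {
      for (i in order) x[i] <- model$table[state_rank(model, x), i]
    }
    out[t + 1L] <- state_to_string(model, x)
  }
  out
}

# ---------------------------------------------------------------------------
# Exports

#' Export the state graph
#'
#' `export_graph_dot()` writes GraphViz DOT with edge weights as labels (6
#' significant digits); self-loops are omitted from the drawing by default,
#' matching the usual state-space figures, but are always present in the
#' edge-list CSV written by `export_graph_csv()`.
#'
#' @param graph an `sdds_graph`.
#' @param path output file path.
#' @param self_loops include self-loops in the DOT rendering.
#' @return the path, invisibly.
#' @export
export_graph_dot <- function(graph, path, self_loops = FALSE) {
  e <- graph$edges
  if (!self_loops) e <- e[e$from != e$to, , drop = FALSE]
  lines <- c("digraph sdds {",
             "  node [shape=box];",
             sprintf("  \"%s\" -> \"%s\" [label=\"%.6g\"];",
                     e$source, e$target, e$weight),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname export_graph_dot
#' @export
export_graph_csv <- function(graph, path) {
  utils::write.csv(
    data.frame(source_state = graph$edges$source,
               target_state = graph$edges$target,
               weight = graph$edges$weight),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a state distribution as CSV
#'
#' @param model an `sdds_model`.
#' @param dist numeric vector over state ranks.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_distribution_csv <- function(model, dist, path) {
  utils::write.csv(data.frame(state = state_labels(model),
                              probability = as.numeric(dist)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
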