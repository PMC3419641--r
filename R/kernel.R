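# Transition kernel: coordinate propensity terms, edge weights and the
# per-state successor distribution of the SDDS Markov chain.

#' Coordinate propensity term
#'
#' For a state `x` the i-th coordinate can move only to its rule target
#' `f_i(x)` or stay at `x_i`.  If the rule calls for an increase
#' (`x_i < f_i(x)`) the move happens with the activation propensity
#' `p_i_up`, if for a decrease with the degradation propensity `p_i_down`,
#' and the complementary probability is assigned to staying.  When
#' `f_i(x) = x_i` the coordinate keeps its value with probability 1.  Any
#' other target level has probability 0.
#'
#' @param model an `sdds_model`.
#' @param x a state (levels vector or state string).
#' @param i variable index in `1..n`.
#' @param target_level the candidate next level of variable `i`.
#' @return the probability of coordinate `i` moving from `x[i]` to
#'   `target_level` in one step.
#' @export
coordinate_propensity <- function(model, x, i, target_level) {
  if (length(i) != 1L || is.na(i) || i < 1L || i > model$n)
    sdds_stop("sdds_validation_error", "variable index %s out of range 1..%d",
              format(i), model$n)
  x <- as_state_matrix(model, x)[1L, ]
  fx <- model$table[state_rank(model, x), i]
  xi <- x[i]
  if (!(target_level %in% c(xi, fx))) return(0)
  if (fx == xi) return(1)
  p_move <- if (xi < fx) model$propensities[i, "up"] else model$propensities[i, "down"]
  if (target_level == fx) p_move else 1 - p_move
}

# per-coordinate move probabilities toward fx (NA where fx == x)
move_probabilities <- function(model, x, fx) {
  p <- rep(NA_real_, model$n)
  up <- fx > x
  down <- fx < x
  p[up] <- model$propensities[up, "up"]
  p[down] <- model$propensities[down, "down"]
  p
}

#' One-step transition weight between two states
#'
#' The weight of the edge `x -> y` is the product over all coordinates of the
#' coordinate propensity terms; it is zero unless every `y[i]` lies in
#' `{x[i], f_i(x)}`.  Factors are multiplied in ascending coordinate order.
#'
#' @param model an `sdds_model`.
#' @param x,y states (levels vectors or state strings).
#' @return the transition probability from `x` to `y`.
#' @export
transition_weight <- function(model, x, y) {
  x <- as_state_matrix(model, x)[1L, ]
  y <- as_state_matrix(model, y)[1L, ]
  fx <- model$table[state_rank(model, x), ]
  if (any(y != x & y != fx)) return(0)
  w <- 1
  for (i in seq_len(model$n)) {
    if (fx[i] == x[i]) next  # factor 1
    p_move <- if (x[i] < fx[i]) model$propensities[i, "up"]
              else model$propensities[i, "down"]
    f <- if (y[i] == fx[i]) p_move else 1 - p_move
    if (f == 0) return(0)
    w <- w * f
  }
  w
}

#' Exact successor distribution of one state
#'
#' Enumerates the at most `2^k` candidate successors (`k` = number of
#' coordinates whose rule target differs from the current level), weighting
#' each by the product of coordinate propensities.  Zero-weight successors
#' are pruned exactly (a propensity of 0 or 1 removes branches before any
#' multiplication), so the support carries only positive probabilities, which
#' sum to 1.
#'
#' @param model an `sdds_model`.
#' @param x a state (levels vector or state string).
#' @return an object of class `sdds_transition`: a list with `source` (state
#'   string), `states` (character vector of successor state strings),
#'   `ranks` (their lexicographic ranks) and `prob` (their probabilities).
#' @examples
#' m <- load_fixture("example_2_1_1")
#' transition_distribution(m, "01")
#' @export
transition_distribution <- function(model, x) {
  x <- as_state_matrix(model, x)[1L, ]
  fx <- model$table[state_rank(model, x), ]
  changed <- which(fx != x)
  k <- length(changed)
  if (k == 0L) {
    out <- list(source = state_to_string(model, x),
                states = state_to_string(model, x),
                ranks = state_rank(model, x),
                prob = 1)
    return(structure(out, class = "sdds_transition"))
  }
  p_move <- move_probabilities(model, x, fx)[changed]
  # per changed coordinate: candidate levels and probabilities, zero pruned
  opts <- vector("list", k)
  for (j in seq_len(k)) {
    i <- changed[j]
    lev <- c(x[i], fx[i])
    pr <- c(1 - p_move[j], p_move[j])
    keep <- pr > 0
    opts[[j]] <- list(lev = lev[keep], pr = pr[keep])
  }
  combos_lev <- expand.grid(lapply(opts, `[[`, "lev"), KEEP.OUT.ATTRS = FALSE)
  combos_pr <- as.matrix(expand.grid(lapply(opts, `[[`, "pr"),
                                     KEEP.OUT.ATTRS = FALSE))
  dimnames(combos_pr) <- NULL
  m <- nrow(combos_lev)
  succ <- matrix(rep(x, each = m), nrow = m)
  succ[, changed] <- as.matrix(combos_lev)
  # multiply factors coordinate by coordinate (same rounding sequence as
  # transition_weight, so both routes agree bit for bit)
  prob <- rep(1, m)
  for (j in seq_len(k)) prob <- prob * combos_pr[, j]
  structure(list(source = state_to_string(model, x),
                 states = state_to_string(model, succ),
                 ranks = state_rank(model, succ),
                 prob = prob),
            class = "sdds_transition")
}

#' @export
print.sdds_transition <- function(x, ...) {
  cat(sprintf("Transition distribution from %s:\n", x$source))
  ord <- order(-x$prob)
  for (j in ord)
    cat(sprintf("  -> %s  %.6g\n", x$states[j], x$prob[j]))
  invisible(x)
}

#' @export
as.data.frame.sdds_transition <- function(x, ...) {
  data.frame(source = x$source, target = x$states, weight = x$prob,
             stringsAsFactors = FALSE)
}
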