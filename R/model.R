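# Model core: multi-valued state spaces, states, update rules, propensities.
#
# A model is stored in fully expanded form: one truth-table column per
# variable over the whole state space, enumerated in lexicographic order
# with variable 1 most significant.  All target models are tiny (<= 48
# states), so the expanded representation is the canonical one and
# expression rules are a convenience layer resolved at construction time.

MAX_ENUM_STATES <- 2^20

sdds_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "sdds_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' @keywords internal
state_place_values <- function(cardinalities) {
  n <- length(cardinalities)
  rev(cumprod(rev(c(cardinalities[-1], 1))))
}

#' Enumerate every state of a finite multi-valued space
#'
#' States are returned in lexicographic order with variable 1 most
#' significant: row r is the state of rank r (see [state_rank()]).
#'
#' @param cardinalities integer vector of per-variable cardinalities.
#' @return integer matrix with one row per state and one column per variable;
#'   entries are levels `0 .. cardinality - 1`.
#' @keywords internal
enumerate_states <- function(cardinalities) {
  n <- length(cardinalities)
  grid <- expand.grid(rev(lapply(cardinalities, function(k) 0:(k - 1L))),
                      KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid[, n:1, drop = FALSE])
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# ---------------------------------------------------------------------------
# Rule expressions
#
# Grammar: variable names, non-negative integer constants, min(...), max(...),
# not(x) (level complement, card-1 - x; not(e, k) for a compound expression
# with explicit cardinality k), arithmetic + - *, comparisons
# == != < <= > >=, and parentheses.  Comparisons evaluate to 0/1.

RULE_ALLOWED_CALLS <- c("min", "max", "not", "+", "-", "*", "(",
                        "==", "!=", "<", "<=", ">", ">=", "&", "|")

check_rule_ast <- function(e, var_names, rule_name) {
  if (is.numeric(e)) {
    if (e != as.integer(e) || e < 0)
      sdds_stop("sdds_parse_error",
                "rule '%s': constant %s is not a non-negative integer",
                rule_name, format(e))
    return(invisible(TRUE))
  }
  if (is.symbol(e)) {
    if (!(as.character(e) %in% var_names))
      sdds_stop("sdds_parse_error", "rule '%s': unknown variable '%s'",
                rule_name, as.character(e))
    return(invisible(TRUE))
  }
  if (is.call(e)) {
    op <- as.character(e[[1]])
    if (!(op %in% RULE_ALLOWED_CALLS))
      sdds_stop("sdds_parse_error", "rule '%s': operator '%s' is not allowed",
                rule_name, op)
    for (a in as.list(e)[-1]) check_rule_ast(a, var_names, rule_name)
    return(invisible(TRUE))
  }
  sdds_stop("sdds_parse_error", "rule '%s': unsupported expression element",
            rule_name)
}

# rewrite not(x) -> (card_x - 1) - x; not(e, k) -> (k - 1) - e
rewrite_not <- function(e, cardinalities) {
  if (!is.call(e)) return(e)
  e[-1] <- lapply(as.list(e)[-1], rewrite_not, cardinalities = cardinalities)
  if (identical(as.character(e[[1]]), "not")) {
    args <- as.list(e)[-1]
    if (length(args) == 1L) {
      if (!is.symbol(args[[1]]))
        sdds_stop("sdds_parse_error",
                  "not() with a compound argument needs an explicit cardinality: not(expr, k)")
      k <- cardinalities[[as.character(args[[1]])]]
      return(call("-", k - 1L, args[[1]]))
    }
    if (length(args) == 2L)
      return(call("-", call("-", args[[2]], 1L), args[[1]]))
    sdds_stop("sdds_parse_error", "not() takes one or two arguments")
  }
  e
}

# Evaluate a rule expression over every enumerated state (vectorised).
eval_rule_expression <- function(text, states, cardinalities, rule_name) {
  ast <- tryCatch(parse(text = text, keep.source = FALSE)[[1]],
                  error = function(e)
                    sdds_stop("sdds_parse_error", "rule '%s': %s",
                              rule_name, conditionMessage(e)))
  var_names <- names(cardinalities)
  check_rule_ast(ast, var_names, rule_name)
  ast <- rewrite_not(ast, cardinalities)
  env <- new.env(parent = baseenv())
  for (j in seq_along(var_names)) assign(var_names[j], states[, j], envir = env)
  assign("min", function(...) do.call(pmin, list(...)), envir = env)
  assign("max", function(...) do.call(pmax, list(...)), envir = env)
  vals <- eval(ast, env)
  if (is.logical(vals)) vals <- as.integer(vals)
  vals <- rep_len(vals, nrow(states))
  vals
}

# ---------------------------------------------------------------------------

#' Construct a stochastic discrete dynamical system
#'
#' An SDDS over variables \eqn{x_1, \dots, x_n} with finite ordered level sets
#' \eqn{X_i = \{0, \dots, k_i - 1\}} is a collection of triplets
#' \eqn{(f_i, p_i^\uparrow, p_i^\downarrow)}: a multi-valued update rule per
#' variable together with an activation propensity (the probability that a
#' called-for increase of the variable actually happens in a time step) and a
#' degradation propensity (likewise for a called-for decrease).
#'
#' Rules may be given either as expression strings over the variable names
#' (operators `min`, `max`, `not`, `+`, `-`, `*`, comparisons, integer
#' constants) or as full-domain truth tables: an integer vector with one
#' entry per state of the whole space, states enumerated in lexicographic
#' order with variable 1 most significant.  Expressions are expanded to truth
#' tables at construction time; the expanded tables are the canonical
#' representation.
#'
#' @param variables named integer vector: names are variable names, values
#'   their cardinalities (number of levels, all >= 2).  Declaration order
#'   fixes the variable order used by state strings and state ranks.
#' @param rules named list, one element per variable: an expression string or
#'   a full-domain truth-table vector of target levels.
#' @param propensities named list, one element per variable, each a numeric
#'   vector with entries `up` and `down` in `[0, 1]`.
#' @return an object of class `sdds_model` with fields `variables`
#'   (data frame of name and cardinality), `cardinalities`, `n`,
#'   `total_states`, `states` (the enumerated state matrix), `table` (the
#'   truth-table matrix, one column per variable), `rule_text` (expression
#'   strings where given), `inputs` (per-rule support variables) and
#'   `propensities` (n x 2 matrix with columns `up`, `down`).
#' @examples
#' m <- sdds_model(
#'   variables = c(x1 = 2, x2 = 2),
#'   rules = list(x1 = "x2", x2 = "min(x1, not(x2))"),
#'   propensities = list(x1 = c(up = .1, down = .2),
#'                       x2 = c(up = .5, down = .9))
#' )
#' fixed_points(m)
#' @seealso [parse_model()], [transition_distribution()], [simulate_cell()]
#' @export
sdds_model <- function(variables, rules, propensities) {
  if (is.data.frame(variables)) {
    nm <- as.character(variables$name)
    cards <- as.integer(variables$cardinality %||% variables$levels)
    names(cards) <- nm
    variables <- cards
  }
  if (is.null(names(variables)) || any(names(variables) == ""))
    sdds_stop("sdds_validation_error", "variables must be a named vector")
  cards <- as.integer(variables)
  names(cards) <- names(variables)
  n <- length(cards)
  if (n < 1L) sdds_stop("sdds_validation_error", "need at least one variable")
  if (any(cards < 2L))
    sdds_stop("sdds_validation_error", "every cardinality must be >= 2")
  total <- prod(as.numeric(cards))
  if (total > MAX_ENUM_STATES)
    sdds_stop("sdds_validation_error",
              "state space has %.3g states; the enumerated representation is capped at %d",
              total, MAX_ENUM_STATES)
  total <- as.integer(total)
  states <- enumerate_states(cards)

  if (is.null(names(rules)) || !setequal(names(rules), names(cards)) ||
      length(rules) != n)
    sdds_stop("sdds_validation_error",
              "rules must be a named list with exactly one rule per variable")
  rules <- rules[names(cards)]

  table <- matrix(0L, nrow = total, ncol = n,
                  dimnames = list(NULL, names(cards)))
  rule_text <- setNames(rep(NA_character_, n), names(cards))
  for (j in seq_len(n)) {
    r <- rules[[j]]
    nm <- names(cards)[j]
    if (is.character(r) && length(r) == 1L) {
      vals <- eval_rule_expression(r, states, cards, nm)
      rule_text[j] <- r
    } else if (is.numeric(r)) {
      if (length(r) != total)
        sdds_stop("sdds_validation_error",
                  "rule '%s': truth table has %d entries, expected %d (one per state)",
                  nm, length(r), total)
      vals <- r
    } else {
      sdds_stop("sdds_validation_error",
                "rule '%s' must be an expression string or a truth-table vector", nm)
    }
    if (any(is.na(vals)) || any(vals != as.integer(vals)))
      sdds_stop("sdds_validation_error",
                "rule '%s' produces non-integer target levels", nm)
    vals <- as.integer(vals)
    if (any(vals < 0L | vals >= cards[j]))
      sdds_stop("sdds_validation_error",
                "rule '%s' targets level %d outside 0..%d",
                nm, vals[which(vals < 0L | vals >= cards[j])[1L]], cards[j] - 1L)
    table[, j] <- vals
  }

  if (is.null(names(propensities)) || !setequal(names(propensities), names(cards)) ||
      length(propensities) != n)
    sdds_stop("sdds_validation_error",
              "propensities must be a named list with one (up, down) pair per variable")
  propensities <- propensities[names(cards)]
  pm <- matrix(NA_real_, nrow = n, ncol = 2,
               dimnames = list(names(cards), c("up", "down")))
  for (j in seq_len(n)) {
    p <- propensities[[j]]
    up <- if (!is.null(names(p))) p[["up"]] else p[1L]
    down <- if (!is.null(names(p))) p[["down"]] else p[2L]
    if (is.null(up) || is.null(down) || is.na(up) || is.na(down))
      sdds_stop("sdds_validation_error",
                "variable '%s': missing activation or degradation propensity",
                names(cards)[j])
    if (up < 0 || up > 1 || down < 0 || down > 1)
      sdds_stop("sdds_validation_error",
                "variable '%s': propensities must lie in [0, 1] (got up=%g, down=%g)",
                names(cards)[j], up, down)
    pm[j, ] <- c(up, down)
  }

  inputs <- lapply(seq_len(n), function(j)
    rule_support_fast(table[, j], states, cards))
  names(inputs) <- names(cards)

  structure(list(
    variables = data.frame(name = names(cards), cardinality = unname(cards),
                           stringsAsFactors = FALSE),
    cardinalities = cards,
    n = n,
    total_states = total,
    states = states,
    table = table,
    rule_text = rule_text,
    inputs = inputs,
    propensities = pm
  ), class = "sdds_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# support detection by direct comparison of table slices along each axis
rule_support_fast <- function(column, states, cards) {
  n <- length(cards)
  total <- length(column)
  depends <- logical(n)
  pv <- state_place_values(cards)
  for (j in seq_len(n)) {
    # compare the column against itself with variable j forced to level 0
    base_rank <- as.integer(seq_len(total) - states[, j] * pv[j])
    depends[j] <- any(column != column[base_rank])
  }
  which(depends)
}

#' Apply the deterministic map G = (f_1, ..., f_n) to states
#'
#' G is the synchronous deterministic system induced by the update rules; the
#' SDDS reduces to it when every propensity equals 1, and shares its fixed
#' points for any propensities.
#'
#' @param model an `sdds_model`.
#' @param x a state: integer vector of levels, a state string, or a matrix of
#'   states (one per row).
#' @return the image state(s), in the same shape as the input (always as
#'   integer levels).
#' @export
deterministic_image <- function(model, x) {
  xm <- as_state_matrix(model, x)
  out <- model$table[state_rank(model, xm), , drop = FALSE]
  dimnames(out) <- NULL
  if (is.matrix(x) || nrow(xm) > 1L) out else out[1L, ]
}

# ---------------------------------------------------------------------------
# States

as_state_matrix <- function(model, x) {
  if (is.character(x)) {
    xm <- do.call(rbind, lapply(x, state_from_string, model = model))
  } else if (is.matrix(x)) {
    xm <- x
  } else {
    xm <- matrix(as.integer(x), nrow = 1L)
  }
  storage.mode(xm) <- "integer"
  if (ncol(xm) != model$n)
    sdds_stop("sdds_validation_error", "state has %d coordinates, expected %d",
              ncol(xm), model$n)
  bad <- xm < 0L | xm >= matrix(model$cardinalities, nrow(xm), model$n, byrow = TRUE)
  if (any(bad))
    sdds_stop("sdds_validation_error", "state level out of range for its variable")
  xm
}

#' Lexicographic rank of states
#'
#' Rank 1 is the all-zero state; variable 1 is most significant.  Ranks index
#' rows of `model$states` and entries of distribution vectors.
#'
#' @param model an `sdds_model`.
#' @param x a state (levels vector, string, or matrix of states by row).
#' @return integer vector of ranks in `1..total_states`.
#' @export
state_rank <- function(model, x) {
  xm <- as_state_matrix(model, x)
  as.integer(xm %*% state_place_values(model$cardinalities) + 1)
}

#' @rdname state_rank
#' @param rank integer vector of ranks.
#' @export
state_from_rank <- function(model, rank) {
  model$states[rank, , drop = FALSE]
}

#' Parse a state from the compact digit-string notation
#'
#' With all cardinalities <= 10 a state is written as one digit per variable,
#' leftmost digit = variable 1 (e.g. `"0011"`).  For larger cardinalities the
#' tuple notation `"(0,12,1)"` is used instead.
#'
#' @param s a single state string.
#' @param model an `sdds_model`.
#' @return integer vector of levels.
#' @export
state_from_string <- function(s, model) {
  s <- trimws(s)
  if (startsWith(s, "(")) {
    parts <- strsplit(gsub("[()]", "", s), ",", fixed = TRUE)[[1]]
    lv <- suppressWarnings(as.integer(trimws(parts)))
  } else {
    if (any(model$cardinalities > 10L))
      sdds_stop("sdds_validation_error",
                "digit-string state notation requires all cardinalities <= 10; use \"(a,b,...)\"")
    chars <- strsplit(s, "")[[1]]
    lv <- suppressWarnings(as.integer(chars))
  }
  if (length(lv) != model$n || any(is.na(lv)))
    sdds_stop("sdds_validation_error",
              "state '%s' does not have %d readable coordinates", s, model$n)
  if (any(lv < 0L | lv >= model$cardinalities))
    sdds_stop("sdds_validation_error", "state '%s' has an out-of-range digit", s)
  lv
}

#' Render states in the notation used throughout the package
#'
#' @param model an `sdds_model`.
#' @param x a state or matrix of states (rows).
#' @return character vector of state strings.
#' @export
state_to_string <- function(model, x) {
  xm <- as_state_matrix(model, x)
  if (all(model$cardinalities <= 10L)) {
    apply(xm, 1L, paste, collapse = "")
  } else {
    apply(xm, 1L, function(r) paste0("(", paste(r, collapse = ","), ")"))
  }
}

#' State strings of the whole space in rank order
#' @param model an `sdds_model`.
#' @return character vector of length `total_states`.
#' @export
state_labels <- function(model) state_to_string(model, model$states)

#' Override one variable's propensity pair
#'
#' @param model an `sdds_model`.
#' @param var variable name.
#' @param up,down replacement propensities in `[0, 1]`; `NULL` keeps the
#'   current value.
#' @return the modified model.
#' @export
set_propensity <- function(model, var, up = NULL, down = NULL) {
  if (!var %in% rownames(model$propensities))
    sdds_stop("sdds_validation_error", "unknown variable '%s'", var)
  for (side in c("up", "down")) {
    v <- if (side == "up") up else down
    if (is.null(v)) next
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1)
      sdds_stop("sdds_validation_error",
                "propensity %s for '%s' must lie in [0, 1]", side, var)
    model$propensities[var, side] <- v
  }
  model
}

#' @export
print.sdds_model <- function(x, ...) {
  cat(sprintf("Stochastic discrete dynamical system: %d variable%s, %d states\n",
              x$n, if (x$n > 1) "s" else "", x$total_states))
  for (j in seq_len(x$n)) {
    cat(sprintf("  %-8s levels 0..%d  p_up=%-5.3g p_down=%-5.3g  %s\n",
                x$variables$name[j], x$cardinalities[j] - 1L,
                x$propensities[j, "up"], x$propensities[j, "down"],
                if (is.na(x$rule_text[j])) "(truth table)" else x$rule_text[j]))
  }
  invisible(x)
}
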