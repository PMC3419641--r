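# Shared fixtures-in-code and independent oracles.

# The two-variable worked example: f1 = x2, f2 = x1 AND NOT x2, with
# asymmetric propensities.  Built in code so the unit tests do not depend on
# the packaged model files.
worked_example <- function() {
  sdds_model(
    variables = c(x1 = 2, x2 = 2),
    rules = list(x1 = "x2", x2 = "min(x1, not(x2))"),
    propensities = list(x1 = c(up = .1, down = .2),
                        x2 = c(up = .5, down = .9))
  )
}

# The eleven positive one-step probabilities of the worked example, frozen as
# the products of their coordinate factors (activation/degradation propensity
# or its complement, in coordinate order).
worked_example_transitions <- function() {
  data.frame(
    source = c("01", "01", "01", "01", "10", "10", "10", "10", "11", "11", "00"),
    target = c("10", "00", "01", "11", "10", "01", "00", "11", "11", "10", "00"),
    weight = c(.1 * .9, (1 - .1) * .9, (1 - .1) * (1 - .9), .1 * (1 - .9),
               (1 - .2) * (1 - .5), .2 * .5, .2 * (1 - .5), (1 - .2) * .5,
               1 * (1 - .9), 1 * .9, 1 * 1),
    stringsAsFactors = FALSE
  )
}

# Brute-force successor distribution: evaluate transition_weight against
# every state of the space and keep the positive entries.
brute_force_distribution <- function(model, x) {
  labels <- state_labels(model)
  w <- vapply(seq_len(model$total_states), function(r)
    transition_weight(model, x, model$states[r, ]), numeric(1))
  keep <- w > 0
  setNames(w[keep], labels[keep])
}

as_named_prob <- function(td) setNames(td$prob, td$states)

# Limit cycles of the synchronous deterministic system, by direct iteration
# from every state until the orbit repeats.
synchronous_attractors_oracle <- function(model) {
  seen_cycles <- list()
  for (r in seq_len(model$total_states)) {
    x <- model$states[r, ]
    orbit <- integer(0)
    rank <- state_rank(model, x)
    while (!(rank %in% orbit)) {
      orbit <- c(orbit, rank)
      x <- deterministic_image(model, x)
      rank <- state_rank(model, x)
    }
    cyc <- sort(orbit[which(orbit == rank)[1]:length(orbit)])
    key <- paste(cyc, collapse = ",")
    seen_cycles[[key]] <- cyc
  }
  lapply(unname(seen_cycles), function(cyc) sort(state_labels(model)[cyc]))
}

# Scalar re-evaluation of a rule expression with base-R semantics (min/max
# instead of pmin/pmax, explicit complement), independent of the package's
# vectorised expansion path.
scalar_rule_oracle <- function(expr_text, model) {
  cards <- model$cardinalities
  vapply(seq_len(model$total_states), function(r) {
    env <- new.env(parent = baseenv())
    for (j in seq_len(model$n))
      assign(model$variables$name[j], model$states[r, j], envir = env)
    assign("not", function(v, k = NULL) {
      if (is.null(k)) k <- cards[[deparse(substitute(v))]]
      k - 1 - v
    }, envir = env)
    as.integer(eval(parse(text = expr_text)[[1]], env))
  }, integer(1))
}

expect_models_equal <- function(a, b) {
  expect_identical(a$cardinalities, b$cardinalities)
  expect_identical(a$table, b$table)
  expect_equal(a$propensities, b$propensities)
}
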