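# State graph, fixed points, attractors, exact propagation, deterministic
# schemes.

test_that("state graphs have the expected node and edge counts", {
  g <- build_state_graph(worked_example())
  expect_identical(g$n_nodes, 4L)
  expect_identical(nrow(g$edges), 11L)
  out_sums <- tapply(g$edges$weight, g$edges$from, sum)
  expect_true(all(abs(out_sums - 1) < 1e-12))

  lam <- load_fixture("phage_lambda")
  glam <- build_state_graph(lam)
  expect_identical(glam$n_nodes, 48L)  # 3 * 4 * 2 * 2 levels
  out_sums <- tapply(glam$edges$weight, glam$edges$from, sum)
  expect_true(all(abs(out_sums - 1) < 1e-12))

  ident <- sdds_model(c(x = 2), list(x = "x"), list(x = c(up = .5, down = .5)))
  gi <- build_state_graph(ident)
  expect_identical(nrow(gi$edges), 2L)
  expect_true(all(gi$edges$from == gi$edges$to))
  expect_identical(gi$edges$weight, c(1, 1))
})

test_that("the state-space cap raises a helpful error", {
  big <- random_model(8, 2, seed = 1)
  expect_error(build_state_graph(big, max_states = 100),
               "simulation", class = "sdds_validation_error")
})

test_that("fixed points of the chain coincide with fixed points of G", {
  models <- c(lapply(fixture_names(), load_fixture),
              lapply(1:50, function(s)
                random_model(1 + s %% 6, cardinalities = 2 + (s %% 2),
                             seed = 2000 + s)))
  for (m in models) {
    fp_det <- state_labels(m)[rowSums(m$table != m$states) == 0]
    # stochastic side: states whose only positive out-edge is a unit self-loop
    g <- build_state_graph(m)
    deg <- table(factor(g$edges$from, levels = seq_len(m$total_states)))
    self_unit <- g$edges$from[g$edges$from == g$edges$to & g$edges$weight == 1]
    fp_chain <- state_labels(m)[intersect(which(deg == 1), self_unit)]
    expect_setequal(fixed_points(m), fp_det)
    expect_setequal(fixed_points(m), fp_chain)
  }
})

test_that("attractors are the closed terminal components", {
  m <- worked_example()
  at <- attractors(build_state_graph(m))
  expect_identical(at$fixed_points, "00")
  expect_length(at$cycles, 0)

  lam <- load_fixture("phage_lambda")
  glam <- build_state_graph(lam)
  at <- attractors(glam)
  expect_identical(at$fixed_points, "2000")
  expect_identical(at$cycles, list(c("0200", "0300")))
  # closedness: no positive weight leaves a terminal component
  members <- c(at$fixed_points, unlist(at$cycles))
  leaving <- glam$edges$source %in% members & !(glam$edges$target %in% members)
  expect_identical(sum(glam$edges$weight[leaving]), 0)
})

test_that("with all propensities 1 attractors equal synchronous limit cycles", {
  for (seed in 1:10) {
    m <- random_model(2 + seed %% 3, cardinalities = 2 + seed %% 2,
                      seed = 3000 + seed)
    m$propensities[, ] <- 1
    at <- attractors(build_state_graph(m))
    sig <- function(l) sort(vapply(l, function(s) paste(sort(s), collapse = ","),
                                   character(1)))
    got <- sig(c(as.list(at$fixed_points), at$cycles))
    oracle <- sig(synchronous_attractors_oracle(m))
    expect_identical(got, oracle)
  }
})

test_that("exact distributions propagate mass correctly", {
  m <- worked_example()
  # absorbing state stays a point mass
  d <- exact_distribution(m, "00", 7)
  expect_identical(unname(d[c("00", "01", "10", "11")]), c(1, 0, 0, 0))
  # one step from 01 reproduces the kernel row
  d1 <- exact_distribution(m, "01", 1)
  expect_equal(unname(d1[c("00", "01", "10", "11")]), c(.81, .09, .09, .01),
               tolerance = 1e-15)
  # mass conservation over a long horizon
  p53 <- load_fixture("p53_mdm2")
  d60 <- exact_distribution(p53, "0011", 60)
  expect_lt(abs(sum(d60) - 1), 1e-9)
  expect_true(all(d60 >= 0))
  # expected levels are bounded by the cardinalities
  ev <- expected_levels(p53, d60)
  expect_true(all(ev >= 0 & ev <= p53$cardinalities - 1))
})

test_that("deterministic trajectories follow the chosen update scheme", {
  m <- worked_example()
  # synchronous iteration of f1 = x2, f2 = x1 AND NOT x2 enters the {10, 01}
  # two-cycle (frozen from direct iteration of G)
  expect_identical(deterministic_trajectory(m, "11", 5),
                   c("11", "10", "01", "10", "01", "10"))
  lam <- load_fixture("phage_lambda")
  expect_identical(deterministic_trajectory(lam, "0200", 4),
                   c("0200", "0300", "0200", "0300", "0200"))
  # asynchronous, ascending order: x1 updates first and x2 sees the new x1
  tr <- deterministic_trajectory(m, "11", 1, scheme = "asynchronous")
  expect_identical(tr, c("11", "10"))
  expect_error(deterministic_trajectory(m, "11", 1, scheme = "asynchronous",
                                        order = c(1, 1)),
               class = "sdds_validation_error")
})

test_that("deterministic scheme steps have positive weight in the chain", {
  # synchronous edges: positive for any propensities in (0, 1]
  for (seed in 1:8) {
    m <- random_model(3, cardinalities = c(2, 3, 2), seed = 4000 + seed,
                      prop_range = c(0.05, 1))
    for (r in seq_len(m$total_states)) {
      x <- m$states[r, ]
      y <- deterministic_image(m, x)
      expect_gt(transition_weight(m, x, y), 0)
    }
  }
  # single-variable asynchronous steps: positive for propensities in (0, 1)
  for (seed in 1:8) {
    m <- random_model(3, cardinalities = 2, seed = 5000 + seed,
                      prop_range = c(0.05, 0.95))
    for (r in seq_len(m$total_states)) {
      x <- m$states[r, ]
      for (i in seq_len(m$n)) {
        y <- x
        y[i] <- m$table[r, i]
        expect_gt(transition_weight(m, x, y), 0)
      }
    }
  }
})

test_that("graph exports carry all edges and weights", {
  m <- worked_example()
  g <- build_state_graph(m)
  csv <- tempfile(fileext = ".csv")
  export_graph_csv(g, csv)
  edges <- utils::read.csv(csv, colClasses = c("character", "character", "numeric"))
  expect_identical(nrow(edges), 11L)
  expect_equal(sort(edges$weight), sort(g$edges$weight))
  dot <- tempfile(fileext = ".dot")
  export_graph_dot(g, dot)
  lines <- readLines(dot)
  # self-loops omitted from the drawing only
  expect_identical(sum(grepl("->", lines, fixed = TRUE)),
                   sum(g$edges$from != g$edges$to))
  dot2 <- tempfile(fileext = ".dot")
  export_graph_dot(g, dot2, self_loops = TRUE)
  expect_identical(sum(grepl("->", readLines(dot2), fixed = TRUE)), 11L)
})
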