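# Stochastic sampling: single steps, trajectories, populations, outcome
# classification, sweeps.

test_that("sample_step respects absorption and the degenerate limits", {
  m <- worked_example()
  for (seed in 1:20)
    expect_identical(sample_step(m, "00", seed = seed), c(0L, 0L))
  det <- m; det$propensities[, ] <- 1
  for (src in c("01", "10", "11"))
    expect_identical(sample_step(det, src, seed = 1),
                     deterministic_image(det, state_from_string(src, det)))
  frozen <- m; frozen$propensities[, ] <- 0
  for (src in c("01", "10", "11"))
    expect_identical(sample_step(frozen, src, seed = 1),
                     state_from_string(src, frozen))
})

test_that("one-step sampling frequencies match the exact kernel", {
  m <- worked_example()
  n <- 20000
  pop <- simulate_population(m, "01", n_cells = n, steps = 1, seed = 42)
  freq <- pop$state_counts[2, ] / n
  exact <- exact_distribution(m, "01", 1)
  for (s in names(exact)) {
    se <- sqrt(exact[s] * (1 - exact[s]) / n)
    expect_lt(abs(freq[s] - exact[s]), max(4 * se, 1e-12))
  }
})

test_that("sampling never leaves the positive-weight support", {
  lam <- load_fixture("phage_lambda")
  tr <- simulate_cell(lam, "0000", steps = 50, seed = 9)
  for (t in seq_len(tr$steps)) {
    w <- transition_weight(lam, tr$levels[t, ], tr$levels[t + 1, ])
    expect_gt(w, 0)
  }
  expect_identical(tr$states[1], "0000")
})

test_that("trajectories are reproducible and zero-step runs are trivial", {
  p53 <- load_fixture("p53_mdm2")
  a <- simulate_cell(p53, "0011", steps = 30, seed = 123)
  b <- simulate_cell(p53, "0011", steps = 30, seed = 123)
  expect_identical(a$states, b$states)
  expect_identical(simulate_cell(p53, "0011", steps = 0, seed = 1)$states,
                   "0011")
  expect_error(simulate_cell(p53, "0011", steps = -1, seed = 1),
               class = "sdds_validation_error")
})

test_that("damage repair is monotone: once repaired, damage stays off", {
  p53 <- load_fixture("p53_mdm2")
  j <- match("dam", p53$variables$name)
  expect_identical(p53$inputs[[j]], integer(0))
  for (seed in 1:10) {
    tr <- simulate_cell(p53, "0011", steps = 60, seed = seed)
    dam <- tr$levels[, j]
    expect_true(all(diff(dam) <= 0))
  }
})

test_that("population summaries are seed-deterministic and match single cells", {
  p53 <- load_fixture("p53_mdm2")
  a <- simulate_population(p53, "0011", n_cells = 50, steps = 20, seed = 11)
  b <- simulate_population(p53, "0011", n_cells = 50, steps = 20, seed = 11)
  expect_identical(a$mean, b$mean)
  expect_identical(a$state_counts, b$state_counts)
  expect_identical(a$final_states, b$final_states)
  # a single-cell population is the trajectory itself, with zero dispersion
  one <- simulate_population(p53, "0011", n_cells = 1, steps = 20, seed = 11)
  expect_true(all(one$sd == 0))
  expect_true(all(rowSums(one$state_counts) == 1))
  visited <- apply(one$state_counts, 1, which.max)
  expect_identical(unname(one$mean), `storage.mode<-`(p53$states[visited, ], "double"))
})

test_that("population means converge to the exact expectation", {
  m <- worked_example()
  n <- 10000
  pop <- simulate_population(m, "01", n_cells = n, steps = 1, seed = 5)
  # E[x1] after one step is .09 + .01 = .10
  p <- .10
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(pop$mean[2, "x1"] - p), 3 * se)
})

test_that("population draws do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_population(worked_example(), "01", 10, 5, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("outcome classification tallies attractor membership", {
  lam <- load_fixture("phage_lambda")
  labels <- list(lysogeny = "2000", lysis = c("0200", "0300"))
  pop <- simulate_population(lam, "0000", n_cells = 500, steps = 10, seed = 3)
  tl <- classify_outcomes(pop, labels)
  expect_identical(sum(tl$count), 500L)
  expect_equal(sum(tl$fraction), 1)
  # invariant to label order
  tl2 <- classify_outcomes(pop, rev(labels))
  byname <- function(t) setNames(t$count, t$outcome)[c("lysogeny", "lysis", "unresolved")]
  expect_identical(byname(tl), byname(tl2))
  # absorbing initialisation gives a pure outcome
  pop2 <- simulate_population(lam, "2000", n_cells = 100, steps = 5, seed = 4)
  tl3 <- classify_outcomes(pop2, labels)
  expect_identical(tl3$count[tl3$outcome == "lysogeny"], 100L)
  # overlapping labels are rejected
  expect_error(classify_outcomes(pop, list(a = "2000", b = c("2000", "0200"))),
               class = "sdds_validation_error")
})

test_that("symmetric propensity sweeps are monotone and reproducible", {
  lam <- load_fixture("phage_lambda")
  labels <- list(lysogeny = "2000", lysis = c("0200", "0300"))
  grid <- seq(.1, .9, by = .2)
  sw <- propensity_sweep(lam, "0000", n_cells = 400, steps = 10, a = grid,
                         var_a = "CI", var_b = "CRO", labels = labels,
                         seed = 17)
  expect_identical(nrow(sw), length(grid))
  # lysogeny percentage rises with the CI-favouring propensity, up to noise
  expect_true(all(diff(sw$fraction_lysogeny) > -0.08))
  expect_gt(sw$fraction_lysogeny[length(grid)], sw$fraction_lysogeny[1])
  sw2 <- propensity_sweep(lam, "0000", n_cells = 400, steps = 10, a = grid,
                          var_a = "CI", var_b = "CRO", labels = labels,
                          seed = 17)
  expect_identical(sw, sw2)
  # the extreme point: CI always activates and never degrades, CRO never
  # activates -- every cell is eventually lysogenic
  sw1 <- propensity_sweep(lam, "0000", n_cells = 200, steps = 40, a = 1,
                          var_a = "CI", var_b = "CRO", labels = labels,
                          seed = 21)
  expect_identical(sw1$fraction_lysogeny, 1)
})
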