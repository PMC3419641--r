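# Bundled models and the random-model generator.
#
# The two biological fixtures are transcriptions of published logical models:
# the four-variable p53-Mdm2 damage-response network (after Abou-Jaoude,
# Ouattara and Kaufman's logical analysis) and the phage lambda
# lysis/lysogeny core circuit (after Thieffry and Thomas).  Because the
# transcriptions were assembled from the published qualitative logic, every
# load re-checks the documented structural facts (fixed points, the lysis
# 2-cycle, the CI repression rules) and fails loudly if any is violated, so
# a mistranscription cannot pass silently.

FIXTURE_NAMES <- c("example_2_1_1", "p53_mdm2", "phage_lambda")

#' Names of the bundled fixture models
#' @return character vector of fixture names for [load_fixture()].
#' @export
fixture_names <- function() FIXTURE_NAMES

#' Propensity sets for the phage lambda switch
#'
#' Two published parameterisations of the lysis/lysogeny switch: the
#' CI-favouring set (`"ci"`: CI .8/.2, CRO .2/.8) and the CRO-favouring set
#' (`"cro"`: CI .3/.7, CRO .7/.3); CII and N are .9/.9 in both.
#'
#' @param which `"ci"` or `"cro"`.
#' @return named list of `c(up, down)` pairs suitable for [sdds_model()].
#' @export
lambda_propensity_set <- function(which = c("ci", "cro")) {
  which <- match.arg(which)
  if (which == "ci")
    list(CI = c(up = .8, down = .2), CRO = c(up = .2, down = .8),
         CII = c(up = .9, down = .9), N = c(up = .9, down = .9))
  else
    list(CI = c(up = .3, down = .7), CRO = c(up = .7, down = .3),
         CII = c(up = .9, down = .9), N = c(up = .9, down = .9))
}

apply_propensity_set <- function(model, set) {
  for (v in names(set))
    model <- set_propensity(model, v, up = set[[v]][["up"]],
                            down = set[[v]][["down"]])
  model
}

#' Load a bundled model
#'
#' Available fixtures:
#' \describe{
#'   \item{`example_2_1_1`}{the two-variable worked example
#'     (`f1 = x2`, `f2 = min(x1, not(x2))`; propensities (.1,.2) and
#'     (.5,.9)); its state graph has 4 nodes and 11 positive-weight edges
#'     and the single fixed point `00`.}
#'   \item{`p53_mdm2`}{four variables P (p53, ternary), Mc (cytoplasmic
#'     Mdm2), Mn (nuclear Mdm2), dam (DNA damage); default propensities .9
#'     everywhere except `p_dam_up = 1`, `p_dam_down = .05`.  Unique fixed
#'     point `0010`; sustained oscillations while damage is present.}
#'   \item{`phage_lambda`}{four variables CI (ternary), CRO (four levels),
#'     CII, N.  Bistable: fixed point `2000` (lysogeny) and terminal 2-cycle
#'     `{0200, 0300}` (lysis).  Default propensities are the CI-favouring
#'     set; see [lambda_propensity_set()].}
#' }
#'
#' @param name fixture name, see [fixture_names()].
#' @param propensity_set for `phage_lambda`: `"ci"` (default) or `"cro"`.
#' @return a validated `sdds_model`.
#' @export
load_fixture <- function(name, propensity_set = NULL) {
  name <- match.arg(name, FIXTURE_NAMES)
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "sdds", mustWork = TRUE)
  model <- read_model_file(path)
  if (name == "phage_lambda" && !is.null(propensity_set))
    model <- apply_propensity_set(model,
                                  lambda_propensity_set(propensity_set))
  check_fixture_integrity(name, model)
  model
}

integrity_fail <- function(name, what) {
  sdds_stop("sdds_integrity_error",
            "fixture '%s' failed its structural check: %s", name, what)
}

check_fixture_integrity <- function(name, model) {
  fp <- fixed_points(model)
  if (name == "example_2_1_1") {
    if (!identical(unname(model$cardinalities), c(2L, 2L)))
      integrity_fail(name, "state space must be {0,1} x {0,1}")
    if (!identical(as.character(fp), "00"))
      integrity_fail(name, "unique fixed point must be 00")
    g <- build_state_graph(model)
    if (nrow(g$edges) != 11L)
      integrity_fail(name, sprintf("expected 11 positive-weight edges, found %d",
                                   nrow(g$edges)))
  } else if (name == "p53_mdm2") {
    if (!identical(unname(model$cardinalities), c(3L, 2L, 2L, 2L)))
      integrity_fail(name, "state space must be [0,2] x [0,1] x [0,1] x [0,1]")
    if (!identical(model$variables$name, c("P", "Mc", "Mn", "dam")))
      integrity_fail(name, "variable order must be P, Mc, Mn, dam")
    if (!identical(as.character(fp), "0010"))
      integrity_fail(name, "unique fixed point must be 0010")
    j <- match("dam", model$variables$name)
    if (!identical(model$inputs[[j]], integer(0)))
      integrity_fail(name, "the damage rule must have no activator (constant repair)")
  } else if (name == "phage_lambda") {
    if (!identical(unname(model$cardinalities), c(3L, 4L, 2L, 2L)))
      integrity_fail(name, "state space must be [0,2] x [0,3] x [0,1] x [0,1]")
    if (!identical(model$variables$name, c("CI", "CRO", "CII", "N")))
      integrity_fail(name, "variable order must be CI, CRO, CII, N")
    if (!identical(as.character(fp), "2000"))
      integrity_fail(name, "unique fixed point must be 2000")
    at <- attractors(build_state_graph(model))
    if (length(at$cycles) != 1L ||
        !identical(at$cycles[[1]], c("0200", "0300")))
      integrity_fail(name, "terminal 2-cycle must be {0200, 0300}")
    s <- model$states
    tab <- model$table
    ci2 <- s[, 1] == 2L
    if (any(tab[ci2, 2:4] != 0L))
      integrity_fail(name, "with CI fully expressed, all other genes must switch off")
    cro0 <- s[, 2] == 0L
    if (any(tab[cro0, 1] != 2L))
      integrity_fail(name, "in the absence of CRO, CI must be fully expressed")
    rep_ci <- s[, 2] >= 1L & s[, 3] == 0L
    if (any(tab[rep_ci, 1] != 0L))
      integrity_fail(name, "CI must be fully repressed when CRO is active and CII absent")
  }
  invisible(model)
}

#' Generate a random SDDS for property-based testing
#'
#' Truth tables are drawn uniformly over the target level sets and
#' propensities uniformly over `prop_range`.  The caller's RNG state is left
#' untouched; the same seed always yields the same model.
#'
#' @param n_vars number of variables (>= 1).
#' @param cardinalities per-variable cardinalities (recycled to `n_vars`).
#' @param seed integer seed.
#' @param prop_range range from which propensities are drawn uniformly.
#' @return an `sdds_model` with variables `v1 .. v<n>`.
#' @export
random_model <- function(n_vars, cardinalities = 2L, seed,
                         prop_range = c(0, 1)) {
  cards <- rep_len(as.integer(cardinalities), n_vars)
  names(cards) <- paste0("v", seq_len(n_vars))
  total <- prod(as.numeric(cards))
  if (total > MAX_ENUM_STATES)
    sdds_stop("sdds_validation_error", "random model state space too large")
  with_preserved_rng({
    set.seed(seed)
    rules <- lapply(seq_len(n_vars), function(j)
      sample(0:(cards[j] - 1L), total, replace = TRUE))
    names(rules) <- names(cards)
    props <- lapply(seq_len(n_vars), function(j)
      c(up = stats::runif(1, prop_range[1], prop_range[2]),
        down = stats::runif(1, prop_range[1], prop_range[2])))
    names(props) <- names(cards)
    sdds_model(cards, rules, props)
  })
}
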