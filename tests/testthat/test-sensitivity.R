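# Random parameter designs, the phage-survival response and random-forest
# permutation importance.

test_that("parameter designs sample uniformly within ranges plus a dummy", {
  d <- sample_parameter_designs(n_combos = 200L, n_reps = 5L, seed = 3L)
  expect_equal(nrow(d), 200L)
  expect_true(all(d$dummy %in% 1:3))
  rngs <- default_rfa_ranges()
  for (nm in names(rngs)) {
    expect_true(all(d[[nm]] >= rngs[[nm]][1] & d[[nm]] <= rngs[[nm]][2]))
    if (isTRUE(attr(rngs[[nm]], "int"))) {
      expect_true(all(d[[nm]] == round(d[[nm]])))
    }
  }
  expect_identical(d, sample_parameter_designs(n_combos = 200L, n_reps = 5L,
                                               seed = 3L))
  expect_false(identical(d, sample_parameter_designs(n_combos = 200L,
                                                     n_reps = 5L, seed = 4L)))
})

test_that("degenerate ranges give identical rows except for the dummy", {
  rngs <- list(p_GT = c(0.3, 0.3), burst_size = structure(c(50, 50), int = TRUE))
  d <- sample_parameter_designs(rngs, n_combos = 50L, seed = 1L)
  expect_true(all(d$p_GT == 0.3))
  expect_true(all(d$burst_size == 50L))
  expect_gt(length(unique(d$dummy)), 1L)
  expect_error(sample_parameter_designs(list(), n_combos = 10L), "empty")
  expect_error(sample_parameter_designs(list(x = c(2, 1)), n_combos = 10L),
               "invalid range")
})

test_that("the phage-survival response is the fraction of surviving replicates", {
  mk <- function(alive) list(phage_survived = alive)
  expect_equal(response_phage_survival(lapply(rep(FALSE, 20), mk)), 0)
  expect_equal(response_phage_survival(lapply(rep(TRUE, 20), mk)), 1)
  expect_equal(response_phage_survival(lapply(c(rep(TRUE, 19), FALSE), mk)),
               0.95)
  expect_error(response_phage_survival(list()), "empty")
})

test_that("permutation importance recovers a planted dependence above the dummy", {
  # synthetic response: depends on p_GT only; every other parameter and the
  # dummy are noise. The planted variable must rank first in >= 95% of
  # seeded repetitions.
  wins <- 0L
  for (rep in 1:20) {
    d <- sample_parameter_designs(n_combos = 250L, seed = rep)
    set.seed(rep)
    y <- d$p_GT + stats::rnorm(nrow(d), sd = 0.05)
    imp <- rfa_importance(d, y, n_trees = 400L, seed = rep)
    if (imp$parameter[1] == "p_GT") wins <- wins + 1L
    dummy_imp <- imp$importance[imp$parameter == "dummy"]
    expect_lt(dummy_imp, imp$importance[imp$parameter == "p_GT"])
  }
  expect_gte(wins, 19L)
})

test_that("a constant response yields zero importances with a warning", {
  d <- sample_parameter_designs(n_combos = 30L, seed = 2L)
  expect_warning(imp <- rfa_importance(d, rep(1, 30L)), "constant")
  expect_true(all(imp$importance == 0))
  expect_equal(sort(imp$rank), seq_len(ncol(d)))
  expect_error(rfa_importance(d, 1:5), "one response per design row")
})
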