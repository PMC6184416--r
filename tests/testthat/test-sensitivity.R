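test_that("Garson importances match hand-derived small cases", {
  # one hidden node: reduces to |W_i| / sum |W_k|
  expect_equal(unname(garson(list(W = matrix(c(1, 1), 2), v = 5))),
               c(0.5, 0.5))
  expect_equal(unname(garson(list(W = diag(2), v = c(1, 1)))), c(0.5, 0.5))
  # W rows = inputs, cols = hidden; v = (1, 2):
  # contributions (2/3 * 1 + 1/2 * 2, 1/3 * 1 + 1/2 * 2) = (5/3, 4/3)
  expect_equal(unname(garson(list(W = matrix(c(2, 1, 1, 1), 2), v = c(1, 2)))),
               c(5 / 9, 4 / 9))
  expect_error(garson(list(W = matrix(0, 2, 2), v = c(0, 0))),
               class = "cceann_undefined_importance_error")
})

test_that("Garson equals a literal loop transcription on random weights", {
  set.seed(61)
  for (i in 1:200) {
    p <- sample(2:6, 1)
    h <- sample(1:4, 1)
    W <- matrix(rnorm(p * h), p, h)
    v <- rnorm(h)
    got <- unname(garson(list(W = W, v = v)))
    expect_equal(got, garson_oracle(W, v), tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-9)
    expect_true(all(got >= 0))
  }
})

test_that("Garson is scale-invariant and ignores v for one hidden node", {
  set.seed(62)
  W <- matrix(rnorm(8), 4, 2)
  v <- rnorm(2)
  expect_equal(garson(list(W = 3 * W, v = 3 * v)), garson(list(W = W, v = v)))
  expect_equal(garson(list(W = -2 * W, v = -2 * v)),
               garson(list(W = W, v = v)))

  W1 <- matrix(rnorm(4), 4, 1)
  expect_equal(garson(list(W = W1, v = 7)), garson(list(W = W1, v = -0.01)))
  expect_equal(unname(garson(list(W = W1, v = 1))),
               abs(W1[, 1]) / sum(abs(W1[, 1])))
})

test_that("column importances aggregate additively onto factors", {
  imp <- c(a.x = 0.1, a.y = 0.2, a.z = 0.1, b = 0.6)
  fm <- tibble::tibble(column = c("a.x", "a.y", "a.z", "b"),
                       factor = c("a", "a", "a", "b"))
  agg <- aggregate_to_factors(imp, fm)
  expect_equal(unname(agg[c("a", "b")]), c(0.4, 0.6))
  expect_equal(sum(agg), 1)

  ident <- tibble::tibble(column = c("p", "q"), factor = c("p", "q"))
  expect_equal(unname(aggregate_to_factors(c(p = 0.3, q = 0.7), ident)),
               c(0.3, 0.7))

  expect_error(aggregate_to_factors(c(zz = 1), ident),
               class = "cceann_mapping_error")
})

test_that("a single restart equals one Garson evaluation", {
  mm <- cohort_matrix(recovery_config(seed = 63))
  spec <- network_spec(seed = 5)
  res <- restart_sensitivity(mm, spec, n_restarts = 1, base_seed = 99)
  direct <- aggregate_to_factors(
    garson(fit_mlp(mm, network_spec(seed = 99))), mm$feature_map
  )
  expect_equal(res$importances, direct[names(res$importances)])
  expect_equal(res$n_restarts, 1L)
})

test_that("restart averaging is deterministic and normalized", {
  mm <- cohort_matrix(recovery_config(seed = 64))
  r1 <- restart_sensitivity(mm, network_spec(), n_restarts = 5, base_seed = 7)
  r2 <- restart_sensitivity(mm, network_spec(), n_restarts = 5, base_seed = 7)
  expect_identical(r1$importances, r2$importances)
  expect_equal(sum(r1$importances), 1, tolerance = 1e-9)
  expect_true(all(r1$importances >= 0))
  expect_equal(dim(r1$per_restart), c(5, 8))
  # ranking sorts importances descending
  expect_equal(r1$ranking, names(sort(r1$importances, decreasing = TRUE)))
})

test_that("ranking ties break lexicographically by factor name", {
  res <- structure(list(importances = c(b = 0.25, a = 0.25, c = 0.5)),
                   class = "sensitivity_result")
  expect_equal(cceann:::rank_factors(res$importances), c("c", "a", "b"))
})

test_that("a factor that alone drives the outcome ranks first", {
  cfg <- sim_config(
    n_records = 2500, n_institutions = 20, noise_sd = 0,
    effect_sizes = c(length_of_stay = 0.8, institution_type = 0,
                     insurance_type = 0, surgery = 0, gender = 0,
                     institution_level = 0, age = 0, admission_season = 0),
    elderly_fraction = 1, genitourinary_fraction = 1, seed = 65
  )
  mm <- cohort_matrix(cfg)
  res <- restart_sensitivity(mm, network_spec(), n_restarts = 10,
                             base_seed = 11)
  expect_equal(res$ranking[1], "length_of_stay")
  # individual restarts can misattribute through mutually cancelling junk
  # weights (the reason the method averages restarts at all), but a clear
  # majority must already agree
  agree <- mean(apply(res$per_restart, 1, which.max) ==
                  which(colnames(res$per_restart) == "length_of_stay"))
  expect_gte(agree, 0.7)
  expect_gt(res$importances["length_of_stay"],
            2 * max(res$importances[names(res$importances) !=
                                      "length_of_stay"]))
})

test_that("convergence report measures checkpoint drift", {
  mk <- function(imp, n) {
    structure(list(importances = imp, n_restarts = as.integer(n)),
              class = "sensitivity_result")
  }
  same <- c(a = 0.5, b = 0.5)
  rep1 <- convergence_report(list(mk(same, 10), mk(same, 20)))
  expect_equal(rep1$max_drift, c(NA, 0))
  expect_true(rep1$converged[2])

  shifted <- c(a = 0.52, b = 0.48)
  rep2 <- convergence_report(list(mk(same, 10), mk(shifted, 20)),
                             threshold = 0.01)
  expect_equal(rep2$max_drift[2], 0.02)
  expect_false(rep2$converged[2])

  expect_error(convergence_report(list(mk(same, 10))),
               class = "cceann_usage_error")
  expect_error(convergence_report(list(mk(same, 20), mk(same, 10))),
               class = "cceann_usage_error")
})

test_that("checkpointed sensitivity nests restarts and stabilizes", {
  mm <- cohort_matrix(recovery_config(seed = 66))
  rep <- sensitivity_checkpoints(mm, network_spec(),
                                 checkpoints = c(5, 10, 20), base_seed = 3)
  expect_equal(rep$n_restarts, c(5, 10, 20))
  # first checkpoint equals a plain restart run with the same seeds
  direct <- restart_sensitivity(mm, network_spec(), n_restarts = 5,
                                base_seed = 3)
  expect_equal(unname(unlist(rep[1, names(direct$importances)])),
               unname(direct$importances), tolerance = 1e-12)
  expect_true(all(is.na(rep$max_drift[1]) | rep$max_drift[1] >= 0))
})
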