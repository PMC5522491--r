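test_that("forest separates a threshold-labelled design almost perfectly", {
  design <- separable_design()
  model <- fit_suitability(design, n_trees = 500, seed = 1)
  oob_class <- as.integer(model$oob >= 0.5)
  expect_gt(mean(oob_class == design$labels), 0.99)
  # class weights follow w_c = N / (2 * N_c)
  expect_equal(unname(model$class_weights["1"]), 550 / (2 * 50))
  expect_equal(unname(model$class_weights["0"]), 550 / (2 * 500))
  # every training row has an OOB estimate
  expect_length(model$oob, 550)
  expect_false(anyNA(model$oob))
})

test_that("refitting with a fixed seed reproduces the OOB vector", {
  design <- separable_design(n1 = 30, n0 = 150)
  m1 <- fit_suitability(design, n_trees = 200, seed = 9)
  m2 <- fit_suitability(design, n_trees = 200, seed = 9)
  expect_identical(m1$oob, m2$oob)
  m3 <- fit_suitability(design, n_trees = 200, seed = 10)
  expect_false(identical(m1$oob, m3$oob))
  # single-class designs are rejected
  bad <- design; bad$labels <- rep(1L, length(bad$labels))
  expect_error(fit_suitability(bad, n_trees = 50, seed = 1), "both classes")
})

test_that("scoring returns RIO in [0,1] and honours the learned signal", {
  design <- separable_design()
  model <- fit_suitability(design, n_trees = 500, seed = 2)
  pts <- data.frame(id = 1:3, x = 0, y = 0, role = "test",
                    Altitude = c(4000, 1500, 2900), Noise = 0.5)
  scored <- score_points(model, pts)
  expect_true(all(scored$rio >= 0 & scored$rio <= 1))
  expect_gt(scored$rio[1], 0.5)   # deep in the presence region
  expect_lt(scored$rio[2], 0.5)   # deep in the absence region
  expect_error(score_points(model, pts[, -5]), "Altitude")
})

test_that("permuted labels yield chance-level balanced probabilities", {
  design <- separable_design(n1 = 40, n0 = 400, seed = 3)
  set.seed(4)
  design$labels <- sample(design$labels)
  model <- fit_suitability(design, n_trees = 500, seed = 5)
  # balanced weighting calibrates the null to 0.5, not to prevalence
  expect_lt(abs(mean(model$oob) - 0.5), 0.1)
  # and no variable stands out
  imp <- variable_importance(model)
  expect_lt(max(imp$score), 3 * median(imp$score))
})

test_that("variable importance is rescaled to a top score of exactly 100", {
  run <- small_run()
  imp <- variable_importance(run$model)
  expect_equal(imp$score[1], 100.0)
  expect_true(all(diff(imp$score) <= 0))
  expect_true(all(imp$score >= 0 & imp$score <= 100))
  # a single-informative-variable design ranks that variable first
  design <- separable_design()
  m <- fit_suitability(design, n_trees = 300, seed = 6)
  expect_equal(variable_importance(m)$variable[1], "Altitude")
})

test_that("response curves track the built-in truth", {
  run <- small_run()
  cv <- response_curve(run$model, "Altitude")
  expect_true(all(cv$rio >= 0 & cv$rio <= 1))
  expect_gte(min(cv$value), min(run$design$features$Altitude))
  expect_lte(max(cv$value), max(run$design$features$Altitude))
  # monotone-increasing truth -> strongly increasing fitted curve
  expect_gt(cor(cv$value, cv$rio, method = "spearman"), 0.9)
  # constant predictor gives a flat curve with a warning
  d2 <- separable_design()
  d2$features$Noise <- 1
  m2 <- suppressWarnings(fit_suitability(d2, n_trees = 100, seed = 7))
  expect_warning(flat <- response_curve(m2, "Noise"), "constant")
  expect_equal(var(flat$rio), 0)
})

test_that("half-maximum crossing locates synthetic sigmoid midpoints", {
  # exact closed-form check: a clean sigmoid curve crosses at its inflection
  x <- seq(1000, 6000, length.out = 41)
  clean <- structure(data.frame(value = x,
                                rio = 1 / (1 + exp(-(x - 2800) / 125))),
                     class = c("response_curve", "data.frame"))
  expect_equal(half_max_crossing(clean), 2800, tolerance = 1)
  # decreasing sigmoid with additive noise: isotonic fit keeps the estimate
  set.seed(77)
  noisy <- structure(data.frame(value = x,
                                rio = 1 / (1 + exp((x - 2800) / 125)) +
                                  rnorm(41, 0, 0.02)),
                     class = c("response_curve", "data.frame"))
  expect_lt(abs(half_max_crossing(noisy) - 2800), 200)
  # flat curve has no crossing
  flat <- structure(data.frame(value = x, rio = rep(0.4, 41)),
                    class = c("response_curve", "data.frame"))
  expect_true(is.na(half_max_crossing(flat)))
})

test_that("training-cell scores track the OOB estimates", {
  run <- small_run()
  all_rows <- rbind(as.data.frame(run$design$presence),
                    as.data.frame(run$design$pseudo_absence))
  scored <- score_points(run$model, all_rows)
  expect_gt(cor(scored$rio, run$model$oob, method = "spearman"), 0.8)
})
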