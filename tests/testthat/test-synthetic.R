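test_that("covariate generation is deterministic, ranged, and seed-sensitive", {
  s1 <- generate_covariates(c(24, 24), 1000, seed = 1)
  s1b <- generate_covariates(c(24, 24), 1000, seed = 1)
  s2 <- generate_covariates(c(24, 24), 1000, seed = 2)
  for (nm in names(s1))
    expect_identical(s1[[nm]]$values, s1b[[nm]]$values)
  frac_diff <- mean(s1$Altitude$values != s2$Altitude$values)
  expect_gt(frac_diff, 0.01)
  expect_gte(min(s1$Altitude$values), 1000)
  expect_lte(max(s1$Altitude$values), 6000)
  expect_gte(min(s1$Bio_5$values), -5)
  expect_lte(max(s1$Bio_5$values), 35)
  expect_gte(min(s1$Bio_4$values), 2000)
  expect_lte(max(s1$Bio_4$values), 12000)
  expect_gte(length(unique(as.vector(s1$Landcv$values))), 3)
  expect_error(generate_covariates(c(8, 8)), "16")
})

test_that("true suitability is the response product times prevalence", {
  stack <- generate_covariates(c(24, 24), 1000, seed = 3)
  spec <- default_response_spec()
  # all responses identically 1 -> suitability == prevalence everywhere
  flat <- spec
  flat$responses <- list()
  suit <- true_suitability(stack, flat)
  expect_true(all(suit$values == spec$prevalence))
  # a cell sitting at every inflection contributes 0.5 per sigmoid
  stack$Altitude$values[] <- 2800
  stack$Bio_5$values[] <- 20.5
  stack$Bio_4$values[] <- 7800
  stack$Landcv$values[] <- 1
  suit <- true_suitability(stack, spec)
  expect_equal(suit$values[1, 1], spec$prevalence * 0.5^3, tolerance = 1e-12)
  # low-elevation cell under the default spec is essentially unsuitable
  stack$Altitude$values[] <- 1000
  suit <- true_suitability(stack, spec)
  expect_lt(max(suit$values), 0.05)
  # referencing a missing layer errors
  bad <- spec
  names(bad$responses)[1] <- "Slope"
  expect_error(true_suitability(stack, bad), "Slope")
})

test_that("occurrence sampling is suitability-weighted, disjoint, deterministic", {
  stack <- generate_covariates(c(32, 32), 1000, seed = 4)
  truth <- true_suitability(stack)
  occ <- sample_occurrences(truth, 183, 102, seed = 5)
  expect_equal(nrow(occ$presence), 183)
  expect_equal(nrow(occ$test), 102)
  key <- function(p) paste(p$x, p$y)
  expect_length(intersect(key(occ$presence), key(occ$test)), 0)
  occ2 <- sample_occurrences(truth, 183, 102, seed = 5)
  expect_identical(occ$presence$x, occ2$presence$x)
  # sampled presences sit on cells more suitable than the landscape mean
  better <- vapply(1:20, function(s) {
    o <- sample_occurrences(truth, 40, 0, seed = s)
    mean(grid_value_at(truth, o$presence$x, o$presence$y)) >
      mean(truth$values)
  }, TRUE)
  expect_true(all(better))
  # single positive cell edge case
  one <- grid_of(matrix(c(0, 0, 0.8, 0), 2, 2))
  o <- sample_occurrences(one, 1, 0, seed = 1)
  ctr <- cell_centre(one, 1, 2)
  expect_equal(c(o$presence$x, o$presence$y), c(ctr$x, ctr$y))
  expect_error(sample_occurrences(one, 2, 1, seed = 1), "positive suitability")
})

test_that("occurrence frequencies converge to suitability weights", {
  # 5,000 draws pooled over a fixed seed batch, each draw small relative
  # to the cell count so without-replacement distortion is negligible;
  # chi-square GOF over ten equal-suitability-mass cell groups
  stack <- generate_covariates(c(32, 32), 1000, seed = 6)
  truth <- true_suitability(stack)
  v <- as.vector(t(truth$values))
  counts <- numeric(length(v))
  for (s in 1:500) {
    o <- sample_occurrences(truth, 10, 0, seed = s)
    rc <- cell_index(truth, o$presence$x, o$presence$y)
    idx <- (rc$row - 1) * ncol(truth$values) + rc$col
    counts[idx] <- counts[idx] + 1
  }
  ord <- order(v)
  mass <- cumsum(v[ord]) / sum(v)
  group <- numeric(length(v))
  group[ord] <- pmin(floor(mass * 10) + 1, 10)  # ~equal expected count each
  obs <- tapply(counts, group, sum)
  p <- tapply(v, group, sum) / sum(v)
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("synthetic HII respects the 0-64 scale and decays with distance", {
  z <- generate_hii(c(24, 24), 1000, seed = 1, settlement_count = 0)
  expect_true(all(z$values == 0))
  h <- generate_hii(c(24, 24), 1000, seed = 7, settlement_count = 5)
  expect_lte(max(h$values), 64)
  expect_gte(min(h$values), 0)
  expect_true(all(h$values == round(h$values)))
  # rank correlation with distance to the nearest settlement is negative
  peaks <- which(h$values == max(h$values), arr.ind = TRUE)
  idx <- expand.grid(row = 1:24, col = 1:24)
  d <- sqrt(outer(idx$row, peaks[, 1], "-")^2 +
              outer(idx$col, peaks[, 2], "-")^2)
  dmin <- apply(d, 1, min)
  expect_lt(cor(dmin, h$values[cbind(idx$row, idx$col)], method = "spearman"),
            0)
})

test_that("protected-area generation hits the requested coverage", {
  expect_length(generate_protected_areas(c(64, 64), 1000, 0, seed = 1)$polygons,
                0)
  pa <- generate_protected_areas(c(64, 64), 1000, 0.25, seed = 7)
  tmpl <- grid_of(matrix(0, 64, 64))
  mask <- rasterize_polygons(pa, tmpl)
  cov <- mean(mask$values)
  expect_gte(cov, 0.20)
  expect_lte(cov, 0.30)
  # polygons stay inside the landscape
  for (poly in pa$polygons) for (ring in poly) {
    expect_true(all(ring[, 1] >= 0 & ring[, 1] <= 64000))
    expect_true(all(ring[, 2] >= 0 & ring[, 2] <= 64000))
  }
  expect_error(generate_protected_areas(c(64, 64), 1000, 1.2, seed = 1),
               "coverage_fraction")
})
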