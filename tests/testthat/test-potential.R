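test_that("buffer exclusion removes exactly the cells within distance", {
  mask <- grid_of(matrix(1, 9, 9), cell_size = 1000)
  # no geometry -> identity
  out <- buffer_exclude(mask, NULL, NULL, distance = 5000)
  expect_equal(out$values, mask$values)
  # one record at the centre cell, distance 1.5 cells -> 3x3 block removed
  ctr <- cell_centre(mask, 5, 5)
  rec <- point_table(ctr$x, ctr$y, "presence")
  out <- buffer_exclude(mask, records = rec, distance = 1500)
  expect_equal(sum(out$values == 0), 9)
  expect_true(all(out$values[4:6, 4:6] == 0))
  # distance 0 removes only the hosting cell (boundary-inclusive)
  out0 <- buffer_exclude(mask, records = rec, distance = 0)
  expect_equal(sum(out0$values == 0), 1)
  # exhaustive distance check against the definition
  d <- 2500
  out <- buffer_exclude(mask, records = rec, distance = d)
  idx <- expand.grid(row = 1:9, col = 1:9)
  cc <- cell_centre(mask, idx$row, idx$col)
  expected <- as.numeric(sqrt((cc$x - ctr$x)^2 + (cc$y - ctr$y)^2) > d)
  expect_equal(out$values[cbind(idx$row, idx$col)], expected)
})

test_that("buffer exclusion covers polygons and grows monotonically", {
  mask <- grid_of(matrix(1, 12, 12), cell_size = 1000)
  cbr <- polygon_set(list(rbind(c(2000, 2000), c(5000, 2000), c(5000, 5000),
                                c(2000, 5000), c(2000, 2000))),
                     label = "current_breeding_range")
  removed <- sapply(c(0, 1000, 3000, 8000), function(d)
    sum(buffer_exclude(mask, known_ranges = cbr, distance = d)$values == 0))
  expect_true(all(diff(removed) >= 0))      # larger buffers remove supersets
  # cells inside the polygon are at distance zero
  out0 <- buffer_exclude(mask, known_ranges = cbr, distance = 0)
  inside <- cell_index(mask, 3500, 3500)
  expect_equal(out0$values[inside$row, inside$col], 0)
  # a huge buffer empties the mask
  expect_equal(sum(buffer_exclude(mask, known_ranges = cbr,
                                  distance = 1e6)$values), 0)
})

test_that("cluster aggregation counts components and conserves pixels", {
  m <- matrix(0, 12, 12)
  m[2:6, 2:6] <- 1            # 25-pixel block
  m[9:11, 2:10] <- 1          # 27-pixel block
  m[1, 12] <- 1               # isolated pixel
  clusters <- aggregate_clusters(grid_of(m), min_pixels = 10)
  expect_equal(nrow(clusters), 2)
  expect_setequal(clusters$pixels, c(25, 27))
  expect_equal(sum(clusters$pixels) + attr(clusters, "unassigned_pixels"),
               attr(clusters, "total_pixels"))
  expect_equal(attr(clusters, "unassigned_pixels"), 1)
  expect_equal(clusters$share_pct, 100 * clusters$pixels / 53)
  # a solid 5x5 block alone is one cluster with share 100
  solo <- aggregate_clusters(grid_of(rbind(cbind(matrix(1, 5, 5),
                                                 matrix(0, 5, 7)),
                                           matrix(0, 7, 12))),
                             min_pixels = 10)
  expect_equal(solo$share_pct, 100)
  # 25 + 75 split shares
  m2 <- matrix(0, 20, 20)
  m2[1:5, 1:5] <- 1
  m2[10:14, 5:19] <- 1
  two <- aggregate_clusters(grid_of(m2), min_pixels = 10)
  expect_setequal(round(two$share_pct, 6), c(25, 75))
  # empty masks give an empty table
  expect_equal(nrow(aggregate_clusters(grid_of(matrix(0, 5, 5)))), 0)
})

test_that("8-connectivity joins diagonals; 4-connectivity does not", {
  m <- matrix(0, 4, 4)
  m[1, 1] <- 1; m[2, 2] <- 1; m[3, 3] <- 1
  c8 <- aggregate_clusters(grid_of(m), min_pixels = 1, connectivity = 8)
  expect_equal(nrow(c8), 1)
  c4 <- aggregate_clusters(grid_of(m), min_pixels = 1, connectivity = 4)
  expect_equal(nrow(c4), 3)
})

test_that("cluster labelling matches a flood-fill oracle on random masks", {
  set.seed(31)
  for (i in 1:100) {
    m <- matrix(rbinom(400, 1, runif(1, 0.2, 0.6)), 20, 20)
    clusters <- aggregate_clusters(grid_of(m), min_pixels = 1)
    oracle <- flood_fill_components(m)
    # same number of components and identical size multiset
    expect_equal(nrow(clusters), max(oracle))
    expect_equal(sort(clusters$pixels),
                 sort(as.integer(table(oracle[oracle > 0]))))
    # label rasters agree up to renumbering
    lab <- attr(clusters, "labels")$values
    agree <- tapply(lab[m == 1], oracle[m == 1],
                    function(v) length(unique(v)))
    expect_true(all(agree == 1))
  }
})

test_that("point density counts pixels within the disc over its area", {
  empty <- point_density(grid_of(matrix(0, 8, 8)), radius = 2000)
  expect_true(all(empty$values == 0))
  # a single presence pixel peaks at itself with density 1 / (pi r^2)
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  d <- point_density(grid_of(m), radius = 2000)
  expect_equal(d$values[5, 5], 1 / (pi * 2000^2))
  expect_equal(d$values[5, 5], max(d$values))  # the pixel is (one) peak
  expect_equal(d$values[1, 1], 0)              # zero beyond the radius
  # uniform interior: count equals the disc-offset count
  full <- point_density(grid_of(matrix(1, 15, 15)), radius = 3000)
  offsets <- expand.grid(di = -3:3, dj = -3:3)
  n_disc <- sum(sqrt(offsets$di^2 + offsets$dj^2) * 1000 <= 3000)
  expect_equal(full$values[8, 8], n_disc / (pi * 3000^2))
  expect_error(point_density(grid_of(matrix(1, 4, 4)), radius = 500),
               "cell size")
})

test_that("focal regions are ordered by share with documented tie-breaks", {
  m <- matrix(0, 30, 30)
  m[1:4, 1:10] <- 1     # 40 px
  m[10:12, 1:5] <- 1    # 15 px
  m[20:24, 10:19] <- 1  # 50 px
  mask <- grid_of(m)
  clusters <- aggregate_clusters(mask, min_pixels = 10)
  dens <- point_density(mask, radius = 2000)
  ranked <- rank_focal_regions(clusters, dens)
  expect_equal(ranked$pixels, c(50, 40, 15))
  expect_true(all(diff(ranked$share_pct) <= 0))
  # each peak lies inside its own cluster and is its density maximum
  lab <- attr(clusters, "labels")
  for (i in seq_len(nrow(ranked))) {
    rc <- cell_index(dens, ranked$peak_x[i], ranked$peak_y[i])
    expect_equal(lab$values[rc$row, rc$col], ranked$id[i])
    inside <- which(lab$values == ranked$id[i])
    expect_equal(ranked$peak_density[i], max(dens$values[inside]))
  }
  expect_warning(rank_focal_regions(clusters, dens, top_k = 9), "top_k")
  expect_error(rank_focal_regions(clusters[0, ], dens), "empty")
})
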