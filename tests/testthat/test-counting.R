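test_that("threshold split partitions components into IS and IG", {
  cfg <- counting_config(th_px = 13)
  m <- add_disk(matrix(0L, 40, 80), 20, 20, 5)    # d ~ 10 < 13
  m <- add_disk(m, 20, 60, 10)                    # d ~ 20 >= 13
  comp <- label_components(m)
  sp <- split_by_threshold(comp, cfg)
  expect_equal(sum(sp$is_mask) + sum(sp$ig_mask), sum(m))
  expect_true(all(sp$is_mask + sp$ig_mask <= 1L))
  expect_equal(sp$is_mask[20, 20], 1L)
  expect_equal(sp$ig_mask[20, 60], 1L)
  # boundary case: areas straddling d = 13 (areas 132 vs 140)
  expect_lt(equivalent_diameter(132), 13)
  expect_gt(equivalent_diameter(140), 13)
  empty <- split_by_threshold(label_components(matrix(0L, 5, 5)), cfg)
  expect_equal(sum(empty$is_mask) + sum(empty$ig_mask), 0)
})

test_that("disjoint plant-sized disks are counted exactly", {
  m <- matrix(0L, 60, 200)
  centers <- seq(20, 180, by = 40)
  for (cx in centers) m <- add_disk(m, 30, cx, 10)
  res <- count_agaves(m)
  expect_equal(res$count, 5)
  expect_false(res$partial)
  # centroids recoverable near the true centers
  expect_equal(sort(round(res$detections$col)), centers, tolerance = 1)
})

test_that("empty mask counts zero in zero iterations", {
  res <- count_agaves(matrix(0L, 10, 10))
  expect_equal(res$count, 0)
  expect_equal(res$iterations_run, 0)
  expect_equal(nrow(res$detections), 0)
})

test_that("a sub-threshold component is harvested before any erosion", {
  m <- add_disk(matrix(0L, 30, 30), 15, 15, 5)    # d = 10 < Th
  res <- count_agaves(m)
  expect_equal(res$count, 1)
  expect_equal(res$detections$captured_at_iteration, 1)
  expect_equal(res$iterations_run, 1)
  # area recorded is the uneroded fragment's area
  expect_equal(res$detections$area_px, sum(m))
})

test_that("overlapping disks are separated by the iterative erosion", {
  m <- add_disk(add_disk(matrix(0L, 80, 100), 40, 41, 12), 40, 59, 12)
  expect_equal(nrow(label_components(m)$table), 1)  # a single clump
  res <- count_agaves(m)
  expect_equal(res$count, 2)
  # the independent oracle loop agrees
  expect_equal(oracle_count(m), 2)
})

test_that("counting agrees with the oracle loop on mixed fixtures", {
  set.seed(31)
  for (i in 1:4) {
    m <- matrix(0L, 60, 90)
    for (k in 1:4) {
      m <- add_disk(m, runif(1, 15, 45), runif(1, 15, 75), runif(1, 4, 11))
    }
    expect_equal(count_agaves(m)$count, oracle_count(m))
  }
})

test_that("count is invariant to translation and 90-degree rotation", {
  base <- add_disk(add_disk(matrix(0L, 70, 90), 30, 31, 12), 30, 49, 12)
  base <- add_disk(base, 55, 75, 6)
  n0 <- count_agaves(base)$count
  shifted <- matrix(0L, 70, 90)
  shifted[6:70, 2:90] <- base[1:65, 1:89]
  expect_equal(count_agaves(shifted)$count, n0)
  expect_equal(count_agaves(t(base)[ncol(base):1, ])$count, n0)   # rot 90
})

test_that("two-disk sweep shows a monotone 1 -> 2 transition", {
  r <- 10
  counts <- sapply(seq(0, 26, by = 2), function(sep) {
    m <- add_disk(add_disk(matrix(0L, 60, 90), 30, 35, r), 30, 35 + sep, r)
    count_agaves(m)$count
  })
  expect_equal(counts[1], 1)                    # coincident disks
  expect_equal(counts[length(counts)], 2)       # fully separate
  expect_true(all(diff(counts) >= 0))           # never falls back
  expect_true(all(counts %in% 1:2))
})

test_that("the loop terminates within the image-diameter bound", {
  set.seed(37)
  for (i in 1:5) {
    m <- random_mask(40, 40, 0.55)
    res <- suppressWarnings(count_agaves(m))
    expect_lte(res$iterations_run, ceiling(max(dim(m)) / 2))
  }
  big <- add_disk(matrix(0L, 120, 120), 60, 60, 50)
  res <- count_agaves(big)
  expect_lte(res$iterations_run, 60)
  expect_equal(res$count, 1)
})

test_that("the iteration cap flags pathological inputs with a warning", {
  solid <- add_disk(matrix(0L, 60, 60), 30, 30, 25)
  expect_warning(res <- count_agaves(solid, counting_config(max_iterations = 2)),
                 "max_iterations")
  expect_true(res$partial)
  expect_equal(res$count, 0)   # nothing harvested yet at iteration 2
})

test_that("fragment and union counting modes are both available", {
  m <- add_disk(add_disk(matrix(0L, 80, 100), 40, 41, 12), 40, 59, 12)
  frag <- count_agaves(m, counting_config(count_mode = "fragments"))
  uni <- count_agaves(m, counting_config(count_mode = "union"))
  expect_equal(frag$count, nrow(frag$detections))
  expect_equal(uni$count,
               nrow(label_components(uni$is_mask)$table))
  s <- summary(frag)
  expect_equal(s$fragment_count, frag$count)
  expect_equal(s$union_count, uni$count)
})

test_that("threshold comparison strictness is configurable", {
  # build a component with equivalent diameter exactly at threshold:
  # area 100 -> d = sqrt(400/pi) = 11.2838; use Th = that d
  m <- matrix(0L, 20, 20); m[6:15, 6:15] <- 1L
  d <- equivalent_diameter(100)
  strict <- count_agaves(m, counting_config(th_px = d, strict_less = TRUE))
  loose <- count_agaves(m, counting_config(th_px = d, strict_less = FALSE))
  expect_gt(strict$iterations_run, 1)   # not captured at iteration 1
  expect_equal(loose$detections$captured_at_iteration[1], 1)
})
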