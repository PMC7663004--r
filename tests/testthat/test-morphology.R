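test_that("structuring elements have the defining offset sets", {
  sq3 <- make_se("square", 3)
  expect_equal(nrow(sq3$offsets), 9)
  d2 <- make_se("diamond", 2)
  expect_equal(nrow(d2$offsets), 13)
  expect_true(all(abs(d2$offsets[, 1]) + abs(d2$offsets[, 2]) <= 2))
  d0 <- make_se("diamond", 0)
  expect_equal(nrow(d0$offsets), 1)
  # origin present, point-symmetric
  for (se in list(sq3, d2)) {
    expect_true(any(se$offsets[, 1] == 0 & se$offsets[, 2] == 0))
    key <- paste(se$offsets[, 1], se$offsets[, 2])
    neg <- paste(-se$offsets[, 1], -se$offsets[, 2])
    expect_setequal(key, neg)
  }
  expect_error(make_se("square", 4), "odd")
  expect_identical(parse_se("diamond:2")$offsets, d2$offsets)
  expect_error(parse_se("blob"), "malformed")
})

test_that("erosion and dilation act as set operators with background outside", {
  m <- matrix(0L, 7, 7); m[2:6, 2:6] <- 1L
  e <- erode(m, "square:3")
  expect_equal(sum(e), 9)                       # 5x5 square -> 3x3
  expect_true(all(e[3:5, 3:5] == 1L))
  expect_identical(erode(matrix(0L, 5, 5), "square:3"), matrix(0L, 5, 5))
  expect_identical(erode(m, make_se("diamond", 0)), m)      # identity SE
  d <- matrix(0L, 9, 9); d[5, 5] <- 1L
  dd <- dilate(d, "diamond:2")
  expect_equal(sum(dd), 13)                     # city-block ball of radius 2
  expect_identical(dilate(matrix(0L, 5, 5), "diamond:2"), matrix(0L, 5, 5))
  expect_identical(dilate(m, make_se("diamond", 0)), m)
  # a plant touching the frame erodes from the border too
  b <- matrix(1L, 5, 5)
  expect_equal(sum(erode(b, "square:3")), 9)
})

test_that("opening removes thin bridges, closing fills small gaps; both idempotent", {
  m <- matrix(0L, 24, 30)
  m[3:12, 3:12] <- 1L; m[3:12, 19:28] <- 1L
  m[7:8, 13:18] <- 1L                          # 2-px bridge
  o <- open_mask(m, "square:3")
  expect_equal(nrow(label_components(o)$table), 2)
  expect_true(all(o[3:12, 3:12] == 1L))        # square bodies preserved
  expect_identical(open_mask(o, "square:3"), o)
  g <- disk_mask(20, 20, 10, 10, 6); g[10, 10] <- 0L
  cl <- close_mask(g, "square:3")
  expect_equal(cl[10, 10], 1L)
  expect_identical(close_mask(cl, "square:3"), cl)
  # a block whose dilation stays inside the frame closes to itself
  blk <- matrix(0L, 8, 8); blk[3:6, 3:6] <- 1L
  expect_identical(close_mask(blk, "square:3"), blk)
  expect_identical(open_mask(matrix(0L, 6, 6), "square:3"), matrix(0L, 6, 6))
  # border policy: outside-image is background for every operator, so
  # closing a full-frame mask erodes its border ring like any other edge
  full <- matrix(1L, 6, 6)
  shrunk <- close_mask(full, "square:3")
  expect_equal(sum(shrunk), 16)
  expect_true(all(shrunk[2:5, 2:5] == 1L))
})

test_that("separation cuts necks between plant-sized disks, preserves disjoint ones", {
  two <- add_disk(add_disk(matrix(0L, 40, 70), 20, 18, 10), 20, 52, 10)
  two[19:20, 28:42] <- 1L                      # 2-px-thick neck
  sep <- separate_objects(two)
  expect_equal(nrow(label_components(sep)$table), 2)
  clean <- add_disk(add_disk(matrix(0L, 40, 70), 20, 18, 10), 20, 52, 10)
  expect_equal(nrow(label_components(separate_objects(clean))$table), 2)
  expect_identical(separate_objects(matrix(0L, 5, 5)), matrix(0L, 5, 5))
})

test_that("all four operators match the brute-force oracle on random masks", {
  set.seed(7)
  ses <- list(make_se("square", 3), make_se("diamond", 2))
  for (i in 1:12) {
    m <- random_mask(32, 32, runif(1, 0.2, 0.7))
    se <- ses[[i %% 2 + 1]]
    expect_identical(erode(m, se), oracle_erode(m, se))
    expect_identical(dilate(m, se), oracle_dilate(m, se))
    expect_identical(open_mask(m, se), oracle_open(m, se))
    expect_identical(close_mask(m, se), oracle_close(m, se))
  }
})

test_that("morphology laws hold: duality, extensivity, monotonicity", {
  set.seed(11)
  se <- make_se("diamond", 2)
  for (i in 1:8) {
    m <- matrix(0L, 24, 24)
    m[5:20, 5:20] <- random_mask(16, 16, 0.5)   # padded: interior content
    comp <- 1L - m
    # duality away from the border
    dual <- 1L - dilate(comp, se)
    expect_identical(erode(m, se)[4:21, 4:21], dual[4:21, 4:21])
    expect_true(all(erode(m, se) <= m))
    expect_true(all(m <= dilate(m, se)))
    expect_true(all(open_mask(m, se) <= m))
    expect_true(all(m <= close_mask(m, se)))
    # increasing: X subset Y => op(X) subset op(Y)
    y <- matrix(as.integer(m | random_mask(24, 24, 0.2)), 24, 24)
    for (op in list(erode, dilate, open_mask, close_mask)) {
      expect_true(all(op(m, se) <= op(y, se)))
    }
  }
})
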