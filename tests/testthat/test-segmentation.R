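# Two-level segmentation: thresholds, masks, morphology, XOR composite.

test_that("maximum-entropy threshold separates classes and matches brute force", {
  img <- as_gray_image(matrix(c(50L, 200L), 16, 16))
  t <- max_entropy_threshold(img)
  expect_gte(t, 50); expect_lt(t, 200)

  tri <- make_trimodal()
  expect_identical(max_entropy_threshold(tri), oracle_kapur(tri))
  # dark class isolated: threshold at/above the overlap level (exactly 60
  # on the noise-free fixture) and below the blade level
  expect_gte(max_entropy_threshold(tri), 60)
  expect_lt(max_entropy_threshold(tri), 140)

  expect_error(max_entropy_threshold(as_gray_image(matrix(128L, 10, 10))),
               "degenerate")
})

test_that("intermeans threshold matches the fixed-point oracle", {
  bim <- as_gray_image(matrix(c(0L, 255L), 16, 16))
  expect_lte(abs(default_threshold(bim) - 127), 1)

  two <- as_gray_image(matrix(c(100L, 101L), 16, 16))
  expect_identical(default_threshold(two), 100L)

  leafish <- as_gray_image(matrix(c(rep(230L, 150), rep(140L, 106)), 16, 16))
  expect_identical(default_threshold(leafish), oracle_intermeans(leafish))
  expect_gt(default_threshold(leafish), 140)
  expect_lt(default_threshold(leafish), 230)

  expect_error(default_threshold(as_gray_image(matrix(7L, 10, 10))),
               "degenerate")
})

test_that("mask construction follows the stated polarity convention", {
  tri <- make_trimodal()
  mk <- make_masks(tri, 0L, 254L)
  expect_true(all(mk$t1_inverted))   # nothing at or below 0
  expect_true(all(mk$t2))            # everything at or below 254
  expect_identical(mask_role(mk$t1_inverted), "T1_INVERTED")
  expect_identical(mask_role(mk$t2), "T2")

  mk <- make_masks(tri, 100L, 185L)
  # T1-inverted background is exactly the overlap; T2 foreground is
  # exactly blade plus overlap
  bare <- function(m) matrix(as.vector(m), nrow(m))
  expect_identical(bare(!mk$t1_inverted), bare(unclass(tri) == 60L))
  expect_identical(bare(mk$t2), bare(unclass(tri) <= 140L))

  expect_error(make_masks(tri, -1, 100), "\\[0, 254\\]")
  expect_error(make_masks(tri, 10, 255), "\\[0, 254\\]")
})

test_that("binary close removes thin dark traces and is idempotent", {
  m <- matrix(TRUE, 40, 40)
  m[20, 5:35] <- FALSE  # 1-px venation-like trace
  mask <- leafknot:::new_binary_mask(m, "T1_INVERTED")
  expect_identical(unclass(binary_close(mask, 0)), unclass(mask))
  closed <- binary_close(mask, 2)
  expect_true(all(closed))  # gap filled
  expect_identical(mask_role(closed), "T1_INVERTED")

  set.seed(42)
  for (k in 1:5) {
    r <- matrix(stats::runif(900) > 0.4, 30, 30)
    rm <- leafknot:::new_binary_mask(r, "T2")
    once <- binary_close(rm, 2)
    twice <- binary_close(once, 2)
    expect_identical(unclass(once), unclass(twice))
  }
})

test_that("XOR composite has the symmetric-difference property", {
  set.seed(1)
  a <- leafknot:::new_binary_mask(matrix(stats::runif(400) > 0.5, 20, 20), "T1_INVERTED")
  b <- leafknot:::new_binary_mask(matrix(stats::runif(400) > 0.5, 20, 20), "T2")
  z <- leafknot:::new_binary_mask(matrix(FALSE, 20, 20), "T2")

  bare <- function(m) matrix(as.vector(m), nrow(m))
  expect_false(any(xor_compose(a, a)))
  expect_identical(bare(xor_compose(a, z)), bare(a))
  expect_identical(mask_role(xor_compose(a, b)), "COMPOSITE")
  expect_identical(sum(xor_compose(a, b)), sum(xor(unclass(a), unclass(b))))
  small <- leafknot:::new_binary_mask(matrix(FALSE, 10, 10), "T2")
  expect_error(xor_compose(a, small), "shapes differ")
})

test_that("thresholds are monotone in the expected direction", {
  tri <- make_trimodal()
  f1 <- integer(0); f2 <- integer(0)
  for (t in c(40L, 90L, 150L, 200L)) {
    mk <- make_masks(tri, t, t)
    f1 <- c(f1, sum(mk$t1_inverted)); f2 <- c(f2, sum(mk$t2))
  }
  expect_true(all(diff(f2) >= 0))   # raising t2 never shrinks T2 foreground
  expect_true(all(diff(f1) <= 0))   # raising t1 never grows T1-inverted foreground
})

test_that("threshold panel has nine row-major entries with an exact center", {
  tri <- make_trimodal()
  t1 <- max_entropy_threshold(tri); t2 <- default_threshold(tri)
  pn <- threshold_panel(tri, t1, t2)
  expect_length(pn$entries, 9L)
  f <- t(vapply(pn$entries, function(e) c(e$f1, e$f2), numeric(2)))
  expect_identical(f[, 1], rep(c(0.95, 1, 1.05), each = 3))
  expect_identical(f[, 2], rep(c(0.95, 1, 1.05), times = 3))

  mk <- make_masks(tri, t1, t2)
  ref <- xor_compose(mk$t1_inverted, mk$t2)
  expect_identical(unclass(pn$entries[[5]]$composite), unclass(ref))

  # clamping at the top of the range
  pn2 <- threshold_panel(tri, 200L, 250L)
  expect_identical(pn2$entries[[9]]$t1, 210L)
  expect_identical(pn2$entries[[9]]$t2, 254L)
})

test_that("on generator output both thresholds fall between adjacent class means", {
  lf <- make_leaf(leaf_preset("both", seed = 3))
  t1 <- max_entropy_threshold(lf$image)
  t2 <- default_threshold(lf$image)
  expect_gt(t1, 60); expect_lt(t1, 140)
  expect_gt(t2, 140); expect_lt(t2, 230)
})
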