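# The splice algorithm: p/q segment test, orientation repair, splicing.

test_that("ring neighbors wrap modularly", {
  expect_identical(neighbor_points(5, 1), list(prev = 5L, nxt = 2L))
  expect_identical(neighbor_points(5, 5), list(prev = 4L, nxt = 1L))
  expect_identical(neighbor_points(3, 2), list(prev = 1L, nxt = 3L))
  expect_error(neighbor_points(2, 1), "at least 3")
})

test_that("segment pair evaluates the printed formulas on the X fixture", {
  a <- rbind(c(0, 0), c(1, 1), c(0, 2))  # a1 = (0,0), a2 = (0,2)
  b <- rbind(c(2, 0), c(1, 1), c(2, 2))  # b1 = (2,0), b2 = (2,2)
  sp <- build_segment_pair(a, b, 2L, 2L)
  expect_equal(sp$p_slope, 1)
  expect_equal(sp$p_intercept, 0)
  expect_equal(sp$q_slope, -1)
  expect_equal(sp$q_intercept, 2)
  expect_equal(unname(sp$Z), c(1, 1))
  expect_identical(unname(sp$R), c(0, 2, 0, 2))
  expect_true(sp$intersects)
  expect_identical(sp$method, "slope")
})

test_that("parallel p and q segments never intersect", {
  a <- rbind(c(0, 0), c(0.5, 1.5), c(0, 3))  # a1 = (0,0), a2 = (0,3)
  b <- rbind(c(1, 4), c(1, 2), c(1, 1))      # b1 = (1,4), b2 = (1,1)
  sp <- build_segment_pair(a, b, 2L, 2L)
  expect_equal(sp$p_slope, sp$q_slope)
  expect_false(sp$intersects)
  expect_null(sp$Z)
})

test_that("vertical chords fall back to the exact predicate", {
  a <- rbind(c(0, 0), c(1, 1), c(0, 2))
  b <- rbind(c(2, 0), c(1, 1), c(0, 4))  # b2 = (0,4): p is vertical
  sp <- build_segment_pair(a, b, 2L, 2L)
  expect_identical(sp$method, "ccw")
  expect_type(sp$intersects, "logical")
})

test_that("slope/range/Z test agrees with the cross-product oracle on random pairs", {
  set.seed(99)
  n <- 10000L
  pts <- matrix(stats::runif(8 * n, 0, 100), ncol = 8)
  checked <- 0L; agreed <- 0L
  for (k in seq_len(n)) {
    a1 <- pts[k, 1:2]; a2 <- pts[k, 3:4]; b1 <- pts[k, 5:6]; b2 <- pts[k, 7:8]
    a <- rbind(a1, (a1 + a2) / 2 + c(0.3, 0.1), a2)
    b <- rbind(b1, (b1 + b2) / 2 + c(0.2, 0.4), b2)
    sp <- build_segment_pair(a, b, 2L, 2L)
    want <- oracle_seg_intersect(a1, b2, a2, b1)
    if (is.na(want)) next
    checked <- checked + 1L
    agreed <- agreed + as.integer(sp$intersects == want)
  }
  expect_gt(checked, 9900L)
  expect_identical(agreed, checked)  # 100% agreement off collinear cases
})

test_that("splice follows the five printed steps on the 4+3 fixture", {
  A <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  B <- rbind(c(5, 5), c(6, 5), c(6, 6))
  merged <- splice_contours(A, B, 1L, 1L)
  expect_identical(nrow(merged), 9L)  # n_A + n_B + 2
  expected <- rbind(c(0, 0), c(5, 5), c(6, 5), c(6, 6), c(5, 5),
                    c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(unname(merged), unname(expected))
  # vertex multiset: all inputs plus one extra copy of each junction vertex
  expect_identical(sum(merged[, 1] == 0 & merged[, 2] == 0), 2L)
  expect_identical(sum(merged[, 1] == 5 & merged[, 2] == 5), 2L)

  # general splice at interior indices
  m2 <- splice_contours(A, B, 3L, 2L)
  expect_identical(nrow(m2), 9L)
  expect_equal(unname(m2[1, ]), c(1, 1))
  expect_equal(unname(m2[2, ]), c(6, 5))
})

test_that("orientation repair enforces the junction condition by reversing B", {
  a <- rbind(c(0, 0), c(1, 1), c(0, 2))
  b <- rbind(c(2, 0), c(1, 1), c(2, 2))
  # the X fixture intersects: a cross junction keeps it unchanged
  ori <- orient_for_junction(a, b, 2L, 2L, "CROSS")
  expect_false(ori$reversed)
  expect_true(ori$pair$intersects)
  # a touch junction demands non-intersection: B is reversed
  ori2 <- orient_for_junction(a, b, 2L, 2L, "TOUCH")
  expect_true(ori2$reversed)
  expect_false(ori2$pair$intersects)
  # and the reverse situation for a cross junction on the swapped fixture
  brev <- reverse_contour(b)
  ori3 <- orient_for_junction(a, brev, 2L, leafknot:::reversed_index(2L, 3L), "CROSS")
  expect_true(ori3$reversed)
  expect_true(ori3$pair$intersects)
})

test_that("concatenation reduces the contour count by one per splice", {
  for (nm in c("tl", "ol", "both")) {
    pr <- preset_run(nm)
    ledger <- pr$res$report$merge_ledger
    nstart <- pr$res$report$contour_count
    expect_identical(ledger$before, seq(nstart, 2L))
    expect_identical(ledger$after, ledger$before - 1L)
    expect_identical(ledger$after[nrow(ledger)], 1L)
    # vertex conservation across all merges
    nverts <- sum(vapply(pr$res$set$contours, function(ct) nrow(ct$xy), 1L))
    expect_identical(nrow(pr$res$contour$xy),
                     nverts + 2L * nrow(ledger))
  }
})

test_that("a single contour concatenates to itself", {
  pr <- preset_run("simple")
  expect_identical(pr$res$report$merges, 0L)
  set <- pr$res$set
  out <- concatenate_all(set, list())
  expect_identical(out$xy, set$contours[[1]]$xy)
})

test_that("concatenation is deterministic", {
  lf <- make_leaf(leaf_preset("both", seed = 13))
  r1 <- run_pipeline(lf$image)
  r2 <- run_pipeline(lf$image)
  expect_identical(r1$contour$xy, r2$contour$xy)
  expect_identical(r1$report$junctions, r2$report$junctions)
})
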