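# Elliptic Fourier analysis and inverse reconstruction.

make_ellipse <- function(a = 2, b = 1, n = 720, phase = 0, center = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + a * cos(t + phase), center[2] + b * sin(t + phase))
}

test_that("a circle is exactly one harmonic of its radius", {
  r <- 3.5
  circ <- make_ellipse(r, r, n = 1440)
  co <- efa_forward(circ, 5)
  expect_equal(unname(co$harmonics[1, "a"]), r, tolerance = 1e-3)
  expect_equal(unname(co$harmonics[1, "d"]), r, tolerance = 1e-3)
  expect_lt(abs(co$harmonics[1, "b"]), 1e-3)
  expect_lt(abs(co$harmonics[1, "c"]), 1e-3)
  hi <- sqrt(rowSums(co$harmonics[-1, ]^2))
  expect_lt(max(hi) / r, 1e-4)
  expect_equal(co$perimeter, 2 * pi * r, tolerance = 1e-3)
})

test_that("an eccentric ellipse matches the chord-length projection oracle", {
  # under chord-length parameterization only a circle is exactly one
  # harmonic; a 2:1 ellipse leaks into the odd harmonics. Expected values
  # frozen from an independent oracle (dense uniform arc-length
  # resampling, direct trigonometric projection).
  co <- efa_forward(make_ellipse(2, 1), 5)
  expect_equal(unname(co$harmonics[1, "a"]), 1.8284, tolerance = 1e-3)
  expect_equal(unname(co$harmonics[1, "d"]), 1.0730, tolerance = 1e-3)
  expect_equal(unname(co$harmonics[3, "a"]), 0.1289, tolerance = 1e-2)
  expect_equal(unname(co$harmonics[3, "d"]), 0.0893, tolerance = 1e-2)
  # harmonic 1 still dominates, and more so for milder eccentricity
  e <- rowSums(co$harmonics^2)
  expect_gt(e[1] / sum(e), 0.99)
  co2 <- efa_forward(make_ellipse(1.2, 1), 5)
  e2 <- rowSums(co2$harmonics^2)
  expect_gt(e2[1] / sum(e2), 0.999)
})

test_that("translation moves only the offset terms", {
  e0 <- make_ellipse(2, 1)
  e1 <- make_ellipse(2, 1, center = c(13, -7))
  c0 <- efa_forward(e0, 10); c1 <- efa_forward(e1, 10)
  expect_equal(c0$harmonics, c1$harmonics, tolerance = 1e-9)
  expect_equal(c1$A0 - c0$A0, 13, tolerance = 1e-9)
  expect_equal(c1$C0 - c0$C0, -7, tolerance = 1e-9)
})

test_that("a 90-degree rotation permutes the coefficient quadruples", {
  xy <- make_ellipse(2, 1, phase = 0.7)
  rot <- cbind(-xy[, 2], xy[, 1])  # (x, y) -> (-y, x)
  c0 <- efa_forward(xy, 8); c1 <- efa_forward(rot, 8)
  expect_equal(c1$harmonics[, "a"], -c0$harmonics[, "c"], tolerance = 1e-9)
  expect_equal(c1$harmonics[, "b"], -c0$harmonics[, "d"], tolerance = 1e-9)
  expect_equal(c1$harmonics[, "c"], c0$harmonics[, "a"], tolerance = 1e-9)
  expect_equal(c1$harmonics[, "d"], c0$harmonics[, "b"], tolerance = 1e-9)
})

test_that("one-harmonic truncation yields the first-harmonic ellipse", {
  pr <- preset_run("simple")
  co <- efa_forward(pr$res$contour, 40)
  rec1 <- efa_inverse(co, 1, n_points = 360)
  back <- efa_forward(rec1$xy, 10)
  p1 <- sum(back$harmonics[1, ]^2)
  expect_lt(sum(back$harmonics[-1, ]^2) / p1, 1e-6)
})

test_that("round trip converges below half a pixel and RMSE is monotone", {
  pr <- preset_run("simple")
  expect_lt(efa_roundtrip_rmse(pr$res$contour, 100), 0.5)
  rms <- vapply(c(5, 20, 60, 100), function(k)
    efa_roundtrip_rmse(pr$res$contour, k), numeric(1))
  expect_true(all(diff(rms) <= 1e-6))
})

test_that("self-intersecting rings are described like simple ones", {
  pr <- preset_run("both")
  expect_lt(efa_roundtrip_rmse(pr$res$contour, 100), 0.5)
})

test_that("stepwise reconstruction produces one contour per step", {
  pr <- preset_run("both")
  co <- efa_forward(pr$res$contour, 270)
  steps <- c(1:15, seq(60, 270, by = 30))
  recs <- stepwise_reconstruction(co, steps, n_points = 100)
  expect_length(recs, 23L)  # 15 unit steps plus 8 steps of thirty
  expect_length(stepwise_reconstruction(co, 270L, 100), 1L)
  expect_length(stepwise_reconstruction(co, integer(0)), 0L)
  expect_error(stepwise_reconstruction(co, c(10, 5)), "ascending")
  expect_error(efa_inverse(co, 271), "between 1 and")
})

test_that("degenerate contours are rejected and duplicates collapsed", {
  expect_error(efa_forward(rbind(c(1, 1), c(1, 1), c(1, 1))), "at least 3 distinct")
  tri <- rbind(c(0, 0), c(4, 0), c(4, 0), c(2, 3))
  co <- efa_forward(tri, 10)
  co2 <- efa_forward(rbind(c(0, 0), c(4, 0), c(2, 3)), 10)
  expect_equal(co$harmonics, co2$harmonics)
})

test_that("coefficient CSV round-trips", {
  pr <- preset_run("simple")
  co <- efa_forward(pr$res$contour, 20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_efa_csv(co, path)
  back <- read_efa_csv(path)
  expect_equal(back$harmonics, co$harmonics)
  expect_equal(back$A0, co$A0)
  expect_equal(back$C0, co$C0)
  expect_identical(back$n_harmonics, 20L)
})
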