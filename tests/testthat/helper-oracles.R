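# Independent oracles and shared fixtures for the test suite. Each oracle
# is written directly from the defining formula, separately from the
# package implementation it checks.

# Brute-force Kapur criterion: recompute both class entropies from the raw
# histogram for every candidate threshold.
oracle_kapur <- function(img) {
  v <- as.integer(img)
  h <- tabulate(v + 1L, 256L)
  p <- h / sum(h)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:254) {
    pl <- p[1:(t + 1L)]; ph <- p[(t + 2L):256L]
    wl <- sum(pl); wh <- sum(ph)
    if (wl <= 0 || wh <= 0) next
    pl <- pl[pl > 0] / wl; ph <- ph[ph > 0] / wh
    crit <- -sum(pl * log(pl)) - sum(ph * log(ph))
    if (crit > best + 1e-12) { best <- crit; best_t <- t }
  }
  best_t
}

# Independent intermeans fixed point on the raw pixel vector.
oracle_intermeans <- function(img) {
  v <- as.numeric(img)
  t <- floor((min(v) + max(v)) / 2)
  for (k in 1:500) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(hi)) { t <- t - 1; next }
    tn <- floor((mean(lo) + mean(hi)) / 2)
    if (tn == t) break
    t <- tn
  }
  as.integer(t)
}

# Segment intersection oracle: orientation signs plus on-segment checks.
# Returns NA for configurations involving collinearity (excluded from the
# agreement comparison, as exact contacts are tolerance-dependent).
oracle_seg_intersect <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  d1 <- orient(p3, p4, p1); d2 <- orient(p3, p4, p2)
  d3 <- orient(p1, p2, p3); d4 <- orient(p1, p2, p4)
  if (d1 == 0 || d2 == 0 || d3 == 0 || d4 == 0) return(NA)
  (d1 != d2) && (d3 != d4)
}

# Deterministic trimodal test image mirroring transillumination levels:
# background 230 (50%), blade 140 (40%), overlap 60 (10%), no noise.
make_trimodal <- function(h = 40, w = 40) {
  img <- matrix(230L, h, w)
  img[11:38, 6:29] <- 140L  # 28 x 24 = 672 px blade
  img[15:30, 10:19] <- 60L  # 16 x 10 = 160 px overlap
  as_gray_image(img)
}

# Build a contour_set by hand from vertex matrices (for topology and
# concatenation tests that do not involve tracing).
mk_set <- function(xys, classes = NULL, shape = c(100L, 100L)) {
  if (is.null(classes)) classes <- rep("OTHER", length(xys))
  ctrs <- lapply(seq_along(xys), function(i) {
    ct <- leafknot:::new_contour(xys[[i]], label = paste0("C", i),
                                 region_class = classes[i])
    ct
  })
  structure(list(contours = ctrs, shape = shape, region_map = NULL),
            class = "contour_set")
}

# Pixel agreement between a filled ring and a reference mask, excusing a
# band of the given width around the ring itself.
band_agreement <- function(fill, mask, ring_xy, band = 2) {
  ringpx <- matrix(1, nrow(mask), ncol(mask))
  xy <- round(ring_xy)
  ok <- xy[, 1] >= 0 & xy[, 1] < ncol(mask) & xy[, 2] >= 0 & xy[, 2] < nrow(mask)
  ringpx[cbind(xy[ok, 2] + 1, xy[ok, 1] + 1)] <- 0
  dmap <- EBImage::distmap(ringpx)
  mean((fill == mask) | (dmap <= band))
}

# Round-trip reconstruction error: RMS of nearest-point distances from the
# original vertices to a densely sampled reconstruction.
efa_roundtrip_rmse <- function(contour, n_harmonics = 100, n_points = 4000) {
  co <- efa_forward(contour, n_harmonics)
  rec <- efa_inverse(co, n_harmonics, n_points = n_points)
  oxy <- leafknot:::collapse_duplicates(leafknot:::contour_xy(contour))
  rxy <- rec$xy
  nn <- vapply(seq_len(nrow(oxy)), function(i)
    sqrt(min((rxy[, 1] - oxy[i, 1])^2 + (rxy[, 2] - oxy[i, 2])^2)), numeric(1))
  sqrt(mean(nn^2))
}

# Memoized preset pipeline runs shared across test files.
.fixtures <- new.env(parent = emptyenv())
preset_run <- function(name, seed = 7L) {
  key <- paste0(name, "_", seed)
  if (is.null(.fixtures[[key]])) {
    lf <- make_leaf(leaf_preset(name, seed = seed))
    res <- run_pipeline(lf$image)
    .fixtures[[key]] <- list(leaf = lf, res = res)
  }
  .fixtures[[key]]
}
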