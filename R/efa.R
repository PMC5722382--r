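# Elliptic Fourier analysis of closed contours (Kuhl-Giardina closed-form
# coefficients under cumulative chord-length parameterization) and the
# truncated/stepwise inverse transform. Self-intersecting rings are handled
# identically to simple rings: the parameterization follows the vertex
# chain, which is exactly what makes overlap and touch features part of
# the harmonic description.

#' Elliptic Fourier coefficients of a closed contour
#'
#' Computes the Kuhl-Giardina coefficients \eqn{(a_n, b_n, c_n, d_n)} for
#' harmonics 1..\code{n_harmonics} of the closed polygonal contour, under
#' cumulative chord-length parameterization, together with the offset
#' terms A0 and C0 (the contour centroid under that parameterization).
#' Consecutive duplicate vertices (which arise at spliced junctions) are
#' collapsed first, since zero-length chords are undefined in the
#' formulation. No size, rotation or phase normalization is applied.
#'
#' @param contour Contour or n x 2 vertex matrix.
#' @param n_harmonics Number of harmonics (>= 1).
#' @return An \code{efa_coefficients} object: list with \code{harmonics}
#'   (n x 4 matrix, columns a, b, c, d), \code{A0}, \code{C0},
#'   \code{n_harmonics} and \code{perimeter}.
#' @export
efa_forward <- function(contour, n_harmonics = 20L) {
  xy <- collapse_duplicates(contour_xy(contour))
  if (nrow(xy) < 3L) stopf("contour needs at least 3 distinct vertices")
  if (n_harmonics < 1L) stopf("n_harmonics must be >= 1")
  n <- nrow(xy)
  j <- c(2:n, 1L)
  dx <- xy[j, 1L] - xy[, 1L]
  dy <- xy[j, 2L] - xy[, 2L]
  dt <- sqrt(dx^2 + dy^2)
  if (all(dt == 0)) stopf("zero-length contour")
  t1 <- c(0, cumsum(dt)[-n])  # t_{i-1}
  t2 <- cumsum(dt)            # t_i
  Tt <- t2[n]
  hs <- seq_len(n_harmonics)
  # phase matrices: rows = harmonics, cols = chords
  ph2 <- 2 * pi * outer(hs, t2) / Tt
  ph1 <- 2 * pi * outer(hs, t1) / Tt
  dcos <- cos(ph2) - cos(ph1)
  dsin <- sin(ph2) - sin(ph1)
  k <- Tt / (2 * pi^2 * hs^2)
  vx <- dx / dt; vy <- dy / dt
  a <- k * as.vector(dcos %*% vx)
  b <- k * as.vector(dsin %*% vx)
  cc <- k * as.vector(dcos %*% vy)
  d <- k * as.vector(dsin %*% vy)
  # offset terms (Kuhl-Giardina A0/C0), closed form
  csum_dx <- c(0, cumsum(dx)[-n]); csum_dy <- c(0, cumsum(dy)[-n])
  xi <- csum_dx - (dx / dt) * t1
  delta <- csum_dy - (dy / dt) * t1
  A0 <- unname(xy[1L, 1L] + (1 / Tt) * sum((dx / (2 * dt)) * (t2^2 - t1^2) + xi * (t2 - t1)))
  C0 <- unname(xy[1L, 2L] + (1 / Tt) * sum((dy / (2 * dt)) * (t2^2 - t1^2) + delta * (t2 - t1)))
  structure(list(harmonics = cbind(a = a, b = b, c = cc, d = d),
                 A0 = A0, C0 = C0,
                 n_harmonics = as.integer(n_harmonics), perimeter = Tt),
            class = "efa_coefficients")
}

#' @export
print.efa_coefficients <- function(x, ...) {
  cat(sprintf("<efa_coefficients: %d harmonics, perimeter %.1f px, center (%.1f, %.1f)>\n",
              x$n_harmonics, x$perimeter, x$A0, x$C0))
  invisible(x)
}

#' Inverse elliptic Fourier transform
#'
#' Re-synthesizes a contour from the first \code{use_n} harmonics, sampled
#' at \code{n_points} equally spaced parameter values.
#'
#' @param coeffs An \code{efa_coefficients} object.
#' @param use_n Number of harmonics to use (1..N).
#' @param n_points Number of points of the reconstruction.
#' @return A \code{leaf_contour}.
#' @export
efa_inverse <- function(coeffs, use_n = coeffs$n_harmonics, n_points = 400L) {
  stopifnot(inherits(coeffs, "efa_coefficients"))
  if (use_n < 1L || use_n > coeffs$n_harmonics)
    stopf("use_n must be between 1 and %d", coeffs$n_harmonics)
  tt <- seq(0, 1, length.out = n_points + 1L)[-(n_points + 1L)]
  hs <- seq_len(use_n)
  ang <- 2 * pi * outer(hs, tt)
  H <- coeffs$harmonics
  x <- coeffs$A0 + as.vector(t(cos(ang)) %*% H[hs, "a"] + t(sin(ang)) %*% H[hs, "b"])
  y <- coeffs$C0 + as.vector(t(cos(ang)) %*% H[hs, "c"] + t(sin(ang)) %*% H[hs, "d"])
  new_contour(cbind(x, y), label = sprintf("efa%d", use_n))
}

#' Stepwise inverse reconstruction
#'
#' One reconstruction per requested harmonic count, for panel rendering of
#' how detail (including overlap and touch features) accrues with
#' harmonics.
#'
#' @param coeffs An \code{efa_coefficients}.
#' @param steps Ascending harmonic counts, each within 1..N.
#' @param n_points Sampling density of each reconstruction.
#' @return List of contours, one per step.
#' @export
stepwise_reconstruction <- function(coeffs, steps, n_points = 400L) {
  if (!length(steps)) return(list())
  if (is.unsorted(steps)) stopf("steps must be ascending")
  lapply(steps, function(s) efa_inverse(coeffs, s, n_points))
}

#' Write / read EFA coefficients as CSV
#'
#' One row per harmonic with columns a, b, c, d, preceded by rows A0 and
#' C0 (in columns term/value layout compatible with \code{read_efa_csv}).
#'
#' @param coeffs An \code{efa_coefficients}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
write_efa_csv <- function(coeffs, path) {
  H <- coeffs$harmonics
  df <- data.frame(term = c("A0", "C0", paste0("H", seq_len(nrow(H)))),
                   a = c(coeffs$A0, coeffs$C0, H[, "a"]),
                   b = c(NA, NA, H[, "b"]),
                   c = c(NA, NA, H[, "c"]),
                   d = c(NA, NA, H[, "d"]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_efa_csv
#' @export
read_efa_csv <- function(path) {
  df <- utils::read.csv(path)
  hrows <- grepl("^H", df$term)
  H <- as.matrix(df[hrows, c("a", "b", "c", "d")])
  dimnames(H) <- list(NULL, c("a", "b", "c", "d"))
  structure(list(harmonics = H,
                 A0 = df$a[df$term == "A0"], C0 = df$a[df$term == "C0"],
                 n_harmonics = sum(hrows),
                 perimeter = NA_real_),
            class = "efa_coefficients")
}
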