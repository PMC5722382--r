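#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Pixel coordinates follow the raster
# convention used by the XY export consumers: x = column, y = row, 0-based,
# y increasing downward. A pixel (x, y) maps to matrix element [y + 1, x + 1].

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Shoelace signed area of a closed ring
#'
#' Computes the signed area of a closed polygon by the shoelace formula
#' \eqn{\frac{1}{2}\sum_i (x_i y_{i+1} - x_{i+1} y_i)}. With y increasing
#' downward (raster convention) a positive value corresponds to a clockwise
#' tour on screen.
#'
#' @param contour A contour object or an n x 2 matrix of (x, y) vertices.
#' @return Signed area in square pixels.
#' @export
#' @examples
#' signed_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
signed_area <- function(contour) {
  xy <- contour_xy(contour)
  n <- nrow(xy)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  0.5 * sum(xy[, 1L] * xy[j, 2L] - xy[j, 1L] * xy[, 2L])
}

# Extract the vertex matrix from a contour or bare matrix.
contour_xy <- function(x) {
  if (inherits(x, "leaf_contour")) return(x$xy)
  if (is.matrix(x) && ncol(x) == 2L) return(x)
  stopf("expected a contour or an n x 2 coordinate matrix")
}

new_contour <- function(xy, label = NA_character_, region_class = "OTHER") {
  storage.mode(xy) <- "double"
  colnames(xy) <- c("x", "y")
  structure(list(xy = xy, label = label, region_class = region_class),
            class = "leaf_contour")
}

#' @export
print.leaf_contour <- function(x, ...) {
  cat(sprintf("<leaf_contour %s: %d vertices, class %s, signed area %.1f px^2>\n",
              x$label, nrow(x$xy), x$region_class, signed_area(x)))
  invisible(x)
}

#' Reverse the orientation of a contour
#'
#' Reverses the vertex order while retaining the starting vertex, so the
#' ring is traversed in the opposite rotational sense. The signed area is
#' negated.
#'
#' @param contour A contour object or n x 2 vertex matrix.
#' @return Object of the same type with reversed orientation.
#' @export
reverse_contour <- function(contour) {
  xy <- contour_xy(contour)
  n <- nrow(xy)
  idx <- if (n > 1L) c(1L, n:2L) else 1L
  if (inherits(contour, "leaf_contour")) {
    contour$xy <- xy[idx, , drop = FALSE]
    contour
  } else {
    xy[idx, , drop = FALSE]
  }
}

# Remove consecutive duplicate vertices (including the wrap-around pair).
collapse_duplicates <- function(xy) {
  n <- nrow(xy)
  if (n < 2L) return(xy)
  keep <- c(TRUE, rowSums(abs(xy[-1L, , drop = FALSE] - xy[-n, , drop = FALSE])) > 0)
  xy <- xy[keep, , drop = FALSE]
  n <- nrow(xy)
  if (n > 1L && all(xy[1L, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  xy
}

# Proper/touching segment intersection by the cross-product (CCW) predicate.
# Endpoint contacts count as intersections; collinear overlaps are resolved
# by on-segment checks.
ccw_sign <- function(ax, ay, bx, by, cx, cy) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  sign(v)
}

seg_intersect_ccw <- function(p1, p2, p3, p4) {
  d1 <- ccw_sign(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- ccw_sign(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- ccw_sign(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- ccw_sign(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

#' Fill a closed ring with the nonzero winding rule
#'
#' Rasterizes the interior of a closed (possibly self-intersecting) ring on
#' a pixel grid. A pixel center is interior when its winding number with
#' respect to the ring is nonzero, which fills regions covered twice by an
#' overlap tour and leaves regions of zero winding (enclosed sinuses) empty.
#'
#' @param contour Contour object or n x 2 vertex matrix (x, y pixel coords).
#' @param shape Canvas dimensions c(height, width).
#' @return Logical matrix of the given shape; TRUE = interior.
#' @export
fill_contour <- function(contour, shape) {
  xy <- collapse_duplicates(contour_xy(contour))
  h <- shape[1L]; w <- shape[2L]
  out <- matrix(FALSE, h, w)
  n <- nrow(xy)
  if (n < 3L) return(out)
  j <- c(2:n, 1L)
  x1 <- xy[, 1L]; y1 <- xy[, 2L]; x2 <- xy[j, 1L]; y2 <- xy[j, 2L]
  for (row in seq_len(h)) {
    yr <- row - 1L  # pixel-center scanline
    up <- (y1 <= yr & y2 > yr)
    dn <- (y2 <= yr & y1 > yr)
    hit <- up | dn
    if (!any(hit)) next
    t <- (yr - y1[hit]) / (y2[hit] - y1[hit])
    xs <- x1[hit] + t * (x2[hit] - x1[hit])
    dir <- ifelse(up[hit], 1L, -1L)
    o <- order(xs)
    xs <- xs[o]; dir <- dir[o]
    wind <- cumsum(dir)
    # spans between consecutive crossings with nonzero winding are interior
    brk <- c(xs, Inf)
    inside <- wind != 0L
    for (k in which(inside)) {
      lo <- ceiling(xs[k])
      hi <- floor(brk[k + 1L] - 1e-9)
      if (hi >= lo) {
        lo <- max(lo, 0L); hi <- min(hi, w - 1L)
        if (hi >= lo) out[row, (lo + 1L):(hi + 1L)] <- TRUE
      }
    }
  }
  out
}

#' Count self-crossings of a ring near a point
#'
#' Counts transversal self-intersections of a closed ring within
#' \code{radius} of \code{center}. Two kinds are recognized: proper
#' interior crossings between non-adjacent edges, and transversal passes
#' through shared geometry. A spliced ring revisits its junction vertices,
#' so two passes may share a vertex or a whole corridor of coincident
#' vertices; such a pair crosses when the four branch directions leaving
#' the shared corridor interleave angularly (one pass's branches separate
#' the other's), and merely touches (osculates) when they do not.
#'
#' @param contour Contour or n x 2 matrix.
#' @param center Numeric c(x, y).
#' @param radius Window radius in pixels.
#' @return Integer number of transversal self-crossings.
#' @export
self_crossings_near <- function(contour, center, radius = 5) {
  xy <- collapse_duplicates(contour_xy(contour))
  n <- nrow(xy)
  if (n < 4L) return(0L)
  j <- c(2:n, 1L)
  wrap <- function(i) ((i - 1L) %% n) + 1L
  d1 <- sqrt((xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2)
  same <- function(p, q) p[1] == q[1] && p[2] == q[2]
  cnt <- 0L

  # proper interior crossings between non-adjacent, non-endpoint-sharing
  # edges lying inside the window
  near <- which(d1 <= radius & d1[j] <= radius)
  if (length(near) >= 2L) {
    for (ii in seq_along(near)) {
      for (kk in seq_len(ii - 1L)) {
        e1 <- near[ii]; e2 <- near[kk]
        if (abs(e1 - e2) <= 1L || abs(e1 - e2) == n - 1L) next
        a1 <- xy[e1, ]; a2 <- xy[j[e1], ]
        b1 <- xy[e2, ]; b2 <- xy[j[e2], ]
        if (same(a1, b1) || same(a1, b2) || same(a2, b1) || same(a2, b2)) next
        s1 <- ccw_sign(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])
        s2 <- ccw_sign(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2])
        s3 <- ccw_sign(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])
        s4 <- ccw_sign(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])
        if (s1 * s2 < 0 && s3 * s4 < 0) cnt <- cnt + 1L
      }
    }
  }

  # transversal crossings at shared vertices/corridors: two passes of the
  # ring through coincident vertices cross when the entry/exit branches of
  # one pass angularly separate those of the other
  pts <- which(d1 <= radius)
  if (length(pts) >= 2L) {
    for (ii in seq_along(pts)) {
      for (kk in seq_len(ii - 1L)) {
        i <- pts[kk]; q <- pts[ii]
        if (!same(xy[i, ], xy[q, ])) next
        # the second pass traverses the corridor with index step s
        s <- if (same(xy[wrap(i + 1L), ], xy[wrap(q - 1L), ]) ||
                 same(xy[wrap(i - 1L), ], xy[wrap(q + 1L), ])) -1L else 1L
        fwd <- 0L
        while (fwd < n && same(xy[wrap(i + fwd + 1L), ], xy[wrap(q + s * (fwd + 1L)), ]))
          fwd <- fwd + 1L
        bwd <- 0L
        while (bwd < n && same(xy[wrap(i - bwd - 1L), ], xy[wrap(q - s * (bwd + 1L)), ]))
          bwd <- bwd + 1L
        # count each corridor once, at its backward-maximal start pair
        if (bwd > 0L) next
        if (fwd + 2L >= n) next  # degenerate: passes identical
        # the two corridor index spans must be disjoint (a 1-px spur is a
        # single pass folded on itself, not two passes)
        span1 <- wrap(i + 0L:fwd)
        span2 <- wrap(q + s * (0L:fwd))
        if (length(intersect(span1, span2))) next
        # strand 1 runs A_in -> corridor -> A_out; strand 2 B_in -> B_out
        A_in <- xy[wrap(i - 1L), ]
        A_out <- xy[wrap(i + fwd + 1L), ]
        if (s == 1L) {
          B_in <- xy[wrap(q - 1L), ]; B_out <- xy[wrap(q + fwd + 1L), ]
        } else {
          B_in <- xy[wrap(q - fwd - 1L), ]; B_out <- xy[wrap(q + 1L), ]
        }
        M <- (xy[i, ] + xy[wrap(i + fwd), ]) / 2
        ang <- function(P) atan2(P[2] - M[2], P[1] - M[1])
        th <- c(ang(A_in), ang(A_out), ang(B_in), ang(B_out))
        if (anyDuplicated(th)) next  # coincident branches: no transversality
        o <- order(th)
        lab <- c("A", "A", "B", "B")[o]
        interleaved <- lab[1L] != lab[2L] && lab[2L] != lab[3L] && lab[3L] != lab[4L]
        if (interleaved) cnt <- cnt + 1L
      }
    }
  }
  cnt
}
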