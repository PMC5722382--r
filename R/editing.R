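# Contour editing (cut/split) and coordinate-file / rendering I/O.

#' Cut a closed contour along a line segment
#'
#' Splits the ring at its two crossings with the cut segment: petiole
#' removal, repair of small breaks of the leaf border, and separation of
#' overlapping leaves all reduce to this. New vertices are inserted at the
#' exact sub-pixel intersection coordinates and each part is closed by the
#' chord between them.
#'
#' @param contour Contour or vertex matrix.
#' @param p0,p1 Endpoints c(x, y) of the cut segment.
#' @return List of two \code{leaf_contour}s (in ring order from the first
#'   crossing). Errors if the segment crosses the ring a number of times
#'   other than two.
#' @export
cut_contour <- function(contour, p0, p1) {
  xy <- collapse_duplicates(contour_xy(contour))
  if (all(p0 == p1)) stopf("cut line endpoints must differ")
  n <- nrow(xy)
  j <- c(2:n, 1L)
  # parametric intersection of each ring edge with the finite cut segment
  ex <- xy[j, 1L] - xy[, 1L]; ey <- xy[j, 2L] - xy[, 2L]
  sx <- p1[1L] - p0[1L]; sy <- p1[2L] - p0[2L]
  den <- ex * sy - ey * sx
  ok <- abs(den) > 1e-12
  t_edge <- rep(NA_real_, n); t_cut <- rep(NA_real_, n)
  t_edge[ok] <- ((p0[1L] - xy[ok, 1L]) * sy - (p0[2L] - xy[ok, 2L]) * sx) / den[ok]
  t_cut[ok] <- ((p0[1L] - xy[ok, 1L]) * ey[ok] - (p0[2L] - xy[ok, 2L]) * ex[ok]) / den[ok]
  hit <- which(ok & t_edge >= 0 & t_edge < 1 & t_cut >= 0 & t_cut <= 1)
  if (length(hit) != 2L)
    stopf("cut line crosses the contour %d times; exactly 2 crossings are required", length(hit))
  pts <- cbind(xy[hit, 1L] + t_edge[hit] * ex[hit],
               xy[hit, 2L] + t_edge[hit] * ey[hit])
  e1 <- hit[1L]; e2 <- hit[2L]
  x1 <- pts[1L, ]; x2 <- pts[2L, ]
  seg_a <- if (e1 + 1L <= e2) (e1 + 1L):e2 else integer(0)
  seg_b <- if (e2 + 1L <= n) (e2 + 1L):n else integer(0)
  seg_b <- c(seg_b, seq_len(e1))
  part1 <- rbind(x1, xy[seg_a, , drop = FALSE], x2)
  part2 <- rbind(x2, xy[seg_b, , drop = FALSE], x1)
  list(new_contour(collapse_duplicates(part1), label = "cut1"),
       new_contour(collapse_duplicates(part2), label = "cut2"))
}

#' Save / load contour vertices as raw XY coordinates
#'
#' Plain text, one vertex per line, x then y separated by a single tab and
#' no header -- the raw format that ImageJ imports via
#' File > Import > XY Coordinates. Integer coordinates are written as
#' integers; fractional ones with three decimals.
#'
#' @param contour Contour or vertex matrix.
#' @param path File path.
#' @param sep Field separator; tab by default, use "," for CSV dialect.
#' @return \code{save_xy}: invisibly, the path. \code{load_xy}: a
#'   \code{leaf_contour}.
#' @export
save_xy <- function(contour, path, sep = "\t") {
  xy <- contour_xy(contour)
  fmt1 <- function(v) {
    ifelse(v == round(v), sprintf("%d", as.integer(round(v))), sprintf("%.3f", v))
  }
  writeLines(paste(fmt1(xy[, 1L]), fmt1(xy[, 2L]), sep = sep), path)
  invisible(path)
}

#' @rdname save_xy
#' @export
load_xy <- function(path, sep = "\t") {
  if (!file.exists(path)) stopf("cannot read XY file: no such file '%s'", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("XY file '%s' is empty", path)
  out <- matrix(NA_real_, length(lines), 2L)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], if (sep == "\t") "\t" else sep, fixed = TRUE)[[1L]]
    parts <- parts[nzchar(parts)]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2L || anyNA(vals))
      stopf("malformed XY line %d in '%s': '%s'", i, path, lines[i])
    out[i, ] <- vals
  }
  new_contour(out, label = tools::file_path_sans_ext(basename(path)))
}

# Integer Bresenham rasterization of one segment; returns (x, y) rows.
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  xs <- integer(0); ys <- integer(0)
  repeat {
    xs <- c(xs, x0); ys <- c(ys, y0)
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x0 <- x0 + sx }
    if (e2 <= dx) { err <- err + dx; y0 <- y0 + sy }
  }
  cbind(xs, ys)
}

#' Render contours onto an RGB canvas
#'
#' Polyline rasterization of each contour in its own color, with optional
#' junction markers (red = cross point, blue = touch point).
#'
#' @param contours List of contours (or a single contour / matrix).
#' @param shape Canvas c(height, width).
#' @param colors Vector of R colors recycled over contours.
#' @param junctions Optional junction list to mark.
#' @param background Canvas background color.
#' @return h x w x 3 numeric array in [0, 1].
#' @export
render_contours <- function(contours, shape, colors = NULL, junctions = NULL,
                            background = "white") {
  if (inherits(contours, "leaf_contour") || is.matrix(contours))
    contours <- list(contours)
  h <- shape[1L]; w <- shape[2L]
  bg <- grDevices::col2rgb(background) / 255
  img <- array(0, c(h, w, 3L))
  for (k in 1:3) img[, , k] <- bg[k]
  if (length(contours)) {
    if (is.null(colors))
      colors <- grDevices::hcl.colors(max(3L, length(contours)), "Dark 3")
    colors <- rep_len(colors, length(contours))
    for (ci in seq_along(contours)) {
      xy <- contour_xy(contours[[ci]])
      rgbv <- grDevices::col2rgb(colors[ci]) / 255
      n <- nrow(xy)
      jj <- c(2:n, 1L)
      for (e in seq_len(n)) {
        px <- bresenham(round(xy[e, 1L]), round(xy[e, 2L]),
                        round(xy[jj[e], 1L]), round(xy[jj[e], 2L]))
        ok <- px[, 1L] >= 0L & px[, 1L] < w & px[, 2L] >= 0L & px[, 2L] < h
        px <- px[ok, , drop = FALSE]
        if (nrow(px)) for (k in 1:3) img[cbind(px[, 2L] + 1L, px[, 1L] + 1L, k)] <- rgbv[k]
      }
    }
  }
  for (jn in junctions) {
    col <- if (jn$kind == "CROSS") c(1, 0, 0) else c(0, 0, 1)
    cxp <- round(jn$point[1L]); cyp <- round(jn$point[2L])
    for (ddx in -2:2) for (ddy in -2:2) {
      if (abs(ddx) + abs(ddy) > 2) next
      xq <- cxp + ddx; yq <- cyp + ddy
      if (xq >= 0 && xq < w && yq >= 0 && yq < h)
        for (k in 1:3) img[yq + 1L, xq + 1L, k] <- col[k]
    }
  }
  img
}
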