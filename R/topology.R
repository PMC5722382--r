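# Junction localization: cross points (overlapping lobes) and touch points
# (touching lobes) between adjacent traced contours.

#' Closest vertex of each of two contours to a reference point
#'
#' @param a,b Contours or n x 2 vertex matrices.
#' @param near Numeric c(x, y) reference point.
#' @return List with 1-based indices \code{a_c} and \code{b_c}. Ties are
#'   broken by the lowest index.
#' @export
closest_vertices <- function(a, b, near) {
  axy <- contour_xy(a); bxy <- contour_xy(b)
  da <- (axy[, 1L] - near[1L])^2 + (axy[, 2L] - near[2L])^2
  db <- (bxy[, 1L] - near[1L])^2 + (bxy[, 2L] - near[2L])^2
  list(a_c = which.min(da), b_c = which.min(db))
}

# circular index distance on a ring of n vertices
ring_dist <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

#' Locate cross and touch points between adjacent contours
#'
#' For every unordered pair of contours, finds the locally minimal
#' vertex-pair distances not exceeding \code{d_adj}; each local minimum
#' (minima are kept at least \code{min_sep} vertices apart along both
#' rings, so long parallel stretches yield a single junction) produces one
#' junction located at the midpoint of its closest vertex pair. A junction
#' is a cross point when either contour is an overlap outline -- the final
#' leaf contour self-intersects there -- and a touch point otherwise.
#'
#' @param set A classified \code{contour_set}.
#' @param d_adj Adjacency distance in pixels: the largest vertex-pair
#'   distance that still counts as contact between two outlines.
#' @param min_sep Minimum separation (in ring vertices) between distinct
#'   junctions of the same contour pair.
#' @return List of junctions, each a \code{leaf_junction} with fields
#'   \code{kind} ("CROSS"/"TOUCH"), \code{point}, contour labels \code{a},
#'   \code{b}, closest vertex indices \code{a_c}, \code{b_c} and
#'   \code{distance}. Ordered by ascending (x, y) of the junction point.
#'   Errors if the junction graph does not connect all contours.
#' @export
find_junctions <- function(set, d_adj = 2, min_sep = 10L) {
  stopifnot(inherits(set, "contour_set"))
  ctrs <- set$contours
  ncont <- length(ctrs)
  junctions <- list()
  if (ncont > 1L) {
    for (i in seq_len(ncont - 1L)) {
      for (j in (i + 1L):ncont) {
        axy <- ctrs[[i]]$xy; bxy <- ctrs[[j]]$xy
        na <- nrow(axy); nb <- nrow(bxy)
        d2 <- outer(axy[, 1L], bxy[, 1L], "-")^2 +
              outer(axy[, 2L], bxy[, 2L], "-")^2
        cand <- which(d2 <= d_adj^2, arr.ind = TRUE)
        if (!nrow(cand)) next
        dv <- sqrt(d2[cand])
        o <- order(dv, cand[, 1L], cand[, 2L])
        cand <- cand[o, , drop = FALSE]; dv <- dv[o]
        kind <- if (ctrs[[i]]$region_class == "OL_OUTLINE" ||
                    ctrs[[j]]$region_class == "OL_OUTLINE") "CROSS" else "TOUCH"
        while (nrow(cand)) {
          ac <- cand[1L, 1L]; bc <- cand[1L, 2L]
          pt <- (axy[ac, ] + bxy[bc, ]) / 2
          junctions[[length(junctions) + 1L]] <- structure(
            list(kind = kind, point = unname(pt),
                 a = ctrs[[i]]$label, b = ctrs[[j]]$label,
                 a_c = unname(ac), b_c = unname(bc),
                 distance = dv[1L]),
            class = "leaf_junction")
          far <- ring_dist(cand[, 1L], ac, na) >= min_sep &
                 ring_dist(cand[, 2L], bc, nb) >= min_sep
          cand <- cand[far, , drop = FALSE]; dv <- dv[far]
        }
      }
    }
  }
  # connectivity of the junction graph over all contours
  labels <- vapply(ctrs, `[[`, character(1), "label")
  if (ncont > 1L) {
    adj <- matrix(FALSE, ncont, ncont, dimnames = list(labels, labels))
    for (jn in junctions) adj[jn$a, jn$b] <- adj[jn$b, jn$a] <- TRUE
    seen <- rep(FALSE, ncont); queue <- 1L; seen[1L] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    if (!all(seen))
      stopf("junction graph is disconnected: contour(s) %s unreachable (no neighbor within d_adj = %g px)",
            paste(labels[!seen], collapse = ", "), d_adj)
  }
  if (length(junctions)) {
    pts <- t(vapply(junctions, `[[`, numeric(2), "point"))
    junctions <- junctions[order(pts[, 1L], pts[, 2L])]
  }
  junctions
}

#' @export
print.leaf_junction <- function(x, ...) {
  cat(sprintf("<%s point at (%.1f, %.1f) linking %s[%d] - %s[%d], d = %.2f px>\n",
              tolower(x$kind), x$point[1], x$point[2],
              x$a, x$a_c, x$b, x$b_c, x$distance))
  invisible(x)
}

#' Junction list to data frame
#' @param junctions List of \code{leaf_junction} objects.
#' @return data.frame with columns kind, x, y, a, b, a_c, b_c, distance.
#' @export
junctions_df <- function(junctions) {
  if (!length(junctions))
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      a = character(), b = character(),
                      a_c = integer(), b_c = integer(), distance = numeric()))
  do.call(rbind, lapply(junctions, function(j)
    data.frame(kind = j$kind, x = j$point[1], y = j$point[2],
               a = j$a, b = j$b, a_c = j$a_c, b_c = j$b_c,
               distance = j$distance)))
}

#' Build junctions from user-supplied points
#'
#' The automatic junction rule derives cross/touch kinds from region
#' classes; this constructor instead takes explicit junction kinds and
#' locations (mirroring an interactive workflow where the user clicks the
#' cross and touch points) and attaches each to the two contours nearest
#' to the given point.
#'
#' @param set A \code{contour_set}.
#' @param df data.frame with columns kind ("CROSS"/"TOUCH"), x, y.
#' @return List of \code{leaf_junction} objects ordered by (x, y).
#' @export
junctions_from_points <- function(set, df) {
  stopifnot(inherits(set, "contour_set"))
  if (!all(c("kind", "x", "y") %in% names(df)))
    stopf("junction table needs columns kind, x, y")
  ctrs <- set$contours
  junctions <- vector("list", nrow(df))
  for (q in seq_len(nrow(df))) {
    pt <- c(df$x[q], df$y[q])
    dmin <- vapply(ctrs, function(ct)
      min((ct$xy[, 1L] - pt[1L])^2 + (ct$xy[, 2L] - pt[2L])^2), numeric(1))
    o <- order(dmin)[1:2]
    cv <- closest_vertices(ctrs[[o[1L]]], ctrs[[o[2L]]], pt)
    junctions[[q]] <- structure(
      list(kind = toupper(df$kind[q]), point = pt,
           a = ctrs[[o[1L]]]$label, b = ctrs[[o[2L]]]$label,
           a_c = cv$a_c, b_c = cv$b_c,
           distance = sqrt(sum((ctrs[[o[1L]]]$xy[cv$a_c, ] -
                                ctrs[[o[2L]]]$xy[cv$b_c, ])^2))),
      class = "leaf_junction")
  }
  pts <- t(vapply(junctions, `[[`, numeric(2), "point"))
  junctions[order(pts[, 1L], pts[, 2L])]
}
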