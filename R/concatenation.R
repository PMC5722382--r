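# Contour concatenation: orientation-aware splicing of contour pairs at
# cross and touch points until a single closed, self-intersecting leaf
# contour remains.
#
# At a junction between contours A and B, with a_c/b_c the vertices
# closest to the junction and a1/a2, b1/b2 their ring predecessors and
# successors, the test segment p joins a1 to b2 and q joins a2 to b1.
# Whether p and q intersect is decided from their slopes, intercepts, the
# common coordinate range R and the line intersection point Z; contours of
# an overlap can be joined only when p and q intersect (the "slalom"),
# contours of a touch only when they do not, and otherwise one contour's
# orientation is inverted first.

EPS_GEOM <- 1e-9

#' Ring predecessor and successor of a vertex index
#'
#' @param n Ring length (number of vertices), at least 3.
#' @param i 1-based vertex index.
#' @return List with \code{prev} (index c-1) and \code{nxt} (index c+1),
#'   with modular wrap-around.
#' @export
neighbor_points <- function(n, i) {
  n <- as.integer(n); i <- as.integer(i)
  if (n < 3L) stopf("a ring needs at least 3 vertices")
  list(prev = ((i - 2L) %% n) + 1L, nxt = (i %% n) + 1L)
}

#' Build and test the p/q segment pair of a junction
#'
#' Computes, for the junction vertices \code{a_c} on contour \code{a} and
#' \code{b_c} on contour \code{b}, the segments p = (a1, b2) and
#' q = (a2, b1), their slopes and midpoint-form intercepts, the common
#' coordinate range R, the line intersection point Z, and whether the two
#' segments intersect (Z inside R). Parallel slopes never intersect. When
#' either segment is vertical the slope algebra is undefined and an exact
#' cross-product segment predicate decides instead (field
#' \code{method = "ccw"}).
#'
#' @param a,b Contours or vertex matrices.
#' @param a_c,b_c 1-based indices of the junction-nearest vertices.
#' @return List of class \code{segment_pair} with the defining points,
#'   regression parameters, range \code{R}, point \code{Z} (or NULL) and
#'   logical \code{intersects}.
#' @export
build_segment_pair <- function(a, b, a_c, b_c) {
  axy <- contour_xy(a); bxy <- contour_xy(b)
  na_ <- nrow(axy); nb_ <- nrow(bxy)
  ai <- neighbor_points(na_, a_c); bi <- neighbor_points(nb_, b_c)
  a1 <- axy[ai$prev, ]; a2 <- axy[ai$nxt, ]
  b1 <- bxy[bi$prev, ]; b2 <- bxy[bi$nxt, ]
  R <- c(Rxmin = min(a1[1], b2[1], a2[1], b1[1]),
         Rxmax = max(a1[1], b2[1], a2[1], b1[1]),
         Rymin = min(a1[2], b2[2], a2[2], b1[2]),
         Rymax = max(a1[2], b2[2], a2[2], b1[2]))
  out <- list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, R = R,
              p_slope = NA_real_, p_intercept = NA_real_,
              q_slope = NA_real_, q_intercept = NA_real_,
              Z = NULL, intersects = FALSE, method = "slope")
  if (abs(a1[1] - b2[1]) < EPS_GEOM || abs(a2[1] - b1[1]) < EPS_GEOM) {
    out$method <- "ccw"
    out$intersects <- seg_intersect_ccw(a1, b2, a2, b1)
  } else {
    p_slope <- (a1[2] - b2[2]) / (a1[1] - b2[1])
    p_intercept <- (a1[2] + b2[2]) / 2 - p_slope * (a1[1] + b2[1]) / 2
    q_slope <- (a2[2] - b1[2]) / (a2[1] - b1[1])
    q_intercept <- (a2[2] + b1[2]) / 2 - q_slope * (a2[1] + b1[1]) / 2
    out$p_slope <- p_slope; out$p_intercept <- p_intercept
    out$q_slope <- q_slope; out$q_intercept <- q_intercept
    if (abs(q_slope - p_slope) >= EPS_GEOM) {
      Zx <- (p_intercept - q_intercept) / (q_slope - p_slope)
      Zy <- p_intercept + p_slope * Zx
      out$Z <- c(Zx = unname(Zx), Zy = unname(Zy))
      # Z must fall in the range COMMON to p and q, i.e. the overlap of
      # the two segments' coordinate spans. (The pooled min/max box R is
      # necessary but not sufficient: Z can land inside it on the
      # extension of the shorter segment, and intersection is claimed as
      # an if-and-only-if condition.)
      cxmin <- max(min(a1[1], b2[1]), min(a2[1], b1[1]))
      cxmax <- min(max(a1[1], b2[1]), max(a2[1], b1[1]))
      cymin <- max(min(a1[2], b2[2]), min(a2[2], b1[2]))
      cymax <- min(max(a1[2], b2[2]), max(a2[2], b1[2]))
      out$intersects <- unname(Zx >= cxmin && Zx <= cxmax &&
                                 Zy >= cymin && Zy <= cymax)
    }
  }
  class(out) <- "segment_pair"
  out
}

#' @export
print.segment_pair <- function(x, ...) {
  cat(sprintf("<segment_pair: %sintersecting (%s test)>\n",
              if (x$intersects) "" else "non-", x$method))
  invisible(x)
}

# Index of a vertex after reversal that keeps the starting vertex in place.
reversed_index <- function(i, n) if (i == 1L) 1L else n - i + 2L

#' Repair contour orientations at a junction
#'
#' A cross point requires the p/q segments to intersect, a touch point
#' requires them not to. If the condition fails with the incoming
#' orientations, contour \code{b} is reversed (the choice of which contour
#' to invert is free; fixing it on \code{b} keeps the procedure
#' deterministic) and the test is repeated.
#'
#' @param a,b Vertex matrices or contours.
#' @param a_c,b_c Junction-nearest vertex indices.
#' @param kind "CROSS" or "TOUCH".
#' @return List with possibly reversed \code{b}, updated \code{b_c},
#'   logical \code{reversed} and the satisfied \code{segment_pair}.
#' @export
orient_for_junction <- function(a, b, a_c, b_c, kind = c("CROSS", "TOUCH")) {
  kind <- match.arg(kind)
  axy <- contour_xy(a); bxy <- contour_xy(b)
  need <- kind == "CROSS"
  sp <- build_segment_pair(axy, bxy, a_c, b_c)
  reversed <- FALSE
  if (sp$intersects != need) {
    bxy <- reverse_contour(bxy)
    b_c <- reversed_index(b_c, nrow(bxy))
    sp <- build_segment_pair(axy, bxy, a_c, b_c)
    reversed <- TRUE
    if (sp$intersects != need)
      stopf("degenerate %s junction: p/q condition unsatisfied in both orientations", tolower(kind))
  }
  list(b = bxy, b_c = b_c, reversed = reversed, pair = sp)
}

#' Splice two contours at a junction
#'
#' Opens contour A at \code{a_c}, links to \code{b_c}, tours contour B
#' completely back to \code{b_c}, links back to \code{a_c} and completes
#' the tour of A. The merged ring has \eqn{n_A + n_B + 2} vertices, with
#' both junction vertices duplicated; it replaces the two inputs.
#' Orientations must already satisfy the junction condition
#' (\code{\link{orient_for_junction}}).
#'
#' @param a,b Contours or vertex matrices.
#' @param a_c,b_c Junction vertex indices.
#' @return Merged vertex matrix (n_A + n_B + 2 rows).
#' @export
splice_contours <- function(a, b, a_c, b_c) {
  axy <- contour_xy(a); bxy <- contour_xy(b)
  na_ <- nrow(axy); nb_ <- nrow(bxy)
  b_tour <- ((b_c - 1L + seq_len(nb_ - 1L)) %% nb_) + 1L  # b_c+1 ... b_c-1
  a_tour <- ((a_c - 1L + seq_len(na_ - 1L)) %% na_) + 1L  # a_c+1 ... a_c-1
  rbind(axy[a_c, , drop = FALSE],
        bxy[b_c, , drop = FALSE],
        bxy[b_tour, , drop = FALSE],
        bxy[b_c, , drop = FALSE],
        axy[a_c, , drop = FALSE],
        axy[a_tour, , drop = FALSE])
}

#' Concatenate all contours into a single closed leaf contour
#'
#' Processes the junctions in ascending (x, y) order. At each junction the
#' two live contours involved are merged by
#' \code{\link{orient_for_junction}} and \code{\link{splice_contours}},
#' with the larger-area contour in the role of A (the blade absorbs its
#' satellites); junctions whose contours were already merged are skipped.
#' Each splice reduces the number of live contours by exactly one, so the
#' procedure ends with a single closed contour that reproduces the leaf
#' outline, self-intersecting at each cross point and self-contacting at
#' each touch point. Remaining junction vertex indices are re-derived from
#' the junction point on the merged ring rather than translated.
#'
#' @param set A classified \code{contour_set}.
#' @param junctions Junction list from \code{\link{find_junctions}}.
#' @return A \code{leaf_contour} of the full outline, with attributes
#'   \code{merge_ledger} (data frame: junction, kind, contours before and
#'   after each splice) and \code{reversed} counts.
#' @export
concatenate_all <- function(set, junctions) {
  stopifnot(inherits(set, "contour_set"))
  ctrs <- set$contours
  labels <- vapply(ctrs, `[[`, character(1), "label")
  if (length(ctrs) == 1L) {
    out <- ctrs[[1L]]
    attr(out, "merge_ledger") <- data.frame(junction = integer(),
                                            kind = character(),
                                            before = integer(),
                                            after = integer())
    return(out)
  }
  parent <- seq_along(ctrs); names(parent) <- labels
  findroot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  live <- lapply(ctrs, `[[`, "xy")
  nlive <- length(ctrs)
  ledger <- list()
  for (q in seq_along(junctions)) {
    jn <- junctions[[q]]
    ra <- findroot(match(jn$a, labels))
    rb <- findroot(match(jn$b, labels))
    if (ra == rb) next  # already part of the same ring
    # the larger-|area| contour plays A and is never reversed
    if (abs(signed_area(live[[rb]])) > abs(signed_area(live[[ra]]))) {
      tmp <- ra; ra <- rb; rb <- tmp
    }
    cv <- closest_vertices(live[[ra]], live[[rb]], jn$point)
    ori <- orient_for_junction(live[[ra]], live[[rb]], cv$a_c, cv$b_c, jn$kind)
    merged <- splice_contours(live[[ra]], ori$b, cv$a_c, ori$b_c)
    parent[rb] <- ra
    live[[ra]] <- merged
    live[[rb]] <- matrix(numeric(0), 0, 2)  # slot dead; roots no longer reach it
    ledger[[length(ledger) + 1L]] <-
      data.frame(junction = q, kind = jn$kind,
                 before = nlive, after = nlive - 1L)
    nlive <- nlive - 1L
  }
  if (nlive != 1L)
    stopf("concatenation ended with %d contours; junction graph incomplete", nlive)
  root <- findroot(1L)
  out <- new_contour(live[[root]], label = paste(labels, collapse = "+"),
                     region_class = "BLADE")
  attr(out, "merge_ledger") <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(junction = integer(), kind = character(),
               before = integer(), after = integer())
  out
}
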