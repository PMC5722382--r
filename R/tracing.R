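# Contour acquisition: connected-component labeling and Moore-neighbor
# boundary tracing of every interior region of a composite mask -- the
# automatic counterpart of contouring each black/white outline with a
# magic-wand tool.

# Connected components of a logical matrix. EBImage::bwlabel provides the
# 4-connected labeling; 8-connectivity is obtained by merging labels that
# touch diagonally (union-find on the small label set).
label_components <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  if (connectivity == 8L && max(lab) > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    pr <- rbind(cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
                cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
    pr <- pr[pr[, 1L] > 0L & pr[, 2L] > 0L & pr[, 1L] != pr[, 2L], , drop = FALSE]
    if (nrow(pr)) {
      parent <- seq_len(max(lab))
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (q in seq_len(nrow(pr))) {
        a <- find(pr[q, 1L]); b <- find(pr[q, 2L])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      remap <- vapply(seq_len(max(lab)), find, integer(1))
      lab[lab > 0L] <- remap[lab[lab > 0L]]
    }
  }
  lab
}

# Moore-neighbor boundary trace of the pixels equal to `id` in `lab`,
# starting at the topmost-then-leftmost region pixel with Jacob's stopping
# criterion. Returns the ordered ring of 0-based (x, y) pixel centers.
moore_trace <- function(lab, id) {
  hit <- which(lab == id)
  nr <- nrow(lab)
  rows <- (hit - 1L) %% nr + 1L
  cols <- (hit - 1L) %/% nr + 1L
  o <- order(rows, cols)
  start <- c(rows[o[1L]], cols[o[1L]])
  # clockwise (on screen, y down) neighbor offsets starting at West
  offs <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                   0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
                 ncol = 2L, byrow = TRUE)  # (drow, dcol): W,NW,N,NE,E,SE,S,SW
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= ncol(lab) &&
    lab[r, c] == id
  # one clockwise scan step: from (cur, backtrack offset) find the next
  # region pixel and the new backtrack offset; NULL for an isolated pixel
  step <- function(cur, back_off) {
    k <- back_off
    for (s in 1:8) {
      k <- k %% 8L + 1L
      r2 <- cur[1L] + offs[k, 1L]; c2 <- cur[2L] + offs[k, 2L]
      if (inside(r2, c2)) {
        prev_k <- if (k == 1L) 8L else k - 1L
        # new backtrack = the empty cell examined just before the found
        # pixel, relative to the new pixel (consecutive Moore-ring cells
        # are 8-adjacent, so this is a valid offset)
        pb <- cur + offs[prev_k, ] - c(r2, c2)
        nb <- which(offs[, 1L] == pb[1L] & offs[, 2L] == pb[2L])
        return(list(cur = c(r2, c2), back_off = nb))
      }
    }
    NULL
  }
  # found by scanning left-to-right, so the initial backtrack is West
  st <- step(start, 1L)
  if (is.null(st))  # isolated pixel
    return(cbind(x = start[2L] - 1L, y = start[1L] - 1L))
  s1 <- st
  maxit <- 8L * length(hit) + 16L
  path_r <- integer(0); path_c <- integer(0)
  for (it in seq_len(maxit)) {
    path_r <- c(path_r, st$cur[1L]); path_c <- c(path_c, st$cur[2L])
    st <- step(st$cur, st$back_off)
    # the walk is a deterministic state machine; the boundary ring is the
    # cycle that re-enters the first state (same pixel, same backtrack)
    if (st$cur[1L] == s1$cur[1L] && st$cur[2L] == s1$cur[2L] &&
        st$back_off == s1$back_off) break
    if (it == maxit) warning("boundary trace safety cap reached")
  }
  # rotate so the ring starts at its topmost-then-leftmost vertex
  o <- order(path_r, path_c)
  k0 <- o[1L]
  if (k0 > 1L) {
    idx <- c(k0:length(path_r), 1:(k0 - 1L))
    path_r <- path_r[idx]; path_c <- path_c[idx]
  }
  cbind(x = path_c - 1L, y = path_r - 1L)
}

#' Trace all interior region contours of a composite mask
#'
#' Labels the connected regions of the composite mask -- foreground (white)
#' regions with 8-connectivity, background (black) regions with
#' 4-connectivity -- and traces the outer boundary ring of every region that
#' does not touch the image border and whose pixel area is at least
#' \code{min_area}. On a composite leaf mask this yields the blade plus
#' every overlap outline and enclosed sinus, while the surrounding
#' background (which touches the border) is skipped.
#'
#' @param composite A \code{binary_mask} (or logical matrix).
#' @param min_area Minimum region area in pixels; small specks left by
#'   venation traces are discarded.
#' @return A \code{contour_set}: list of contours (labels "C1", "C2", ... in
#'   top-to-bottom scan order of their starting pixels) plus the source
#'   shape and a region map used by \code{\link{classify_regions}}.
#' @export
trace_contours <- function(composite, min_area = 16) {
  m <- composite
  if (inherits(m, "binary_mask")) m <- unclass(m)
  attr(m, "role") <- NULL
  if (!any(m)) stopf("empty mask: nothing to trace")
  labw <- label_components(m, 8L)
  labb <- label_components(!m, 4L)
  nr <- nrow(m); nc <- ncol(m)
  border_w <- setdiff(unique(c(labw[1, ], labw[nr, ], labw[, 1], labw[, nc])), 0L)
  border_b <- setdiff(unique(c(labb[1, ], labb[nr, ], labb[, 1], labb[, nc])), 0L)
  # one combined region map; black components offset past white ones
  off <- max(labw)
  region <- labw
  region[labb > 0L] <- labb[labb > 0L] + off
  drop_ids <- c(border_w, border_b + off)
  keep <- setdiff(seq_len(max(region)), drop_ids)
  areas <- tabulate(region, nbins = max(region))
  keep <- keep[areas[keep] >= min_area & areas[keep] > 0L]
  if (!length(keep)) stopf("no interior region to trace (only border-touching regions found)")
  # deterministic order: scan order (topmost, then leftmost) of region starts
  starts <- t(vapply(keep, function(id) {
    idx <- which(region == id)
    rows <- (idx - 1L) %% nr + 1L; cols <- (idx - 1L) %/% nr + 1L
    o <- order(rows, cols)
    c(rows[o[1L]], cols[o[1L]])
  }, integer(2)))
  ord <- order(starts[, 1L], starts[, 2L])
  keep <- keep[ord]
  contours <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    xy <- moore_trace(region, keep[i])
    contours[[i]] <- new_contour(xy, label = paste0("C", i))
    contours[[i]]$region_id <- keep[i]
    contours[[i]]$area_px <- areas[keep[i]]
  }
  structure(list(contours = contours, shape = c(nr, nc), region_map = region),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set: %d contours on %d x %d canvas>\n",
              length(x$contours), x$shape[1], x$shape[2]))
  for (ct in x$contours) print(ct)
  invisible(x)
}

#' Classify traced regions as blade, overlap outline or sinus
#'
#' The contour of largest absolute area is the main leaf blade. Every other
#' region is an overlap outline when at least half of its pixels belong to
#' the dark intensity class (background of the inverted maximum-entropy
#' mask) -- the signature of doubled tissue under transillumination -- and an
#' enclosed sinus otherwise.
#'
#' @param set A \code{contour_set} from \code{\link{trace_contours}}.
#' @param t1_inverted The T1 inverted \code{binary_mask} of the same image.
#' @return The \code{contour_set} with \code{region_class} filled in.
#' @export
classify_regions <- function(set, t1_inverted) {
  stopifnot(inherits(set, "contour_set"))
  if (!all(dim(t1_inverted) == set$shape))
    stopf("mask shape does not match the contour set")
  areas <- vapply(set$contours, function(ct) abs(signed_area(ct)), numeric(1))
  blade <- which.max(areas)
  for (i in seq_along(set$contours)) {
    if (i == blade) { set$contours[[i]]$region_class <- "BLADE"; next }
    id <- set$contours[[i]]$region_id
    px <- set$region_map == id
    dark_frac <- mean(!t1_inverted[px])
    set$contours[[i]]$region_class <-
      if (dark_frac >= 0.5) "OL_OUTLINE" else "SINUS"
  }
  set
}
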