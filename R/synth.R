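# Synthetic transilluminated leaf images with analytic ground truth.
#
# The blade is a polar-harmonic shape (radius = base + lobe cosine term).
# Closed-sinus features (touching or overlapping lobes) are built in
# axis-aligned local windows on the four sinus axes, where every wall,
# pinch and enclosed region is laid out in exact integer pixels, so the
# region classes, junction kinds/locations and contour counts are known
# by construction rather than measured.
#
# Region label codes: 0 background, 1 blade, 2 overlap lens, 3 enclosed
# sinus. The ground-truth label image additionally numbers each distinct
# lens/sinus region.

#' Specify a synthetic leaf
#'
#' @param n_lobes Number of lobes of the polar blade model. Closed-sinus
#'   features (touching or overlapping lobes) require \code{n_lobes = 4},
#'   which places the four sinus axes on the pixel grid axes so junction
#'   pinches can be laid out exactly.
#' @param sinus_depth Fractional depth of the open sinuses (0-1): the polar
#'   radius is \eqn{R_{max}(1 - d/2 + (d/2)\cos n\theta)}.
#' @param overlap_lobes Integer indices (1-4) of sinus axes closed by an
#'   overlapping lobe (axes 1:4 = +x, -y, -x, +y).
#' @param touch_lobes Integer indices of sinus axes closed by touching
#'   lobes. Must be disjoint from \code{overlap_lobes}.
#' @param gray_levels Intensities c(background, blade, overlap). Under
#'   transillumination the doubled tissue of an overlap is darkest, so
#'   background > blade > overlap is required.
#' @param noise_sigma Standard deviation of the additive Gaussian intensity
#'   noise. Noise is truncated at 3 sigma (then clamped to [0, 255]) so the
#'   rendered class geometry is exactly the constructed label map.
#' @param seed Integer seed for the noise generator.
#' @param canvas Canvas c(height, width) in pixels.
#' @param venation If TRUE, draws thin dark radial venation traces on the
#'   blade (to exercise the binary close step).
#' @return A \code{leaf_spec} list.
#' @export
leaf_spec <- function(n_lobes = 4L, sinus_depth = 0.538,
                      overlap_lobes = integer(), touch_lobes = integer(),
                      gray_levels = c(230L, 140L, 60L),
                      noise_sigma = 3, seed = 1L,
                      canvas = c(320L, 320L), venation = FALSE) {
  if (!(gray_levels[1] > gray_levels[2] && gray_levels[2] > gray_levels[3]))
    stopf("gray levels must satisfy background > blade > overlap")
  if (length(intersect(overlap_lobes, touch_lobes)))
    stopf("overlap_lobes and touch_lobes must be disjoint")
  structure(list(n_lobes = as.integer(n_lobes), sinus_depth = sinus_depth,
                 overlap_lobes = as.integer(overlap_lobes),
                 touch_lobes = as.integer(touch_lobes),
                 gray_levels = as.integer(gray_levels),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 canvas = as.integer(canvas), venation = isTRUE(venation)),
            class = "leaf_spec")
}

#' Preset leaf specifications
#'
#' Four presets mirror the canonical leaf classes: \code{"simple"} (open
#' sinuses only), \code{"tl"} (two sinuses closed by touching lobes),
#' \code{"ol"} (two sinuses closed by overlapping lobes) and \code{"both"}
#' (both kinds at once; its composite mask carries one blade, two overlap
#' outlines, two overlap-closed sinuses and two touch-closed sinuses --
#' seven traceable contours in all).
#'
#' @param name Preset name.
#' @param seed Noise seed.
#' @param ... Further arguments passed to \code{\link{leaf_spec}}.
#' @return A \code{leaf_spec}.
#' @export
leaf_preset <- function(name = c("simple", "tl", "ol", "both"), seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    simple = list(),
    tl     = list(touch_lobes = c(2L, 4L)),
    ol     = list(overlap_lobes = c(1L, 3L)),
    both  = list(overlap_lobes = c(1L, 3L), touch_lobes = c(2L, 4L))
  )
  do.call(leaf_spec, c(args, list(seed = seed), list(...)))
}

# Local feature frames. Axis k in 1:4 points along +x, -y, -x, +y.
# u = outward distance along the axis, v = tangential offset, both in
# pixels relative to the leaf center; the frames are right-handed copies
# of each other so templates are written once.
axis_uv <- function(k, dx, dy) {
  switch(k,
         list(u = dx,  v = dy),
         list(u = -dy, v = dx),
         list(u = -dx, v = -dy),
         list(u = dy,  v = -dx))
}

axis_xy <- function(k, u, v, cx, cy) {
  switch(k,
         c(cx + u, cy + v),
         c(cx + v, cy - u),
         c(cx - u, cy - v),
         c(cx - v, cy + u))
}

# Template geometry constants (local u/v pixel units). The lens is the
# strip where the overlapping lobe tip lies over the flank of the next
# lobe; the bay is the enclosed sinus; the notch stays open to the outer
# background. Walls between white regions of the composite mask are kept
# one pixel thick and axis-aligned so that 8-connected white regions stay
# separated while their boundary vertices remain within the junction
# adjacency distance.
.window_u <- c(60L, 134L)
.window_v <- 45L

feature_labels <- function(u, v, kind) {
  # u, v integer matrices over the window; returns label overrides
  # (NA = keep blade), for one feature in its local frame.
  lab <- matrix(NA_integer_, nrow(u), ncol(u))
  lab[u >= 131L & u <= 134L] <- 0L                        # exit strip
  if (kind == "OL") {
    lab[u >= 127L & u <= 130L & abs(v) <= 18L] <- 0L       # open notch
    # notch corner pixel: puts the wall pixel beside the lens end on the
    # blade's outer ring (edge-adjacent to background, not just diagonal)
    lab[u == 127L & v == 19L] <- 0L
    lab[u >= 64L & u <= 103L & abs(v) <= 18L] <- 3L        # enclosed bay
    lab[u >= 105L & u <= 125L & v >= 19L & v <= 26L] <- 2L # overlap lens
    # bright bay arm alongside the lens edge forming the inner cross-point
    # pinch (bright, so a binary close of the dark class cannot erase it).
    # The stem runs one pixel clear of the lens; only the 3-pixel tooth is
    # within the adjacency distance, so the junction falls mid-edge on
    # straight chain stretches of both rings.
    lab[u == 102L & v >= 19L & v <= 30L] <- 3L             # arm stem
    lab[u == 103L & v >= 24L & v <= 26L] <- 3L             # contact tooth
  } else {
    lab[u >= 106L & u <= 130L & abs(v) <= 18L] <- 0L       # open notch
    lab[u >= 64L & u <= 102L & abs(v) <= 18L] <- 3L        # enclosed bay
    lab[u == 103L & v == 0L] <- 3L                         # sinus tongue
    lab[u == 105L & v == 0L] <- 0L                         # notch tongue
  }
  lab
}

# Ground-truth junctions of one feature, in local coordinates.
feature_junctions <- function(kind) {
  if (kind == "OL") {
    data.frame(kind = c("CROSS", "CROSS"),
               u = c(125.5, 104), v = c(19.5, 25))
  } else {
    data.frame(kind = "TOUCH", u = 103.5, v = 0)
  }
}

#' Generate a synthetic transilluminated leaf image
#'
#' Renders the leaf described by a \code{\link{leaf_spec}} and returns the
#' 8-bit image together with its analytic ground truth: a region label
#' image, the class of every enclosed region, the kind and location of
#' every junction between adjacent contours of the composite mask, and the
#' number of contours the tracing stage is expected to find.
#'
#' @param spec A \code{\link{leaf_spec}}.
#' @return List with elements \code{image} (a \code{gray_image}) and
#'   \code{truth} (list: \code{region_label_image}, \code{region_classes},
#'   \code{junctions} data frame with columns kind/x/y,
#'   \code{expected_contour_count}, \code{seed}).
#' @export
make_leaf <- function(spec) {
  stopifnot(inherits(spec, "leaf_spec"))
  h <- spec$canvas[1L]; w <- spec$canvas[2L]
  features <- length(spec$overlap_lobes) + length(spec$touch_lobes) > 0L
  if (features && spec$n_lobes != 4L)
    stopf("closed-sinus features require the 4-lobe axis-aligned blade model")
  if (features && (h < 300L || w < 300L))
    stopf("canvas %d x %d is too small for closed-sinus features (need >= 300)", h, w)
  if (features && any(c(spec$overlap_lobes, spec$touch_lobes) > 4L))
    stopf("sinus axis indices must be in 1..4")

  # integer center keeps the local feature frames on exact pixel positions
  cx <- floor(w / 2); cy <- floor(h / 2)
  rmax <- 130; d <- spec$sinus_depth
  xs <- matrix(rep(0:(w - 1L), each = h), h, w)
  ys <- matrix(rep(0:(h - 1L), times = w), h, w)
  dx <- xs - cx; dy <- ys - cy
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  rad <- rmax * (1 - d / 2 + (d / 2) * cos(spec$n_lobes * (th - pi / 4)))
  lab <- matrix(0L, h, w)
  lab[r <= rad] <- 1L

  gt_regions <- data.frame(label = integer(), class = character())
  gt_junc <- data.frame(kind = character(), x = numeric(), y = numeric())
  region_img <- lab  # 0 bg, 1 blade; enclosed regions renumbered from 10
  next_region <- 10L
  n_contours <- 1L  # the blade

  all_axes <- c(spec$overlap_lobes, spec$touch_lobes)
  kinds <- c(rep("OL", length(spec$overlap_lobes)),
             rep("TL", length(spec$touch_lobes)))
  for (i in seq_along(all_axes)) {
    k <- all_axes[i]; kind <- kinds[i]
    uv <- axis_uv(k, dx, dy)
    u <- uv$u; v <- uv$v
    inwin <- u >= .window_u[1L] & u <= .window_u[2L] & abs(v) <= .window_v
    # window overrides: blade everywhere, then carve the template
    lab[inwin] <- 1L
    region_img[inwin] <- 1L
    ov <- feature_labels(u, v, kind)
    sel <- inwin & !is.na(ov)
    lab[sel] <- ov[sel]
    region_img[sel] <- ov[sel]
    # number the enclosed regions and record classes
    if (kind == "OL") {
      lens_id <- next_region; bay_id <- next_region + 1L
      region_img[inwin & !is.na(ov) & ov == 2L] <- lens_id
      region_img[inwin & !is.na(ov) & ov == 3L] <- bay_id
      gt_regions <- rbind(gt_regions,
                          data.frame(label = c(lens_id, bay_id),
                                     class = c("OL_OUTLINE", "SINUS")))
      next_region <- next_region + 2L
      n_contours <- n_contours + 2L
    } else {
      bay_id <- next_region
      region_img[inwin & !is.na(ov) & ov == 3L] <- bay_id
      gt_regions <- rbind(gt_regions,
                          data.frame(label = bay_id, class = "SINUS"))
      next_region <- next_region + 1L
      n_contours <- n_contours + 1L
    }
    fj <- feature_junctions(kind)
    for (q in seq_len(nrow(fj))) {
      p <- axis_xy(k, fj$u[q], fj$v[q], cx, cy)
      gt_junc <- rbind(gt_junc,
                       data.frame(kind = fj$kind[q], x = p[1], y = p[2]))
    }
  }

  g <- spec$gray_levels
  img <- matrix(g[1L], h, w)
  img[lab == 1L] <- g[2L]
  img[lab == 2L] <- g[3L]
  # enclosed sinuses are background-bright
  img[lab == 3L] <- g[1L]

  if (spec$venation) {
    # thin dark radial traces toward the lobe apices (diagonals), kept clear
    # of the axis-aligned feature windows
    for (ang in pi / 4 + (0:3) * pi / 2) {
      tt <- seq(0.15, 0.8, length.out = 200)
      px <- round(cx + cos(ang) * tt * rmax)
      py <- round(cy + sin(ang) * tt * rmax)
      ok <- px >= 0 & px < w & py >= 0 & py < h
      idx <- cbind(py[ok] + 1L, px[ok] + 1L)
      on_blade <- lab[idx] == 1L
      img[idx[on_blade, , drop = FALSE]] <- g[3L]
    }
  }

  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    z <- stats::rnorm(h * w, 0, spec$noise_sigma)
    lim <- 3 * spec$noise_sigma
    z[z > lim] <- lim; z[z < -lim] <- -lim
    img <- img + matrix(z, h, w)
  }

  truth <- list(region_label_image = region_img,
                region_classes = gt_regions,
                junctions = gt_junc,
                expected_contour_count = n_contours,
                seed = spec$seed)
  list(image = as_gray_image(img), truth = truth)
}
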