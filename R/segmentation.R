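# Two-level segmentation of transilluminated leaf images.
#
# Overlapping lobes appear as small regions of doubled optical density, so
# a maximum-entropy threshold isolates them (T1); an intermeans threshold
# on the (effectively bimodal) blade/background split captures the whole
# leaf (T2). XOR of the inverted T1 mask with T2 yields a composite in
# which overlap outlines, closed sinuses and the background are distinct
# white areas inside/around the black blade.

image_histogram <- function(image) {
  img <- as_gray_image(image)
  tabulate(as.integer(img) + 1L, nbins = 256L)
}

#' Maximum-entropy threshold (Kapur-Sahoo-Wong)
#'
#' Evaluates, for every candidate threshold t in 0..254 of the 256-bin
#' histogram, the sum of the Shannon entropies of the dark class
#' (intensity <= t) and bright class (> t), each normalized to its own
#' probability mass, and returns the t maximizing the sum. Ties are broken
#' by the smallest t. On a transilluminated leaf this isolates the dark
#' doubled-tissue overlap regions from the rest.
#'
#' @param image A \code{gray_image} (or convertible matrix).
#' @return Integer threshold in [0, 254]; pixels <= t form the dark class.
#' @export
max_entropy_threshold <- function(image) {
  h <- image_histogram(image)
  if (sum(h > 0L) < 2L)
    stopf("degenerate histogram: image has fewer than 2 distinct intensities")
  p <- h / sum(h)
  cum <- cumsum(p)
  # partial entropies: -sum p log p over bins <= t, and total
  plogp <- ifelse(p > 0, p * log(p), 0)
  cum_plogp <- cumsum(plogp)
  tot_plogp <- cum_plogp[256L]
  best_t <- -1L; best_h <- -Inf
  for (t in 0:254) {
    pb <- cum[t + 1L]; pf <- 1 - pb
    if (pb <= 0 || pf <= 0) next
    hb <- -cum_plogp[t + 1L] / pb + log(pb)
    hf <- -(tot_plogp - cum_plogp[t + 1L]) / pf + log(pf)
    crit <- hb + hf
    if (crit > best_h + 1e-12) { best_h <- crit; best_t <- t }
  }
  best_t
}

#' Iterative intermeans (bimodal default) threshold
#'
#' Starting from the midpoint of the occupied intensity range, iterates
#' t <- floor((mean of class <= t + mean of class > t) / 2) to a fixed
#' point. This is the classic automatic threshold for a bimodal histogram;
#' on a transilluminated leaf it separates the blade from the bright
#' background.
#'
#' @param image A \code{gray_image} (or convertible matrix).
#' @return Integer threshold in [0, 254].
#' @export
default_threshold <- function(image) {
  h <- image_histogram(image)
  occ <- which(h > 0L) - 1L
  if (length(occ) < 2L)
    stopf("degenerate histogram: image has fewer than 2 distinct intensities")
  vals <- 0:255
  t <- floor((min(occ) + max(occ)) / 2)
  t <- min(t, max(occ) - 1L)  # both classes non-empty at the start
  seen <- integer(0)
  repeat {
    lo <- vals <= t
    m1 <- sum(vals[lo] * h[lo]) / sum(h[lo])
    m2 <- sum(vals[!lo] * h[!lo]) / sum(h[!lo])
    tn <- floor((m1 + m2) / 2)
    tn <- max(min(occ), min(tn, max(occ) - 1L))
    if (tn == t || tn %in% seen) { t <- tn; break }
    seen <- c(seen, t)
    t <- tn
  }
  as.integer(t)
}

#' Build the T1-inverted and T2 binary masks
#'
#' The T1 mask selects the dark class (intensity <= t1) and is inverted,
#' so its foreground is everything except the overlap regions; the T2 mask
#' selects everything at most t2, i.e. the whole leaf against the bright
#' background.
#'
#' @param image A \code{gray_image}.
#' @param t1 Maximum-entropy threshold in [0, 254].
#' @param t2 Default (bimodal) threshold in [0, 254].
#' @return List with \code{t1_inverted} and \code{t2} binary masks.
#' @export
make_masks <- function(image, t1, t2) {
  img <- as_gray_image(image)
  if (t1 < 0 || t1 > 254 || t2 < 0 || t2 > 254)
    stopf("thresholds must lie in [0, 254] (got t1 = %s, t2 = %s)", t1, t2)
  list(t1_inverted = new_binary_mask(unclass(img) > t1, "T1_INVERTED"),
       t2 = new_binary_mask(unclass(img) <= t2, "T2"))
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a disk structuring element, removing
#' background features (such as thin venation traces in the inverted T1
#' mask) narrower than about twice the radius. Radius 0 is the identity.
#'
#' @param mask A \code{binary_mask}.
#' @param radius Disk radius in pixels.
#' @return Closed \code{binary_mask} with the same role.
#' @export
binary_close <- function(mask, radius = 2) {
  stopifnot(inherits(mask, "binary_mask"))
  if (radius < 0) stopf("radius must be >= 0")
  if (radius == 0) return(mask)
  role <- mask_role(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  closed <- EBImage::closing(unclass(mask) * 1, brush) > 0.5
  new_binary_mask(closed, role)
}

#' XOR composition of the T1-inverted and T2 masks
#'
#' Pixelwise exclusive-or. On a leaf image this produces the composite in
#' which overlap outlines, closed sinuses and the background are white and
#' the blade is black.
#'
#' @param t1_mask,t2_mask Binary masks of equal shape.
#' @return \code{binary_mask} with role COMPOSITE.
#' @export
xor_compose <- function(t1_mask, t2_mask) {
  if (!all(dim(t1_mask) == dim(t2_mask)))
    stopf("mask shapes differ: %s vs %s",
          paste(dim(t1_mask), collapse = "x"), paste(dim(t2_mask), collapse = "x"))
  new_binary_mask(xor(unclass(t1_mask), unclass(t2_mask)), "COMPOSITE")
}

#' Panel of composites under perturbed thresholds
#'
#' Automated thresholds depend on image composition and illumination, so a
#' panel of composites built from slightly varied thresholds (each of t1
#' and t2 scaled by 0.95, 1.00 and 1.05, rounded and clamped to [0, 254])
#' lets the most suitable combination be chosen by eye. Entries are in
#' row-major (f1, f2) order; the center entry is the unperturbed composite.
#'
#' @param image A \code{gray_image}.
#' @param t1,t2 Base thresholds.
#' @return A \code{threshold_panel}: list with \code{entries} (9 items of
#'   f1, f2, t1, t2 and the composite mask) and the base thresholds.
#' @export
threshold_panel <- function(image, t1, t2) {
  img <- as_gray_image(image)
  factors <- c(0.95, 1.00, 1.05)
  entries <- list()
  for (f1 in factors) for (f2 in factors) {
    tt1 <- max(0L, min(254L, as.integer(round(f1 * t1))))
    tt2 <- max(0L, min(254L, as.integer(round(f2 * t2))))
    mk <- make_masks(img, tt1, tt2)
    entries[[length(entries) + 1L]] <-
      list(f1 = f1, f2 = f2, t1 = tt1, t2 = tt2,
           composite = xor_compose(mk$t1_inverted, mk$t2))
  }
  structure(list(entries = entries, t1_value = t1, t2_value = t2),
            class = "threshold_panel")
}

#' @export
print.threshold_panel <- function(x, ...) {
  cat(sprintf("<threshold_panel: %d composites around t1 = %d, t2 = %d>\n",
              length(x$entries), x$t1_value, x$t2_value))
  invisible(x)
}
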