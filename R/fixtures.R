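# Deterministic labeled fixture images with controllable plume, escape
# and necrosis geometry, for exercising the morphometric classifier
# without running simulations.

#' Generate a deterministic labeled fixture image
#'
#' Builds a three-channel raster realizing a requested geometry: a red
#' tumor ellipse, an optional green annulus with optional radial green
#' fingers (plume-like), optional green blobs outside the tumor
#' (escape-like), and an optional central necrotic disc sized to a
#' requested area fraction.
#'
#' @param resolution image side, px
#' @param px_scale um/px (metadata only; geometry is specified in px)
#' @param tumor_axes semi-axes (a, b) of the red tumor ellipse, px
#' @param annulus green annulus \code{c(r_inner, r_outer)} in px, or
#'   \code{NULL} for no green ring
#' @param fingers list with \code{count}, \code{length_px} and optional
#'   \code{width_px} (default 20): radial green fingers starting at the
#'   annulus outer radius (or the tumor edge), equally spaced in angle
#' @param blobs numeric vector of outside-green blob areas, px^2; blobs
#'   are placed along the +x axis beyond the tumor with a gap
#' @param necrotic_fraction requested necrotic area fraction of all
#'   labeled pixels, in [0, 1)
#' @return a \code{labeled_image}
#' @export
generate_fixture_image <- function(resolution = 1000, px_scale = 3,
                                   tumor_axes = c(200, 200),
                                   annulus = NULL, fingers = NULL,
                                   blobs = NULL, necrotic_fraction = 0) {
  if (necrotic_fraction < 0 || necrotic_fraction >= 1)
    stop("`necrotic_fraction` must lie in [0, 1)")
  cx <- resolution / 2; cy <- resolution / 2
  xs <- matrix(rep(seq_len(resolution) - 0.5, each = resolution),
               resolution, resolution)           # col index = x
  ys <- matrix(rep(seq_len(resolution) - 0.5, times = resolution),
               resolution, resolution)           # row index = y
  r2 <- ((xs - cx) / tumor_axes[1])^2 + ((ys - cy) / tumor_axes[2])^2
  rad <- sqrt((xs - cx)^2 + (ys - cy)^2)
  tumor <- r2 <= 1
  green <- matrix(FALSE, resolution, resolution)
  if (!is.null(annulus)) {
    if (annulus[1] >= annulus[2])
      stop("inconsistent annulus: inner radius must be below outer")
    if (annulus[2] > max(tumor_axes))
      stop("inconsistent geometry: annulus extends beyond the tumor")
    green <- green | (rad >= annulus[1] & rad <= annulus[2])
  }
  start_r <- if (!is.null(annulus)) annulus[2] else max(tumor_axes)
  if (!is.null(fingers) && fingers$count > 0) {
    w <- if (is.null(fingers$width_px)) 20 else fingers$width_px
    angles <- seq(0, 2 * pi, length.out = fingers$count + 1)[seq_len(fingers$count)]
    for (a in angles) {
      ux <- cos(a); uy <- sin(a)
      # signed coordinates along/across the ray
      t_par <- (xs - cx) * ux + (ys - cy) * uy
      t_per <- -(xs - cx) * uy + (ys - cy) * ux
      green <- green | (t_par >= start_r - 2 & t_par <= start_r + fingers$length_px &
                          abs(t_per) <= w / 2)
    }
  }
  if (!is.null(blobs)) {
    # blobs go along the -x axis so they never merge with the first
    # finger (drawn along +x)
    gap <- 40
    bx <- max(tumor_axes) + gap
    for (area in blobs) {
      rb <- sqrt(area / pi)
      green <- green | ((xs - (cx - bx - rb))^2 + (ys - cy)^2 <= rb^2)
      bx <- bx + 2 * rb + gap
    }
  }
  necro <- matrix(FALSE, resolution, resolution)
  if (necrotic_fraction > 0) {
    # total labeled area is (tumor union green) plus nothing else;
    # solve the necrotic radius from the requested fraction
    total <- sum(tumor | green)
    rn <- sqrt(necrotic_fraction * total / pi)
    if (rn >= min(tumor_axes))
      stop("inconsistent geometry: necrotic disc exceeds the tumor")
    necro <- rad <= rn
  }
  red <- tumor & !green & !necro
  green <- green & !necro
  labeled_image(red, green, necro, px_scale = px_scale)
}
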