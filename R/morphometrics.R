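# Morphometric Boolean classifier: renders simulation snapshots to
# labeled raster masks and detects invasive plumes, cell escape and a
# necrotic core.
#
# Conventions: masks are logical matrices indexed [row = y, col = x];
# pixel (i, j) has center coordinates (j - 0.5, i - 0.5) in px units.
# The reference pixel thresholds are defined at 3 um/px and are scaled
# proportionally when a different resolution is used.

#' A labeled three-channel raster image
#'
#' @param red,green,necrotic logical matrices of identical shape
#' @param px_scale physical size of one pixel, um/px
#' @return an object of class \code{labeled_image}
#' @export
labeled_image <- function(red, green, necrotic, px_scale = 3) {
  if (!all(dim(red) == dim(green)) || !all(dim(red) == dim(necrotic)))
    stop("channel masks must be congruent in shape")
  structure(list(red = red > 0, green = green > 0, necrotic = necrotic > 0,
                 px_scale = px_scale),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf(
    "labeled_image: %dx%d px at %g um/px; red %d, green %d, necrotic %d px\n",
    nrow(x$red), ncol(x$red), x$px_scale,
    sum(x$red), sum(x$green), sum(x$necrotic)))
  invisible(x)
}

#' Classifier thresholds
#'
#' Defaults are the reference values at a resolution of
#' 3 um/px: plume tolerance 30 px, escape area 20 px^2, necrotic area
#' fraction 0.06.
#'
#' @param eps_P plume tolerance: maximum vertex-to-ellipse distance, px
#' @param eps_S escape tolerance: summed outside-green area, px^2
#' @param eps_N necrotic-core tolerance: area fraction, dimensionless
#' @param ref_px_scale resolution the pixel thresholds refer to, um/px
#' @return an object of class \code{morphometric_thresholds}
#' @export
morphometric_thresholds <- function(eps_P = 30, eps_S = 20, eps_N = 0.06,
                                    ref_px_scale = 3) {
  if (eps_P <= 0 || eps_S <= 0 || eps_N <= 0) stop("thresholds must be > 0")
  structure(list(eps_P = eps_P, eps_S = eps_S, eps_N = eps_N,
                 ref_px_scale = ref_px_scale),
            class = "morphometric_thresholds")
}

# rescale pixel thresholds to the image's own px scale
.scaled_thresholds <- function(th, px_scale) {
  f <- th$ref_px_scale / px_scale
  list(eps_P = th$eps_P * f, eps_S = th$eps_S * f^2, eps_N = th$eps_N)
}

#' Render a cell snapshot to a labeled raster image
#'
#' Each viable cell is drawn as a filled disc of its radius: GFP-switched
#' cells into the green channel, unswitched into the red channel;
#' necrotic cells into the necrotic channel.
#'
#' @param cells data frame with columns \code{x_um}, \code{y_um},
#'   \code{state} (\code{3} or \code{"necrotic"} = necrotic) and
#'   \code{switched} (1 = GFP)
#' @param domain_um physical domain side, um
#' @param resolution image side, px (>= 100)
#' @param cell_radius cell radius, um
#' @return a \code{labeled_image} with \code{px_scale = domain_um /
#'   resolution}
#' @export
render_snapshot <- function(cells, domain_um, resolution = round(domain_um / 3),
                            cell_radius = 8.412) {
  if (resolution < 100) stop("`resolution` must be at least 100 px")
  px <- domain_um / resolution
  red <- matrix(FALSE, resolution, resolution)
  green <- matrix(FALSE, resolution, resolution)
  necro <- matrix(FALSE, resolution, resolution)
  if (nrow(cells) > 0) {
    r_px <- cell_radius / px
    ro <- ceiling(r_px)
    off <- expand.grid(di = -ro:ro, dj = -ro:ro)
    off <- off[off$di^2 + off$dj^2 <= r_px^2, ]
    necrotic <- cells$state == 3 | cells$state == "necrotic"
    switched <- as.logical(cells$switched)
    ci <- as.integer(cells$y_um / px) + 1L
    cj <- as.integer(cells$x_um / px) + 1L
    for (k in seq_len(nrow(cells))) {
      ii <- ci[k] + off$di; jj <- cj[k] + off$dj
      ok <- ii >= 1 & ii <= resolution & jj >= 1 & jj <= resolution
      idx <- cbind(ii[ok], jj[ok])
      if (necrotic[k]) necro[idx] <- TRUE
      else if (switched[k]) green[idx] <- TRUE
      else red[idx] <- TRUE
    }
  }
  labeled_image(red, green, necro, px_scale = px)
}

#' Write / read a labeled image as a 3-channel PNG
#'
#' Channel mapping: red mask to R, green to G, necrotic to B.
#'
#' @param image a \code{labeled_image}
#' @param path file path
#' @param px_scale um/px used when reading (PNG carries no scale)
#' @export
write_labeled_image <- function(image, path) {
  stopifnot(inherits(image, "labeled_image"))
  arr <- array(0, c(nrow(image$red), ncol(image$red), 3))
  arr[, , 1] <- image$red
  arr[, , 2] <- image$green
  arr[, , 3] <- image$necrotic
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname write_labeled_image
#' @export
read_labeled_image <- function(path, px_scale = 3) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3 || dim(arr)[3] < 3)
    stop("expected a 3-channel PNG")
  labeled_image(arr[, , 1] > 0.5, arr[, , 2] > 0.5, arr[, , 3] > 0.5,
                px_scale = px_scale)
}

# ---- ellipse utilities ---------------------------------------------------

# Direct least-squares conic (ellipse) fit; points as two-column matrix
# of (x, y).  Returns list(cx, cy, a, b, theta) or NULL when degenerate.
.fit_ellipse <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y), 1e-9)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) return(NULL)
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  k <- which(cond > 1e-12)
  if (length(k) == 0) return(NULL)
  a1 <- evec[, k[1]]
  coef <- c(a1, T1 %*% a1) # A B C D E F in scaled frame
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; Fc <- coef[6]
  den <- B^2 - 4 * A * C
  if (abs(den) < 1e-14) return(NULL)
  cx0 <- (2 * C * D - B * E) / den
  cy0 <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + Fc * B^2 - B * D * E - 4 * A * C * Fc)
  s1 <- A + C; s2 <- sqrt((A - C)^2 + B^2)
  ax2 <- num / (den * (s2 - s1)); bx2 <- num / (den * (-s2 - s1))
  if (!is.finite(ax2) || !is.finite(bx2) || ax2 <= 0 || bx2 <= 0) return(NULL)
  theta <- 0.5 * atan2(B, A - C)
  list(cx = cx0 * sc + mx, cy = cy0 * sc + my,
       a = sqrt(ax2) * sc, b = sqrt(bx2) * sc, theta = theta)
}

# fallback: circle through centroid and rms radius
.fit_circle <- function(pts) {
  cx <- mean(pts[, 1]); cy <- mean(pts[, 2])
  r <- sqrt(mean((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2))
  list(cx = cx, cy = cy, a = r, b = r, theta = 0)
}

.ellipse_points <- function(el, n = 1440) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ct <- cos(el$theta); st <- sin(el$theta)
  xx <- el$a * cos(t); yy <- el$b * sin(t)
  cbind(el$cx + xx * ct - yy * st, el$cy + xx * st + yy * ct)
}

# unsigned distance from points (m x 2) to the ellipse outline
.dist_to_ellipse <- function(pts, el, n = 1440) {
  ep <- .ellipse_points(el, n)
  apply(pts, 1, function(p) sqrt(min((ep[, 1] - p[1])^2 + (ep[, 2] - p[2])^2)))
}

.inside_ellipse <- function(pts, el) {
  ct <- cos(el$theta); st <- sin(el$theta)
  dx <- pts[, 1] - el$cx; dy <- pts[, 2] - el$cy
  u <- dx * ct + dy * st; v <- -dx * st + dy * ct
  (u / el$a)^2 + (v / el$b)^2 <= 1
}

# periodic moving-average smoothing of a closed contour (m x 2), window
# in points (contour points are ~1 px apart)
.smooth_contour <- function(contour, window = 21) {
  m <- nrow(contour)
  if (m <= window) return(contour)
  half <- window %/% 2
  idx <- c((m - half + 1):m, 1:m, 1:half)
  xs <- stats::filter(contour[idx, 1], rep(1 / window, window), sides = 2)
  ys <- stats::filter(contour[idx, 2], rep(1 / window, window), sides = 2)
  cbind(xs[(half + 1):(half + m)], ys[(half + 1):(half + m)])
}

# largest connected component of a mask (by area), after a morphological
# closing (fuses the single-cell speckle of rendered snapshots into a
# coherent cluster) and opening (suppresses isolated speckle); returns
# list(mask, contour (m x 2 px coords))
.largest_component_contour <- function(mask, open_px = 3, close_px = 5) {
  img <- EBImage::Image(t(mask) * 1) # EBImage is column-major x, y
  if (close_px > 0)
    img <- EBImage::closing(img, EBImage::makeBrush(close_px, shape = "disc"))
  if (open_px > 0)
    img <- EBImage::opening(img, EBImage::makeBrush(open_px, shape = "disc"))
  lab <- EBImage::bwlabel(img)
  n_obj <- max(lab)
  if (n_obj < 1) return(NULL)
  areas <- tabulate(as.integer(lab[lab > 0]), nbins = n_obj)
  biggest <- which.max(areas)
  oc <- EBImage::ocontour(lab == biggest)
  if (length(oc) == 0) return(NULL)
  contour <- oc[[1]] # (x, y) pixel coordinates, ordered along boundary
  list(mask = t(EBImage::imageData(lab) == biggest), contour = contour)
}

# ---- the three tests -----------------------------------------------------

#' Detect invasive plumes in the green channel
#'
#' Extracts the largest connected green cluster (after a morphological
#' closing and opening that fuse single-cell speckle and suppress
#' isolated specks), fits its outer contour by a least-squares ellipse
#' \code{E_G}, and represents the contour by a closed piecewise curve
#' \code{F_G}: a periodic local-mean smoothing of the contour in
#' arc-length order, with vertices subsampled every
#' \code{vertex_spacing_px} along it.  A plume is declared when the
#' largest vertex-to-ellipse distance over vertices lying outside
#' \code{E_G} exceeds \code{eps_P} (plumes are outward protrusions;
#' inward notches of a ragged ring do not count).
#'
#' @param image a \code{labeled_image}
#' @param eps_P plume tolerance in px at the reference resolution
#'   (3 um/px); rescaled to the image's own resolution
#' @param vertex_spacing_px approximate arc spacing of \code{F_G}
#'   vertices, px
#' @return list: \code{plume} (logical), \code{d_max} (px), and
#'   \code{ellipse}
#' @export
detect_plumes <- function(image, eps_P = 30, vertex_spacing_px = 10) {
  stopifnot(inherits(image, "labeled_image"))
  sc <- .scaled_thresholds(
    morphometric_thresholds(eps_P = eps_P), image$px_scale)
  if (!any(image$green)) return(list(plume = FALSE, d_max = 0, ellipse = NULL))
  comp <- .largest_component_contour(image$green)
  if (is.null(comp) || nrow(comp$contour) < 6)
    return(list(plume = FALSE, d_max = 0, ellipse = NULL))
  contour <- .smooth_contour(comp$contour)
  el <- .fit_ellipse(contour)
  if (is.null(el)) el <- .fit_circle(contour)
  step <- max(1L, as.integer(round(vertex_spacing_px)))
  verts <- contour[seq(1, nrow(contour), by = step), , drop = FALSE]
  # plumes are outward protrusions: only vertices outside E_G count
  # (inward notches of a ragged ring are not invasive structures)
  outside <- !.inside_ellipse(verts, el)
  d_max <- if (any(outside))
    max(.dist_to_ellipse(verts[outside, , drop = FALSE], el)) else 0
  list(plume = d_max > sc$eps_P, d_max = d_max, ellipse = el)
}

#' Detect escape of green cells from the tumor bulk
#'
#' Fits an ellipse \code{E_T} to the convex hull of all tumor pixels
#' (red, green and necrotic) and sums the areas of green connected
#' components whose centroid lies outside \code{E_T}.  Escape is declared
#' when the summed area exceeds \code{eps_S}.
#'
#' @param image a \code{labeled_image}
#' @param eps_S escape tolerance in px^2 at the reference resolution
#' @return list: \code{escape} (logical), \code{A} (summed outside area,
#'   px^2), \code{ellipse}
#' @export
detect_escape <- function(image, eps_S = 20) {
  stopifnot(inherits(image, "labeled_image"))
  sc <- .scaled_thresholds(
    morphometric_thresholds(eps_S = eps_S), image$px_scale)
  tumor <- image$red | image$green | image$necrotic
  if (!any(tumor)) stop("empty tumor: no red, green or necrotic pixels")
  idx <- which(tumor, arr.ind = TRUE)
  pts <- cbind(idx[, 2] - 0.5, idx[, 1] - 0.5) # (x, y)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  # densify hull edges so the conic fit is well conditioned
  dense <- do.call(rbind, lapply(seq_len(nrow(hull)), function(k) {
    p <- hull[k, ]; q <- hull[if (k == nrow(hull)) 1 else k + 1, ]
    tt <- seq(0, 1, length.out = 20)[-20]
    cbind(p[1] + tt * (q[1] - p[1]), p[2] + tt * (q[2] - p[2]))
  }))
  el <- .fit_ellipse(dense)
  if (is.null(el)) el <- .fit_circle(dense)
  if (!any(image$green)) return(list(escape = FALSE, A = 0, ellipse = el))
  lab <- EBImage::bwlabel(EBImage::Image(t(image$green) * 1))
  n_obj <- max(lab)
  if (n_obj < 1) return(list(escape = FALSE, A = 0, ellipse = el))
  labm <- t(EBImage::imageData(lab))
  A <- 0
  for (o in seq_len(n_obj)) {
    w <- which(labm == o, arr.ind = TRUE)
    centroid <- c(mean(w[, 2]) - 0.5, mean(w[, 1]) - 0.5)
    if (!.inside_ellipse(rbind(centroid), el)) A <- A + nrow(w)
  }
  list(escape = A > sc$eps_S, A = A, ellipse = el)
}

#' Detect a necrotic core
#'
#' The necrotic area fraction \code{F_N} is the necrotic pixel count over
#' all tumor pixels (red + green + necrotic); a core is declared when
#' \code{F_N} strictly exceeds \code{eps_N}.
#'
#' @param image a \code{labeled_image}
#' @param eps_N area-fraction tolerance
#' @return list: \code{necrotic_core} (logical), \code{F_N}
#' @export
detect_necrotic_core <- function(image, eps_N = 0.06) {
  stopifnot(inherits(image, "labeled_image"))
  total <- sum(image$red) + sum(image$green) + sum(image$necrotic)
  if (total == 0) stop("empty tumor: no red, green or necrotic pixels")
  F_N <- sum(image$necrotic) / total
  list(necrotic_core = F_N > eps_N, F_N = F_N)
}

#' Boolean morphometric classification of a labeled image
#'
#' Composition of the plume, escape and necrotic-core tests.
#'
#' @param image a \code{labeled_image}
#' @param thresholds a [morphometric_thresholds()]
#' @return an object of class \code{morphometric_report}: logicals
#'   \code{plume}, \code{escape}, \code{necrotic_core} and the measured
#'   quantities \code{d_max} (px), \code{A} (px^2), \code{F_N}
#' @export
classify <- function(image, thresholds = morphometric_thresholds()) {
  stopifnot(inherits(image, "labeled_image"),
            inherits(thresholds, "morphometric_thresholds"))
  p <- detect_plumes(image, thresholds$eps_P)
  e <- detect_escape(image, thresholds$eps_S)
  n <- detect_necrotic_core(image, thresholds$eps_N)
  structure(list(plume = p$plume, escape = e$escape,
                 necrotic_core = n$necrotic_core,
                 d_max = p$d_max, A = e$A, F_N = n$F_N,
                 thresholds = thresholds),
            class = "morphometric_report")
}

#' @export
print.morphometric_report <- function(x, ...) {
  cat(sprintf(
    "morphometric_report: plume=%s (d_max %.1f px), escape=%s (A %.0f px^2), necrotic_core=%s (F_N %.3f)\n",
    x$plume, x$d_max, x$escape, x$A, x$necrotic_core, x$F_N))
  invisible(x)
}
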