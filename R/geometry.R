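#' Curvature profile of an elliptical embryo contour
#'
#' Arc-length-parameterized signed curvature of an ellipse with the given
#' semi-axes. Position 0 is one pole of the long axis (the anterior pole in
#' simulations); half the circumference is the opposite pole. Curvature is
#' maximal (`a/b^2`) at the poles and minimal (`b/a^2`) at the lateral
#' midpoints; the lateral minimum is the baseline against which excess
#' curvature is measured.
#'
#' @param semi_major,semi_minor semi-axes, um (`semi_major >= semi_minor`).
#' @param n number of equally spaced arc-length grid points (>= 16).
#' @return A tibble of class `curvature_profile` with columns `position`
#'   (um) and `curvature` (1/um), and attributes `baseline` and
#'   `circumference`.
#' @examples
#' ellipse_curvature(25, 15, 256)
#' @export
ellipse_curvature <- function(semi_major, semi_minor, n = 256) {
  if (n < 16) stop("need at least 16 grid points", call. = FALSE)
  if (!(semi_major >= semi_minor && semi_minor > 0)) {
    stop("require semi_major >= semi_minor > 0", call. = FALSE)
  }
  a <- semi_major
  b <- semi_minor
  # dense parameter grid, arc length by trapezoidal integration
  m <- 8192
  th <- seq(0, 2 * pi, length.out = m + 1)
  sp <- sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2) # |d(x,y)/dtheta|
  ds <- (th[2] - th[1]) * (sp[-1] + sp[-(m + 1)]) / 2
  s <- c(0, cumsum(ds))
  L <- s[m + 1]
  s_grid <- seq(0, L, length.out = n + 1)[1:n]
  th_grid <- approx(s, th, xout = s_grid, ties = "ordered")$y
  kappa <- a * b / (a^2 * sin(th_grid)^2 + b^2 * cos(th_grid)^2)^1.5
  new_curvature_profile(s_grid, kappa, baseline = b / a^2, circumference = L)
}

#' Curvature profile of a rounded equilateral triangle contour
#'
#' Models an embryo squeezed into a triangular microchamber: zero curvature
#' along the flat sides and curvature `1/r` along the three rounded-corner
#' arcs, each subtending 2*pi/3. `corner_radius` may be a single value
#' (three identical corners) or a vector of three radii, which emulates the
#' unequal squeezing of a real embryo whose sharpest-pressed corner carries
#' the highest curvature. Position 0 is the middle of the first corner arc.
#'
#' @param side side length of the triangle, um.
#' @param corner_radius corner rounding radius (um), scalar or length-3.
#' @param n number of equally spaced arc-length grid points (>= 16).
#' @return A `curvature_profile` tibble (baseline 0 on the flat sides).
#' @examples
#' triangle_curvature(40, 5, 256)
#' @export
triangle_curvature <- function(side, corner_radius, n = 256) {
  if (n < 16) stop("need at least 16 grid points", call. = FALSE)
  r <- rep_len(corner_radius, 3)
  if (any(r <= 0)) stop("corner radii must be positive", call. = FALSE)
  # tangent length cut from each side end is r*tan(60 deg) = r*sqrt(3)
  flats <- c(
    side - sqrt(3) * (r[1] + r[2]),
    side - sqrt(3) * (r[2] + r[3]),
    side - sqrt(3) * (r[3] + r[1])
  )
  if (any(flats <= 0)) {
    stop("corner rounding too large for this side length", call. = FALSE)
  }
  arcs <- r * 2 * pi / 3
  # walk the contour: half arc 1, flat 1-2, arc 2, flat 2-3, arc 3, flat 3-1,
  # half arc 1 (wrap). curvature is piecewise constant in arc length.
  seg_len <- c(arcs[1] / 2, flats[1], arcs[2], flats[2], arcs[3], flats[3], arcs[1] / 2)
  seg_cur <- c(1 / r[1], 0, 1 / r[2], 0, 1 / r[3], 0, 1 / r[1])
  L <- sum(seg_len)
  s_grid <- seq(0, L, length.out = n + 1)[1:n]
  edges <- cumsum(seg_len)
  idx <- findInterval(s_grid, c(0, edges), rightmost.closed = TRUE)
  idx[idx > length(seg_cur)] <- length(seg_cur)
  kappa <- seg_cur[idx]
  new_curvature_profile(s_grid, kappa, baseline = 0, circumference = L)
}

#' Curvature profile of an embryo squeezed into a triangular chamber
#'
#' Cortex contour of an embryo pressed into a triangular microchamber: the
#' cortex contacts the three corners over narrow arcs, where its curvature
#' peaks, and bulges gently along the chamber walls in between. The profile
#' is a baseline curvature plus three Gaussian curvature peaks; the
#' baseline is fixed by closure (total turning of a convex closed contour
#' is 2*pi) and serves as the central-cortex reference for excess
#' curvature. This is the contour an embryo itself adopts in the chamber,
#' as opposed to [triangle_curvature()], which describes the rigid chamber
#' wall.
#'
#' @param perimeter cortex perimeter, um.
#' @param peak_excess excess curvature of the three corner-contact peaks
#'   over the baseline, 1/um. Slightly unequal defaults reflect the
#'   unequal corner contact of a real squeezed embryo, whose most curved
#'   corner is the observed preferred domain site.
#' @param peak_width Gaussian width of each contact arc, um.
#' @param n number of equally spaced arc-length grid points (>= 16).
#' @return A `curvature_profile` tibble; baseline equals the side-bulge
#'   curvature.
#' @export
embryo_triangle_curvature <- function(perimeter = 110,
                                      peak_excess = c(0.140, 0.130, 0.119),
                                      peak_width = 3, n = 256) {
  if (n < 16) stop("need at least 16 grid points", call. = FALSE)
  stopifnot(length(peak_excess) == 3, all(peak_excess > 0), peak_width > 0)
  L <- perimeter
  x <- seq(0, L, length.out = n + 1)[seq_len(n)]
  centers <- c(0, L / 3, 2 * L / 3)
  excess <- rep(0, n)
  for (i in 1:3) {
    excess <- excess +
      peak_excess[i] * exp(-circ_dist(x, centers[i], L)^2 / (2 * peak_width^2))
  }
  base <- (2 * pi - sum(excess) * L / n) / L
  if (base <= 0) {
    stop("curvature peaks too strong for a convex closed contour", call. = FALSE)
  }
  new_curvature_profile(x, base + excess, baseline = base, circumference = L)
}

new_curvature_profile <- function(position, curvature, baseline, circumference) {
  out <- tibble::tibble(position = position, curvature = curvature)
  attr(out, "baseline") <- baseline
  attr(out, "circumference") <- circumference
  class(out) <- c("curvature_profile", class(out))
  out
}

#' Spatially varying posterior attachment rate from curvature
#'
#' The posterior species' membrane attachment rate is enhanced by `alpha`
#' times the excess curvature over the baseline (central-cortex) curvature;
#' the excess is clamped at zero, so flat or concave regions keep the base
#' rate.
#'
#' @param curv a [ellipse_curvature()] / [triangle_curvature()] profile.
#' @param kon_P base attachment rate, um/s.
#' @param alpha attachment gain per unit excess curvature, um^2/s.
#' @return A tibble with columns `position` and `kon_P`.
#' @export
attachment_profile <- function(curv, kon_P, alpha) {
  stopifnot(inherits(curv, "curvature_profile"), alpha >= 0, kon_P >= 0)
  base <- attr(curv, "baseline")
  tibble::tibble(
    position = curv$position,
    kon_P = kon_P + alpha * pmax(curv$curvature - base, 0)
  )
}
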