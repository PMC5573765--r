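#' Vessel centreline
#'
#' An ordered polyline of centreline points with the per-point
#' maximum-inscribed-sphere radius, the post-processing product of vessel
#' reconstruction from which sectional radii, curvature and Dean numbers are
#' derived.
#'
#' @param points Numeric `n x 3` matrix of coordinates, m (n >= 4,
#'   consecutive points distinct).
#' @param radius Per-point inscribed-sphere radius, m (> 0).
#' @return An object of class `centreline`.
#' @export
centreline <- function(points, radius) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 4L,
            length(radius) == nrow(points), all(radius > 0))
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive centreline points must be distinct")
  structure(list(points = points, radius = as.numeric(radius)),
            class = "centreline")
}

#' @export
print.centreline <- function(x, ...) {
  cat(sprintf("Centreline: %d points, arclength %.4g m, radius [%.3g, %.3g] m\n",
              nrow(x$points), sum(arc_lengths(x)), min(x$radius),
              max(x$radius)))
  invisible(x)
}

# per-segment lengths
arc_lengths <- function(c) {
  p <- c$points
  sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
}

# cumulative arclength from the first point
cum_arclength <- function(c) c(0, cumsum(arc_lengths(c)))

#' Resample a centreline uniformly in arclength
#'
#' Linear interpolation of points and radii onto `n` arclength-uniform
#' stations; total arclength of the polyline is preserved (up to the
#' piecewise-linear representation).
#'
#' @param c A [centreline()].
#' @param n Number of output points (>= 4).
#' @return A [centreline()] with `n` points.
#' @export
resample_centreline <- function(c, n) {
  stopifnot(inherits(c, "centreline"), n >= 4L)
  s <- cum_arclength(c)
  total <- s[length(s)]
  if (total <= 0) stop("degenerate centreline with zero length")
  so <- seq(0, total, length.out = n)
  pts <- vapply(1:3, function(j) approx(s, c$points[, j], xout = so)$y,
                numeric(n))
  rad <- approx(s, c$radius, xout = so)$y
  centreline(pts, rad)
}

#' Discrete curvature of a centreline
#'
#' Frenet curvature magnitude by finite differences of unit tangents with
#' respect to arclength; endpoint values are copied from their neighbours.
#' Best applied to an arclength-resampled, smooth centreline.
#'
#' @param c A [centreline()].
#' @return Nonnegative per-point curvature, 1/m.
#' @export
curvature <- function(c) {
  stopifnot(inherits(c, "centreline"))
  p <- c$points
  n <- nrow(p)
  seg <- p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  tang <- seg / len  # unit tangent per segment
  # dT/ds at interior points: difference of adjacent segment tangents over
  # the mean of their lengths
  dT <- tang[-1L, , drop = FALSE] - tang[-(n - 1L), , drop = FALSE]
  ds <- (len[-1L] + len[-(n - 1L)]) / 2
  kap_int <- sqrt(rowSums(dT^2)) / ds
  c(kap_int[1L], kap_int, kap_int[length(kap_int)])
}

#' Dean number
#'
#' \deqn{De = Re \sqrt{\kappa_A D_A / 2},} characterizing secondary-flow
#' strength in a curved tube of local curvature `kappa_A` and diameter
#' `D_A` at Reynolds number `Re`. The critical value for multiple unsteady
#' vortices in a planar curved tube is around 900.
#'
#' @param Re Reynolds number (>= 0).
#' @param kappa_A Local centreline curvature, 1/m (>= 0; vectorized).
#' @param D_A Local lumen diameter, m (>= 0; vectorized).
#' @return Dean number(s).
#' @export
dean_number <- function(Re, kappa_A, D_A) {
  stopifnot(all(Re >= 0), all(kappa_A >= 0), all(D_A >= 0))
  Re * sqrt(kappa_A * D_A / 2)
}

#' Section-averaged centreline radii
#'
#' Splits the centreline into `n_sections` equisized arclength sections,
#' replaces each point's radius by its section's mean radius (the smoothing
#' applied before lofting an idealized vessel surface), and exposes a smooth
#' monotone-cubic interpolation through the section midpoints as the
#' `smooth` attribute (a function of arclength).
#'
#' @param c A [centreline()].
#' @param n_sections Number of equisized sections (>= 1; default 5).
#' @return A [centreline()] with sectionally averaged radii; attribute
#'   `section_means` (numeric) and attribute `smooth` (function s -> radius).
#' @export
section_average_radii <- function(c, n_sections = 5L) {
  stopifnot(inherits(c, "centreline"), n_sections >= 1L)
  s <- cum_arclength(c)
  total <- s[length(s)]
  # assign each point to a section by arclength
  sec <- pmin(floor(s / total * n_sections) + 1L, n_sections)
  means <- vapply(seq_len(n_sections),
                  function(j) mean(c$radius[sec == j]), numeric(1L))
  out <- centreline(c$points, means[sec])
  mid <- (seq_len(n_sections) - 0.5) / n_sections * total
  sm <- if (n_sections == 1L) {
    function(x) rep(means, length(x))
  } else {
    splinefun(mid, means, method = "monoH.FC")
  }
  attr(out, "section_means") <- means
  attr(out, "smooth") <- sm
  out
}

#' Anastomosis specification
#'
#' Geometric parameters of the vein-to-artery connection: the anastomosis
#' angle with the local arterial centreline (default 35 degrees), the
#' vein-to-artery diameter ratio (default 1) and the side of the arterial
#' bend the vein joins.
#'
#' @param angle Anastomosis angle, degrees, in (0, 90).
#' @param vein_to_artery_diameter_ratio Positive ratio.
#' @param side `"inner"` or `"outer"` curvature of the arterial bend.
#' @return An object of class `anastomosis_spec`.
#' @export
anastomosis_spec <- function(angle = 35, vein_to_artery_diameter_ratio = 1,
                             side = c("inner", "outer")) {
  stopifnot(angle > 0, angle < 90, vein_to_artery_diameter_ratio > 0)
  side <- match.arg(side)
  structure(list(angle = angle,
                 vein_to_artery_diameter_ratio = vein_to_artery_diameter_ratio,
                 side = side),
            class = "anastomosis_spec")
}
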