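#' Maximum-likelihood standard ellipse for a bivariate isotope cloud
#'
#' Fits the standard ellipse of a set of (delta13C, delta15N) points: the
#' 1-SD contour of the bivariate normal with the sample mean and covariance.
#' Its area is \eqn{SEA = \pi \sqrt{\det \Sigma}}; the small-sample corrected
#' area is \eqn{SEAc = SEA \, (n-1)/(n-2)}.
#'
#' @param points A two-column matrix or data frame, columns (delta13C, delta15N)
#'   in per mil; at least 3 non-collinear rows.
#' @return An object of class `niche_ellipse`: list with `mu` (2-vector),
#'   `sigma` (2x2 sample covariance, n-1 denominator), `n`, `sea`, `seac`
#'   (per mil squared).
#' @export
fit_standard_ellipse <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("points must have two columns", call. = FALSE)
  if (!all(is.finite(pts))) stop("points must be finite", call. = FALSE)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points to fit an ellipse", call. = FALSE)
  mu <- colMeans(pts)
  sigma <- stats::cov(pts)
  det_s <- det(sigma)
  if (!is.finite(det_s) || det_s <= .Machine$double.eps * sum(diag(sigma))^2) {
    stop("degenerate geometry: points are (near-)collinear", call. = FALSE)
  }
  sea <- pi * sqrt(det_s)
  structure(list(mu = mu, sigma = sigma, n = n, sea = sea,
                 seac = sea * (n - 1) / (n - 2)),
            class = "niche_ellipse")
}

#' @export
print.niche_ellipse <- function(x, ...) {
  cat(sprintf("niche_ellipse: n = %d, mu = (%.3f, %.3f), SEA = %.4f, SEAc = %.4f\n",
              x$n, x$mu[1], x$mu[2], x$sea, x$seac))
  invisible(x)
}

# signed area of a polygon by the shoelace formula; positive when CCW
shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Convex-hull total area (TA)
#'
#' Area of the convex hull of a bivariate isotope cloud, the maximal-extent
#' niche metric. Fewer than 3 unique non-collinear points give area 0 with the
#' degenerate flag set.
#'
#' @param points A two-column matrix or data frame of isotope values.
#' @return A list of class `hull_area`: `vertices` (counter-clockwise), `area`
#'   (per mil squared), `degenerate` (logical).
#' @export
total_area <- function(points) {
  pts <- unique(as.matrix(points))
  if (ncol(pts) != 2 || !all(is.finite(pts))) {
    stop("points must be a finite two-column set", call. = FALSE)
  }
  if (nrow(pts) < 3) {
    return(structure(list(vertices = pts, area = 0, degenerate = TRUE),
                     class = "hull_area"))
  }
  idx <- grDevices::chull(pts)          # clockwise order
  verts <- pts[rev(idx), , drop = FALSE] # counter-clockwise
  area <- shoelace_area(verts)
  structure(list(vertices = verts, area = abs(area),
                 degenerate = abs(area) < .Machine$double.eps),
            class = "hull_area")
}

#' Polygonal discretization of a niche ellipse boundary
#'
#' Returns `m` points on the ellipse boundary, either the 1-SD standard
#' ellipse (`scale = "standard"`, area SEA) or the ellipse inflated so its area
#' equals SEAc (`scale = "seac"`). The inscribed polygon's area converges to
#' the ellipse area from below as `m` grows.
#'
#' @param e A [fit_standard_ellipse()] result.
#' @param m Number of vertices, >= 16.
#' @param scale `"standard"` or `"seac"`.
#' @return An `m` x 2 matrix of boundary points (counter-clockwise).
#' @export
ellipse_boundary_polygon <- function(e, m = 1024, scale = c("seac", "standard")) {
  stopifnot(inherits(e, "niche_ellipse"))
  scale <- match.arg(scale)
  if (m < 16) stop("m must be >= 16", call. = FALSE)
  eig <- eigen(e$sigma, symmetric = TRUE)
  if (min(eig$values) <= 0) {
    stop("degenerate geometry: singular covariance", call. = FALSE)
  }
  infl <- if (scale == "seac") sqrt(e$seac / e$sea) else 1
  theta <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  circ <- rbind(cos(theta), sin(theta))
  pts <- t(eig$vectors %*% (sqrt(eig$values) * infl * circ)) # axes scaled
  sweep(pts, 2, e$mu, "+")
}

# Sutherland-Hodgman clipping of a convex subject polygon against a convex
# clip polygon; both counter-clockwise. Returns the intersection polygon
# (possibly with 0 rows).
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]
    b <- clip[if (i == nc) 1 else i + 1, ]
    # inside = left of directed edge a->b for CCW clip polygon
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    input <- out
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(input)
    s_prev <- side(input[n, ])
    prev <- input[n, ]
    for (j in seq_len(n)) {
      cur <- input[j, ]
      s_cur <- side(cur)
      if (s_cur >= 0) {
        if (s_prev < 0) {
          t <- s_prev / (s_prev - s_cur)
          out <- rbind(out, prev + t * (cur - prev))
        }
        out <- rbind(out, cur)
      } else if (s_prev >= 0) {
        t <- s_prev / (s_prev - s_cur)
        out <- rbind(out, prev + t * (cur - prev))
      }
      prev <- cur
      s_prev <- s_cur
    }
  }
  out
}

#' Overlap between two niche ellipses
#'
#' Intersects the SEAc-equivalent (or 1-SD) boundary polygons of two ellipses
#' by convex polygon clipping and reports the shared area and the shared
#' proportions under the three denominator conventions: the union of the two
#' areas (`prop_union`, the headline number), and each ellipse's own area
#' (`prop_a`, `prop_b`).
#'
#' @param a,b [fit_standard_ellipse()] results.
#' @param m Vertices per boundary polygon (default 1024).
#' @param scale Passed to [ellipse_boundary_polygon()].
#' @return A list of class `overlap_result`: `overlap_area`, `area_a`,
#'   `area_b`, `prop_union`, `prop_a`, `prop_b`.
#' @export
ellipse_overlap <- function(a, b, m = 1024, scale = c("seac", "standard")) {
  scale <- match.arg(scale)
  pa <- ellipse_boundary_polygon(a, m, scale)
  pb <- ellipse_boundary_polygon(b, m, scale)
  area_a <- abs(shoelace_area(pa))
  area_b <- abs(shoelace_area(pb))
  inter <- clip_convex(pa, pb)
  overlap <- if (nrow(inter) >= 3) abs(shoelace_area(inter)) else 0
  overlap <- min(overlap, area_a, area_b)
  structure(list(overlap_area = overlap, area_a = area_a, area_b = area_b,
                 prop_union = overlap / (area_a + area_b - overlap),
                 prop_a = overlap / area_a, prop_b = overlap / area_b),
            class = "overlap_result")
}
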