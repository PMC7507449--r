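## Polygon and mask utilities.
##
## Convention used throughout: image pixels live on a grid with 0-based
## centre coordinates, x = column - 1, y = row - 1.  Polygons are
## two-column matrices (x, y) of vertices at pixel-centre coordinates and
## are implicitly closed.  Containment is the even-odd (crossing-number)
## rule evaluated at pixel centres, which makes masks bit-stable across
## platforms.

#' Rasterize a polygon to a logical pixel mask
#'
#' Evaluates the even-odd containment rule at every pixel centre of an
#' \code{dim[1] x dim[2]} image (rows x columns, 0-based centres).
#'
#' @param poly two-column matrix of (x, y) vertices in pixel units.
#' @param dim integer(2), image dimensions (rows, columns).
#' @return Logical matrix of the same dimensions.
#' @export
#' @examples
#' sq <- cbind(c(1, 4, 4, 1), c(1, 1, 4, 4))
#' sum(polygonMask(sq, c(8, 8)))  # 4x4 block of pixel centres
polygonMask <- function(poly, dim) {
  stopifnot(is.matrix(poly), ncol(poly) == 2L, nrow(poly) >= 3L)
  H <- as.integer(dim[1]); W <- as.integer(dim[2])
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  nx <- c(px[-1], px[1]); ny <- c(py[-1], py[1])
  r0 <- max(0L, floor(min(py))); r1 <- min(H - 1L, ceiling(max(py)))
  c0 <- max(0L, floor(min(px))); c1 <- min(W - 1L, ceiling(max(px)))
  out <- matrix(FALSE, H, W)
  if (r0 > r1 || c0 > c1) return(out)
  ys <- r0:r1
  xs <- c0:c1
  cnt <- matrix(0L, length(ys), length(xs))
  for (e in seq_len(n)) {
    y1 <- py[e]; y2 <- ny[e]
    if (y1 == y2) next
    spans <- (y1 > ys) != (y2 > ys)
    if (!any(spans)) next
    xc <- px[e] + (ys[spans] - y1) * (nx[e] - px[e]) / (y2 - y1)
    cnt[spans, ] <- cnt[spans, ] + outer(xc, xs, ">")
  }
  out[ys + 1L, xs + 1L] <- cnt %% 2L == 1L
  out
}

#' @rdname polygonMask
#' @param center disk centre c(x, y) in pixel units.
#' @param radius disk radius in pixels.
#' @export
diskMask <- function(center, radius, dim) {
  H <- as.integer(dim[1]); W <- as.integer(dim[2])
  X <- matrix(0:(W - 1L), H, W, byrow = TRUE)
  Y <- matrix(0:(H - 1L), H, W)
  (X - center[1])^2 + (Y - center[2])^2 <= radius^2
}

#' @rdname polygonMask
#' @param semiAxes ellipse semi-axes c(ax, ay) in pixels.
#' @export
ellipseMask <- function(center, semiAxes, dim) {
  H <- as.integer(dim[1]); W <- as.integer(dim[2])
  X <- matrix(0:(W - 1L), H, W, byrow = TRUE)
  Y <- matrix(0:(H - 1L), H, W)
  ((X - center[1]) / semiAxes[1])^2 + ((Y - center[2]) / semiAxes[2])^2 <= 1
}

## shoelace area of a polygon (pixel^2 units); sign dropped
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

## uniform scaling of a polygon about its vertex centroid
scalePolygon <- function(poly, factor) {
  ctr <- colMeans(poly)
  sweep(sweep(poly, 2, ctr), 2, c(factor, factor), "*") +
    matrix(ctr, nrow(poly), 2, byrow = TRUE)
}

## closed polygonal approximation of an annular sector in (possibly
## anisotropic) ellipse coordinates: rho in [rho0, rho1] (fraction of the
## semi-axes), theta in [th0, th1]; used by the default phantom spec
sectorPolygon <- function(center, semiAxes, rho0, rho1, th0, th1,
                          stepDeg = 6) {
  nth <- max(3L, ceiling((th1 - th0) / (stepDeg * pi / 180)))
  th <- seq(th0, th1, length.out = nth + 1L)
  outer_arc <- cbind(center[1] + semiAxes[1] * rho1 * cos(th),
                     center[2] + semiAxes[2] * rho1 * sin(th))
  inner_arc <- cbind(center[1] + semiAxes[1] * rho0 * cos(rev(th)),
                     center[2] + semiAxes[2] * rho0 * sin(rev(th)))
  rbind(outer_arc, inner_arc)
}

## regular polygonal approximation of a disk (used for cylinder fixtures)
circlePolygon <- function(center, radius, nVertices = 72L) {
  th <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

## evaluate a seed-scoped RNG block without disturbing the caller's stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
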