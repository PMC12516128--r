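## Internal geometry / coordinate helpers.
##
## Pixel convention: the image is a matrix indexed (row, col), row 1 at the
## top.  The centre of pixel (r, c) sits at physical coordinates
## x = (c - 0.5) * pixel_size_um (rightwards), y = (r - 0.5) * pixel_size_um
## (downwards).  All physical quantities are micrometres and seconds.

umToCol <- function(x_um, pixel_size_um) x_um / pixel_size_um + 0.5
umToRow <- function(y_um, pixel_size_um) y_um / pixel_size_um + 0.5
colToUm <- function(col, pixel_size_um) (col - 0.5) * pixel_size_um
rowToUm <- function(row, pixel_size_um) (row - 0.5) * pixel_size_um

## Euclidean norm of rows of a 2-column matrix (or a length-2 vector).
vecNorm <- function(v) {
  if (is.matrix(v)) sqrt(rowSums(v^2)) else sqrt(sum(v^2))
}

## Polygon area by the shoelace formula; vertices as n x 2 matrix (x, y).
polygonArea <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygonCentroid <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1))
  cross <- x[j] * y - x * y[j]
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x[j] + x) * cross) / (6 * a), sum((y[j] + y) * cross) / (6 * a))
}

## Point-in-polygon (even-odd rule), vectorised over points (n x 2).
pointsInPolygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  px <- poly[, 1]; py <- poly[, 2]
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Arc length of a polyline given as n x 2 matrix.
polylineLength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(vecNorm(diff(pts)))
}

## Unit vector; zero-length input returns c(0, 0).
unitVec <- function(v) {
  n <- vecNorm(v)
  if (n < .Machine$double.eps) c(0, 0) else v / n
}

## Draw from a truncated-at-zero normal by resampling (means well above 0
## in all uses; truncation is a guard, not a distributional statement).
rnormPos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x <= 0
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x <= 0
  }
  x
}

## Step lengths with the given mean and coefficient of variation, drawn from
## a gamma distribution (unimodal, positive; speed histograms come out
## near-Gaussian as observed for MTOC speeds in homeostatic skin).
rStepLength <- function(n, mean, cv = 0.25) {
  if (mean <= 0) return(rep(0, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
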