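## shared fixtures, built in code

## uniformly random rotation matrix (via QR of a Gaussian matrix)
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

randomTransform <- function(tSd = 50) {
  rigidTransform(randomRotation(), rnorm(3, 0, tSd))
}

## maximum angle (deg) between matching axes of two frames
frameAxisError <- function(a, b) {
  d <- pmin(1, pmax(-1, colSums(axes(a) * axes(b))))
  max(abs(acos(d))) * 180 / pi
}

frameOriginError <- function(a, b) sqrt(sum((origin(a) - origin(b))^2))

## angular difference between two rotations (deg); the Frobenius form
## ||Ra - Rb||_F = 2*sqrt(2)*sin(theta/2) stays accurate for tiny angles
## where the acos-of-trace form loses precision
rotationAngleError <- function(Ra, Rb) {
  fn <- sqrt(sum((Ra - Rb)^2))
  2 * asin(pmin(1, fn / (2 * sqrt(2)))) * 180 / pi
}

## dense points exactly on an ellipse (2D)
ellipsePoints <- function(a, b, n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th))
}

smallCamera <- function(px = 256) cameraModel(imageSize = px)

cross3v <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
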