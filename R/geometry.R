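## Small 3D geometry helpers shared by terminus fixing and the fixture
## builders (internal-coordinate atom placement, NeRF-style).

# split text into lines, preserving interior blank lines (strsplit alone
# would drop a "" element entirely and shift line numbers)
split_lines <- function(x) {
  strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
}

unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

measure_distance <- function(p, q) sqrt(sum((p - q)^2))

measure_angle <- function(p, a, q) {
  u <- unit(p - a); v <- unit(q - a)
  acos(max(-1, min(1, sum(u * v))))
}

# signed dihedral p1-p2-p3-p4, radians in (-pi, pi]
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Place a new atom X with |X-a| = r, angle(X, a, b) = theta and dihedral
# X-a-b-c = phi (radians).
place_internal <- function(a, b, c, r, theta, phi) {
  e1 <- unit(b - a)
  v <- c - b
  n <- v - sum(v * e1) * e1
  if (sqrt(sum(n * n)) < 1e-10) {
    # collinear reference: pick any perpendicular
    n <- if (abs(e1[1]) < 0.9) cross3(e1, c(1, 0, 0)) else cross3(e1, c(0, 1, 0))
  }
  e2 <- unit(n)
  e3 <- cross3(e1, e2)
  a + r * (cos(theta) * e1 +
           sin(theta) * (cos(phi) * e2 + sin(phi) * e3))
}
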