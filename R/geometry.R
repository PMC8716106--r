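# Polygon geometry primitives used throughout the mesh code.
# Cells are simple CCW polygons; all routines are vectorized over the
# ring CSR arrays built by index_complex().

polygon_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  0.5 * sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])
}

polygon_centroid <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  cr <- xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2]
  a <- 0.5 * sum(cr)
  if (abs(a) < 1e-12) return(colMeans(xy))
  c(sum((xy[, 1] + xy[j, 1]) * cr), sum((xy[, 2] + xy[j, 2]) * cr)) / (6 * a)
}

# Principal axes of a polygon from its area second moments.
# Returns list(len = c(max, min), dir = 2x2 matrix, rows = unit axes).
polygon_principal_axes <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  x <- xy[, 1]; y <- xy[, 2]
  cr <- x * y[j] - x[j] * y
  a <- 0.5 * sum(cr)
  cx <- sum((x + x[j]) * cr) / (6 * a)
  cy <- sum((y + y[j]) * cr) / (6 * a)
  sxx <- sum((x^2 + x * x[j] + x[j]^2) * cr) / 12
  syy <- sum((y^2 + y * y[j] + y[j]^2) * cr) / 12
  sxy <- sum((x * y[j] + 2 * x * y + 2 * x[j] * y[j] + x[j] * y) * cr) / 24
  # central covariance (per unit area)
  cxx <- sxx / a - cx^2
  cyy <- syy / a - cy^2
  cxy <- sxy / a - cx * cy
  tr <- cxx + cyy
  dd <- sqrt(max(0, (cxx - cyy)^2 / 4 + cxy^2))
  l1 <- tr / 2 + dd
  l2 <- max(tr / 2 - dd, 0)
  if (dd < 1e-14) {
    v1 <- c(1, 0)
  } else if (abs(cxy) > 1e-14) {
    v1 <- c(l1 - cyy, cxy); v1 <- v1 / sqrt(sum(v1^2))
  } else {
    v1 <- if (cxx >= cyy) c(1, 0) else c(0, 1)
  }
  v2 <- c(-v1[2], v1[1])
  list(len = 2 * sqrt(c(l1, l2)), dir = rbind(v1, v2))
}

# Is a polygon simple (no self intersections)? O(n^2); used by the validator.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(FALSE)
  j <- c(2:n, 1)
  for (e1 in 1:(n - 1)) {
    for (e2 in (e1 + 1):n) {
      # skip adjacent edges (share a vertex)
      if (e2 == e1 + 1 || (e1 == 1 && e2 == n)) next
      if (segments_intersect(xy[e1, ], xy[j[e1], ], xy[e2, ], xy[j[e2], ]))
        return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

# Intersections of an infinite line (point p0, unit direction u) with the
# edges of a polygon ring. Returns a data.frame with edge index and the
# parameter t in [0,1] along the edge, ordered by edge.
line_polygon_intersections <- function(xy, p0, u) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  # normal of the line
  nx <- -u[2]; ny <- u[1]
  s <- (xy[, 1] - p0[1]) * nx + (xy[, 2] - p0[2]) * ny  # signed distance
  s2 <- s[j]
  hit <- which((s > 0 & s2 <= 0) | (s <= 0 & s2 > 0))
  if (length(hit) == 0) return(data.frame(edge = integer(0), t = numeric(0)))
  t <- s[hit] / (s[hit] - s2[hit])
  data.frame(edge = hit, t = t)
}

rot90 <- function(m) cbind(m[, 2], -m[, 1])  # (x,y) -> (y,-x)

unit_rows <- function(m) {
  L <- sqrt(m[, 1]^2 + m[, 2]^2)
  L[L == 0] <- 1
  m / L
}
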