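# Point-in-convex-hull testing by brute-force facet enumeration. For every
# triple of points, the plane through it is a hull facet iff all remaining
# points lie on one side; the hull interior is then the intersection of
# the facet half-spaces. Pocket atom sets are small (tens of atoms), so
# the O(n^3) facet scan is well within budget and avoids the numerical
# bookkeeping of an incremental hull.

# half-space representation: list(normal = k x 3, offset = length k) with
# interior satisfying normal . p <= offset (within tolerance); NULL when
# the point set is degenerate (fewer than 4 unique points, or coplanar)
convex_hull_halfspaces <- function(points, tol = 1e-7) {
  pts <- unique(round(as.matrix(points), 10))
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 4) return(NULL)
  # degenerate if all points are coplanar
  centered <- sweep(pts, 2, colMeans(pts))
  if (qr(centered, tol = 1e-9)$rank < 3) return(NULL)
  scale <- max(1, max(abs(pts)))
  eps <- tol * scale
  triples <- combn(n, 3)
  normals <- matrix(0, 0, 3)
  offsets <- numeric()
  for (k in seq_len(ncol(triples))) {
    i <- triples[1, k]; j <- triples[2, k]; l <- triples[3, k]
    u <- pts[j, ] - pts[i, ]
    v <- pts[l, ] - pts[i, ]
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    len <- sqrt(sum(nrm^2))
    if (len < eps) next  # collinear triple
    nrm <- nrm / len
    d <- pts %*% nrm - sum(nrm * pts[i, ])
    if (all(d <= eps)) {
      normals <- rbind(normals, nrm)
      offsets <- c(offsets, sum(nrm * pts[i, ]))
    } else if (all(d >= -eps)) {
      normals <- rbind(normals, -nrm)
      offsets <- c(offsets, -sum(nrm * pts[i, ]))
    }
  }
  if (nrow(normals) == 0) return(NULL)
  list(normal = normals, offset = offsets, eps = eps)
}

# TRUE for query points inside or on the hull boundary
points_in_hull <- function(query, halfspaces) {
  q <- as.matrix(query)
  storage.mode(q) <- "double"
  if (nrow(q) == 0) return(logical())
  s <- q %*% t(halfspaces$normal)
  lim <- matrix(halfspaces$offset + halfspaces$eps, nrow(q),
                length(halfspaces$offset), byrow = TRUE)
  rowSums(s <= lim) == length(halfspaces$offset)
}
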