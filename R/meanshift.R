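# MeanShift mode-seeking clustering with a flat (uniform) kernel. The
# number of clusters is not specified in advance: each point is shifted to
# the mean of its bandwidth-neighbourhood until convergence, and converged
# modes closer than bandwidth / 2 are merged in input order, which makes
# the procedure fully deterministic for a given input ordering.

#' MeanShift clustering
#'
#' @param points Numeric matrix (n x d) of coordinates.
#' @param bandwidth Neighbourhood radius of the flat kernel (same units as
#'   `points`).
#' @param max_iter Maximum shift iterations per seed.
#' @param tol Convergence tolerance on the shift length.
#' @return List with `cluster` (integer assignment per point, 1-based in
#'   order of first appearance) and `modes` (k x d matrix of cluster
#'   modes).
#' @export
mean_shift <- function(points, bandwidth, max_iter = 300, tol = 1e-4) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n == 0) return(list(cluster = integer(), modes = points))
  if (bandwidth <= 0) abort("bandwidth must be positive")
  bw2 <- bandwidth^2
  modes <- points
  for (i in seq_len(n)) {
    m <- points[i, , drop = FALSE]
    for (iter in seq_len(max_iter)) {
      d2 <- cross_dist2(m, points)[1, ]
      nb <- d2 <= bw2
      new_m <- matrix(colMeans(points[nb, , drop = FALSE]), nrow = 1)
      if (sqrt(sum((new_m - m)^2)) < tol) {
        m <- new_m
        break
      }
      m <- new_m
    }
    modes[i, ] <- m
  }
  # merge modes closer than bandwidth / 2, scanning in input order
  cluster <- integer(n)
  centers <- matrix(0, 0, ncol(points))
  for (i in seq_len(n)) {
    assigned <- 0L
    if (nrow(centers) > 0) {
      d2 <- cross_dist2(modes[i, , drop = FALSE], centers)[1, ]
      j <- which(d2 <= (bandwidth / 2)^2)
      if (length(j) > 0) assigned <- j[[which.min(d2[j])]]
    }
    if (assigned == 0L) {
      centers <- rbind(centers, modes[i, ])
      assigned <- nrow(centers)
    }
    cluster[[i]] <- assigned
  }
  list(cluster = cluster, modes = centers)
}
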