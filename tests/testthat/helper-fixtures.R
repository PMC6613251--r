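# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# package's own geometry code paths: containment is re-derived by ray
# casting, areas by Monte-Carlo point sampling, distances by geodesy or
# plain Euclidean arithmetic.

unitSquare <- function(dx = 0, dy = 0, size = 1) {
  planarPolygon(rbind(c(dx, dy), c(dx + size, dy), c(dx + size, dy + size),
                      c(dx, dy + size), c(dx, dy)))
}

# crossing-number (ray-casting) containment oracle; boundary not handled
# (test points are kept off boundaries)
rayCastInside <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1L]; yi <- ring[i, 2L]
    xj <- ring[j, 1L]; yj <- ring[j, 2L]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# Monte-Carlo area of an arbitrary region given an indicator function
mcArea <- function(indicator, xmin, xmax, ymin, ymax, n = 1e6) {
  x <- runif(n, xmin, xmax)
  y <- runif(n, ymin, ymax)
  mean(indicator(x, y)) * (xmax - xmin) * (ymax - ymin)
}

# random convex polygon: convex hull of random points around a center
randomConvexPolygon <- function(center = c(0, 0), scale = 1, n = 8) {
  pts <- cbind(center[1L] + runif(n, -scale, scale),
               center[2L] + runif(n, -scale, scale))
  h <- chull(pts)
  ring <- pts[h, , drop = FALSE]
  planarPolygon(rbind(ring, ring[1L, ]))
}

# exhaustive 2^n enumeration oracle for the signed-rank two-sided p-value
wilcoxonEnumP <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  wObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w >= wObs - 1e-12), mean(w <= wObs + 1e-12)))
}

# small deterministic block layout: a 2 x 1 pair of unit-kilometre squares
twoBlockFixture <- function(pop = c(100, 200), gq = c(0, 0), hu = c(40, 80)) {
  g <- list(unitSquare(0, 0, 1000), unitSquare(1000, 0, 1000))
  censusBlocks(g, c("B1", "B2"), pop, gq, hu)
}

rhuTable <- function(x, y, block_id = NULL, id = NULL) {
  n <- length(x)
  df <- data.frame(candidate_id = if (is.null(id)) sprintf("r%03d",
                                                           seq_len(n)) else id,
                   x = x, y = y, source = "address",
                   verified_removed = FALSE, stringsAsFactors = FALSE)
  if (!is.null(block_id)) df$block_id <- block_id
  df
}
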