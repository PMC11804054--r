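# Delaunay triangulation via incremental insertion (Bowyer-Watson).
# O(n^2) triangle scans; intended for the point-set sizes typical of
# imaging-based spatial omics sections (thousands of cells).

# > 0 if point d lies inside the circumcircle of (a, b, c) given CCW.
in_circumcircle <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  adx <- ax - dx; ady <- ay - dy
  bdx <- bx - dx; bdy <- by - dy
  cdx <- cx - dx; cdy <- cy - dy
  ad2 <- adx * adx + ady * ady
  bd2 <- bdx * bdx + bdy * bdy
  cd2 <- cdx * cdx + cdy * cdy
  adx * (bdy * cd2 - bd2 * cdy) -
    ady * (bdx * cd2 - bd2 * cdx) +
    ad2 * (bdx * cdy - bdy * cdx)
}

orient2d <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

#' Delaunay triangulation spatial graph
#'
#' Connects spots that share a Delaunay edge (empty-circumcircle
#' triangulation) and stores the Euclidean edge length in the `distance`
#' attribute, ready for [distances_to_connectivities()].
#'
#' @param points numeric 2-column matrix of coordinates.
#' @return A [spot_graph] with unit weights and distances.
#' @export
build_delaunay_graph <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop_sm("Delaunay triangulation needs 2-D points")
  n <- nrow(points)
  if (n < 3) stop_sm("need at least 3 points")
  dup <- duplicated(points)
  if (any(dup))
    stop_sm("duplicate points at rows: %s", paste(which(dup), collapse = ", "))
  x <- points[, 1]; y <- points[, 2]
  # collinearity check (all cross products ~ 0 relative to extent)
  scale2 <- (diff(range(x))^2 + diff(range(y))^2)
  cr <- orient2d(x[1], y[1], x[2], y[2], x, y)
  if (all(abs(cr) <= 1e-12 * scale2)) stop_sm("all points are collinear")

  # super-triangle well outside the bounding box
  cxm <- mean(range(x)); cym <- mean(range(y))
  r <- sqrt(scale2) * 10 + 1
  sx <- c(cxm - 2 * r, cxm + 2 * r, cxm)
  sy <- c(cym - r, cym - r, cym + 2 * r)
  px <- c(x, sx); py <- c(y, sy)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L

  # triangles as rows (a, b, c), CCW
  tri <- matrix(c(s1, s2, s3), ncol = 3)
  for (p in seq_len(n)) {
    bad <- in_circumcircle(px[tri[, 1]], py[tri[, 1]],
                           px[tri[, 2]], py[tri[, 2]],
                           px[tri[, 3]], py[tri[, 3]],
                           px[p], py[p]) > 0
    hole <- tri[bad, , drop = FALSE]
    tri <- tri[!bad, , drop = FALSE]
    # boundary = edges of the hole that appear exactly once
    e <- rbind(hole[, c(1, 2)], hole[, c(2, 3)], hole[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    once <- key %in% names(which(table(key) == 1))
    be <- e[once, , drop = FALSE]
    if (nrow(be)) {
      newt <- cbind(be[, 1], be[, 2], p)
      # enforce CCW orientation
      o <- orient2d(px[newt[, 1]], py[newt[, 1]],
                    px[newt[, 2]], py[newt[, 2]],
                    px[newt[, 3]], py[newt[, 3]])
      flip <- o < 0
      tmp <- newt[flip, 1]; newt[flip, 1] <- newt[flip, 2]; newt[flip, 2] <- tmp
      tri <- rbind(tri, newt[o != 0, , drop = FALSE])
    }
  }
  keep <- tri[, 1] <= n & tri[, 2] <= n & tri[, 3] <= n
  tri <- tri[keep, , drop = FALSE]
  if (!nrow(tri)) stop_sm("triangulation degenerate (collinear input?)")
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  d <- sqrt((x[a] - x[b])^2 + (y[a] - y[b])^2)
  spot_graph(n, a, b, weight = rep(1, length(a)), distance = d)
}
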