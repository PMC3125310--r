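# Planar polyline geometry. All coordinates are projected metres; all
# lengths Euclidean arc lengths.

# polyline: numeric matrix n x 2, n >= 2
polyline_length <- function(poly) {
  d <- diff(poly)
  sum(sqrt(rowSums(d^2)))
}

polyline_cumlen <- function(poly) {
  d <- diff(poly)
  c(0, cumsum(sqrt(rowSums(d^2))))
}

# Point at arc length s along the polyline (clamped to [0, L]).
point_at <- function(poly, s) {
  cl <- polyline_cumlen(poly)
  L <- cl[length(cl)]
  s <- min(max(s, 0), L)
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- min(i, nrow(poly) - 1L)
  seg_len <- cl[i + 1L] - cl[i]
  t <- if (seg_len > 0) (s - cl[i]) / seg_len else 0
  poly[i, ] + t * (poly[i + 1L, ] - poly[i, ])
}

# Sub-polyline between arc lengths s0 < s1, keeping interior vertices.
polyline_cut <- function(poly, s0, s1) {
  cl <- polyline_cumlen(poly)
  L <- cl[length(cl)]
  s0 <- min(max(s0, 0), L)
  s1 <- min(max(s1, 0), L)
  p0 <- point_at(poly, s0)
  p1 <- point_at(poly, s1)
  keep <- which(cl > s0 + 1e-12 & cl < s1 - 1e-12)
  rbind(p0, poly[keep, , drop = FALSE], p1)
}

# Distance from point p to each straight edge of a set of edges given as
# columns x1,y1,x2,y2; returns list(dist, t) with t in [0,1] along each edge.
point_edges_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- ((px - x1) * dx + (py - y1) * dy) / ifelse(len2 > 0, len2, 1)
  t <- pmin(pmax(t, 0), 1)
  cx <- x1 + t * dx
  cy <- y1 + t * dy
  list(dist = sqrt((px - cx)^2 + (py - cy)^2), t = t)
}
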