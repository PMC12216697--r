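# Brute-force oracles, independent of the package's analytic geometry:
# dense sampling along segments, exhaustive cell-center enumeration,
# densified-vertex distances, and an orientation-test segment/rectangle
# predicate.

oracle_line_length <- function(segs, center, radius, n = 1e4) {
  total <- 0
  for (i in seq_len(nrow(segs))) {
    t <- (seq_len(n) - 0.5) / n
    px <- segs[i, 1] + t * (segs[i, 3] - segs[i, 1])
    py <- segs[i, 2] + t * (segs[i, 4] - segs[i, 2])
    len <- sqrt((segs[i, 3] - segs[i, 1])^2 + (segs[i, 4] - segs[i, 2])^2)
    inside <- (px - center[1])^2 + (py - center[2])^2 <= radius^2
    total <- total + mean(inside) * len
  }
  total
}

oracle_raster_mean <- function(grid, center, radius) {
  ctr <- grid_centers(grid)
  d2 <- (ctr[, 1] - center[1])^2 + (ctr[, 2] - center[2])^2
  mean(as.vector(grid$values)[d2 <= radius^2])
}

oracle_distance <- function(segs, center, spacing = 1) {
  best <- Inf
  for (i in seq_len(nrow(segs))) {
    len <- sqrt((segs[i, 3] - segs[i, 1])^2 + (segs[i, 4] - segs[i, 2])^2)
    t <- seq(0, 1, length.out = max(2, ceiling(len / spacing)))
    px <- segs[i, 1] + t * (segs[i, 3] - segs[i, 1])
    py <- segs[i, 2] + t * (segs[i, 4] - segs[i, 2])
    best <- min(best, sqrt((px - center[1])^2 + (py - center[2])^2))
  }
  best
}

oracle_seg_in_rect <- function(seg, xmin, ymin, xmax, ymax) {
  inside <- function(px, py)
    px >= xmin && px <= xmax && py >= ymin && py <= ymax
  if (inside(seg[1], seg[2]) || inside(seg[3], seg[4])) return(TRUE)
  cross <- function(ax, ay, bx, by, cx, cy)
    (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- cross(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
    d2 <- cross(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
    d3 <- cross(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
    d4 <- cross(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
    (d1 * d2 <= 0) && (d3 * d4 <= 0)
  }
  edges <- list(
    list(c(xmin, ymin), c(xmax, ymin)), list(c(xmax, ymin), c(xmax, ymax)),
    list(c(xmax, ymax), c(xmin, ymax)), list(c(xmin, ymax), c(xmin, ymin)))
  for (e in edges)
    if (seg_int(seg[1:2], seg[3:4], e[[1]], e[[2]])) return(TRUE)
  FALSE
}
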