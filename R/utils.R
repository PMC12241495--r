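# Internal geometry and helper routines.

# Shoelace area of a polygon given as an n x 2 matrix (not closed).
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

# Simple-polygon check: no two non-adjacent edges intersect.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  segs <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_intersect(segs[i, 1:2], segs[i, 3:4],
                             segs[j, 1:2], segs[j, 3:4])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# Do two convex polygons (n x 2 matrices, CCW or CW) intersect?
# Separating-axis test: convex sets are disjoint iff some edge normal separates.
convex_polygons_intersect <- function(a, b) {
  axes_of <- function(v) {
    n <- nrow(v)
    e <- v[c(2:n, 1L), , drop = FALSE] - v
    cbind(-e[, 2], e[, 1])
  }
  for (ax in list(axes_of(a), axes_of(b))) {
    for (k in seq_len(nrow(ax))) {
      u <- ax[k, ]
      nrm <- sqrt(sum(u^2))
      if (nrm == 0) next
      pa <- a %*% u
      pb <- b %*% u
      if (max(pa) < min(pb) || max(pb) < min(pa)) return(FALSE)
    }
  }
  TRUE
}

# Points strictly/boundary-inclusively inside polygon, via mgcv::in.out.
points_in_polygon <- function(x, y, vertices) {
  bnd <- rbind(vertices, vertices[1, , drop = FALSE])
  mgcv::in.out(bnd, cbind(x, y))
}

# Fixed-radius neighbour test using a uniform grid (cell list). For each row of
# `ref`, TRUE iff some row of `other` lies at distance < radius. Agrees exactly
# with the brute-force all-pairs computation.
has_neighbour_within <- function(ref, other, radius) {
  stopifnot(radius > 0)
  n <- nrow(ref); m <- nrow(other)
  if (n == 0L) return(logical(0))
  if (m == 0L) return(rep(FALSE, n))
  x0 <- min(ref[, 1], other[, 1]); y0 <- min(ref[, 2], other[, 2])
  cs <- radius
  key <- function(p) {
    ix <- floor((p[, 1] - x0) / cs)
    iy <- floor((p[, 2] - y0) / cs)
    list(ix = ix, iy = iy)
  }
  ko <- key(other)
  # bucket other points by cell id
  span <- max(ko$ix) + 2L
  id_o <- ko$ix + 1L + ko$iy * span
  buckets <- split(seq_len(m), id_o)
  kr <- key(ref)
  out <- logical(n)
  r2 <- radius^2
  for (i in seq_len(n)) {
    found <- FALSE
    for (dx in -1:1) {
      for (dy in -1:1) {
        id <- (kr$ix[i] + dx) + 1L + (kr$iy[i] + dy) * span
        idx <- buckets[[as.character(id)]]
        if (is.null(idx)) next
        dd <- (other[idx, 1] - ref[i, 1])^2 + (other[idx, 2] - ref[i, 2])^2
        if (any(dd < r2)) { found <- TRUE; break }
      }
      if (found) break
    }
    out[i] <- found
  }
  out
}

# Run a block with a temporary RNG seed, restoring caller RNG state.
with_seed <- function(seed, code) withr::with_seed(seed, code)

# Derive a bounded sub-seed from a master seed and a stream label.
sub_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483629L
}
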