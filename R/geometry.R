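## Planar geometry primitives.
##
## All coordinates are projected planar meters (e.g. UTM).  Geographic
## (lon/lat) input is not supported; project before use.
##
## Representations:
##   * point    -- length-2 numeric, or an n x 2 matrix for many points
##   * polyline -- n x 2 numeric matrix of ordered vertices (n >= 2)
##   * polygon  -- "lc_polygon": a union of one or more parts, each part a
##                 list of rings (n x 2 matrices, stored open, implicitly
##                 closed) with even-odd interior semantics, so holes and
##                 multi-part regions are uniform.  The union-of-parts
##                 layer lets dilations of non-convex shapes be represented
##                 exactly (part + per-edge capsules) without a polygon
##                 clipping library.

.lc_eps <- 1e-9

.check_coords <- function(m, what = "geometry") {
  m <- as.matrix(m)
  if (!is.numeric(m) || ncol(m) != 2L)
    stop("invalid geometry: ", what, " must be a numeric n x 2 matrix", call. = FALSE)
  if (!all(is.finite(m)))
    stop("invalid geometry: non-finite coordinates in ", what, call. = FALSE)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Validate a polyline
#'
#' @param m an n x 2 numeric matrix of vertices (planar meters), n >= 2.
#' @return the validated matrix.
#' @export
as_path <- function(m) {
  m <- .check_coords(m, "polyline")
  if (nrow(m) < 2L)
    stop("invalid geometry: polyline needs at least 2 vertices", call. = FALSE)
  m
}

.ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

.normalize_ring <- function(ring) {
  ring <- .check_coords(ring, "ring")
  n <- nrow(ring)
  if (n >= 2L && all(abs(ring[n, ] - ring[1, ]) < .lc_eps))
    ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3L)
    stop("invalid geometry: ring needs at least 3 distinct vertices", call. = FALSE)
  ring
}

.ring_edges <- function(ring) {
  n <- nrow(ring)
  cbind(ring, ring[c(2:n, 1L), , drop = FALSE])  # x1 y1 x2 y2
}

.path_edges <- function(path) {
  n <- nrow(path)
  cbind(path[-n, , drop = FALSE], path[-1, , drop = FALSE])
}

## strict transversal crossing test between every segment of P (n x 4) and
## every segment of Q (m x 4); endpoint tangency and collinear overlap are
## excluded by the strict inequality.
.seg_cross_matrix <- function(P, Q) {
  dxp <- P[, 3] - P[, 1]; dyp <- P[, 4] - P[, 2]
  dxq <- Q[, 3] - Q[, 1]; dyq <- Q[, 4] - Q[, 2]
  ## orientation of Q endpoints relative to each directed P segment
  o1 <- outer(dxp, Q[, 2]) - outer(dyp, Q[, 1]) + (dyp * P[, 1] - dxp * P[, 2])
  o2 <- outer(dxp, Q[, 4]) - outer(dyp, Q[, 3]) + (dyp * P[, 1] - dxp * P[, 2])
  ## orientation of P endpoints relative to each directed Q segment
  o3 <- outer(P[, 2], dxq) - outer(P[, 1], dyq) + rep(dyq * Q[, 1] - dxq * Q[, 2], each = nrow(P))
  o4 <- outer(P[, 4], dxq) - outer(P[, 3], dyq) + rep(dyq * Q[, 1] - dxq * Q[, 2], each = nrow(P))
  (o1 * o2 < 0) & (o3 * o4 < 0)
}

.as_polyline_list <- function(features) {
  if (is.matrix(features) || is.data.frame(features)) features <- list(features)
  lapply(features, as_path)
}

#' Count transversal crossings between a path and line features
#'
#' Counts intersection points where a path segment properly crosses a
#' feature segment.  Tangential touches and collinear overlaps do not
#' count: a path running along a feature has not crossed it.  A single
#' path segment crossing k distinct feature segments contributes k.
#'
#' @param path polyline matrix (>= 2 vertices).
#' @param features a polyline matrix or list of polyline matrices.
#' @return non-negative integer crossing count.
#' @export
count_crossings <- function(path, features) {
  path <- as_path(path)
  feats <- .as_polyline_list(features)
  P <- .path_edges(path)
  keep <- (P[, 1] != P[, 3]) | (P[, 2] != P[, 4])  # zero-length segments contribute 0
  P <- P[keep, , drop = FALSE]
  if (nrow(P) == 0L) return(0L)
  total <- 0L
  for (f in feats) {
    Q <- .path_edges(f)
    qk <- (Q[, 1] != Q[, 3]) | (Q[, 2] != Q[, 4])
    Q <- Q[qk, , drop = FALSE]
    if (nrow(Q) == 0L) next
    total <- total + sum(.seg_cross_matrix(P, Q))
  }
  as.integer(total)
}

## ---------------------------------------------------------------- polygons

.ring_is_simple <- function(ring) {
  E <- .ring_edges(ring)
  n <- nrow(E)
  if (n > 400L) return(TRUE)  # skip O(n^2) check for dense (arc-approximated) rings
  cross <- .seg_cross_matrix(E, E)
  !any(cross[upper.tri(cross)])
}

.new_polygon <- function(parts) {
  structure(list(parts = parts), class = "lc_polygon")
}

#' Construct a polygon
#'
#' @param rings a ring matrix or list of ring matrices forming one part
#'   (first ring exterior; further rings holes, even-odd semantics).
#'   Rings may be given closed (first vertex repeated) or open.
#' @param parts alternatively, a list of parts, each a list of rings, whose
#'   union is the region (used for multi-part regions and dilations).
#' @return an object of class `lc_polygon`.
#' @export
lc_polygon <- function(rings = NULL, parts = NULL) {
  if (is.null(parts)) {
    if (is.matrix(rings) || is.data.frame(rings)) rings <- list(rings)
    parts <- list(lapply(rings, .normalize_ring))
  } else {
    parts <- lapply(parts, function(p) {
      if (is.matrix(p) || is.data.frame(p)) p <- list(p)
      lapply(p, .normalize_ring)
    })
  }
  for (p in parts) {
    if (abs(.ring_signed_area(p[[1]])) < .lc_eps)
      stop("invalid geometry: polygon part has zero area", call. = FALSE)
    if (!.ring_is_simple(p[[1]]))
      stop("invalid geometry: self-intersecting exterior ring", call. = FALSE)
  }
  .new_polygon(parts)
}

#' @export
print.lc_polygon <- function(x, ...) {
  nr <- sum(vapply(x$parts, length, 1L))
  cat(sprintf("<lc_polygon: %d part(s), %d ring(s), area %.6g m^2>\n",
              length(x$parts), nr, polygon_area(x)))
  invisible(x)
}

#' Axis-aligned rectangle polygon
#' @param xmin,ymin,xmax,ymax rectangle bounds in meters.
#' @export
lc_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  lc_polygon(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

.as_polygon <- function(poly) {
  if (!inherits(poly, "lc_polygon")) poly <- lc_polygon(poly)
  poly
}

#' Polygon bounding box
#' @param poly an `lc_polygon`.
#' @return numeric c(xmin, ymin, xmax, ymax).
#' @export
polygon_bbox <- function(poly) {
  poly <- .as_polygon(poly)
  all_pts <- do.call(rbind, unlist(poly$parts, recursive = FALSE))
  c(min(all_pts[, 1]), min(all_pts[, 2]), max(all_pts[, 1]), max(all_pts[, 2]))
}

.points_in_part <- function(pts, part, boundary = TRUE) {
  k <- nrow(pts)
  crossings <- integer(k)
  on_edge <- logical(k)
  px <- pts[, 1]; py <- pts[, 2]
  tol2 <- .lc_eps^2 * 1e6                        # ~1e-6 m boundary snap
  for (ring in part) {
    E <- .ring_edges(ring)                       # e x 4
    e <- nrow(E)
    if (k <= 4L * e) {
      ## few points: vectorize over edges (k x e matrices)
      x1 <- E[, 1]; y1 <- E[, 2]; x2 <- E[, 3]; y2 <- E[, 4]
      dy <- y2 - y1; dx <- x2 - x1
      straddle <- outer(py, y1, `<`) != outer(py, y2, `<`)
      slope <- ifelse(dy != 0, dx / dy, 0)
      xint <- outer(py, y1, `-`) * rep(slope, each = k) + rep(x1, each = k)
      crossings <- crossings + rowSums(straddle & (px < xint))
      if (boundary) {
        L2 <- pmax(dx * dx + dy * dy, .lc_eps^2)
        tnum <- outer(px, x1, `-`) * rep(dx, each = k) +
          outer(py, y1, `-`) * rep(dy, each = k)
        t <- sweep(tnum, 2, L2, `/`)
        t[t < 0] <- 0; t[t > 1] <- 1
        ex <- t * rep(dx, each = k) + rep(x1, each = k)
        ey <- t * rep(dy, each = k) + rep(y1, each = k)
        d2 <- (px - ex)^2 + (py - ey)^2
        d2min <- d2[cbind(seq_len(k), max.col(-d2, ties.method = "first"))]
        on_edge <- on_edge | (d2min <= tol2)
      }
    } else {
      ## many points: loop over edges, vectorize over points
      for (j in seq_len(e)) {
        x1 <- E[j, 1]; y1 <- E[j, 2]; x2 <- E[j, 3]; y2 <- E[j, 4]
        straddle <- (y1 > py) != (y2 > py)
        if (any(straddle)) {
          xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
          crossings <- crossings + (straddle & (px < xint))
        }
        if (boundary) {
          dx <- x2 - x1; dy <- y2 - y1
          L2 <- max(dx * dx + dy * dy, .lc_eps^2)
          t <- ((px - x1) * dx + (py - y1) * dy) / L2
          t[t < 0] <- 0; t[t > 1] <- 1
          d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
          on_edge <- on_edge | (d2 <= tol2)
        }
      }
    }
  }
  (crossings %% 2L == 1L) | on_edge
}

#' Which points lie inside a polygon (boundary inclusive)
#'
#' Even-odd rule per part; a point inside any part of a multi-part region
#' is inside.  Points on a ring (within ~1 micrometer) count as inside: a
#' relocation on a habitat edge at GPS precision is in that habitat.
#'
#' @param points length-2 numeric or n x 2 matrix.
#' @param poly an `lc_polygon`.
#' @return logical vector.
#' @export
points_in_polygon <- function(points, poly) {
  poly <- .as_polygon(poly)
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  pts <- .check_coords(points, "points")
  inside <- logical(nrow(pts))
  for (part in poly$parts) inside <- inside | .points_in_part(pts, part)
  inside
}

#' Count points inside a polygon (boundary inclusive)
#' @inheritParams points_in_polygon
#' @return non-negative integer.
#' @export
count_points_in_polygon <- function(points, poly) {
  poly <- .as_polygon(poly)
  if (polygon_area(poly) <= 0)
    stop("invalid geometry: degenerate (zero-area) polygon", call. = FALSE)
  sum(points_in_polygon(points, poly))
}

## ------------------------------------------------------------------- hull

#' Minimum convex polygon (100% MCP)
#'
#' Convex hull of a point set, the classical home-range MCP.
#'
#' @param points n x 2 matrix, n >= 3, not all collinear.
#' @return an `lc_polygon` with one convex counter-clockwise ring.
#' @export
minimum_convex_polygon <- function(points) {
  pts <- .check_coords(points, "points")
  pts <- unique(pts)
  if (nrow(pts) < 3L)
    stop("degenerate input: need at least 3 distinct points for an MCP", call. = FALSE)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[idx, , drop = FALSE]
  if (nrow(hull) < 3L || abs(.ring_signed_area(hull)) < .lc_eps)
    stop("degenerate input: points are collinear", call. = FALSE)
  if (.ring_signed_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  lc_polygon(hull)
}

.ring_is_convex <- function(ring) {
  n <- nrow(ring)
  nxt <- c(2:n, 1L); nxt2 <- c(3:n, 1L, 2L)
  e1x <- ring[nxt, 1] - ring[, 1]; e1y <- ring[nxt, 2] - ring[, 2]
  e2x <- ring[nxt2, 1] - ring[nxt, 1]; e2y <- ring[nxt2, 2] - ring[nxt, 2]
  cr <- e1x * e2y - e1y * e2x
  all(cr >= -.lc_eps * max(abs(cr), 1)) || all(cr <= .lc_eps * max(abs(cr), 1))
}

## Sutherland-Hodgman: clip `subject` ring by convex CCW `clip` ring.
.clip_by_convex <- function(subject, clip) {
  if (.ring_signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) return(out)
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    inp <- out
    n <- nrow(inp)
    prev <- inp[c(n, seq_len(n - 1L)), , drop = FALSE]
    side <- function(p) (b[1] - a[1]) * (p[, 2] - a[2]) - (b[2] - a[2]) * (p[, 1] - a[1])
    s_cur <- side(inp); s_prev <- side(prev)
    keep <- list()
    for (j in seq_len(n)) {
      cur_in <- s_cur[j] >= 0; prev_in <- s_prev[j] >= 0
      if (cur_in != prev_in) {
        t <- s_prev[j] / (s_prev[j] - s_cur[j])
        keep[[length(keep) + 1L]] <- prev[j, ] + t * (inp[j, ] - prev[j, ])
      }
      if (cur_in) keep[[length(keep) + 1L]] <- inp[j, ]
    }
    out <- if (length(keep)) do.call(rbind, keep) else matrix(numeric(0), 0, 2)
  }
  out
}

.part_area <- function(part) {
  abs(sum(vapply(part, .ring_signed_area, 0)))
}

.parts_overlap <- function(p1, p2) {
  b1 <- c(min(p1[[1]][, 1]), min(p1[[1]][, 2]), max(p1[[1]][, 1]), max(p1[[1]][, 2]))
  b2 <- c(min(p2[[1]][, 1]), min(p2[[1]][, 2]), max(p2[[1]][, 1]), max(p2[[1]][, 2]))
  if (b1[3] < b2[1] || b2[3] < b1[1] || b1[4] < b2[2] || b2[4] < b1[2]) return(FALSE)
  if (any(.points_in_part(p1[[1]], p2, boundary = FALSE))) return(TRUE)
  if (any(.points_in_part(p2[[1]], p1, boundary = FALSE))) return(TRUE)
  any(.seg_cross_matrix(.ring_edges(p1[[1]]), .ring_edges(p2[[1]])))
}

.area_grid <- function(poly, n_side = 220L) {
  bb <- polygon_bbox(poly)
  xs <- seq(bb[1], bb[3], length.out = n_side)
  ys <- seq(bb[2], bb[4], length.out = n_side)
  grid <- cbind(rep(xs, times = n_side), rep(ys, each = n_side))
  cell <- (xs[2] - xs[1]) * (ys[2] - ys[1])
  sum(points_in_polygon(grid, poly)) * cell
}

#' Polygon area
#'
#' Exact (shoelace, with inclusion-exclusion via convex clipping) whenever
#' parts are disjoint or pairwise overlaps involve a convex part;
#' otherwise estimated on a regular grid (documented approximation used
#' only for dilations of non-convex shapes).
#'
#' @param poly an `lc_polygon`.
#' @return area in square meters.
#' @export
polygon_area <- function(poly) {
  poly <- .as_polygon(poly)
  parts <- poly$parts
  if (length(parts) == 1L) return(.part_area(parts[[1]]))
  np <- length(parts)
  overlaps <- list()
  for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    if (.parts_overlap(parts[[i]], parts[[j]])) overlaps[[length(overlaps) + 1L]] <- c(i, j)
  }
  if (length(overlaps) == 0L)
    return(sum(vapply(parts, .part_area, 0)))
  if (np == 2L && length(parts[[1]]) == 1L && length(parts[[2]]) == 1L &&
      (.ring_is_convex(parts[[1]][[1]]) || .ring_is_convex(parts[[2]][[1]]))) {
    r1 <- parts[[1]][[1]]; r2 <- parts[[2]][[1]]
    inter <- if (.ring_is_convex(r2)) .clip_by_convex(r1, r2) else .clip_by_convex(r2, r1)
    ia <- if (nrow(inter) >= 3L) abs(.ring_signed_area(inter)) else 0
    return(.part_area(parts[[1]]) + .part_area(parts[[2]]) - ia)
  }
  .area_grid(poly)
}

## --------------------------------------------------------------- set ops

.part_within <- function(inner, outer) {
  if (any(.seg_cross_matrix(.ring_edges(inner[[1]]), .ring_edges(outer[[1]])))) return(FALSE)
  all(.points_in_part(inner[[1]], outer))
}

#' Union of two polygons
#'
#' If one polygon contains the other the larger is returned; otherwise the
#' result is the multi-part union region (with exact containment tests and
#' inclusion-exclusion area).
#'
#' @param a,b `lc_polygon` objects.
#' @return an `lc_polygon` containing both inputs.
#' @export
union_polygons <- function(a, b) {
  a <- .as_polygon(a); b <- .as_polygon(b)
  if (length(a$parts) == 1L && length(b$parts) == 1L) {
    if (.part_within(a$parts[[1]], b$parts[[1]])) return(b)
    if (.part_within(b$parts[[1]], a$parts[[1]])) return(a)
  }
  .new_polygon(c(a$parts, b$parts))
}

#' Dilate a polygon by a distance (Minkowski buffer)
#'
#' Convex parts dilate to an exact offset ring with circular arcs
#' approximated by `quarter_segments` chords per quarter circle.
#' Non-convex parts are represented exactly as the union of the part and a
#' convex capsule around each edge (containment exact; area then
#' grid-estimated).
#'
#' @param poly an `lc_polygon`.
#' @param distance buffer distance in meters, >= 0.
#' @param quarter_segments arc resolution (>= 16 enforced).
#' @return an `lc_polygon`.
#' @export
buffer_polygon <- function(poly, distance, quarter_segments = 24L) {
  poly <- .as_polygon(poly)
  if (!is.finite(distance) || distance < 0)
    stop("unsupported operation: buffer distance must be >= 0", call. = FALSE)
  if (distance == 0) return(poly)
  quarter_segments <- max(16L, as.integer(quarter_segments))
  ang <- seq(0, 2 * pi, length.out = 4L * quarter_segments + 1L)[-1L]
  circ <- distance * cbind(cos(ang), sin(ang))
  out_parts <- list()
  for (part in poly$parts) {
    ring <- part[[1]]
    if (length(part) == 1L && .ring_is_convex(ring)) {
      pts <- ring[rep(seq_len(nrow(ring)), each = nrow(circ)), , drop = FALSE] +
        circ[rep(seq_len(nrow(circ)), times = nrow(ring)), , drop = FALSE]
      hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
      if (.ring_signed_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
      out_parts[[length(out_parts) + 1L]] <- list(hull)
    } else {
      out_parts[[length(out_parts) + 1L]] <- part
      E <- .ring_edges(ring)
      for (j in seq_len(nrow(E))) {
        ends <- rbind(E[j, 1:2], E[j, 3:4])
        pts <- ends[rep(1:2, each = nrow(circ)), ] + rbind(circ, circ)
        hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
        if (.ring_signed_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
        out_parts[[length(out_parts) + 1L]] <- list(hull)
      }
    }
  }
  .new_polygon(out_parts)
}

## ---------------------------------------------------------- rigid motions

#' Rotate a path about a pivot
#' @param path polyline matrix.
#' @param angle rotation angle in radians (counter-clockwise).
#' @param pivot length-2 numeric pivot point.
#' @export
rotate_path <- function(path, angle, pivot) {
  path <- as_path(path)
  pivot <- as.numeric(pivot)
  co <- cos(angle); si <- sin(angle)
  dx <- path[, 1] - pivot[1]; dy <- path[, 2] - pivot[2]
  cbind(pivot[1] + co * dx - si * dy, pivot[2] + si * dx + co * dy)
}

#' Translate a path to a new starting point
#' @param path polyline matrix.
#' @param new_start length-2 numeric; the first vertex is moved here.
#' @export
translate_path <- function(path, new_start) {
  path <- as_path(path)
  shift <- as.numeric(new_start) - path[1, ]
  cbind(path[, 1] + shift[1], path[, 2] + shift[2])
}

#' Sample points uniformly inside a polygon
#'
#' Rejection sampling from the bounding box; uses the current RNG stream.
#'
#' @param poly an `lc_polygon` with positive area.
#' @param n number of points.
#' @return n x 2 matrix.
#' @export
sample_points_in_polygon <- function(poly, n) {
  poly <- .as_polygon(poly)
  bb <- polygon_bbox(poly)
  if (polygon_area(poly) <= 0)
    stop("invalid geometry: cannot sample from zero-area polygon", call. = FALSE)
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    cand <- cbind(stats::runif(m, bb[1], bb[3]), stats::runif(m, bb[2], bb[4]))
    keep <- cand[points_in_polygon(cand, poly), , drop = FALSE]
    if (nrow(keep) > 0L) {
      take <- min(nrow(keep), n - got)
      out[(got + 1L):(got + take), ] <- keep[seq_len(take), ]
      got <- got + take
    }
  }
  out
}

## --------------------------------------------------------------- landscape

#' Assemble a landscape of linear features and habitat polygons
#'
#' @param roads,trails lists of polyline matrices (may be empty).
#' @param powerline an `lc_polygon` (possibly multi-part) of clear cuts.
#' @param road_buffer an `lc_polygon`: habitat within the buffer distance
#'   of a road (typically `buffer_polygon(road_polygon, 5)`).
#' @param study_area an `lc_polygon` delimiting the study area.
#' @param road_polygon optional paved-road footprint `lc_polygon`.
#' @return an object of class `lc_landscape`.
#' @export
landscape <- function(roads, trails, powerline, road_buffer, study_area,
                      road_polygon = NULL) {
  obj <- structure(list(
    roads = .as_polyline_list(roads),
    trails = .as_polyline_list(trails),
    powerline = .as_polygon(powerline),
    road_buffer = .as_polygon(road_buffer),
    study_area = .as_polygon(study_area),
    road_polygon = if (!is.null(road_polygon)) .as_polygon(road_polygon)
  ), class = "lc_landscape")
  obj
}

#' @export
print.lc_landscape <- function(x, ...) {
  cat(sprintf("<lc_landscape: %d road line(s), %d trail line(s), study area %.4g ha>\n",
              length(x$roads), length(x$trails), polygon_area(x$study_area) / 1e4))
  invisible(x)
}
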