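# Independent brute-force oracles used to cross-check the geometry and
# likelihood code.  Implementations here deliberately use different
# algorithms from the package (scalar loops, winding numbers, gift
# wrapping, grid search) so agreement is informative.

# scalar all-pairs transversal segment-intersection enumerator
oracle_crossings <- function(path, features) {
  if (is.matrix(features)) features <- list(features)
  cross1 <- function(a1, a2, b1, b2) {
    orient <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    o1 <- orient(a1, a2, b1); o2 <- orient(a1, a2, b2)
    o3 <- orient(b1, b2, a1); o4 <- orient(b1, b2, a2)
    (o1 * o2 < 0) && (o3 * o4 < 0)
  }
  total <- 0L
  for (f in features) {
    for (i in seq_len(nrow(path) - 1L)) for (j in seq_len(nrow(f) - 1L)) {
      if (cross1(path[i, ], path[i + 1L, ], f[j, ], f[j + 1L, ])) total <- total + 1L
    }
  }
  total
}

# winding-number point-in-ring test (angle summation), boundary inclusive
oracle_point_in_ring <- function(pt, ring) {
  n <- nrow(ring)
  on_seg <- function(p, a, b) {
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cross) > 1e-9 * max(1, sum(abs(b - a)))) return(FALSE)
    all(p >= pmin(a, b) - 1e-9) && all(p <= pmax(a, b) + 1e-9)
  }
  total <- 0
  for (i in seq_len(n)) {
    a <- ring[i, ]; b <- ring[if (i == n) 1L else i + 1L, ]
    if (on_seg(pt, a, b)) return(TRUE)
    a1 <- atan2(a[2] - pt[2], a[1] - pt[1])
    a2 <- atan2(b[2] - pt[2], b[1] - pt[1])
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    total <- total + d
  }
  abs(total) > pi
}

# gift-wrapping (Jarvis march) convex hull vertex set
oracle_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1L) 2L else 1L
    for (k in seq_len(n)) {
      if (k == cur) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
        (pts[cand, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      if (cand == cur || cr < 0 ||
          (cr == 0 && sum((pts[k, ] - pts[cur, ])^2) > sum((pts[cand, ] - pts[cur, ])^2)))
        cand <- k
    }
    cur <- cand
    if (cur == start) break
  }
  pts[hull, , drop = FALSE]
}

# direct conditional-logistic log-likelihood (per-stratum loop), for
# grid-search maximization on small fixtures
oracle_clogit_ll <- function(beta, sets, covariate) {
  ll <- 0
  for (sid in unique(sets$stratum_id)) {
    s <- sets[sets$stratum_id == sid, ]
    eta <- beta * s[[covariate]]
    ll <- ll + eta[s$used == 1] - log(sum(exp(eta)))
  }
  ll
}

# small hand-built toy landscape on [0, 100]^2:
#  - vertical road line x = 50 with a 4 m wide footprint and 5 m buffer
#  - horizontal trail y = 20
#  - powerline clear cut rectangle x in [0, 100], y in [60, 70]
toy_landscape <- function() {
  road <- rbind(c(50, 0), c(50, 100))
  trail <- rbind(c(0, 20), c(100, 20))
  road_poly <- lc_rect(48, 0, 52, 100)
  landscape(roads = list(road), trails = list(trail),
            powerline = lc_rect(0, 60, 100, 70),
            road_buffer = buffer_polygon(road_poly, 5),
            study_area = lc_rect(0, 0, 100, 100),
            road_polygon = road_poly)
}

# relocation table builder for hand fixtures: one row per relocation
make_relocs <- function(xy, animal_id = "A1", sex = "F", year = 2020) {
  n <- nrow(xy)
  moved <- c(FALSE, sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2) > 1)
  df <- data.frame(animal_id = animal_id, sex = sex, year = year,
                   timestamp = as.POSIXct(sprintf("%d-05-01", year), tz = "UTC") +
                     86400 * (seq_len(n) - 1L),
                   x = xy[, 1], y = xy[, 2], moved = moved,
                   stringsAsFactors = FALSE)
  class(df) <- c("lc_relocations", "data.frame")
  df
}

# small feature-indifferent simulation config (used by calibration tests)
indifferent_config <- function(seed, n_animals = 6L, n_relocations = 60L) {
  sim_config(n_animals_per_sex = n_animals,
             years_per_animal = list(M = 0, F = 1),
             n_relocations = n_relocations,
             move_prob = c(buffer = 0.5, powerline = 0.5, other = 0.5),
             beta = c(road_cross = 0, trail_cross = 0,
                      end_in_powerline = 0, end_in_buffer = 0),
             seed = seed)
}
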