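## Trajectory-randomization null models.
##
## For each animal-year path we build 1000 randomized versions under two
## schemes -- (1) rigid rotation by a uniform random angle about the true
## starting location, and (2) translation to a uniform random start inside
## the study area plus a uniform random rotation -- and compare observed
## feature-interaction counts (road/trail crossings, powerline and
## road-buffer occupancy) with the pooled null distribution via a
## percentile statistic P_i.  Because the animals are sit-and-wait
## predators with long stationary runs, randomizations recycle the
## observed path shape rather than a correlated random walk.

#' Define a null-path randomization scheme
#'
#' @param kind "random_angle" (rotation about the true start) or
#'   "random_start_random_angle" (uniform random start in the study area,
#'   then rotation).
#' @param n_paths number of random paths per trajectory (default 1000).
#' @param seed master seed; per-trajectory substreams are derived from it
#'   so removing one individual never perturbs another's paths.
#' @export
null_scheme <- function(kind = c("random_angle", "random_start_random_angle"),
                        n_paths = 1000L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_paths >= 1L)
  structure(list(kind = kind, n_paths = as.integer(n_paths),
                 seed = as.integer(seed)), class = "lc_null_scheme")
}

## stable per-trajectory substream seed, kept under 2^31
.substream_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + 104729 * as.numeric(index)) %% 2147483629 + 1)
}

.traj_polyline <- function(traj) {
  ## full relocation polyline, stationary repeats included: occupancy is
  ## counted over all relocations, so null paths must carry the repeats too
  as_path(as.matrix(traj[, c("x", "y")]))
}

#' Random-angle null paths
#'
#' Rigid rotations of the observed path about its first relocation by
#' independent uniform angles on [0, 2*pi).  Step lengths (and stationary
#' repeats) are preserved exactly; only orientation changes.
#'
#' @param traj one animal-year data.frame (or a polyline matrix).
#' @param scheme an [null_scheme()] with kind "random_angle".
#' @return list of polyline matrices, length `scheme$n_paths`.
#' @export
random_angle_paths <- function(traj, scheme) {
  stopifnot(scheme$kind == "random_angle")
  path <- if (is.matrix(traj)) as_path(traj) else .traj_polyline(traj)
  if (!is.null(scheme$seed)) set.seed(scheme$seed)
  angles <- stats::runif(scheme$n_paths, 0, 2 * pi)
  pivot <- path[1, ]
  lapply(angles, function(a) rotate_path(path, a, pivot))
}

#' Random-start random-angle null paths
#'
#' The observed path translated to an independent uniform random start
#' inside the study area, then rotated by an independent uniform angle.
#' Only the start is constrained to the study area; the rest of the path
#' may leave it.
#'
#' @param traj one animal-year data.frame (or a polyline matrix).
#' @param study_area an `lc_polygon` with positive area.
#' @param scheme an [null_scheme()] with kind "random_start_random_angle".
#' @return list of polyline matrices.
#' @export
random_start_paths <- function(traj, study_area, scheme) {
  stopifnot(scheme$kind == "random_start_random_angle")
  path <- if (is.matrix(traj)) as_path(traj) else .traj_polyline(traj)
  if (polygon_area(study_area) <= 0)
    stop("invalid geometry: study area has zero area", call. = FALSE)
  if (!is.null(scheme$seed)) set.seed(scheme$seed)
  starts <- sample_points_in_polygon(study_area, scheme$n_paths)
  angles <- stats::runif(scheme$n_paths, 0, 2 * pi)
  lapply(seq_len(scheme$n_paths), function(j) {
    rotate_path(translate_path(path, starts[j, ]), angles[j], starts[j, ])
  })
}

.feature_names <- c("road_cross", "trail_cross", "powerline_occupancy", "buffer_occupancy")

#' Tally feature interactions of one path
#'
#' Road and trail crossings are transversal segment crossings of the path;
#' powerline and buffer occupancy count path vertices (all relocations,
#' stationary repeats included) inside the polygon.
#'
#' @param path polyline matrix.
#' @param landscape an `lc_landscape`.
#' @return named integer vector road_cross, trail_cross,
#'   powerline_occupancy, buffer_occupancy.
#' @export
tally_features <- function(path, landscape) {
  path <- as_path(path)
  c(road_cross = count_crossings(path, landscape$roads),
    trail_cross = count_crossings(path, landscape$trails),
    powerline_occupancy = count_points_in_polygon(path, landscape$powerline),
    buffer_occupancy = count_points_in_polygon(path, landscape$road_buffer))
}

## batched tally of many same-shape paths: stack edges/vertices once
.tally_paths <- function(paths, landscape) {
  np <- length(paths)
  nv <- nrow(paths[[1]])
  all_pts <- do.call(rbind, paths)
  pid <- rep(seq_len(np), each = nv)
  occ_pl <- points_in_polygon(all_pts, landscape$powerline)
  occ_bf <- points_in_polygon(all_pts, landscape$road_buffer)
  E_all <- do.call(rbind, lapply(paths, .path_edges))
  eid <- rep(seq_len(np), each = nv - 1L)
  nz <- (E_all[, 1] != E_all[, 3]) | (E_all[, 2] != E_all[, 4])
  cross_layer <- function(layer) {
    out <- numeric(np)
    if (!any(nz) || length(layer) == 0L) return(out)
    P <- E_all[nz, , drop = FALSE]
    id <- eid[nz]
    for (f in layer) {
      Q <- .path_edges(as_path(f))
      qk <- (Q[, 1] != Q[, 3]) | (Q[, 2] != Q[, 4])
      Q <- Q[qk, , drop = FALSE]
      if (nrow(Q) == 0L) next
      hits <- rowSums(.seg_cross_matrix(P, Q))
      agg <- rowsum(hits, id)
      out[as.integer(rownames(agg))] <- out[as.integer(rownames(agg))] + agg[, 1]
    }
    out
  }
  cbind(road_cross = cross_layer(landscape$roads),
        trail_cross = cross_layer(landscape$trails),
        powerline_occupancy = rowsum(as.numeric(occ_pl), pid)[, 1],
        buffer_occupancy = rowsum(as.numeric(occ_bf), pid)[, 1])
}

#' Percentile statistic of an observed count within its null distribution
#'
#' Mid-rank tie rule: P_i = (#\{null < obs\} + 0.5 #\{null = obs\}) / n.
#' Values below 0.05 indicate the observed count is lower than expected
#' under random movement (avoidance); above 0.95, higher (preference).
#'
#' @param observed observed count.
#' @param null_counts numeric vector of null counts.
#' @return fraction in [0, 1].
#' @export
percentile_statistic <- function(observed, null_counts) {
  stopifnot(length(null_counts) >= 1L)
  (sum(null_counts < observed) + 0.5 * sum(null_counts == observed)) /
    length(null_counts)
}

## per-trajectory randomization + tallies, cached for pooling and LOIOCV
.null_tallies <- function(relocs, landscape, scheme) {
  trajs <- split_trajectories(relocs)
  keys <- names(trajs)
  cache <- vector("list", length(trajs))
  names(cache) <- keys
  for (i in seq_along(trajs)) {
    tr <- trajs[[i]]
    sub <- scheme
    sub$seed <- .substream_seed(scheme$seed, i)
    paths <- switch(scheme$kind,
      random_angle = random_angle_paths(tr, sub),
      random_start_random_angle = random_start_paths(tr, landscape$study_area, sub))
    cache[[i]] <- list(
      animal_id = tr$animal_id[1], sex = tr$sex[1], year = tr$year[1],
      observed = tally_features(.traj_polyline(tr), landscape),
      nulls = .tally_paths(paths, landscape))
  }
  cache
}

.pool_cache <- function(cache, n_paths) {
  sexes <- unique(vapply(cache, `[[`, "", "sex"))
  rows <- list(); nulls <- list()
  for (sx in sort(sexes)) {
    sel <- cache[vapply(cache, function(z) z$sex == sx, TRUE)]
    obs <- Reduce(`+`, lapply(sel, `[[`, "observed"))
    nl <- Reduce(`+`, lapply(sel, `[[`, "nulls"))  # paired: j-th path of each trajectory summed
    for (ft in .feature_names) {
      rows[[length(rows) + 1L]] <- data.frame(
        sex = sx, feature = ft, observed = obs[[ft]],
        p_i = percentile_statistic(obs[[ft]], nl[, ft]),
        null_mean = mean(nl[, ft]),
        null_q025 = unname(stats::quantile(nl[, ft], 0.025)),
        null_q975 = unname(stats::quantile(nl[, ft], 0.975)),
        stringsAsFactors = FALSE)
      nulls[[paste(sx, ft, sep = ".")]] <- nl[, ft]
    }
  }
  list(results = do.call(rbind, rows), null_counts = nulls)
}

#' Pooled null-path analysis by sex
#'
#' Observed counts are summed over each sex's trajectories; the j-th
#' pooled null count is the sum of the j-th random path's tally across
#' those trajectories (paired summation), giving exactly n_paths pooled
#' null values per sex and feature.
#'
#' @param relocs an `lc_relocations` data.frame (see [build_trajectories()]).
#' @param landscape an `lc_landscape`.
#' @param scheme an [null_scheme()].
#' @return object of class `lc_nullresult`: `$results` data.frame (sex,
#'   feature, observed, p_i, null summaries), `$null_counts` named list of
#'   full null vectors, `$cache` per-trajectory tallies (reused by
#'   [loiocv()]), `$scheme`.
#' @export
pooled_null_analysis <- function(relocs, landscape, scheme) {
  cache <- .null_tallies(relocs, landscape, scheme)
  pooled <- .pool_cache(cache, scheme$n_paths)
  structure(list(results = pooled$results, null_counts = pooled$null_counts,
                 cache = cache, scheme = scheme), class = "lc_nullresult")
}

#' @export
print.lc_nullresult <- function(x, ...) {
  cat("Null-path analysis (", x$scheme$kind, ", n_paths = ",
      x$scheme$n_paths, ")\n", sep = "")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Leave-one-individual-out cross-validation of P_i
#'
#' Recomputes each sex's pooled P_i with one individual removed at a time,
#' reusing the cached per-trajectory tallies (the same random paths; no
#' re-randomization), to gauge how much any one animal drives the result.
#'
#' @param x an `lc_nullresult` from [pooled_null_analysis()], or an
#'   `lc_relocations` table (then `landscape` and `scheme` are required).
#' @param landscape,scheme used only when `x` is a relocation table.
#' @return data.frame: sex, feature, left_out (animal id), p_i.
#' @export
loiocv <- function(x, landscape = NULL, scheme = NULL) {
  if (!inherits(x, "lc_nullresult")) {
    stopifnot(!is.null(landscape), !is.null(scheme))
    x <- pooled_null_analysis(x, landscape, scheme)
  }
  cache <- x$cache
  sexes <- unique(vapply(cache, `[[`, "", "sex"))
  rows <- list()
  for (sx in sort(sexes)) {
    sel <- cache[vapply(cache, function(z) z$sex == sx, TRUE)]
    ids <- unique(vapply(sel, `[[`, "", "animal_id"))
    if (length(ids) < 2L) {
      warning("LOIOCV: sex ", sx, " has a single individual; skipped", call. = FALSE)
      next
    }
    for (id in sort(ids)) {
      keep <- sel[vapply(sel, function(z) z$animal_id != id, TRUE)]
      obs <- Reduce(`+`, lapply(keep, `[[`, "observed"))
      nl <- Reduce(`+`, lapply(keep, `[[`, "nulls"))
      for (ft in .feature_names) {
        rows[[length(rows) + 1L]] <- data.frame(
          sex = sx, feature = ft, left_out = id,
          p_i = percentile_statistic(obs[[ft]], nl[, ft]),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Histogram of a pooled null distribution with the observed count marked
#'
#' @param x an `lc_nullresult`.
#' @param sex,feature which pooled distribution to draw.
#' @param ... passed to [graphics::hist()].
#' @export
plot_null_distribution <- function(x, sex, feature, ...) {
  key <- paste(sex, feature, sep = ".")
  nl <- x$null_counts[[key]]
  if (is.null(nl)) stop("no null distribution for ", key, call. = FALSE)
  row <- x$results[x$results$sex == sex & x$results$feature == feature, ]
  graphics::hist(nl, main = sprintf("%s (%s): P_i = %.3f", feature, sex, row$p_i),
                 xlab = "count per set of pooled random paths", col = "grey85",
                 border = "white", ...)
  graphics::abline(v = row$observed, lwd = 2)
  invisible(x)
}
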