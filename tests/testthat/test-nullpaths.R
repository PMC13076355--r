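test_that("random-angle paths are exact isometries anchored at the start", {
  cfg <- sim_config(n_animals_per_sex = 1, years_per_animal = list(M = 0, F = 1),
                    n_relocations = 40, seed = 17)
  tr <- split_trajectories(build_trajectories(simulate_population(cfg)$fixes))[[1]]
  paths <- random_angle_paths(tr, null_scheme("random_angle", n_paths = 100, seed = 4))
  obs <- unname(as.matrix(tr[, c("x", "y")]))
  lens <- function(p) sort(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2))
  for (p in paths) {
    expect_equal(unname(p[1, ]), obs[1, ], tolerance = 1e-12)
    expect_equal(lens(p), lens(obs), tolerance = 1e-9)
  }
})

test_that("random-angle bearings are uniform on the circle (Rayleigh test)", {
  path <- rbind(c(0, 0), c(10, 0), c(15, 5))
  paths <- random_angle_paths(path, null_scheme("random_angle", n_paths = 10000, seed = 99))
  bearings <- vapply(paths, function(p) atan2(p[2, 2] - p[1, 2], p[2, 1] - p[1, 1]), 0)
  n <- length(bearings)
  rbar <- sqrt(mean(cos(bearings))^2 + mean(sin(bearings))^2)
  p_value <- exp(-n * rbar^2)   # Rayleigh approximation
  expect_gt(p_value, 0.01)
})

test_that("random-start paths begin uniformly inside the study area", {
  sq <- lc_rect(0, 0, 100, 100)
  path <- rbind(c(40, 40), c(50, 45), c(55, 60))
  paths <- random_start_paths(path, sq,
                              null_scheme("random_start_random_angle",
                                          n_paths = 10000, seed = 12))
  starts <- t(vapply(paths, function(p) p[1, ], c(0, 0)))
  expect_true(all(points_in_polygon(starts, sq)))
  # mean within 3 standard errors of the centroid
  se <- 100 / sqrt(12) / sqrt(nrow(starts))
  expect_lt(abs(mean(starts[, 1]) - 50), 3 * se)
  expect_lt(abs(mean(starts[, 2]) - 50), 3 * se)
  # degenerate limit: a tiny cell around the true start pins the start
  tiny <- lc_rect(39.999, 39.999, 40.001, 40.001)
  p2 <- random_start_paths(path, tiny,
                           null_scheme("random_start_random_angle",
                                       n_paths = 20, seed = 3))
  for (p in p2) expect_equal(p[1, ], c(40, 40), tolerance = 0.01)
})

test_that("tally_features hand-constructed counts match brute force", {
  land <- toy_landscape()
  far <- rbind(c(5, 90), c(10, 95))
  expect_identical(unname(tally_features(far, land)), c(0L, 0L, 0L, 0L))
  # crosses the road once; three relocations inside the powerline cut
  path <- rbind(c(30, 65), c(35, 65), c(40, 65), c(70, 55))
  tl <- tally_features(path, land)
  expect_identical(unname(tl), c(1L, 0L, 3L, 0L))
  expect_identical(tl[["road_cross"]], oracle_crossings(path, land$roads))
  # reversal invariance
  expect_identical(tally_features(path[4:1, ], land), tl)
})

test_that("percentile statistic uses the mid-rank tie rule", {
  expect_equal(percentile_statistic(5, c(0, 1, 2, 3, 4)), 1)
  expect_equal(percentile_statistic(0, c(1, 2, 3)), 0)
  expect_equal(percentile_statistic(1, c(0, 1, 1, 2)), 0.5)
  # monotone non-decreasing in the observed count
  set.seed(8)
  nulls <- rpois(100, 4)
  p <- vapply(0:12, percentile_statistic, 0, null_counts = nulls)
  expect_true(all(diff(p) >= 0))
  # mid-rank symmetry: P(obs vs nulls) + P(reflected) = 1
  expect_equal(percentile_statistic(3, nulls) +
                 (sum(nulls > 3) + 0.5 * sum(nulls == 3)) / 100, 1)
})

test_that("pooled analysis pairs the j-th path across trajectories", {
  cfg <- sim_config(n_animals_per_sex = 2, years_per_animal = list(M = 0, F = 1),
                    n_relocations = 30, seed = 23)
  sim <- simulate_population(cfg)
  rel <- build_trajectories(sim$fixes)
  pn <- pooled_null_analysis(rel, sim$landscape,
                             null_scheme("random_angle", n_paths = 7, seed = 2))
  expect_length(pn$null_counts[["F.road_cross"]], 7L)
  # pooled nulls are the paired elementwise sums of per-trajectory tallies
  manual <- Reduce(`+`, lapply(pn$cache, `[[`, "nulls"))
  for (ft in colnames(manual)) {
    expect_equal(unname(pn$null_counts[[paste0("F.", ft)]]), unname(manual[, ft]))
  }
  obs <- Reduce(`+`, lapply(pn$cache, `[[`, "observed"))
  expect_identical(pn$results$observed,
                   as.integer(obs[pn$results$feature]))
})

test_that("the null analysis is reproducible and LOIOCV reuses cached tallies", {
  cfg <- sim_config(n_animals_per_sex = 3, years_per_animal = list(M = 1, F = 1),
                    n_relocations = 30, seed = 29)
  sim <- simulate_population(cfg)
  rel <- build_trajectories(sim$fixes)
  sch <- null_scheme("random_start_random_angle", n_paths = 25, seed = 77)
  a <- pooled_null_analysis(rel, sim$landscape, sch)
  b <- pooled_null_analysis(rel, sim$landscape, sch)
  expect_identical(a$results, b$results)
  expect_identical(a$null_counts, b$null_counts)
  lo <- loiocv(a)
  expect_true(all(lo$p_i >= 0 & lo$p_i <= 1))
  expect_identical(lo, loiocv(b))
  # leaving out an animal re-pools the cached tallies of the others
  keep <- a$cache[vapply(a$cache, function(z)
    z$sex == "F" & z$animal_id != "F01", TRUE)]
  manual <- percentile_statistic(
    Reduce(`+`, lapply(keep, `[[`, "observed"))[["buffer_occupancy"]],
    Reduce(`+`, lapply(keep, `[[`, "nulls"))[, "buffer_occupancy"])
  expect_equal(lo$p_i[lo$sex == "F" & lo$left_out == "F01" &
                        lo$feature == "buffer_occupancy"], manual)
})

test_that("identical individuals give exchangeable leave-one-out values", {
  # each trajectory draws its own null-path substream (so that LOIOCV can
  # drop an animal without perturbing the others), hence two clones agree
  # in observed tallies exactly and in P_i up to null Monte-Carlo error
  xy <- rbind(c(20, 40), c(40, 46), c(62, 52), c(70, 63), c(81, 69))
  rel <- rbind(make_relocs(xy, "A1", "F"), make_relocs(xy, "A2", "F"))
  class(rel) <- c("lc_relocations", "data.frame")
  land <- toy_landscape()
  pn <- pooled_null_analysis(rel, land, null_scheme("random_angle", 400, seed = 6))
  expect_identical(pn$cache[[1]]$observed, pn$cache[[2]]$observed)
  lo <- loiocv(pn)
  for (ft in unique(lo$feature)) {
    vals <- lo$p_i[lo$feature == ft]
    expect_lt(abs(vals[1] - vals[2]), 3 * sqrt(0.25 / 400) + 1e-9)
  }
})

test_that("a sex with a single individual is skipped in LOIOCV with a warning", {
  xy <- rbind(c(0, 0), c(10, 3), c(22, 9))
  rel <- rbind(make_relocs(xy, "A1", "F"), make_relocs(xy + 5, "A2", "M"),
               make_relocs(xy + 9, "A3", "M"))
  class(rel) <- c("lc_relocations", "data.frame")
  pn <- pooled_null_analysis(rel, toy_landscape(),
                             null_scheme("random_angle", n_paths = 10, seed = 1))
  expect_warning(lo <- loiocv(pn), "single individual")
  expect_true(all(lo$sex == "M"))
})
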