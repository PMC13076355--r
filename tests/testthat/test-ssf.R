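test_that("gamma MLE recovers parameters and matches the sample mean", {
  set.seed(101)
  x <- rgamma(10000, shape = 2, scale = 10)
  fit <- fit_gamma(x)
  expect_equal(fit$shape, 2, tolerance = 0.05)
  expect_equal(fit$mean, mean(x), tolerance = 0.01)   # MLE mean-matching
  # skewed small sample still mean-matches
  y <- rgamma(200, shape = 0.6, scale = 40)
  expect_equal(fit_gamma(y)$mean, mean(y), tolerance = 0.01)
  expect_error(fit_gamma(rep(5, 10)), "degenerate")
  expect_error(fit_gamma(c(1, 2, -3, 4, 5)), "positive")
  expect_error(fit_gamma(c(1, 2)), ">= 5")
})

test_that("choice sets have the right shape and are seed-reproducible", {
  # 12 unique locations -> 11 movement steps -> 10 strata (first lacks a turn)
  set.seed(55)
  xy <- cbind(cumsum(runif(12, 5, 30)), cumsum(runif(12, -20, 20)))
  tr <- make_relocs(xy)
  gf <- fit_gamma(derive_steps(tr)$length)
  cs <- generate_choice_sets(tr, gf, n_random = 10, seed = 9)
  expect_identical(length(unique(cs$stratum_id)), 10L)
  expect_identical(nrow(cs), 110L)
  expect_true(all(tapply(cs$used, cs$stratum_id, sum) == 1L))
  # random steps share the realized start
  expect_true(all(tapply(cs$x0, cs$stratum_id, function(v) length(unique(v))) == 1L))
  expect_identical(cs, generate_choice_sets(tr, gf, n_random = 10, seed = 9))
  # used step geometry reproduces the realized step
  used <- cs[cs$used == 1, ]
  st <- derive_steps(tr)
  expect_equal(used$length, st$length[!is.na(st$turn_angle)])
})

test_that("random step lengths follow the generating gamma", {
  set.seed(77)
  xy <- cbind(cumsum(runif(60, 5, 30)), cumsum(runif(60, -20, 20)))
  tr <- make_relocs(xy)
  gf <- list(shape = 1.5, scale = 20, mean = 30)
  class(gf) <- "lc_gamma_fit"
  cs <- generate_choice_sets(tr, gf, n_random = 40, seed = 2)
  lens <- cs$length[cs$used == 0]
  ks <- suppressWarnings(stats::ks.test(lens, "pgamma", shape = 1.5, scale = 20))
  expect_gt(ks$p.value, 0.01)
})

test_that("annotation flags crossings and endpoint occupancy on a toy landscape", {
  land <- toy_landscape()
  sets <- data.frame(
    stratum_id = "s1", animal_id = "A", sex = "F", year = 2020,
    used = c(1L, 0L, 0L, 0L),
    x0 = 30, y0 = 30,
    x1 = c(35, 56, 44, 30), y1 = c(35, 30, 30, 65))
  ann <- annotate_choice_sets(sets, land)
  covs <- c("road_cross", "trail_cross", "end_in_powerline", "end_in_buffer")
  expect_identical(ann$road_cross, c(0L, 1L, 0L, 0L))
  # ends at 56 and 44 are within 5 m of the 48-52 road footprint; only the
  # first of those crossed the centerline to get there
  expect_identical(ann$end_in_buffer, c(0L, 1L, 1L, 0L))
  expect_identical(ann$end_in_powerline, c(0L, 0L, 0L, 1L))
  expect_identical(ann$trail_cross, c(0L, 0L, 0L, 0L))
  # invariant to stratum relabeling
  sets2 <- sets; sets2$stratum_id <- "zz"
  expect_identical(annotate_choice_sets(sets2, land)[, covs], ann[, covs])
})

# a small frozen single-covariate fixture: 6 strata of 1 used + 2 random
clogit_fixture <- function() {
  data.frame(
    stratum_id = rep(sprintf("s%d", 1:6), each = 3),
    animal_id = rep(c("A", "A", "B", "B", "C", "C"), each = 3),
    sex = "F",
    used = rep(c(1L, 0L, 0L), 6),
    x = c(1, 0, 0,  0, 1, 1,  1, 0, 1,  0, 0, 1,  1, 1, 0,  0, 1, 0))
}

test_that("the conditional-logistic maximizer matches a grid-search oracle", {
  sets <- clogit_fixture()
  fit <- fit_conditional_logistic(sets, covariates = "x")
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, oracle_clogit_ll, 0, sets = sets, covariate = "x")
  expect_equal(fit$coefficients$estimate, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("direct maximizer, Poisson reformulation and clogit agree", {
  cfg <- sim_config(n_animals_per_sex = 3, years_per_animal = list(M = 1, F = 1),
                    n_relocations = 60, seed = 41)
  sim <- simulate_population(cfg)
  rel <- build_trajectories(sim$fixes)
  sets <- do.call(rbind, lapply(build_ssf_data(rel, sim$landscape, 10, 3), `[[`, "sets"))
  covs <- c("road_cross", "trail_cross", "end_in_powerline", "end_in_buffer")
  keep <- covs[vapply(covs, function(cv)
    any(tapply(sets[[cv]], sets$stratum_id, function(v) max(v) - min(v)) > 0), TRUE)]
  direct <- fit_conditional_logistic(sets, covariates = keep)
  pois <- fit_clogit_poisson(sets, covariates = keep)
  expect_equal(unname(pois), direct$coefficients$estimate, tolerance = 1e-3)
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  sv <- survival::clogit(
    stats::as.formula(paste("used ~", paste(keep, collapse = "+"),
                            "+ strata(stratum_id)")), data = sets)
  expect_equal(unname(stats::coef(sv)), direct$coefficients$estimate,
               tolerance = 1e-4)
})

test_that("only within-stratum contrasts matter", {
  sets <- clogit_fixture()
  base <- fit_conditional_logistic(sets, covariates = "x")
  shifted <- sets
  shifts <- stats::setNames(c(3, -1, 0.5, 2, -4, 10), sprintf("s%d", 1:6))
  shifted$x <- shifted$x + shifts[shifted$stratum_id]
  fit2 <- fit_conditional_logistic(shifted, covariates = "x")
  expect_equal(fit2$coefficients$estimate, base$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("degenerate designs raise informative errors", {
  sets <- clogit_fixture()
  sets$z <- rep(c(1, 1, 1), 6)        # constant within every stratum
  expect_error(fit_conditional_logistic(sets, covariates = "z"),
               "non-identifiable.*'z'")
  # perfect separation: used always has x = 1, alternatives 0
  sep <- clogit_fixture()
  sep$x <- rep(c(1, 0, 0), 6)
  expect_warning(fit_sep <- fit_conditional_logistic(sep, covariates = "x"),
                 "separation")
  expect_lte(abs(fit_sep$coefficients$estimate), 15)
})

test_that("random-slope fit agrees with fixed effects under homogeneity", {
  cfg <- sim_config(n_animals_per_sex = 4, years_per_animal = list(M = 1, F = 1),
                    n_relocations = 50, seed = 47)
  sim <- simulate_population(cfg)
  rel <- build_trajectories(sim$fixes)
  sets <- do.call(rbind, lapply(build_ssf_data(rel, sim$landscape, 10, 3), `[[`, "sets"))
  covs <- c("end_in_powerline", "end_in_buffer")
  fe <- fit_conditional_logistic(sets, covariates = covs)
  re <- fit_conditional_logistic(sets, random_effects = TRUE, covariates = covs)
  # simulated animals share one beta, so random slopes should shrink away
  expect_equal(re$coefficients$estimate, fe$coefficients$estimate, tolerance = 0.15)
  expect_true(all(re$coefficients$lwr < re$coefficients$estimate))
  expect_true(all(re$coefficients$upr > re$coefficients$estimate))
  expect_true(all(re$ranef_sd < 1))
})

test_that("RSS transforms are reciprocal and interval-consistent", {
  expect_equal(rss(0), 1)
  expect_equal(log_rss(0.37), 0.37)
  for (b in c(-2.1, -0.3, 0.8, 1.6)) expect_equal(rss(-b), 1 / rss(b))
  sets <- clogit_fixture()
  fit <- fit_conditional_logistic(sets, covariates = "x")
  tb <- rss_table(fit)
  expect_equal(tb$rss, exp(tb$estimate))
  expect_equal(tb$rss_lwr, exp(tb$lwr))
  expect_true(tb$lwr < tb$estimate && tb$estimate < tb$upr)
})
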