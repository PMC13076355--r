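## End-to-end analysis pipeline: preprocess -> null paths -> SSF ->
## movement models -> report bundle.  Every stage consumes and emits
## files, so any stage can be re-run in isolation; the manifest records
## the configuration and seed needed to reproduce every number.

#' Assemble hurdle-model records from relocations
#'
#' One record per relocation after the first of each animal-year: the
#' move/remain response and, for moves, the realized step length.
#'
#' @param relocs an `lc_relocations` data.frame.
#' @return data.frame: animal_id, sex, moved, length.
#' @export
hurdle_records <- function(relocs) {
  out <- lapply(split_trajectories(relocs), function(tr) {
    n <- nrow(tr)
    if (n < 2L) return(NULL)
    d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    data.frame(animal_id = tr$animal_id[1], sex = tr$sex[1],
               moved = as.integer(tr$moved[-1]),
               length = ifelse(tr$moved[-1], d, NA_real_),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble context-dependent movement records
#'
#' One record per relocation after the first: the move/remain response
#' and whether the *previous* relocation lay inside the habitat polygon.
#'
#' @param relocs an `lc_relocations` data.frame.
#' @param landscape an `lc_landscape`.
#' @param habitat "buffer" (roadside) or "powerline".
#' @return data.frame: animal_id, sex, moved, in_habitat_prior.
#' @export
context_records <- function(relocs, landscape, habitat = c("buffer", "powerline")) {
  habitat <- match.arg(habitat)
  poly <- if (habitat == "buffer") landscape$road_buffer else landscape$powerline
  out <- lapply(split_trajectories(relocs), function(tr) {
    n <- nrow(tr)
    if (n < 2L) return(NULL)
    prior_in <- points_in_polygon(as.matrix(tr[, c("x", "y")]), poly)[-n]
    data.frame(animal_id = tr$animal_id[1], sex = tr$sex[1],
               moved = as.integer(tr$moved[-1]),
               in_habitat_prior = as.integer(prior_in),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build annotated step-selection data per sex
#'
#' Fits the step-length gamma on each sex's pooled observed movement
#' steps, generates choice sets per trajectory (with per-trajectory seed
#' substreams), and annotates them against the landscape.
#'
#' @param relocs an `lc_relocations` data.frame.
#' @param landscape an `lc_landscape`.
#' @param n_random random steps per stratum (default 10).
#' @param seed master seed.
#' @return named list by sex: `$sets` annotated choice sets,
#'   `$gamma_fit`.
#' @export
build_ssf_data <- function(relocs, landscape, n_random = 10L, seed = 1L) {
  trajs <- split_trajectories(relocs)
  out <- list()
  for (sx in sort(unique(relocs$sex))) {
    sel <- trajs[vapply(trajs, function(tr) tr$sex[1] == sx, TRUE)]
    lens <- unlist(lapply(sel, function(tr) derive_steps(tr)$length))
    gf <- fit_gamma(lens)
    sets <- list()
    for (i in seq_along(sel)) {
      cs <- generate_choice_sets(sel[[i]], gf, n_random = n_random,
                                 seed = .substream_seed(seed, 10000L + i))
      if (nrow(cs)) sets[[length(sets) + 1L]] <- cs
    }
    sets <- annotate_choice_sets(do.call(rbind, sets), landscape)
    out[[sx]] <- list(sets = sets, gamma_fit = gf)
  }
  out
}

#' Pipeline run configuration
#'
#' @param relocations,landscape input file paths (CSV, GeoJSON); ignored
#'   when `simulate` is TRUE.
#' @param simulate generate inputs with [simulate_population()].
#' @param sim an [sim_config()] used when simulating (its seed is
#'   overridden by `seed`).
#' @param n_random_paths null paths per trajectory (default 1000).
#' @param n_random_steps random steps per SSF stratum (default 10).
#' @param buffer_distance roadside buffer distance in meters (default 5).
#' @param ssf_random_effects fit individual random slopes in the SSF.
#' @param sex_split analyze sexes separately (default TRUE).
#' @param seed master seed.
#' @param out_dir output directory for the report bundle.
#' @export
run_config <- function(relocations = NULL, landscape = NULL, simulate = FALSE,
                       sim = sim_config(), n_random_paths = 1000L,
                       n_random_steps = 10L, buffer_distance = 5,
                       ssf_random_effects = TRUE, sex_split = TRUE,
                       seed = 1L, out_dir = "linecross_run") {
  stopifnot(n_random_paths >= 1L, n_random_steps >= 1L, buffer_distance >= 0)
  structure(list(relocations = relocations, landscape = landscape,
                 simulate = simulate, sim = sim,
                 n_random_paths = as.integer(n_random_paths),
                 n_random_steps = as.integer(n_random_steps),
                 buffer_distance = buffer_distance,
                 ssf_random_effects = ssf_random_effects,
                 sex_split = sex_split, seed = as.integer(seed),
                 out_dir = out_dir), class = "lc_run_config")
}

.write_table <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Produces, in `config$out_dir`: the (simulated or copied) inputs, a
#' trajectory summary, null-path result tables with full null-count
#' vectors and histograms, the LOIOCV table, the SSF coefficient/RSS
#' table with a log-RSS forest plot, hurdle and context model summaries
#' with figures, and a machine-readable manifest.
#'
#' @param config an [run_config()].
#' @return (invisibly) a list with the in-memory results.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ## ---- inputs
  if (isTRUE(config$simulate)) {
    simcfg <- config$sim
    simcfg$seed <- config$seed
    sim <- simulate_population(simcfg)
    land <- sim$landscape
    fixes <- sim$fixes
    write_sim(sim, file.path(config$out_dir, "inputs"))
  } else {
    if (is.null(config$relocations) || is.null(config$landscape))
      stop("provide relocations and landscape paths, or set simulate = TRUE",
           call. = FALSE)
    fixes <- read_relocations(config$relocations)
    land <- read_landscape(config$landscape, config$buffer_distance)
  }
  ## ---- preprocess
  relocs <- build_trajectories(fixes)
  trajs <- split_trajectories(relocs)
  summ <- do.call(rbind, lapply(trajs, function(tr) data.frame(
    animal_id = tr$animal_id[1], sex = tr$sex[1], year = tr$year[1],
    n_relocations = nrow(tr), n_unique = nrow(unique_locations(tr)),
    total_path_m = sum(derive_steps(tr)$length))))
  rownames(summ) <- NULL
  .write_table(summ, config$out_dir, "trajectory_summary.csv")
  write_relocations(relocs, file.path(config$out_dir, "relocations_clean.csv"))
  message(sprintf("preprocess: %d relocations, %d animal-year trajectories",
                  nrow(relocs), nrow(summ)))
  ## ---- null paths (both schemes)
  null_results <- list()
  loio <- list()
  for (kind in c("random_angle", "random_start_random_angle")) {
    sch <- null_scheme(kind, n_paths = config$n_random_paths, seed = config$seed)
    res <- pooled_null_analysis(relocs, land, sch)
    res$results$scheme <- kind
    null_results[[kind]] <- res
    lo <- loiocv(res)
    if (!is.null(lo)) { lo$scheme <- kind; loio[[kind]] <- lo }
    for (key in names(res$null_counts)) {
      png_path <- file.path(config$out_dir,
                            sprintf("null_hist_%s_%s.png", kind, key))
      grDevices::png(png_path, width = 700, height = 500)
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      plot_null_distribution(res, parts[1], parts[2])
      grDevices::dev.off()
    }
    message(sprintf("nullpaths[%s]: %d paths/trajectory", kind, sch$n_paths))
  }
  .write_table(do.call(rbind, lapply(null_results, `[[`, "results")),
               config$out_dir, "null_results.csv")
  nc <- do.call(rbind, lapply(names(null_results), function(kind) {
    r <- null_results[[kind]]
    do.call(rbind, lapply(names(r$null_counts), function(key) data.frame(
      scheme = kind, key = key, j = seq_along(r$null_counts[[key]]),
      count = r$null_counts[[key]])))
  }))
  .write_table(nc, config$out_dir, "null_counts.csv")
  if (length(loio))
    .write_table(do.call(rbind, loio), config$out_dir, "loiocv.csv")
  ## ---- SSF
  ssf_data <- build_ssf_data(relocs, land, n_random = config$n_random_steps,
                             seed = config$seed)
  groups <- if (config$sex_split) names(ssf_data) else "all"
  ssf_fits <- list()
  ssf_tables <- list()
  for (g in groups) {
    sets <- if (g == "all") do.call(rbind, lapply(ssf_data, `[[`, "sets"))
            else ssf_data[[g]]$sets
    fit <- tryCatch(
      fit_conditional_logistic(sets, random_effects = config$ssf_random_effects),
      error = function(e) {
        warning("SSF fit failed for ", g, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    ssf_fits[[g]] <- fit
    tb <- rss_table(fit)
    tb$sex <- g
    ssf_tables[[g]] <- tb
    grDevices::png(file.path(config$out_dir, sprintf("ssf_forest_%s.png", g)),
                   width = 700, height = 400)
    plot_log_rss(fit, main = paste("log RSS,", g))
    grDevices::dev.off()
    message(sprintf("ssf[%s]: %d strata", g, fit$n_strata))
  }
  if (length(ssf_tables))
    .write_table(do.call(rbind, ssf_tables), config$out_dir, "ssf_table.csv")
  ## ---- movement models
  hr <- hurdle_records(relocs)
  hurdle <- fit_hurdle(hr)
  .write_table(hurdle$means, config$out_dir, "hurdle_means.csv")
  ctx_fits <- list()
  ctx_rows <- list()
  for (hb in c("buffer", "powerline")) {
    cr <- context_records(relocs, land, hb)
    ft <- tryCatch(fit_context_movement(cr), error = function(e) {
      warning("context model (", hb, ") failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(ft)) next
    ctx_fits[[hb]] <- ft
    ctx_rows[[hb]] <- data.frame(
      habitat = hb, beta = ft$beta, lwr = ft$ci[1], upr = ft$ci[2],
      odds_pct_change = odds_percent_change(ft$beta),
      p_out = ft$p_out[1], p_out_lwr = ft$p_out[2], p_out_upr = ft$p_out[3],
      p_in = ft$p_in[1], p_in_lwr = ft$p_in[2], p_in_upr = ft$p_in[3])
    grDevices::png(file.path(config$out_dir, sprintf("context_%s.png", hb)),
                   width = 500, height = 400)
    plot_context_fit(ft, main = paste("P(move) by", hb, "occupancy"))
    grDevices::dev.off()
  }
  if (length(ctx_rows))
    .write_table(do.call(rbind, ctx_rows), config$out_dir, "context_models.csv")
  ## ---- manifest
  manifest <- list(
    package = "linecross",
    version = as.character(utils::packageVersion("linecross")),
    r_version = R.version.string,
    seed = config$seed,
    n_random_paths = config$n_random_paths,
    n_random_steps = config$n_random_steps,
    buffer_distance = config$buffer_distance,
    ssf_random_effects = config$ssf_random_effects,
    simulate = config$simulate,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(relocations = relocs, null_results = null_results,
                 loiocv = if (length(loio)) do.call(rbind, loio),
                 ssf_fits = ssf_fits, hurdle = hurdle, context = ctx_fits,
                 summary = summ))
}
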