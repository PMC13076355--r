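## Movement-frequency and step-length models.
##
## A sit-and-wait forager yields zero-inflated displacement data: many
## relocations repeat the previous coordinates.  The hurdle model
## separates (i) the probability of moving at all (binomial, logit) from
## (ii) step length given movement (gamma, log link), each with a sex
## fixed effect and an animal-level random intercept.  The two parts have
## disjoint parameters, so the joint likelihood factorizes and the parts
## are fit independently.  The context-dependent movement model asks
## whether the habitat occupied at the previous relocation (road buffer,
## or powerline clear cut) changes the probability of moving; sexes are
## pooled.

.fit_glmm <- function(formula, data, family, random_effects) {
  if (random_effects && length(unique(data$animal_id)) < 2L) {
    warning("single animal: random intercept dropped", call. = FALSE)
    random_effects <- FALSE
  }
  if (random_effects) {
    fml <- stats::update.formula(formula, . ~ . + (1 | animal_id))
    fit <- lme4::glmer(fml, data = data, family = family)
    list(fixef = lme4::fixef(fit), vcov = as.matrix(stats::vcov(fit)),
         ranef_var = unname(lme4::VarCorr(fit)$animal_id[1, 1]),
         loglik = as.numeric(stats::logLik(fit)), fit = fit,
         dispersion = stats::sigma(fit)^2)
  } else {
    fit <- stats::glm(formula, data = data, family = family)
    disp <- summary(fit)$dispersion
    list(fixef = stats::coef(fit), vcov = as.matrix(stats::vcov(fit)),
         ranef_var = NA_real_, loglik = as.numeric(stats::logLik(fit)),
         fit = fit, dispersion = disp)
  }
}

## percentile bootstrap interval for exp(linear predictor) from the
## asymptotic normal of the fixed effects
.exp_lincomb_ci <- function(fixef, vcov, L, n = 1000L, seed = 1L) {
  set.seed(seed)
  ch <- chol(vcov + diag(1e-12, nrow(vcov)))
  draws <- matrix(stats::rnorm(n * length(fixef)), n) %*% ch
  draws <- sweep(draws, 2, fixef, `+`)
  vals <- exp(draws %*% L)
  c(stats::quantile(vals, 0.025), stats::quantile(vals, 0.975))
}

#' Sex-specific gamma hurdle model of movement
#'
#' @param records data.frame with columns moved (0/1), length (meters,
#'   used where moved == 1), sex ("F"/"M"), animal_id.
#' @param random_effects include animal random intercepts (default TRUE).
#' @return object of class `lc_hurdle_fit` with `$binomial`, `$gamma`
#'   component summaries, `$means` (per-sex predicted mean step length
#'   with a 95% parametric-bootstrap interval), and `$loglik`
#'   (binomial + gamma parts, which add to the hurdle total).
#' @export
fit_hurdle <- function(records, random_effects = TRUE) {
  stopifnot(all(c("moved", "length", "sex", "animal_id") %in% names(records)))
  records$sex <- factor(records$sex, levels = c("F", "M"))
  if (nlevels(droplevels(records$sex)) < 2L)
    stop("both sexes must be present", call. = FALSE)
  degenerate <- FALSE
  if (all(records$moved == 1) || all(records$moved == 0)) {
    warning("binomial part degenerate: moved indicator is constant", call. = FALSE)
    degenerate <- TRUE
  }
  binom <- if (degenerate) NULL else
    .fit_glmm(moved ~ sex, records, stats::binomial(), random_effects)
  movers <- records[records$moved == 1 & !is.na(records$length), ]
  for (sx in c("F", "M")) {
    if (sum(movers$sex == sx) < 2L)
      stop("gamma part cannot be fit: no movements for sex ", sx, call. = FALSE)
  }
  gam <- .fit_glmm(length ~ sex, movers, stats::Gamma(link = "log"), random_effects)
  means <- do.call(rbind, lapply(c("F", "M"), function(sx) {
    L <- c(1, as.numeric(sx == "M"))
    ci <- .exp_lincomb_ci(gam$fixef, gam$vcov, L)
    data.frame(sex = sx, mean_step_m = exp(sum(gam$fixef * L)),
               lwr = ci[1], upr = ci[2])
  }))
  rownames(means) <- NULL
  structure(list(
    binomial = binom, gamma = gam, means = means,
    gamma_shape = 1 / gam$dispersion,
    loglik = c(binomial = if (!is.null(binom)) binom$loglik else NA_real_,
               gamma = gam$loglik),
    degenerate_binomial = degenerate), class = "lc_hurdle_fit")
}

#' @export
print.lc_hurdle_fit <- function(x, ...) {
  cat("Gamma hurdle model of movement\n")
  if (!is.null(x$binomial)) {
    cat(sprintf("  P(move): sex effect %.3f (logit scale)\n", x$binomial$fixef[["sexM"]]))
  } else cat("  P(move): degenerate (constant response)\n")
  cat(sprintf("  step length | moved: sex effect %.3f (log scale), shape %.2f\n",
              x$gamma$fixef[["sexM"]], x$gamma_shape))
  print(x$means, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Context-dependent movement model
#'
#' Mixed binomial logistic regression of the move/remain response on a
#' binary indicator of the habitat occupied at the *previous* relocation,
#' with an animal random intercept; individuals of both sexes pooled.
#'
#' @param records data.frame with columns moved (0/1), in_habitat_prior
#'   (0/1), animal_id.
#' @param random_effects include the animal random intercept.
#' @return object of class `lc_context_fit`: `$beta` (habitat
#'   coefficient), `$ci`, `$p_in`, `$p_out` (movement probability inside /
#'   outside the habitat, with 95% CIs), `$fit`.
#' @export
fit_context_movement <- function(records, random_effects = TRUE) {
  stopifnot(all(c("moved", "in_habitat_prior", "animal_id") %in% names(records)))
  if (length(unique(records$in_habitat_prior)) < 2L)
    stop("non-identifiable: habitat indicator is constant", call. = FALSE)
  m <- .fit_glmm(moved ~ in_habitat_prior, records, stats::binomial(), random_effects)
  b <- m$fixef[["in_habitat_prior"]]
  se <- sqrt(m$vcov[2, 2])
  prob_ci <- function(L) {
    est <- stats::plogis(sum(m$fixef * L))
    set.seed(1L)
    ch <- chol(m$vcov + diag(1e-12, 2))
    draws <- sweep(matrix(stats::rnorm(2000), 1000) %*% ch, 2, m$fixef, `+`)
    q <- stats::quantile(stats::plogis(draws %*% L), c(0.025, 0.975))
    c(est = est, lwr = unname(q[1]), upr = unname(q[2]))
  }
  structure(list(
    beta = b, se = se, ci = c(b - 1.96 * se, b + 1.96 * se),
    intercept = m$fixef[[1]],
    p_out = prob_ci(c(1, 0)), p_in = prob_ci(c(1, 1)),
    ranef_var = m$ranef_var, loglik = m$loglik, fit = m$fit),
    class = "lc_context_fit")
}

#' @export
print.lc_context_fit <- function(x, ...) {
  cat(sprintf("Context-dependent movement: beta = %.3f (95%% CI %.3f, %.3f)\n",
              x$beta, x$ci[1], x$ci[2]))
  cat(sprintf("  P(move | outside) = %.2f (%.2f-%.2f)\n",
              x$p_out[1], x$p_out[2], x$p_out[3]))
  cat(sprintf("  P(move | inside)  = %.2f (%.2f-%.2f)\n",
              x$p_in[1], x$p_in[2], x$p_in[3]))
  invisible(x)
}

#' Percent change in odds for a logistic coefficient
#'
#' @param beta coefficient on the log-odds scale.
#' @return (exp(beta) - 1) * 100, the percent change in odds.
#' @export
odds_percent_change <- function(beta) (exp(beta) - 1) * 100

#' Human-readable odds change
#'
#' Negative coefficients read as "X% lower" (nearest percent); positive
#' ones as "Y times higher" (odds multiplier to 1 decimal).
#'
#' @param beta coefficient on the log-odds scale.
#' @export
describe_odds_change <- function(beta) {
  if (beta < 0) sprintf("%d%% lower", round(-odds_percent_change(beta)))
  else if (beta > 0) sprintf("%.1f times higher", exp(beta))
  else "unchanged"
}

#' Shift a probability by a log-odds increment
#'
#' @param p_base baseline probability, strictly inside (0, 1).
#' @param beta log-odds shift.
#' @return inverse-logit(logit(p_base) + beta).
#' @export
shift_probability <- function(p_base, beta) {
  if (any(p_base <= 0) || any(p_base >= 1))
    stop("p_base must lie strictly inside (0, 1)", call. = FALSE)
  stats::plogis(stats::qlogis(p_base) + beta)
}

#' Point-and-interval plot of habitat-specific movement probabilities
#' @param fit an `lc_context_fit`.
#' @param labels x labels for the outside/inside states.
#' @param ... passed to [graphics::plot()].
#' @export
plot_context_fit <- function(fit, labels = c("outside", "inside"), ...) {
  est <- c(fit$p_out[1], fit$p_in[1])
  lo <- c(fit$p_out[2], fit$p_in[2]); hi <- c(fit$p_out[3], fit$p_in[3])
  graphics::plot(1:2, est, xlim = c(0.5, 2.5), ylim = c(0, 1), xaxt = "n",
                 pch = 16, xlab = "", ylab = "P(move)", ...)
  graphics::axis(1, at = 1:2, labels = labels)
  graphics::segments(1:2, lo, 1:2, hi, lwd = 2)
  invisible(fit)
}
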