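## Step selection functions.
##
## Each realized movement step is paired with random available steps that
## share its start: lengths drawn from a gamma fitted to the observed
## movement steps, turn angles uniform on (-pi, pi].  Binary covariates
## (road/trail crossing of the straight step; endpoint inside powerline or
## road-buffer polygons) enter a conditional logistic regression whose
## likelihood conditions on one used step per stratum.  The same model can
## be fit through the Poisson reformulation with stratum intercepts (their
## variance taken to the large-variance limit, where the stratum terms
## drop out of the profile exactly), and with individual-level Gaussian
## random slopes integrated by a Laplace approximation.  exp(beta) is the
## relative selection strength (RSS).

#' Maximum-likelihood gamma fit to step lengths
#'
#' @param lengths positive step lengths in meters (>= 5 values).
#' @return list with shape, scale (meters), mean, loglik.
#' @export
fit_gamma <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 5L) stop("invalid input: need >= 5 step lengths", call. = FALSE)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("invalid input: step lengths must be positive and finite", call. = FALSE)
  m <- mean(lengths)
  s <- log(m) - mean(log(lengths))
  if (s < 1e-12) stop("degenerate fit: step lengths have (near) zero variance", call. = FALSE)
  shape <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {  # Newton on the profile likelihood in shape
    delta <- (log(shape) - digamma(shape) - s) / (1 / shape - trigamma(shape))
    shape <- shape - delta
    if (abs(delta) < 1e-12 * shape) break
  }
  scale <- m / shape
  structure(list(shape = shape, scale = scale, mean = shape * scale,
                 loglik = sum(stats::dgamma(lengths, shape = shape, scale = scale,
                                            log = TRUE))),
            class = "lc_gamma_fit")
}

#' @export
print.lc_gamma_fit <- function(x, ...) {
  cat(sprintf("<gamma fit: shape %.4g, scale %.4g m, mean %.4g m>\n",
              x$shape, x$scale, x$mean))
  invisible(x)
}

#' Build choice sets (strata) for a trajectory
#'
#' One stratum per realized movement step with a defined turn angle (the
#' first movement step of a trajectory has none and is skipped).  Each
#' stratum holds the used step plus `n_random` random steps from the same
#' start: gamma lengths from `fit`, absolute bearing = previous movement
#' heading + a uniform turn on (-pi, pi].
#'
#' @param traj one animal-year data.frame.
#' @param fit an `lc_gamma_fit` (typically pooled per sex).
#' @param n_random random steps per stratum (default 10).
#' @param seed optional integer seed.
#' @return data.frame: stratum_id, animal_id, sex, year, used,
#'   x0, y0, x1, y1, length.
#' @export
generate_choice_sets <- function(traj, fit, n_random = 10L, seed = NULL) {
  steps <- derive_steps(traj, movement_only = TRUE)
  usable <- which(!is.na(steps$turn_angle))
  if (length(usable) == 0L) {
    warning("trajectory too short for choice sets (needs >= 3 unique locations)",
            call. = FALSE)
    return(data.frame())
  }
  if (!is.null(seed)) set.seed(seed)
  aid <- traj$animal_id[1]; sx <- traj$sex[1]; yr <- traj$year[1]
  out <- vector("list", length(usable))
  for (k in seq_along(usable)) {
    i <- usable[k]
    prev_heading <- steps$heading[i] - steps$turn_angle[i]
    len <- stats::rgamma(n_random, shape = fit$shape, scale = fit$scale)
    turn <- stats::runif(n_random, -pi, pi)
    bearing <- prev_heading + turn
    sid <- sprintf("%s.%s.%03d", aid, yr, i)
    out[[k]] <- data.frame(
      stratum_id = sid, animal_id = aid, sex = sx, year = yr,
      used = c(1L, rep(0L, n_random)),
      x0 = steps$x0[i], y0 = steps$y0[i],
      x1 = c(steps$x1[i], steps$x0[i] + len * cos(bearing)),
      y1 = c(steps$y1[i], steps$y0[i] + len * sin(bearing)),
      length = c(steps$length[i], len),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.ssf_covariates <- c("road_cross", "trail_cross", "end_in_powerline", "end_in_buffer")

#' Annotate choice sets with binary feature covariates
#'
#' road_cross / trail_cross: the straight segment start -> end crosses a
#' road / trail line transversally.  end_in_powerline / end_in_buffer: the
#' end point lies inside the polygon (boundary inclusive).
#'
#' @param sets choice-set data.frame from [generate_choice_sets()].
#' @param landscape an `lc_landscape`.
#' @return `sets` with four 0/1 covariate columns appended.
#' @export
annotate_choice_sets <- function(sets, landscape) {
  if (nrow(sets) == 0L) return(sets)
  segs <- cbind(sets$x0, sets$y0, sets$x1, sets$y1)
  cross_any <- function(layer) {
    hit <- rep(FALSE, nrow(segs))
    for (f in layer) {
      Q <- .path_edges(as_path(f))
      hit <- hit | (rowSums(.seg_cross_matrix(segs, Q)) > 0)
    }
    as.integer(hit)
  }
  ends <- cbind(sets$x1, sets$y1)
  sets$road_cross <- cross_any(landscape$roads)
  sets$trail_cross <- cross_any(landscape$trails)
  sets$end_in_powerline <- as.integer(points_in_polygon(ends, landscape$powerline))
  sets$end_in_buffer <- as.integer(points_in_polygon(ends, landscape$road_buffer))
  sets
}

## ---- conditional logistic likelihood machinery ---------------------------

.clogit_prepare <- function(sets, covariates) {
  X <- as.matrix(sets[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  sid <- as.integer(factor(sets$stratum_id))
  ord <- order(sid)
  X <- X[ord, , drop = FALSE]
  y <- sets$used[ord]
  sid <- sid[ord]
  if (any(tapply(y, sid, sum) != 1L))
    stop("each stratum must contain exactly one used step", call. = FALSE)
  ## identifiability: a covariate must vary within at least one stratum
  for (j in seq_along(covariates)) {
    rng <- tapply(X[, j], sid, function(v) max(v) - min(v))
    if (all(rng == 0))
      stop("non-identifiable: covariate '", covariates[j],
           "' is constant within every stratum", call. = FALSE)
  }
  list(X = X, y = y, sid = sid,
       animal = as.character(sets$animal_id[ord]))
}

## loglik, gradient, Hessian of the stratum-conditional (softmax) likelihood
.clogit_llk <- function(beta, X, y, sid) {
  eta <- drop(X %*% beta)
  eta <- eta - ave(eta, sid, FUN = max)          # stabilize
  w <- exp(eta)
  denom <- ave(w, sid, FUN = sum)
  p <- w / denom
  ll <- sum(eta[y == 1]) - sum(log(tapply(w, sid, sum)))
  mu <- rowsum(p * X, sid)                        # E[x | stratum]
  grad <- colSums(X[y == 1, , drop = FALSE]) - colSums(mu)
  list(ll = ll, grad = grad, p = p)
}

.clogit_hessian <- function(beta, X, y, sid) {
  eta <- drop(X %*% beta)
  eta <- eta - ave(eta, sid, FUN = max)
  w <- exp(eta)
  p <- w / ave(w, sid, FUN = sum)
  mu <- rowsum(p * X, sid)
  -(crossprod(X, p * X) - crossprod(mu))
}

.clogit_newton <- function(X, y, sid, beta0 = NULL, max_iter = 60L, tol = 1e-10,
                           cap = 15) {
  p <- ncol(X)
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  diverged <- FALSE
  for (it in seq_len(max_iter)) {
    lk <- .clogit_llk(beta, X, y, sid)
    H <- .clogit_hessian(beta, X, y, sid)
    step <- tryCatch(solve(H - diag(1e-10, p), lk$grad),
                     error = function(e) lk$grad / max(abs(diag(H)), 1))
    cand <- beta - step
    ## step halving on the likelihood
    for (h in 1:30) {
      if (.clogit_llk(cand, X, y, sid)$ll >= lk$ll - 1e-12) break
      cand <- (beta + cand) / 2
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    if (any(abs(beta) > cap)) {
      diverged <- TRUE
      beta <- pmin(pmax(beta, -cap), cap)
      break
    }
    if (delta < tol) break
  }
  if (diverged)
    warning("possible separation: estimate capped at |beta| = ", cap, call. = FALSE)
  H <- .clogit_hessian(beta, X, y, sid)
  vcov <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, vcov = vcov, loglik = .clogit_llk(beta, X, y, sid)$ll,
       diverged = diverged)
}

## Laplace-approximate marginal likelihood with per-animal Gaussian random
## slopes (diagonal covariance).  Conditioning on the used-step-per-stratum
## totals removes the stratum intercepts exactly, so this is the
## large-variance limit of the Poisson reformulation.
.clogit_laplace_nll <- function(theta, X, y, sid, animal, n_cov) {
  p <- n_cov
  beta <- theta[seq_len(p)]
  log_sd <- theta[p + seq_len(p)]
  sd <- exp(log_sd)
  nll <- 0
  for (a in unique(animal)) {
    idx <- animal == a
    Xa <- X[idx, , drop = FALSE]; ya <- y[idx]; sa <- sid[idx]
    obj <- function(b) {
      -.clogit_llk(beta + b, Xa, ya, sa)$ll + sum(b^2 / (2 * sd^2))
    }
    gr <- function(b) {
      -.clogit_llk(beta + b, Xa, ya, sa)$grad + b / sd^2
    }
    opt <- stats::optim(rep(0, p), obj, gr, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10))
    bh <- opt$par
    H <- -.clogit_hessian(beta + bh, Xa, ya, sa) + diag(1 / sd^2, p)
    ld <- determinant(H, logarithm = TRUE)$modulus
    ## the (2*pi)^(p/2) of the Laplace integral cancels the prior's
    nll <- nll + opt$value + 0.5 * as.numeric(ld) + sum(log_sd)
  }
  nll
}

#' Fit the step-selection conditional logistic regression
#'
#' With `random_effects = FALSE`, maximizes the exact stratum-conditional
#' likelihood by Newton iteration.  With `random_effects = TRUE`, adds
#' individual-level Gaussian random slopes (diagonal covariance) for every
#' covariate, integrated out by a Laplace approximation; the stratum
#' intercepts of the equivalent Poisson reformulation are removed exactly
#' by the conditioning.  Confidence intervals are Wald, on the link scale.
#'
#' @param sets annotated choice-set data.frame (see
#'   [annotate_choice_sets()]).
#' @param random_effects logical.
#' @param covariates covariate column names (default the four binary
#'   feature covariates).
#' @return object of class `lc_ssf_fit`: `$coefficients` data.frame (term,
#'   estimate, se, lwr, upr, rss, rss_lwr, rss_upr), `$vcov`, `$loglik`,
#'   `$ranef_sd` (RE mode only).
#' @export
fit_conditional_logistic <- function(sets, random_effects = FALSE,
                                     covariates = .ssf_covariates) {
  dat <- .clogit_prepare(sets, covariates)
  p <- length(covariates)
  fe <- .clogit_newton(dat$X, dat$y, dat$sid)
  ranef_sd <- NULL
  if (random_effects) {
    theta0 <- c(fe$beta, rep(log(0.1), p))
    opt <- stats::optim(theta0, .clogit_laplace_nll, method = "Nelder-Mead",
                        X = dat$X, y = dat$y, sid = dat$sid,
                        animal = dat$animal, n_cov = p,
                        control = list(maxit = 2000, reltol = 1e-8))
    beta <- opt$par[seq_len(p)]
    ranef_sd <- exp(opt$par[p + seq_len(p)])
    names(ranef_sd) <- covariates
    hfun <- function(b) .clogit_laplace_nll(c(b, opt$par[p + seq_len(p)]),
                                            dat$X, dat$y, dat$sid, dat$animal, p)

    H <- stats::optimHess(beta, hfun)
    vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
    loglik <- -opt$value
  } else {
    beta <- fe$beta
    vcov <- fe$vcov
    loglik <- fe$loglik
  }
  se <- sqrt(pmax(diag(vcov), 0))
  lwr <- beta - 1.96 * se
  upr <- beta + 1.96 * se
  coefs <- data.frame(term = covariates, estimate = beta, se = se,
                      lwr = lwr, upr = upr,
                      rss = exp(beta), rss_lwr = exp(lwr), rss_upr = exp(upr),
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, vcov = vcov, loglik = loglik,
                 ranef_sd = ranef_sd, random_effects = random_effects,
                 n_strata = length(unique(dat$sid))),
            class = "lc_ssf_fit")
}

#' @export
print.lc_ssf_fit <- function(x, ...) {
  cat(sprintf("Step-selection fit (%s, %d strata)\n",
              if (x$random_effects) "individual random slopes" else "fixed effects",
              x$n_strata))
  print(x$coefficients, row.names = FALSE, digits = 3)
  if (!is.null(x$ranef_sd)) {
    cat("random-slope SDs:\n")
    print(round(x$ranef_sd, 3))
  }
  invisible(x)
}

#' Conditional logistic regression via the Poisson reformulation
#'
#' Poisson GLM of the used indicator on the covariates plus one fixed
#' intercept per stratum: the exact limit of a stratum random intercept
#' with its variance fixed very large, and identical in its covariate
#' estimates to the conditional likelihood maximizer.
#'
#' @inheritParams fit_conditional_logistic
#' @return named coefficient vector for `covariates`.
#' @export
fit_clogit_poisson <- function(sets, covariates = .ssf_covariates) {
  dat <- .clogit_prepare(sets, covariates)
  df <- as.data.frame(dat$X)
  names(df) <- covariates
  df$.y <- dat$y
  df$.stratum <- factor(dat$sid)
  fml <- stats::as.formula(paste(".y ~", paste(covariates, collapse = " + "),
                                 "+ .stratum - 1"))
  fit <- stats::glm(fml, family = stats::poisson(), data = df)
  stats::coef(fit)[covariates]
}

#' Relative selection strength
#'
#' The multiplicative odds of choosing a step with a binary covariate over
#' an otherwise identical step without it.
#'
#' @param beta coefficient(s) on the link scale.
#' @return exp(beta).
#' @export
rss <- function(beta) exp(beta)

#' @rdname rss
#' @export
log_rss <- function(beta) beta

#' Selection-strength table for a fitted SSF
#'
#' One row per covariate with the coefficient, its 95% CI, and the same on
#' the RSS (odds) scale -- the layout of a published selection table.
#'
#' @param fit an `lc_ssf_fit`.
#' @export
rss_table <- function(fit) {
  stopifnot(inherits(fit, "lc_ssf_fit"))
  fit$coefficients
}

#' Forest plot of log-RSS estimates
#' @param fit an `lc_ssf_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_log_rss <- function(fit, ...) {
  co <- fit$coefficients
  k <- nrow(co)
  graphics::plot(co$estimate, seq_len(k), xlim = range(co$lwr, co$upr, 0),
                 ylim = c(0.5, k + 0.5), yaxt = "n", pch = 16,
                 xlab = "log RSS", ylab = "", ...)
  graphics::axis(2, at = seq_len(k), labels = co$term, las = 1, cex.axis = 0.8)
  graphics::segments(co$lwr, seq_len(k), co$upr, seq_len(k), lwd = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(fit)
}
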