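# Profile-likelihood identifiability and the least-squares baseline.
#
# Everything here is integration-based (trajectories solved from the ODEs
# at candidate rates), not surrogate-based, so confidence intervals are
# independent of the neural fit that produced the point estimates.

# Residual vector over all retained observations of a dataset.  A failed
# integration (blow-up under unphysical rates) yields a large flat penalty;
# once one experiment fails the rest are skipped, since the optimizer only
# needs to know this parameter set is inadmissible.
.ode_residuals <- function(model, params, dataset) {
  out <- vector("list", length(dataset$experiments))
  failed <- FALSE
  for (i in seq_along(dataset$experiments)) {
    e <- dataset$experiments[[i]]
    al <- .align_dataset_one(dataset, model, e)
    n_i <- sum(al$M == 1)
    if (failed) { out[[i]] <- rep(1e6, n_i); next }
    traj <- tryCatch(
      suppressWarnings(rom_integrate(
        model, params, .initial_state(model, e$y0, dataset$normalization),
        e$times, rtol = 1e-7, atol = 1e-9, maxsteps = 500)),
      error = function(err) NULL)
    if (is.null(traj)) {
      failed <- TRUE
      out[[i]] <- rep(1e6, n_i)
    } else {
      out[[i]] <- (traj$states - al$Y)[al$M == 1]
    }
  }
  unlist(out, use.names = FALSE)
}

# single-experiment version of the dataset/model bin alignment
.align_dataset_one <- function(ds, model, e) {
  nsp <- model$n_species
  n_t <- length(e$times)
  Y <- matrix(0, n_t, nsp); M <- matrix(0, n_t, nsp)
  if (identical(ds$species, model$species$name)) {
    keep <- !is.na(e$observed)
    Y[keep] <- e$observed[keep]; M[keep] <- 1
  } else {
    v <- e$observed[, length(ds$species)]
    keep <- !is.na(v)
    Y[keep, nsp] <- v[keep]; M[keep, nsp] <- 1
  }
  list(Y = Y, M = M)
}

#' Gaussian negative log-likelihood of a parameter set
#'
#' i.i.d. Gaussian observation model on the retained observations, with
#' trajectories obtained by integrating the ODEs at `params`.  With known
#' `sigma` the NLL is \eqn{n \log\sigma + SSE/(2\sigma^2)} (additive
#' constants dropped); with `sigma = NULL` the noise scale is profiled out
#' analytically, giving the concentrated form \eqn{(n/2) \log(SSE/n)}.
#'
#' @param model a `rom_model`.
#' @param params named rate vector.
#' @param dataset a `rom_dataset`.
#' @param sigma observation noise sd, or `NULL` to profile it out.
#' @return scalar NLL (up to an additive constant).
#' @export
negative_log_likelihood <- function(model, params, dataset, sigma = NULL) {
  r <- .ode_residuals(model, .check_params(model, params), dataset)
  sse <- sum(r^2)
  n <- length(r)
  if (is.null(sigma)) return(n / 2 * log(max(sse, 1e-300) / n))
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  n * log(sigma) + sse / (2 * sigma^2)
}

#' Levenberg-Marquardt least-squares fit
#'
#' Estimates the rate constants by damped least squares
#' (\code{\link[minpack.lm]{nls.lm}}) on the residuals between integrated
#' trajectories and observations -- the classical baseline against which
#' the physics-informed fit is compared.
#'
#' @param model a `rom_model`.
#' @param dataset a `rom_dataset`.
#' @param init optional named starting rates; defaults to a uniform draw in
#'   `param_init` under `seed`.
#' @param seed seed for the default start.
#' @param param_init range of the default uniform start.
#' @param max_iter iteration cap.
#' @return list with `params`, `sse`, `mae`, `converged`, `predictions`
#'   (per experiment on the data grid) and the `nls.lm` info code.
#' @export
fit_least_squares <- function(model, dataset, init = NULL, seed = 1,
                              param_init = c(0.01, 0.5), max_iter = 100) {
  stopifnot(inherits(model, "rom_model"), inherits(dataset, "rom_dataset"))
  if (is.null(init)) {
    set.seed(seed)
    init <- stats::runif(model$n_params, param_init[1], param_init[2])
  }
  init <- unname(.check_params(model, init))
  if (!all(is.finite(init))) stop("non-finite initial rates", call. = FALSE)
  fn <- function(p) .ode_residuals(model, stats::setNames(p, model$param_names),
                                   dataset)
  res <- minpack.lm::nls.lm(par = init, fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ptol = 1e-12, ftol = 1e-12))
  params <- stats::setNames(as.numeric(res$par), model$param_names)
  r <- fn(res$par)
  predictions <- lapply(dataset$experiments, function(e) {
    y0 <- .initial_state(model, e$y0, dataset$normalization)
    traj <- tryCatch(
      suppressWarnings(rom_integrate(model, params, y0, e$times)),
      error = function(err) NULL)
    st <- if (is.null(traj))
      matrix(NA_real_, length(e$times), model$n_species)
    else traj$states
    colnames(st) <- model$species$name
    st
  })
  list(params = params, sse = sum(r^2), mae = mean(abs(r)),
       converged = res$info %in% 1:4 &&
         !anyNA(predictions[[1]][1, 1]), info = res$info,
       niter = res$niter, predictions = predictions)
}

#' Profile likelihood of one rate parameter
#'
#' Steps the parameter of interest over a grid, re-optimizing all other
#' rates at every grid value (warm-started from the neighboring solution,
#' with a restart from the global optimum kept if better), and records the
#' profile of the negative log-likelihood.  The 95% confidence interval is
#' the region where the profile stays within \eqn{\chi^2_1(0.95)/2 = 1.92}
#' of its minimum.
#'
#' @param model a `rom_model`.
#' @param dataset a `rom_dataset`.
#' @param fit a `rom_fit` (or a named rate vector) giving the point
#'   estimate the profile is centered on.
#' @param parameter name of the rate to profile (e.g. `"a1"`).
#' @param grid optional explicit grid; must bracket the point estimate.
#'   Default: 21 points, log-spaced over `[mle/10, mle*10]` for positive
#'   estimates, linear symmetric otherwise.
#' @param n_grid grid size for the default grid.
#' @param span default grid half-range factor (decades for positive MLEs).
#' @param sigma observation sd, or `NULL` to profile it out.
#' @param level confidence level for the reported interval.
#' @param refine adaptively bisect the threshold-crossing brackets (adding
#'   the evaluated points to the stored grid) so the linearly interpolated
#'   interval endpoints are accurate; default TRUE.
#' @return an object of class `rom_profile`.
#' @export
profile_likelihood <- function(model, dataset, fit, parameter, grid = NULL,
                               n_grid = 21, span = 10, sigma = NULL,
                               level = 0.95, refine = TRUE) {
  stopifnot(inherits(model, "rom_model"))
  mle <- if (inherits(fit, "rom_fit")) coef(fit) else .check_params(model, fit)
  if (!parameter %in% model$param_names)
    stop("parameter '", parameter, "' is not a rate of model ",
         model$model_id, call. = FALSE)
  theta_hat <- unname(mle[[parameter]])
  if (!is.null(grid) && (min(grid) > theta_hat || max(grid) < theta_hat))
    stop("grid does not bracket the point estimate ", signif(theta_hat, 4),
         call. = FALSE)
  if (is.null(grid)) {
    grid <- if (theta_hat > 0)
      exp(seq(log(theta_hat / span), log(theta_hat * span),
              length.out = n_grid))
    else
      seq(theta_hat - span * max(abs(theta_hat), 0.05),
          theta_hat + span * max(abs(theta_hat), 0.05), length.out = n_grid)
  }
  grid <- sort(unique(c(grid, theta_hat)))
  free <- setdiff(model$param_names, parameter)
  nll_at <- function(theta, start) {
    # re-optimize the free rates at fixed parameter value
    fn <- function(p) {
      full <- stats::setNames(numeric(model$n_params), model$param_names)
      full[free] <- p; full[parameter] <- theta
      .ode_residuals(model, full, dataset)
    }
    sol <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = fn,
                         control = minpack.lm::nls.lm.control(maxiter = 60)),
      error = function(e) NULL)
    if (is.null(sol)) return(list(nll = NA_real_, par = start))
    r <- fn(sol$par)
    sse <- sum(r^2); n <- length(r)
    nll <- if (is.null(sigma)) n / 2 * log(max(sse, 1e-300) / n)
           else n * log(sigma) + sse / (2 * sigma^2)
    list(nll = nll, par = as.numeric(sol$par))
  }
  idx_hat <- which(grid == theta_hat)
  prof <- rep(NA_real_, length(grid))
  pars <- vector("list", length(grid))
  start0 <- unname(mle[free])
  at_hat <- nll_at(theta_hat, start0)
  prof[idx_hat] <- at_hat$nll
  pars[[idx_hat]] <- at_hat$par
  # walk outward in both directions, warm-starting from the neighbor
  for (dir in c(1L, -1L)) {
    start <- at_hat$par
    ii <- idx_hat + dir
    while (ii >= 1L && ii <= length(grid)) {
      res <- nll_at(grid[ii], start)
      alt <- nll_at(grid[ii], start0)  # restart from the MLE values
      if (!is.na(alt$nll) && (is.na(res$nll) || alt$nll < res$nll)) res <- alt
      prof[ii] <- res$nll
      pars[[ii]] <- res$par
      if (length(res$par)) start <- res$par
      ii <- ii + dir
    }
  }
  if (refine) {
    # Bisect each threshold-crossing bracket and fold the evaluated points
    # back into the grid: on a coarse grid, linear interpolation between
    # the optimum and a far-off point collapses the interval toward the
    # estimate, so the crossing needs a locally dense grid.
    thr <- min(prof, na.rm = TRUE) + stats::qchisq(level, 1) / 2
    for (iter in seq_len(24)) {
      ok <- !is.na(prof)
      gg <- grid[ok]; pp <- prof[ok]
      imin <- which.min(pp)
      cand <- NULL
      for (dir in c(1L, -1L)) {
        ii <- imin + dir
        while (ii >= 1L && ii <= length(gg)) {
          if (pp[ii] > thr) {
            inner <- ii - dir
            wide <- abs(pp[ii] - pp[inner]) > 0.5 &&
              abs(gg[ii] - gg[inner]) >
                1e-4 * max(abs(theta_hat), 1e-8)
            if (wide) cand <- c(cand, (gg[ii] + gg[inner]) / 2)
            break
          }
          ii <- ii + dir
        }
      }
      if (is.null(cand)) break
      for (x in cand) {
        near <- which.min(abs(grid - x))
        res <- nll_at(x, if (length(pars[[near]])) pars[[near]] else start0)
        pos <- findInterval(x, grid)
        grid <- append(grid, x, after = pos)
        prof <- append(prof, res$nll, after = pos)
        pars <- append(pars, list(res$par), after = pos)
      }
    }
  }
  pr <- structure(list(parameter_name = parameter, grid = grid,
                       profile_nll = prof, mle_value = theta_hat,
                       nll_min = min(prof, na.rm = TRUE),
                       level = level, sigma = sigma,
                       model_id = model$model_id),
                  class = "rom_profile")
  ci <- confidence_interval(pr, level)
  pr$ci_95 <- ci
  pr$identifiable <- attr(ci, "identifiable")
  pr
}

#' Confidence interval from a likelihood profile
#'
#' Finds where the profile NLL crosses `min + qchisq(level, 1)/2` by linear
#' interpolation between grid points.  A side with no crossing inside the
#' grid is reported as unbounded (`-Inf`/`Inf`) and the parameter flagged
#' non-identifiable.  Identifiability additionally requires the closed
#' interval to span fewer than two decades (for positive intervals).
#'
#' @param profile a `rom_profile`, or any list with `grid` and
#'   `profile_nll`.
#' @param level confidence level in (0, 1).
#' @return numeric `(lo, hi)` with attribute `"identifiable"`.
#' @export
confidence_interval <- function(profile, level = 0.95) {
  stopifnot(level > 0, level < 1)
  g <- profile$grid
  nll <- profile$profile_nll
  ok <- !is.na(nll)
  g <- g[ok]; nll <- nll[ok]
  thr <- min(nll) + stats::qchisq(level, 1) / 2
  imin <- which.min(nll)
  cross <- function(idx_seq) {
    # first crossing of thr walking away from the minimum
    prev_i <- imin
    for (i in idx_seq) {
      if (nll[i] > thr) {
        x0 <- g[prev_i]; x1 <- g[i]
        y0 <- nll[prev_i]; y1 <- nll[i]
        return(x0 + (thr - y0) / (y1 - y0) * (x1 - x0))
      }
      prev_i <- i
    }
    NA_real_
  }
  lo <- if (imin > 1) cross(seq(imin - 1, 1)) else NA_real_
  hi <- if (imin < length(g)) cross(seq(imin + 1, length(g))) else NA_real_
  lo <- if (is.na(lo)) -Inf else lo
  hi <- if (is.na(hi)) Inf else hi
  identifiable <- is.finite(lo) && is.finite(hi)
  if (identifiable && lo > 0 && hi / lo >= 100) identifiable <- FALSE
  structure(c(lo = lo, hi = hi), identifiable = identifiable)
}

#' @export
confint.rom_profile <- function(object, parm, level = 0.95, ...) {
  ci <- confidence_interval(object, level)
  m <- matrix(as.numeric(ci), 1, 2,
              dimnames = list(object$parameter_name,
                              paste0(100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2), " %")))
  m
}

#' @export
print.rom_profile <- function(x, ...) {
  cat("Profile likelihood for ", x$parameter_name, " (model ", x$model_id,
      ")\n", sep = "")
  cat("  point estimate: ", signif(x$mle_value, 5), "\n", sep = "")
  cat("  ", round(100 * x$level), "% CI: [", signif(x$ci_95[[1]], 5), ", ",
      signif(x$ci_95[[2]], 5), "]  identifiable: ", x$identifiable,
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.rom_profile <- function(x, ...) {
  plot(x$grid, x$profile_nll - x$nll_min, type = "b", pch = 16,
       log = if (all(x$grid > 0)) "x" else "",
       xlab = x$parameter_name, ylab = "profile NLL - min",
       main = paste0("profile likelihood, model ", x$model_id))
  graphics::abline(h = stats::qchisq(x$level, 1) / 2, lty = 2)
  graphics::abline(v = x$mle_value, col = 2)
  if (is.finite(x$ci_95[[1]])) graphics::abline(v = x$ci_95[[1]], lty = 3)
  if (is.finite(x$ci_95[[2]])) graphics::abline(v = x$ci_95[[2]], lty = 3)
  invisible(x)
}

#' @export
profile.rom_fit <- function(fitted, which = NULL, ...) {
  model <- fitted$model
  if (is.null(which)) which <- model$param_names
  out <- lapply(which, function(p)
    profile_likelihood(model, fitted$dataset, fitted, p, ...))
  names(out) <- which
  if (length(out) == 1L) out[[1]] else out
}
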